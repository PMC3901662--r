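# Programmatic fixtures: toy receptors, ligands, planted-optimum complexes
# and synthetic random-forest training data.  Everything is generated in
# code, deterministically under a seed, so the whole pipeline is testable
# without any external dataset.  Funnel complexes certify their own ground
# truth at build time by an exhaustive coarse scan of the engine's own
# scoring function.

#' Fixture specification
#'
#' @param seed Integer seed.
#' @param ligand_n_heavy Heavy atoms in the ligand chain (>= 3).
#' @param ligand_n_torsions Rotatable bonds of the chain (each moves heavy
#'   atoms, so all stay active).
#' @param pocket_radius Distance from ligand atoms to the pocket wall,
#'   Angstrom.
#' @param noise Gaussian jitter applied to pocket atom positions, Angstrom.
#' @return Named list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, ligand_n_heavy = 5L,
                         ligand_n_torsions = 0L, pocket_radius = 3.8,
                         noise = 0) {
  stopifnot(ligand_n_heavy >= 3, ligand_n_torsions >= 0, pocket_radius > 0,
            noise >= 0,
            ligand_n_heavy >= ligand_n_torsions + 3)
  structure(list(seed = as.integer(seed),
                 ligand_n_heavy = as.integer(ligand_n_heavy),
                 ligand_n_torsions = as.integer(ligand_n_torsions),
                 pocket_radius = pocket_radius, noise = noise),
            class = "fixture_spec")
}

# zig-zag carbon chain, bond length 1.54, tetrahedral-ish bond angle
chain_coords <- function(n) {
  b <- 1.54
  theta <- (180 - 109.5) / 2 * pi / 180
  x <- cumsum(c(0, rep(b * cos(theta), n - 1)))
  y <- b * sin(theta) * (seq_len(n) %% 2)
  cbind(x = x, y = y, z = rep(0, n))
}

format_fixture_atom <- function(serial, name, x, y, z, ad_type,
                                record = "ATOM", res = "LIG") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          record, serial, substr(name, 1, 4), res, "A", 1L,
          x, y, z, 1.00, 0.00, 0.000, ad_type)
}

# ligand PDBQT text: chain split into ROOT + nested BRANCH frames.  The
# first atom is an oxygen acceptor (the rest carbons), so the chain has
# distinct ends and hydrogen-bond anchors in the pocket wall can pin both the
# registration and the handedness of the bound pose
ligand_chain_pdbqt <- function(coords, n_torsions) {
  n <- nrow(coords)
  atom_line <- function(i) {
    ad <- if (i == 1L) "OA" else "C"
    nm <- if (ad == "OA") sprintf("O%d", i) else sprintf("C%d", i)
    format_fixture_atom(i, nm, coords[i, 1], coords[i, 2], coords[i, 3], ad)
  }
  # last frame keeps 2 atoms so every torsion moves a non-axis heavy atom
  n_root <- if (n_torsions == 0L) n else n - n_torsions - 1L
  lines <- c("ROOT", vapply(seq_len(n_root), atom_line, character(1)),
             "ENDROOT")
  at <- n_root
  for (t in seq_len(n_torsions)) {
    lines <- c(lines, sprintf("BRANCH %3d %3d", at, at + 1L))
    n_in_frame <- if (t == n_torsions) n - at else 1L
    for (j in seq_len(n_in_frame)) {
      at <- at + 1L
      lines <- c(lines, atom_line(at))
    }
  }
  for (t in seq_len(n_torsions)) {
    lines <- c(lines, "ENDBRANCH")
  }
  # rewrite ENDBRANCH with serials, innermost first
  ends <- which(lines == "ENDBRANCH")
  starts <- grep("^BRANCH", lines)
  for (k in seq_along(ends)) {
    src <- lines[starts[length(starts) - k + 1L]]
    lines[ends[k]] <- sub("^BRANCH", "ENDBRANCH", src)
  }
  paste0(paste(c(lines, sprintf("TORSDOF %d", n_torsions)), collapse = "\n"),
         "\n")
}

# pocket wall: a groove (cradle) open toward +y so the binding funnel is
# reachable by rigid-body descent -- carbon probes below and beside each
# ligand atom, end caps, and two metal hydrogen-bond donors on the open side
# anchoring the terminal oxygen (they pin the registration along the groove
# and break its flip symmetry)
pocket_coords <- function(lig, radius, noise) {
  pts <- list()
  types <- character(0)
  add <- function(p, t = "C") {
    pts[[length(pts) + 1L]] <<- p
    types[length(types) + 1L] <<- t
  }
  # near-full rings (every 45 degrees except straight up) in the y-z plane,
  # centred on the chain midline so the zig-zag offset stays clash-free; the
  # missing +y direction leaves an entrance corridor above the slot
  midline_y <- mean(range(lig[, 2]))
  ring_r <- radius + 0.2
  phis <- setdiff(seq(0, 315, by = 45), 90) * pi / 180
  for (i in seq_len(nrow(lig))) {
    for (phi in phis) {
      add(c(lig[i, 1], midline_y + ring_r * cos(phi), ring_r * sin(phi)))
    }
  }
  cap_dirs <- rbind(c(1, 0, 0), c(0.7071, -0.7071, 0),
                    c(0.7071, 0, 0.7071), c(0.7071, 0, -0.7071))
  for (k in seq_len(nrow(cap_dirs))) {
    add(lig[1, ] - radius * cap_dirs[k, ])
    add(lig[nrow(lig), ] + radius * cap_dirs[k, ])
  }
  # metal donors 2.5 A from the terminal oxygen on the open (+y) side:
  # surface distance 2.5 - (1.2 + 1.7) = -0.4, near the optimum of the
  # hbond ramp against repulsion; two anchors pin every half-turn decoy
  add(lig[1, ] + c(0, 2.5, 0), "Zn")
  add(lig[1, ] + 2.5 * c(0, 0.7071, 0.7071), "Zn")
  # sparse attractors high above the groove mouth: their long-range gaussian
  # tails widen the funnel's capture basin without creating competitive
  # minima of their own
  for (i in seq(2L, nrow(lig), by = 2L)) {
    add(lig[i, ] + c(0, 6.5, 0))
  }
  m <- do.call(rbind, pts)
  keep <- !duplicated(round(m, 4))
  m <- m[keep, , drop = FALSE]
  types <- types[keep]
  if (noise > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise), nrow(m))
  list(coords = m, types = types)
}

receptor_pdbqt_from_coords <- function(coords, ad_types) {
  if (length(ad_types) == 1) ad_types <- rep(ad_types, nrow(coords))
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    nm <- if (ad_types[i] == "C") sprintf("C%d", i %% 100)
          else toupper(ad_types[i])
    format_fixture_atom(i, nm, coords[i, 1], coords[i, 2], coords[i, 3],
                        ad_types[i], res = "REC")
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Build a planted-optimum funnel complex
#'
#' Generates a carbon-chain ligand and a snug hydrophobic pocket around its
#' input geometry, so the input pose is the energy funnel's bottom: moving
#' the ligand loses wall contacts (attractive gaussian terms) or drives into
#' the walls (quadratic repulsion).  The construction is certified at build
#' time: an exhaustive translation scan of the engine's own scoring function
#' on a coarse lattice (plus random rigid perturbations) must find no pose
#' scoring below the planted one, otherwise the builder retries with a fresh
#' jitter (bounded retries) and finally fails.
#'
#' @param spec A [fixture_spec()].
#' @param certify Run the exhaustive-scan certification (default TRUE).
#' @param scan_step Scan lattice step, Angstrom.
#' @param max_retries Rebuild attempts if certification fails.
#' @return List with `receptor_pdbqt`, `ligand_pdbqt` (text), `receptor`,
#'   `template` (parsed), `planted_coords` (heavy atoms), `planted_conf`,
#'   `box` (a `search_box` around the pocket), and `certified`.
#' @export
make_funnel_complex <- function(spec = fixture_spec(), certify = TRUE,
                                scan_step = 1.0, max_retries = 5L) {
  set.seed(spec$seed)
  lig <- chain_coords(spec$ligand_n_heavy)
  lig_text <- ligand_chain_pdbqt(lig, spec$ligand_n_torsions)
  template <- parse_ligand(lig_text)
  table <- precalculate_table(n_samples = 2048L)

  for (attempt in seq_len(max_retries)) {
    pocket <- pocket_coords(lig, spec$pocket_radius, spec$noise)
    rec_text <- receptor_pdbqt_from_coords(pocket$coords, pocket$types)
    receptor <- parse_receptor(rec_text)
    box <- auto_search_box(lig, margin = 8, granularity = 0.15625)
    planted_conf <- identity_conformation(template)
    heavy <- which(!template$atoms$is_hydrogen)
    planted_coords <- realize(template, planted_conf)[heavy, , drop = FALSE]
    ok <- !certify ||
      certify_funnel(receptor, template, box, table, planted_conf, scan_step)
    if (ok) {
      return(list(receptor_pdbqt = rec_text, ligand_pdbqt = lig_text,
                  receptor = receptor, template = template,
                  planted_coords = planted_coords,
                  planted_conf = planted_conf, box = box,
                  certified = certify, spec = spec))
    }
  }
  stop("funnel certification failed after retries", call. = FALSE)
}

# exhaustive coarse scan: translations of the input geometry on a lattice,
# systematic half-turn/shift decoys, plus random rigid perturbations; TRUE
# iff every pose scoring below the planted one lies in the planted basin
# (within 1 A heavy-atom RMSD), i.e. the funnel bottom is where it was built
certify_funnel <- function(receptor, template, box, table, planted_conf,
                           scan_step) {
  heavy <- which(!template$atoms$is_hydrogen)
  htypes <- template$atoms$type[heavy]
  planted_hc <- realize(template, planted_conf)[heavy, , drop = FALSE]
  score_of <- function(conf) {
    coords <- realize(template, conf)
    direct_inter(receptor, coords[heavy, , drop = FALSE], htypes, table) +
      intra_score(template, coords, table)
  }
  beats_plant <- function(conf) {
    if (score_of(conf) >= planted - 1e-9) return(FALSE)
    hc <- realize(template, conf)[heavy, , drop = FALSE]
    rmsd(hc, planted_hc) >= 1.0
  }
  planted <- score_of(planted_conf)
  offs <- seq(-box$size / 2, box$size / 2, by = scan_step)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    if (ox == 0 && oy == 0 && oz == 0) next
    conf <- planted_conf
    conf$position <- conf$position + c(ox, oy, oz)
    if (beats_plant(conf)) return(FALSE)
  }
  # half-turns about each axis combined with axial shifts: the decoy family
  # a tubular pocket is most prone to
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    for (shift in seq(-3, 3, by = 0.25)) {
      conf <- planted_conf
      conf$orientation <- quat_normalize(
        quat_multiply(quat_from_axis_angle(axis, pi), conf$orientation))
      conf$position <- conf$position + shift * c(1, 0, 0)
      if (beats_plant(conf)) return(FALSE)
    }
  }
  for (k in seq_len(50)) {
    conf <- planted_conf
    conf$position <- conf$position + stats::rnorm(3, 0, 2)
    conf$orientation <- quat_normalize(
      quat_multiply(quat_from_axis_angle(stats::rnorm(3), stats::runif(1, 0, pi)),
                    conf$orientation))
    if (length(conf$torsions)) {
      conf$torsions <- stats::runif(length(conf$torsions), -pi, pi)
    }
    if (beats_plant(conf)) return(FALSE)
  }
  TRUE
}

#' Synthetic training data for the rescoring forest
#'
#' Emulates the statistical structure the rescoring model assumes:
#' non-negative Poisson contact counts for the 36 element-pair features,
#' with affinity a sparse linear function of a few counts plus one mild
#' pairwise interaction and Gaussian noise, shifted into a pKd-like range.
#' The generating coefficients are returned for recovery tests.
#'
#' @param n Number of complexes.
#' @param sigma Noise standard deviation, pKd units.
#' @param seed Integer seed.
#' @return List with `features` (n x 36 count matrix), `pkd`, and `truth`
#'   (list of the generating coefficients).
#' @export
make_rf_training_set <- function(n = 500L, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  p <- 36L
  # fixed contact rates and coefficients: the ground-truth function is the
  # same for every seed, so independently seeded draws share one regression
  # surface; the seed drives only the Poisson counts and the noise
  lambda <- 3 + 4 * ((seq_len(p) - 1) %% 9) / 8   # 3..7 mean contacts
  X <- matrix(stats::rpois(n * p, rep(lambda, each = n)), n, p)
  colnames(X) <- rf_feature_names()
  beta <- numeric(p)
  signal_idx <- c(1L, 10L, 19L, 28L)
  beta[signal_idx] <- c(0.80, -0.70, 0.60, 0.50)
  inter <- 0.03 * X[, 1] * X[, 10]
  y <- 4 + as.numeric(X %*% beta) + inter + stats::rnorm(n, 0, sigma)
  list(features = X, pkd = y,
       truth = list(beta = beta, interaction = c(1L, 10L, 0.03),
                    intercept = 4, sigma = sigma, lambda = lambda))
}
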