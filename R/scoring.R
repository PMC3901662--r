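# The conformation-dependent empirical scoring function and its
# precalculated pair-potential table.
#
# A pose is scored as a weighted sum of five terms over all atom pairs that
# can move relative to each other, as a function of the surface distance
# d = r - (R_a + R_b) (interatomic distance minus the van der Waals radii),
# with the interatomic distance cut off at 8 Angstrom:
#
#   gauss1      exp(-(d / 0.5)^2)              steric, short range
#   gauss2      exp(-((d - 3) / 2)^2)          steric, long range
#   repulsion   d^2 for d < 0, else 0          steric clash
#   hydrophobic ramp 1 -> 0 over d in [0.5, 1.5]   (hydrophobic pairs only)
#   hbond       ramp 1 -> 0 over d in [-0.7, 0]    (donor-acceptor pairs only)
#
# The score splits into inter-molecular (receptor-ligand) and intra-molecular
# (movable ligand pairs, 1-4 exclusions removed) contributions.  To make
# evaluation O(1) per pair the weighted curve for each of the 120 unordered
# type pairs is sampled at 16,384 uniformly spaced distances in [0, 8] and
# served by nearest-sample lookup (no interpolation).

#' Surface distance between two typed atoms
#'
#' @param r Interatomic distance(s), Angstrom; `r >= 0`.
#' @param type_a,type_b Heavy-atom type codes (see [atom_type_table()]).
#' @return `r - (R_a + R_b)`; negative values mean overlapping vdW surfaces.
#' @export
surface_distance <- function(r, type_a, type_b) {
  r - (vdw_radius_of(type_a) + vdw_radius_of(type_b))
}

#' Unweighted values of the five scoring terms
#'
#' Evaluates all five terms at surface distance `d`.  Masking by atom-type
#' flags (hydrophobic term only for hydrophobic-hydrophobic pairs, hydrogen
#' bond only for donor-acceptor pairs) is the caller's responsibility.
#'
#' @param d Surface distance(s), Angstrom.
#' @return For scalar `d` a named 5-vector; for vector `d` a matrix with one
#'   row per element and columns gauss1, gauss2, repulsion, hydrophobic,
#'   hbond.
#' @export
term_values <- function(d) {
  g1 <- exp(-(d / 0.5)^2)
  g2 <- exp(-((d - 3) / 2)^2)
  rep_ <- ifelse(d < 0, d^2, 0)
  phi <- pmin(pmax((1.5 - d), 0), 1)      # 1 for d<=0.5, 0 for d>=1.5
  hb <- pmin(pmax(-d / 0.7, 0), 1)        # 1 for d<=-0.7, 0 for d>=0
  if (length(d) == 1L) {
    c(gauss1 = g1, gauss2 = g2, repulsion = rep_, hydrophobic = phi, hbond = hb)
  } else {
    cbind(gauss1 = g1, gauss2 = g2, repulsion = rep_,
          hydrophobic = phi, hbond = hb)
  }
}

# analytic derivatives of the five terms with respect to d
term_derivatives <- function(d) {
  g1 <- exp(-(d / 0.5)^2) * (-2 * d / 0.25)
  g2 <- exp(-((d - 3) / 2)^2) * (-2 * (d - 3) / 4)
  rep_ <- ifelse(d < 0, 2 * d, 0)
  phi <- ifelse(d > 0.5 & d < 1.5, -1, 0)
  hb <- ifelse(d > -0.7 & d < 0, -1 / 0.7, 0)
  cbind(gauss1 = g1, gauss2 = g2, repulsion = rep_,
        hydrophobic = phi, hbond = hb)
}

# does the (unordered) type pair take the hydrophobic / hbond term?
pair_masks <- function(type_a, type_b) {
  tt <- atom_types()
  ia <- type_code_to_index(type_a)
  ib <- type_code_to_index(type_b)
  list(
    hydrophobic = tt$is_hydrophobic[ia] & tt$is_hydrophobic[ib],
    hbond = (tt$is_hbond_donor[ia] & tt$is_hbond_acceptor[ib]) |
            (tt$is_hbond_donor[ib] & tt$is_hbond_acceptor[ia])
  )
}

#' Weighted pair score at an interatomic distance
#'
#' The masked weighted sum of the five terms at the surface distance; exactly
#' zero at and beyond the distance cutoff.
#'
#' @param r Interatomic distance(s), Angstrom; `r >= 0`.
#' @param type_a,type_b Heavy-atom type codes.
#' @param weights A [scoring_weights()] object.
#' @param r_cutoff Distance cutoff, Angstrom.
#' @return Score value(s), same length as `r`.
#' @export
pair_score <- function(r, type_a, type_b, weights = scoring_weights(),
                       r_cutoff = 8) {
  stopifnot(all(r >= 0))
  d <- surface_distance(r, type_a, type_b)
  tv <- term_values(d)
  if (is.null(dim(tv))) tv <- matrix(tv, nrow = 1)
  m <- pair_masks(type_a, type_b)
  s <- weights$gauss1 * tv[, 1] + weights$gauss2 * tv[, 2] +
    weights$repulsion * tv[, 3] +
    (if (m$hydrophobic) weights$hydrophobic * tv[, 4] else 0) +
    (if (m$hbond) weights$hbond * tv[, 5] else 0)
  s[r >= r_cutoff] <- 0
  unname(s)
}

# d(pair score)/dr at distance r (zero at/beyond cutoff)
pair_score_derivative <- function(r, type_a, type_b,
                                  weights = scoring_weights(), r_cutoff = 8) {
  d <- surface_distance(r, type_a, type_b)
  td <- term_derivatives(d)
  m <- pair_masks(type_a, type_b)
  s <- weights$gauss1 * td[, 1] + weights$gauss2 * td[, 2] +
    weights$repulsion * td[, 3] +
    (if (m$hydrophobic) weights$hydrophobic * td[, 4] else 0) +
    (if (m$hbond) weights$hbond * td[, 5] else 0)
  s[r >= r_cutoff] <- 0
  unname(s)
}

#' Precalculate the pair-potential table
#'
#' Samples the weighted score curve (and its analytic derivative) of every
#' unordered type pair at `n_samples` uniformly spaced distances in
#' `[0, r_cutoff]`.  With 15 types there are 120 curves; the defaults sample
#' each at 16,384 points over [0, 8] Angstrom.  The last sample sits exactly
#' at the cutoff and stores 0.
#'
#' @param weights A [scoring_weights()] object.
#' @param n_samples Number of samples per curve (>= 2).
#' @param r_cutoff Distance cutoff, Angstrom.
#' @return Object of class `pair_potential_table`: matrices `values` and
#'   `derivatives` (`n_samples` rows x 120 columns), the sample spacing `dr`,
#'   and the generating parameters.
#' @export
precalculate_table <- function(weights = scoring_weights(),
                               n_samples = 16384L, r_cutoff = 8) {
  stopifnot(n_samples >= 2)
  n_samples <- as.integer(n_samples)
  codes <- atom_types()$code
  k <- length(codes)
  npair <- k * (k + 1L) / 2L
  r <- seq(0, r_cutoff, length.out = n_samples)
  values <- matrix(0, n_samples, npair)
  derivs <- matrix(0, n_samples, npair)
  for (i in seq_len(k)) {
    for (j in i:k) {
      p <- pair_index(i, j)
      values[, p] <- pair_score(r, codes[i], codes[j], weights, r_cutoff)
      derivs[, p] <- pair_score_derivative(r, codes[i], codes[j], weights,
                                           r_cutoff)
    }
  }
  structure(list(values = values, derivatives = derivs,
                 n_samples = n_samples, r_cutoff = r_cutoff,
                 dr = r_cutoff / (n_samples - 1L), weights = weights),
            class = "pair_potential_table")
}

#' O(1) table lookup of the pair score
#'
#' Returns the stored value at the *nearest* sampled distance -- table lookup,
#' not linear interpolation.  Zero at and beyond the cutoff.
#'
#' @param table A `pair_potential_table`.
#' @param r Interatomic distance(s), Angstrom; negative is a domain error.
#' @param type_a,type_b Heavy-atom type codes.
#' @param deriv If TRUE return the stored derivative instead of the value.
#' @return Score (or derivative) value(s).
#' @export
lookup_score <- function(table, r, type_a, type_b, deriv = FALSE) {
  if (any(r < 0)) stop("negative interatomic distance", call. = FALSE)
  p <- pair_index(type_code_to_index(type_a), type_code_to_index(type_b))
  lookup_by_pair(table, r, p, deriv)
}

# vectorized core: r and pair-column index (recycled) -> values
lookup_by_pair <- function(table, r, p, deriv = FALSE) {
  idx <- as.integer(round(r / table$dr)) + 1L
  out <- numeric(length(r))
  ok <- r < table$r_cutoff
  idx <- pmin(idx, table$n_samples)
  src <- if (deriv) table$derivatives else table$values
  if (length(p) == 1L) {
    out[ok] <- src[idx[ok], p]
  } else {
    out[ok] <- src[cbind(idx[ok], p[ok])]
  }
  out
}

#' @export
print.pair_potential_table <- function(x, ...) {
  cat(sprintf("<pair_potential_table> %d pairs x %d samples over [0, %g] A\n",
              ncol(x$values), x$n_samples, x$r_cutoff))
  invisible(x)
}

#' Intra-molecular score of a realized ligand conformation
#'
#' Sums the table lookup over the precomputed movable heavy-atom pairs of the
#' template: pairs in different rigid frames separated by at least one active
#' torsion, excluding 1-4 interactions (atoms separated by three or fewer
#' consecutive covalent bonds).  A rigid ligand scores exactly 0.
#'
#' @param template A `ligand_template`.
#' @param coords Realized n x 3 coordinate matrix (all atoms, template order).
#' @param table A `pair_potential_table`.
#' @return Scalar intra-molecular score.
#' @export
intra_score <- function(template, coords, table) {
  pr <- template$intra_pairs
  if (!nrow(pr)) return(0)
  ti <- type_code_to_index(template$atoms$type[pr[, 1]])
  tj <- type_code_to_index(template$atoms$type[pr[, 2]])
  dv <- coords[pr[, 1], , drop = FALSE] - coords[pr[, 2], , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  sum(lookup_by_pair(table, r, pair_index(ti, tj)))
}

#' Flexibility-penalized free energy of a conformation
#'
#' The conformation-independent part of the score penalizes ligand
#' flexibility.  The reported free energy of conformation i is
#' `(e_i - e_intra_1) / (1 + w_flex * (n_active + 0.5 * n_inactive))`, where
#' `e_intra_1` is the intra-molecular score of the lowest-scoring conformation
#' of the same ligand.  Subtracting `e_intra_1` (a constant per ligand) keeps
#' the output ordering identical to the ordering by `e_i`.
#'
#' @param e_i Conformation-dependent score of conformation i.
#' @param e_intra_1 Intra score of the best (lowest-scoring) conformation.
#' @param n_active,n_inactive Torsion counts of the ligand.
#' @param weights A [scoring_weights()] object (uses `flex`).
#' @return Predicted free energy, kcal/mol.
#' @export
flexibility_penalized_energy <- function(e_i, e_intra_1, n_active, n_inactive,
                                         weights = scoring_weights()) {
  (e_i - e_intra_1) / (1 + weights$flex * (n_active + 0.5 * n_inactive))
}

#' Convert a predicted free energy to pKd units
#'
#' From `Kd = exp(dG / (R T))`, `pKd = -log10 Kd = -dG / (R T ln 10)`.
#'
#' @param delta_g Free energy, kcal/mol.
#' @param constants A [thermo_constants()] object.
#' @return Binding affinity in pKd units.
#' @export
kcal_to_pkd <- function(delta_g, constants = thermo_constants()) {
  -delta_g / (constants$gas_constant * constants$temperature * log(10))
}

#' @rdname kcal_to_pkd
#' @param pkd Affinity in pKd units.
#' @export
pkd_to_kcal <- function(pkd, constants = thermo_constants()) {
  -pkd * constants$gas_constant * constants$temperature * log(10)
}

#' Consensus of engine and random-forest affinities
#'
#' The arithmetic mean of the two predictions, both in pKd units, so the
#' consensus directly reflects predicted potency.
#'
#' @param pkd_engine,pkd_rf Affinities in pKd units.
#' @return Consensus affinity, pKd.
#' @export
consensus_score <- function(pkd_engine, pkd_rf) {
  stopifnot(is.finite(pkd_engine), is.finite(pkd_rf))
  (pkd_engine + pkd_rf) / 2
}

#' Ligand efficiency
#'
#' Predicted free energy per ligand heavy atom.
#'
#' @param delta_g Free energy, kcal/mol.
#' @param n_heavy Number of ligand heavy atoms (>= 1).
#' @return kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(delta_g, n_heavy) {
  if (any(n_heavy < 1)) stop("n_heavy must be >= 1", call. = FALSE)
  delta_g / n_heavy
}

#' Putative hydrogen bonds between receptor and a ligand pose
#'
#' Reports every donor-acceptor heavy-atom pair (in either direction,
#' including metal donors) whose distance does not exceed the threshold,
#' sorted by distance.  A purely geometric criterion is used; hydrogen
#' positions in PDBQT are too unreliable for angle tests.
#'
#' @param receptor A `receptor`.
#' @param ligand_atoms Data.frame with ligand `serial`, `type` and realized
#'   coordinates in columns `x`, `y`, `z` (heavy atoms; hydrogens ignored).
#' @param threshold Distance threshold, Angstrom (default 3.5).
#' @return Data.frame with `receptor_serial`, `ligand_serial`, `distance`.
#' @export
detect_hbonds <- function(receptor, ligand_atoms, threshold = 3.5) {
  tt <- atom_types()
  ra <- receptor$atoms[receptor$heavy, ]
  la <- ligand_atoms[ligand_atoms$type != "H", , drop = FALSE]
  ri <- type_code_to_index(ra$type)
  li <- type_code_to_index(la$type)
  cand_r <- which(tt$is_hbond_donor[ri] | tt$is_hbond_acceptor[ri])
  cand_l <- which(tt$is_hbond_donor[li] | tt$is_hbond_acceptor[li])
  out <- data.frame(receptor_serial = integer(0), ligand_serial = integer(0),
                    distance = numeric(0))
  if (!length(cand_r) || !length(cand_l)) return(out)
  rc <- as.matrix(ra[cand_r, c("x", "y", "z")])
  lc <- as.matrix(la[cand_l, c("x", "y", "z")])
  d2 <- outer(rowSums(rc^2), rowSums(lc^2), "+") - 2 * rc %*% t(lc)
  hit <- which(d2 <= threshold^2, arr.ind = TRUE)
  if (!nrow(hit)) return(out)
  ii <- cand_r[hit[, 1]]
  jj <- cand_l[hit[, 2]]
  pairable <- (tt$is_hbond_donor[ri[ii]] & tt$is_hbond_acceptor[li[jj]]) |
    (tt$is_hbond_acceptor[ri[ii]] & tt$is_hbond_donor[li[jj]])
  keep <- which(pairable)
  if (!length(keep)) return(out)
  out <- data.frame(
    receptor_serial = ra$serial[ii[keep]],
    ligand_serial = la$serial[jj[keep]],
    distance = sqrt(pmax(d2[hit[keep, , drop = FALSE]], 0))
  )
  out[order(out$distance), , drop = FALSE]
}
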