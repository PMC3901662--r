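# Monte-Carlo global search with BFGS quasi-Newton local optimization.
#
# Each chain starts from a random pose (position uniform in the box,
# orientation uniform on SO(3), torsions uniform in (-pi, pi)) and repeats
# mutate -> BFGS -> Metropolis.  The local optimizer uses the value AND the
# gradient of the scoring function with respect to position, orientation and
# the active torsions; the gradient is assembled by back-propagating per-atom
# force vectors through the torsion tree.  BFGS stops exactly when the
# backtracking line search can find no acceptable step.  Accepted minima are
# pooled over chains, clustered, and at most `max_poses` poses are returned.

#' Search configuration
#'
#' @param n_runs Number of independent Monte-Carlo chains.
#' @param iterations_base Base per-chain iteration count; the actual budget is
#'   `iterations_base * (1 + n_heavy/32 + n_active/4)`, scaling with ligand
#'   complexity.
#' @param metropolis_temperature Temperature of the Metropolis criterion, in
#'   score units.
#' @param max_poses Maximum number of output poses (default 9).
#' @param cluster_rmsd Heavy-atom RMSD radius used to deduplicate minima.
#' @param seed Integer seed; chain k is seeded with `seed + k` so results are
#'   independent of chain execution order.
#' @param mutation_position,mutation_angle Mutation amplitudes (Angstrom,
#'   radians).
#' @param bfgs_max_iter Safety cap on BFGS iterations per local optimization.
#' @return Named list of class `search_config`.
#' @export
search_config <- function(n_runs = 64L, iterations_base = 20L,
                          metropolis_temperature = 1.2, max_poses = 9L,
                          cluster_rmsd = 1.0, seed = 1L,
                          mutation_position = 2, mutation_angle = pi / 6,
                          bfgs_max_iter = 100L) {
  stopifnot(n_runs >= 1, max_poses >= 1, metropolis_temperature > 0)
  structure(list(n_runs = as.integer(n_runs),
                 iterations_base = as.integer(iterations_base),
                 metropolis_temperature = metropolis_temperature,
                 max_poses = as.integer(max_poses),
                 cluster_rmsd = cluster_rmsd, seed = as.integer(seed),
                 mutation_position = mutation_position,
                 mutation_angle = mutation_angle,
                 bfgs_max_iter = as.integer(bfgs_max_iter)),
            class = "search_config")
}

#' Score a conformation and its gradient
#'
#' Realizes the conformation, reads the inter-molecular energy (and per-atom
#' Cartesian forces) from the grid maps and the intra-molecular energy from
#' the pair table, and back-propagates the forces through the torsion tree
#' into derivatives with respect to position (3), orientation (3, a rotation
#' vector about the root anchor), and each active torsion.  Inactive torsions
#' carry no gradient component: they are not optimization variables.
#'
#' With `exact = TRUE` the analytic pair potential is evaluated directly
#' (no table, no lattice); this smooth path is the reference the lookup path
#' approximates and is what finite-difference checks differentiate.
#'
#' @param template A `ligand_template`.
#' @param conf A `conformation`.
#' @param maps Grid maps from [build_grid_maps()] (lookup mode).
#' @param table A `pair_potential_table`.
#' @param receptor Required in exact mode.
#' @param exact Use direct analytic evaluation instead of lookups.
#' @return List with `score`, `e_inter`, `e_intra`, `gradient` (length
#'   `6 + n_active`), `coords`.
#' @export
score_and_gradient <- function(template, conf, maps = NULL, table,
                               receptor = NULL, exact = FALSE) {
  coords <- realize(template, conf)
  heavy <- template$heavy_idx
  if (is.null(heavy)) heavy <- which(!template$atoms$is_hydrogen)
  hcoords <- coords[heavy, , drop = FALSE]
  htypes <- template$heavy_types
  if (is.null(htypes)) htypes <- template$atoms$type[heavy]

  if (exact) {
    inter <- direct_inter(receptor, hcoords, htypes, table, per_atom = TRUE,
                          analytic = TRUE)
    g_heavy <- direct_inter_gradient(receptor, hcoords, htypes, table)
  } else {
    ge <- grid_eval(maps, hcoords, htypes, clamp = TRUE)
    inter <- list(e_inter = ge$e_inter, per_atom = ge$per_atom)
    g_heavy <- ge$grad
  }

  # intra-molecular part over precomputed movable pairs
  e_intra <- 0
  pr <- template$intra_pairs
  if (nrow(pr)) {
    dv <- coords[pr[, 1], , drop = FALSE] - coords[pr[, 2], , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv^2)), 1e-9)
    pidx <- template$intra_pair_idx
    if (is.null(pidx)) {
      pidx <- pair_index(type_code_to_index(template$atoms$type[pr[, 1]]),
                         type_code_to_index(template$atoms$type[pr[, 2]]))
    }
    if (exact) {
      vals <- numeric(nrow(pr))
      dd <- numeric(nrow(pr))
      for (k in seq_len(nrow(pr))) {
        ta <- template$atoms$type[pr[k, 1]]
        tb <- template$atoms$type[pr[k, 2]]
        vals[k] <- pair_score(r[k], ta, tb, table$weights, table$r_cutoff)
        dd[k] <- pair_score_derivative(r[k], ta, tb, table$weights,
                                       table$r_cutoff)
      }
    } else {
      vals <- lookup_by_pair(table, r, pidx)
      dd <- lookup_by_pair(table, r, pidx, deriv = TRUE)
    }
    e_intra <- sum(vals)
    hp <- template$intra_hpos
    if (is.null(hp)) hp <- cbind(match(pr[, 1], heavy), match(pr[, 2], heavy))
    fmat <- dv * (dd / r)
    for (k in seq_len(nrow(pr))) {
      g_heavy[hp[k, 1], ] <- g_heavy[hp[k, 1], ] + fmat[k, ]
      g_heavy[hp[k, 2], ] <- g_heavy[hp[k, 2], ] - fmat[k, ]
    }
  }

  # back-propagate per-atom forces through the torsion tree
  p_root <- conf$position
  g_pos <- colSums(g_heavy)
  rel <- sweep(hcoords, 2, p_root)
  g_ori <- c(sum(rel[, 2] * g_heavy[, 3] - rel[, 3] * g_heavy[, 2]),
             sum(rel[, 3] * g_heavy[, 1] - rel[, 1] * g_heavy[, 3]),
             sum(rel[, 1] * g_heavy[, 2] - rel[, 2] * g_heavy[, 1]))
  act <- template$active_ids
  if (is.null(act)) act <- active_frame_ids(template)
  g_tor <- numeric(length(act))
  if (length(act)) {
    for (k in seq_along(act)) {
      f <- act[k]
      ai <- template$frames[[f]]$axis_idx
      pb <- coords[ai[2], ]
      u <- coords[ai[2], ] - coords[ai[1], ]
      u <- u / sqrt(sum(u^2))
      sub_h <- if (!is.null(template$active_sub_heavy))
        template$active_sub_heavy[[k]]
      else {
        sub_atoms <- unlist(lapply(frame_subtree(template$frames, f),
                                   function(g) template$frames[[g]]$atoms))
        match(intersect(sub_atoms, heavy), heavy)
      }
      if (!length(sub_h)) next
      relb <- sweep(hcoords[sub_h, , drop = FALSE], 2, pb)
      gh <- g_heavy[sub_h, , drop = FALSE]
      torque <- c(sum(relb[, 2] * gh[, 3] - relb[, 3] * gh[, 2]),
                  sum(relb[, 3] * gh[, 1] - relb[, 1] * gh[, 3]),
                  sum(relb[, 1] * gh[, 2] - relb[, 2] * gh[, 1]))
      g_tor[k] <- sum(u * torque)
    }
  }
  list(score = inter$e_inter + e_intra, e_inter = inter$e_inter,
       e_intra = e_intra, per_atom_inter = inter$per_atom,
       gradient = c(g_pos, g_ori, g_tor), coords = coords)
}

# analytic per-atom gradient of the inter-molecular energy (oracle path)
direct_inter_gradient <- function(receptor, hcoords, htypes, table) {
  ratoms <- receptor$atoms[receptor$heavy, , drop = FALSE]
  rc <- as.matrix(ratoms[, c("x", "y", "z")])
  g <- matrix(0, nrow(hcoords), 3)
  for (i in seq_len(nrow(hcoords))) {
    dv <- sweep(rc, 2, hcoords[i, ], "-")      # receptor - ligand
    r <- pmax(sqrt(rowSums(dv^2)), 1e-9)
    for (a in seq_len(nrow(rc))) {
      if (r[a] >= table$r_cutoff) next
      dd <- pair_score_derivative(r[a], htypes[i], ratoms$type[a],
                                  table$weights, table$r_cutoff)
      g[i, ] <- g[i, ] - dd * dv[a, ] / r[a]   # d r / d x_lig = -(dv)/r
    }
  }
  g
}

# apply a step in the pose tangent space: x = (d_pos, rot_vec, d_tors)
apply_conformation_step <- function(conf, step) {
  n_tor <- length(conf$torsions)
  conf$position <- conf$position + step[1:3]
  conf$orientation <- quat_normalize(
    quat_multiply(quat_from_rotation_vector(step[4:6]), conf$orientation))
  if (n_tor) conf$torsions <- conf$torsions + step[7:(6 + n_tor)]
  conf
}

#' Generic BFGS minimizer with backtracking line search
#'
#' Maintains an inverse-Hessian approximation, takes Armijo backtracking
#' steps, and terminates exactly when the line search fails to find an
#' acceptable step length.
#'
#' @param fn Function of `x` returning `list(value =, grad =)`.
#' @param x0 Start vector.
#' @param max_iter Iteration cap.
#' @param alpha0 Initial trial step length.
#' @param c1 Armijo constant.
#' @param alpha_min Smallest step length tried before declaring failure.
#' @return List with `x`, `value`, `n_iter`.
#' @export
bfgs_minimize <- function(fn, x0, max_iter = 200L, alpha0 = 1,
                          c1 = 1e-4, alpha_min = 1e-10) {
  n <- length(x0)
  H <- diag(n)
  x <- x0
  ev <- fn(x)
  for (it in seq_len(max_iter)) {
    p <- -as.numeric(H %*% ev$grad)
    gp <- sum(ev$grad * p)
    if (!is.finite(gp) || gp >= 0) {  # not a descent direction: restart H
      H <- diag(n)
      p <- -ev$grad
      gp <- sum(ev$grad * p)
      if (gp >= 0) return(list(x = x, value = ev$value, n_iter = it - 1L))
    }
    alpha <- alpha0
    ok <- FALSE
    while (alpha >= alpha_min) {
      xt <- x + alpha * p
      evt <- fn(xt)
      if (is.finite(evt$value) && evt$value <= ev$value + c1 * alpha * gp) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) return(list(x = x, value = ev$value, n_iter = it - 1L))
    s <- alpha * p
    y <- evt$grad - ev$grad
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      V <- I - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    x <- xt
    ev <- evt
  }
  list(x = x, value = ev$value, n_iter = max_iter)
}

#' BFGS local optimization of a pose
#'
#' BFGS over the pose tangent space (position, rotation vector, active
#' torsions) with the orientation re-anchored after every accepted step.
#' The returned score never exceeds the start score; iteration stops exactly
#' when the backtracking line search fails.
#'
#' @param template A `ligand_template`.
#' @param conf Start `conformation`.
#' @param scorer Function of a conformation returning the
#'   [score_and_gradient()] list.
#' @param max_iter Iteration cap.
#' @return List with `conf`, `score`, `n_iter`.
#' @export
bfgs_local_optimize <- function(template, conf, scorer, max_iter = 100L,
                                step_max = 1.0) {
  n <- 6L + length(conf$torsions)
  H <- diag(n)
  ev <- scorer(conf)
  c1 <- 1e-4
  alpha_min <- 1e-8
  for (it in seq_len(max_iter)) {
    g <- ev$gradient
    p <- -as.numeric(H %*% g)
    gp <- sum(g * p)
    if (!is.finite(gp) || gp >= 0) {
      H <- diag(n)
      p <- -g
      gp <- sum(g * p)
      if (gp >= 0) return(list(conf = conf, score = ev$score, n_iter = it - 1L))
    }
    # cap the first trial so a steep clash gradient cannot fling the pose
    # across the box in one step
    alpha <- min(1, step_max / max(abs(p)))
    ok <- FALSE
    while (alpha >= alpha_min) {
      conf_t <- apply_conformation_step(conf, alpha * p)
      ev_t <- scorer(conf_t)
      if (is.finite(ev_t$score) && ev_t$score <= ev$score + c1 * alpha * gp) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) return(list(conf = conf, score = ev$score, n_iter = it - 1L))
    s <- alpha * p
    y <- ev_t$gradient - ev$gradient   # torque block re-anchored; see notes
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      I <- diag(n)
      V <- I - rho * outer(s, y)
      H <- V %*% H %*% t(V) + rho * outer(s, s)
    }
    conf <- conf_t
    ev <- ev_t
  }
  list(conf = conf, score = ev$score, n_iter = max_iter)
}

#' Metropolis acceptance
#'
#' Always accept a non-positive score change; accept an increase `delta` with
#' probability `exp(-delta / temperature)`.
#'
#' @param delta Score change (candidate minus current).
#' @param temperature Metropolis temperature, score units; > 0.
#' @return Logical.
#' @export
metropolis_accept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  if (delta <= 0) return(TRUE)
  stats::runif(1) < exp(-delta / temperature)
}

#' Greedy clustering and selection of pose minima
#'
#' Best-first: walk minima by increasing score, discard any candidate within
#' `cluster_rmsd` (heavy-atom RMSD) of an already selected pose, stop at
#' `max_poses`.
#'
#' @param minima List of `list(conf =, score =, coords =)` entries
#'   (`coords` = heavy-atom coordinates).
#' @param cluster_rmsd RMSD radius, Angstrom.
#' @param max_poses Selection cap.
#' @return The selected sublist, score-ascending.
#' @export
cluster_and_select <- function(minima, cluster_rmsd, max_poses) {
  if (!length(minima)) return(list())
  ord <- order(vapply(minima, `[[`, numeric(1), "score"))
  selected <- list()
  for (i in ord) {
    cand <- minima[[i]]
    dup <- any(vapply(selected, function(s) {
      rmsd(s$coords, cand$coords) < cluster_rmsd
    }, logical(1)))
    if (!dup) selected[[length(selected) + 1L]] <- cand
    if (length(selected) >= max_poses) break
  }
  selected
}

random_conformation <- function(template, box) {
  tor <- stats::runif(template$n_active, -pi, pi)
  pos <- box$center + (stats::runif(3) - 0.5) * box$size
  conformation(pos, quat_random_uniform(), tor)
}

#' Dock a ligand by Monte Carlo with BFGS local optimization
#'
#' Builds (or reuses) the pair-potential table and the grid maps, runs
#' `n_runs` independent chains of mutate -> BFGS -> Metropolis with a
#' per-chain iteration budget scaling with ligand complexity, pools the
#' accepted local minima, clusters them, and returns at most `max_poses`
#' poses sorted by energy.  Pose energies are the flexibility-penalized free
#' energies with the best pose's intra-molecular score as the reference.
#' Chain k is seeded with `seed + k`, so the pose list is deterministic under
#' a fixed seed and invariant to chain execution order.
#'
#' @param receptor A `receptor`.
#' @param template A `ligand_template`.
#' @param box A `search_box`.
#' @param config A [search_config()].
#' @param engine An [engine_config()].
#' @param table,maps Optional prebuilt pair table / grid maps (cached reuse
#'   across ligands sharing a receptor and box).
#' @param start Optional `conformation` injected as the start of chain 1
#'   (e.g. the crystal pose in redocking experiments).
#' @return List of poses of class `docked_poses`; each pose carries `conf`,
#'   `coords`, `score`, `energy_kcal`, a `breakdown`, and `hbonds`.
#' @export
monte_carlo_dock <- function(receptor, template, box,
                             config = search_config(),
                             engine = engine_config(),
                             table = NULL, maps = NULL, start = NULL) {
  lig_span <- apply(template$coords0[!template$atoms$is_hydrogen, ,
                                     drop = FALSE], 2, function(v) diff(range(v)))
  if (max(lig_span) > box$size) {
    stop("ligand is larger than the search box", call. = FALSE)
  }
  if (is.null(table)) {
    table <- precalculate_table(engine$weights, engine$n_samples,
                                engine$r_cutoff)
  }
  heavy <- which(!template$atoms$is_hydrogen)
  htypes <- template$atoms$type[heavy]
  if (is.null(maps)) {
    maps <- build_grid_maps(receptor, box, table, unique(htypes))
  }
  scorer <- function(conf) score_and_gradient(template, conf, maps, table)
  budget <- ceiling(config$iterations_base *
                      (1 + template$n_heavy / 32 + template$n_active / 4))
  amplitudes <- list(position = config$mutation_position,
                     angle = config$mutation_angle)
  minima <- list()
  record <- function(opt) {
    minima[[length(minima) + 1L]] <<- list(
      conf = opt$conf, score = opt$score,
      coords = realize(template, opt$conf)[heavy, , drop = FALSE])
  }
  for (run in seq_len(config$n_runs)) {
    set.seed(config$seed + run)
    conf <- if (run == 1L && !is.null(start)) start
            else random_conformation(template, box)
    cur <- bfgs_local_optimize(template, conf, scorer, config$bfgs_max_iter)
    record(cur)
    for (iter in seq_len(budget)) {
      cand <- mutate_conformation(cur$conf, amplitudes)
      cand$position <- pmin(pmax(cand$position, box$center - box$size / 2),
                            box$center + box$size / 2)
      opt <- bfgs_local_optimize(template, cand, scorer, config$bfgs_max_iter)
      if (metropolis_accept(opt$score - cur$score,
                            config$metropolis_temperature)) {
        cur <- opt
        record(cur)
      }
    }
  }
  selected <- cluster_and_select(minima, config$cluster_rmsd, config$max_poses)
  finalize_poses(receptor, template, selected, maps, table, engine)
}

# attach energies (flexibility penalty vs the best pose), per-atom
# decomposition, term sums, and putative hydrogen bonds
finalize_poses <- function(receptor, template, selected, maps, table, engine) {
  if (!length(selected)) {
    return(structure(list(), class = "docked_poses"))
  }
  heavy <- which(!template$atoms$is_hydrogen)
  htypes <- template$atoms$type[heavy]
  best_coords <- realize(template, selected[[1]]$conf)
  e_intra_1 <- intra_score(template, best_coords, table)
  poses <- lapply(selected, function(mn) {
    coords <- realize(template, mn$conf)
    hcoords <- coords[heavy, , drop = FALSE]
    inter <- grid_lookup(maps, hcoords, htypes, clamp = TRUE)
    e_intra <- intra_score(template, coords, table)
    energy <- flexibility_penalized_energy(inter$e_inter + e_intra, e_intra_1,
                                           template$n_active,
                                           template$n_inactive,
                                           engine$weights)
    lig_at <- data.frame(serial = template$atoms$serial[heavy],
                         type = htypes,
                         x = hcoords[, 1], y = hcoords[, 2], z = hcoords[, 3])
    list(conf = mn$conf, coords = coords, score = mn$score,
         energy_kcal = energy,
         breakdown = list(
           e_total = inter$e_inter + e_intra,
           e_inter = inter$e_inter, e_intra = e_intra,
           per_atom_inter = inter$per_atom,
           term_sums = unweighted_term_sums(receptor, template, coords,
                                            table$r_cutoff)),
         hbonds = detect_hbonds(receptor, lig_at, engine$hbond_distance))
  })
  structure(poses, class = "docked_poses")
}

# unweighted totals of the five terms over inter pairs plus movable intra
# pairs (direct evaluation; used for reporting, not in the search loop)
unweighted_term_sums <- function(receptor, template, coords, r_cutoff = 8) {
  tt <- atom_types()
  heavy <- which(!template$atoms$is_hydrogen)
  lt <- type_code_to_index(template$atoms$type[heavy])
  ratoms <- receptor$atoms[receptor$heavy, , drop = FALSE]
  rt <- type_code_to_index(ratoms$type)
  rc <- as.matrix(ratoms[, c("x", "y", "z")])
  sums <- c(gauss1 = 0, gauss2 = 0, repulsion = 0, hydrophobic = 0, hbond = 0)
  add_pair <- function(r, ia, ib) {
    d <- r - (tt$vdw_radius[ia] + tt$vdw_radius[ib])
    tv <- term_values(d)
    phob <- tt$is_hydrophobic[ia] & tt$is_hydrophobic[ib]
    hb <- (tt$is_hbond_donor[ia] & tt$is_hbond_acceptor[ib]) |
      (tt$is_hbond_donor[ib] & tt$is_hbond_acceptor[ia])
    sums <<- sums + c(tv[1], tv[2], tv[3],
                      if (phob) tv[4] else 0, if (hb) tv[5] else 0)
  }
  for (i in seq_along(heavy)) {
    dv <- sweep(rc, 2, coords[heavy[i], ])
    r <- sqrt(rowSums(dv^2))
    for (a in which(r < r_cutoff)) add_pair(r[a], lt[i], rt[a])
  }
  pr <- template$intra_pairs
  if (nrow(pr)) {
    ti <- type_code_to_index(template$atoms$type[pr[, 1]])
    tj <- type_code_to_index(template$atoms$type[pr[, 2]])
    dvp <- coords[pr[, 1], , drop = FALSE] - coords[pr[, 2], , drop = FALSE]
    rp <- sqrt(rowSums(dvp^2))
    for (k in which(rp < r_cutoff)) add_pair(rp[k], ti[k], tj[k])
  }
  sums
}

#' @export
print.docked_poses <- function(x, ...) {
  cat(sprintf("<docked_poses> %d pose(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  %d: %8.3f kcal/mol (inter %7.3f, intra %7.3f)\n",
                i, x[[i]]$energy_kcal, x[[i]]$breakdown$e_inter,
                x[[i]]$breakdown$e_intra))
  }
  invisible(x)
}
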