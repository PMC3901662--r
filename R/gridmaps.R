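# Per-atom-type energy lattices over the search box.
#
# A grid map for atom type t places a virtual probe atom of type t at every
# lattice node of the cubic search box and precalculates the sum of the
# pair-potential lookups against every receptor heavy atom within the cutoff.
# Ligand inter-molecular energies (and their Cartesian gradients) are then
# served by nearest-node lookup, one read per heavy atom.

#' Define a cubic search box
#'
#' @param center 3-vector, Angstrom.
#' @param size Edge length, Angstrom (cube).
#' @param granularity Lattice spacing, Angstrom; default 0.15625.
#' @return Object of class `search_box` with derived `origin`, `dims` and the
#'   spanned extent (the lattice covers the whole box).
#' @export
search_box <- function(center, size, granularity = 0.15625) {
  stopifnot(length(center) == 3, size > 0, granularity > 0)
  n <- as.integer(ceiling(size / granularity)) + 1L
  n <- max(n, 2L)
  span <- (n - 1L) * granularity
  origin <- as.numeric(center) - span / 2
  structure(list(center = as.numeric(center), size = size,
                 granularity = granularity, origin = origin,
                 dims = rep(n, 3L), span = span),
            class = "search_box")
}

box_contains <- function(box, coords) {
  lo <- box$center - box$size / 2
  hi <- box$center + box$size / 2
  all(sweep(coords, 2, lo, ">=")) && all(sweep(coords, 2, hi, "<="))
}

clamp_to_box <- function(box, coords) {
  lo <- box$origin
  hi <- box$origin + box$span
  for (k in 1:3) coords[, k] <- pmin(pmax(coords[, k], lo[k]), hi[k])
  coords
}

#' Build grid maps for the atom types a ligand needs
#'
#' For each requested heavy-atom type, evaluates at every lattice node the sum
#' of pair-potential table lookups over all receptor heavy atoms within the
#' cutoff, plus the three Cartesian derivative lattices (chain rule through
#' the stored d(score)/dr curves).  Maps are built lazily per type set.
#'
#' @param receptor A `receptor`.
#' @param box A `search_box`.
#' @param table A `pair_potential_table`.
#' @param needed_types Character vector of heavy-atom type codes.
#' @return Named list of `grid_map` objects (one per type), each holding
#'   `values` and `dx`, `dy`, `dz` arrays of dim `box$dims`.
#' @export
build_grid_maps <- function(receptor, box, table, needed_types) {
  needed_types <- unique(needed_types)
  n <- box$dims[1]
  ax <- box$origin[1] + (seq_len(n) - 1L) * box$granularity
  ay <- box$origin[2] + (seq_len(n) - 1L) * box$granularity
  az <- box$origin[3] + (seq_len(n) - 1L) * box$granularity
  nodes_x <- rep(ax, times = n * n)
  nodes_y <- rep(rep(ay, each = n), times = n)
  nodes_z <- rep(az, each = n * n)
  ratoms <- receptor$atoms[receptor$heavy, , drop = FALSE]
  # keep only receptor atoms that can reach the lattice
  reach <- table$r_cutoff
  lo <- box$origin - reach
  hi <- box$origin + box$span + reach
  keep <- ratoms$x >= lo[1] & ratoms$x <= hi[1] &
    ratoms$y >= lo[2] & ratoms$y <= hi[2] &
    ratoms$z >= lo[3] & ratoms$z <= hi[3]
  ratoms <- ratoms[keep, , drop = FALSE]
  r_ti <- if (nrow(ratoms)) type_code_to_index(ratoms$type) else integer(0)

  maps <- list()
  for (t in needed_types) {
    vals <- numeric(n^3)
    gx <- numeric(n^3); gy <- numeric(n^3); gz <- numeric(n^3)
    ti <- type_code_to_index(t)
    for (a in seq_len(nrow(ratoms))) {
      dxv <- nodes_x - ratoms$x[a]
      dyv <- nodes_y - ratoms$y[a]
      dzv <- nodes_z - ratoms$z[a]
      r <- sqrt(dxv^2 + dyv^2 + dzv^2)
      p <- pair_index(ti, r_ti[a])
      within <- r < table$r_cutoff
      if (!any(within)) next
      vals[within] <- vals[within] + lookup_by_pair(table, r[within], p)
      dd <- lookup_by_pair(table, r[within], p, deriv = TRUE)
      rr <- pmax(r[within], 1e-9)
      gx[within] <- gx[within] + dd * dxv[within] / rr
      gy[within] <- gy[within] + dd * dyv[within] / rr
      gz[within] <- gz[within] + dd * dzv[within] / rr
    }
    maps[[t]] <- structure(
      list(atom_type = t, origin = box$origin, spacing = box$granularity,
           dims = box$dims,
           values = array(vals, box$dims),
           dx = array(gx, box$dims), dy = array(gy, box$dims),
           dz = array(gz, box$dims)),
      class = "grid_map")
  }
  maps
}

# nearest-node flat index for coords (n x 3); error or clamp at box edge
grid_node_index <- function(map, coords, clamp = FALSE) {
  ijk <- sweep(coords, 2, map$origin) / map$spacing
  ijk <- round(ijk)
  if (clamp) {
    for (k in 1:3) ijk[, k] <- pmin(pmax(ijk[, k], 0), map$dims[k] - 1L)
  } else if (any(ijk < 0) || any(sweep(ijk, 2, map$dims - 1L, ">"))) {
    stop("atom outside the search box", call. = FALSE)
  }
  as.integer(1L + ijk[, 1] + map$dims[1] * (ijk[, 2] + map$dims[2] * ijk[, 3]))
}

#' Look up inter-molecular energy of ligand heavy atoms from grid maps
#'
#' Each atom reads the value stored at its *nearest* lattice node (table
#' lookup, not trilinear interpolation).
#'
#' @param maps Named list of `grid_map`s from [build_grid_maps()].
#' @param coords m x 3 matrix of heavy-atom coordinates.
#' @param types Character vector of their heavy-atom type codes.
#' @param clamp Clamp out-of-box atoms to the lattice edge instead of
#'   raising an error (used during search).
#' @return List with `e_inter` (sum) and `per_atom` (vector of length m).
#' @export
grid_lookup <- function(maps, coords, types, clamp = FALSE) {
  m <- nrow(coords)
  per_atom <- numeric(m)
  for (t in unique(types)) {
    sel <- which(types == t)
    map <- maps[[t]]
    if (is.null(map)) stop(sprintf("no grid map for type '%s'", t),
                           call. = FALSE)
    idx <- grid_node_index(map, coords[sel, , drop = FALSE], clamp = clamp)
    per_atom[sel] <- map$values[idx]
  }
  list(e_inter = sum(per_atom), per_atom = per_atom)
}

# combined value + gradient lookup for the search hot path: one nearest-node
# index computation per atom serves all four lattices
grid_eval <- function(maps, coords, types, clamp = TRUE) {
  m <- nrow(coords)
  per_atom <- numeric(m)
  g <- matrix(0, m, 3)
  for (t in unique(types)) {
    sel <- which(types == t)
    map <- maps[[t]]
    if (is.null(map)) stop(sprintf("no grid map for type '%s'", t),
                           call. = FALSE)
    cs <- coords[sel, , drop = FALSE]
    sp <- map$spacing
    d1 <- map$dims[1]; d2 <- map$dims[2]; d3 <- map$dims[3]
    i1 <- round((cs[, 1] - map$origin[1]) / sp)
    i2 <- round((cs[, 2] - map$origin[2]) / sp)
    i3 <- round((cs[, 3] - map$origin[3]) / sp)
    if (clamp) {
      i1[i1 < 0] <- 0; i1[i1 > d1 - 1] <- d1 - 1
      i2[i2 < 0] <- 0; i2[i2 > d2 - 1] <- d2 - 1
      i3[i3 < 0] <- 0; i3[i3 > d3 - 1] <- d3 - 1
    } else if (any(i1 < 0 | i1 > d1 - 1 | i2 < 0 | i2 > d2 - 1 |
                   i3 < 0 | i3 > d3 - 1)) {
      stop("atom outside the search box", call. = FALSE)
    }
    idx <- 1L + as.integer(i1 + d1 * (i2 + d2 * i3))
    per_atom[sel] <- map$values[idx]
    g[sel, 1] <- map$dx[idx]
    g[sel, 2] <- map$dy[idx]
    g[sel, 3] <- map$dz[idx]
  }
  list(e_inter = sum(per_atom), per_atom = per_atom, grad = g)
}

# gradient (m x 3) of the inter-molecular energy w.r.t. atom positions
grid_gradient <- function(maps, coords, types, clamp = FALSE) {
  m <- nrow(coords)
  g <- matrix(0, m, 3)
  for (t in unique(types)) {
    sel <- which(types == t)
    map <- maps[[t]]
    idx <- grid_node_index(map, coords[sel, , drop = FALSE], clamp = clamp)
    g[sel, 1] <- map$dx[idx]
    g[sel, 2] <- map$dy[idx]
    g[sel, 3] <- map$dz[idx]
  }
  g
}

# direct (lattice-free) inter-molecular energy: oracle-grade reference used
# by tests and by exact scoring mode
direct_inter <- function(receptor, coords, types, table, per_atom = FALSE,
                         analytic = FALSE) {
  ratoms <- receptor$atoms[receptor$heavy, , drop = FALSE]
  rt <- type_code_to_index(ratoms$type)
  lt <- type_code_to_index(types)
  pa <- numeric(nrow(coords))
  rc <- as.matrix(ratoms[, c("x", "y", "z")])
  for (i in seq_len(nrow(coords))) {
    dv <- sweep(rc, 2, coords[i, ])
    r <- sqrt(rowSums(dv^2))
    if (analytic) {
      s <- 0
      for (a in seq_along(r)) {
        if (r[a] < table$r_cutoff) {
          s <- s + pair_score(r[a], types[i], ratoms$type[a], table$weights,
                              table$r_cutoff)
        }
      }
      pa[i] <- s
    } else {
      pa[i] <- sum(lookup_by_pair(table, r, pair_index(lt[i], rt)))
    }
  }
  if (per_atom) list(e_inter = sum(pa), per_atom = pa) else sum(pa)
}
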