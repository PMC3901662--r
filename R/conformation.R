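# Pose parameterization and forward kinematics.
#
# A pose (conformation) is the triple (position, orientation, torsions):
# the absolute position of the root-frame anchor, a unit quaternion for the
# rigid-body orientation, and one dihedral angle (radians) per ACTIVE
# torsion.  Inactive torsions are frozen at the input geometry.  realize()
# walks the torsion tree: the root frame is rigidly transformed, and each
# branch rotates its whole subtree about its rotor axis.

# ---- quaternion helpers (w, x, y, z) ----

quat_identity <- function() c(1, 0, 0, 0)

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(quat_identity())
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

# rotation vector v (axis * angle) -> quaternion
quat_from_rotation_vector <- function(v) {
  angle <- sqrt(sum(v^2))
  if (angle < 1e-12) return(quat_identity())
  quat_from_axis_angle(v, angle)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

quat_random_uniform <- function() {
  # Shoemake's method: uniform on the unit quaternions / SO(3)
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

# Rodrigues rotation of points (rows) about axis through origin_pt
rotate_about_axis <- function(points, origin_pt, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  R <- quat_to_matrix(quat_from_axis_angle(u, angle))
  sweep(sweep(points, 2, origin_pt) %*% t(R), 2, origin_pt, "+")
}

# ---- conformation ----

#' Construct a conformation for a ligand template
#'
#' @param position 3-vector, Angstrom: absolute position of the root-frame
#'   anchor (the centroid of the root frame's heavy atoms at input geometry).
#' @param orientation Unit quaternion (w, x, y, z).
#' @param torsions Numeric vector of active-torsion angles, radians.
#' @return Object of class `conformation`.
#' @export
conformation <- function(position, orientation = quat_identity(),
                         torsions = numeric(0)) {
  stopifnot(length(position) == 3, length(orientation) == 4,
            abs(sum(orientation^2) - 1) < 1e-6)
  structure(list(position = as.numeric(position),
                 orientation = quat_normalize(as.numeric(orientation)),
                 torsions = as.numeric(torsions)),
            class = "conformation")
}

#' Identity conformation of a template
#'
#' The conformation that realizes exactly the input geometry: anchor at its
#' input position, identity orientation, all torsions zero.
#' @param template A `ligand_template`.
#' @return A `conformation`.
#' @export
identity_conformation <- function(template) {
  conformation(root_anchor(template), quat_identity(),
               rep(0, template$n_active))
}

root_anchor <- function(template) {
  if (!is.null(template$root_anchor)) return(template$root_anchor)
  ra <- template$frames[[1]]$atoms
  heavy <- ra[!template$atoms$is_hydrogen[ra]]
  if (!length(heavy)) heavy <- ra
  colMeans(template$coords0[heavy, , drop = FALSE])
}

active_frame_ids <- function(template) {
  if (!is.null(template$active_ids)) return(template$active_ids)
  which(vapply(template$frames, function(f) isTRUE(f$active), logical(1)))
}

#' Realize a conformation to Cartesian coordinates
#'
#' Torsion-tree forward kinematics: the root frame is rigidly transformed by
#' (position, orientation); each branch frame then rotates its subtree about
#' its rotor axis by the frame's torsion angle (0 for inactive torsions).
#'
#' @param template A `ligand_template`.
#' @param conf A `conformation` with `length(torsions) == template$n_active`.
#' @return n x 3 matrix of coordinates for all atoms in template order.
#' @export
realize <- function(template, conf) {
  if (length(conf$torsions) != template$n_active) {
    stop(sprintf("conformation has %d torsions but template has %d active",
                 length(conf$torsions), template$n_active), call. = FALSE)
  }
  frames <- template$frames
  x0 <- template$coords0
  if (length(frames) == 1L) {  # rigid ligand: one matrix product
    c0 <- root_anchor(template)
    R <- quat_to_matrix(conf$orientation)
    return(x0 %*% t(R) +
             rep(conf$position - as.numeric(R %*% c0), each = nrow(x0)))
  }
  coords <- matrix(NA_real_, nrow(x0), 3)
  act_ids <- active_frame_ids(template)
  angle_of <- stats::setNames(rep(0, length(frames)), seq_along(frames))
  angle_of[as.character(act_ids)] <- conf$torsions

  c0 <- root_anchor(template)
  R_root <- quat_to_matrix(conf$orientation)
  # frame transforms: x' = R (x0 - c) + p
  Rs <- vector("list", length(frames))
  cs <- vector("list", length(frames))
  ps <- vector("list", length(frames))
  kids <- frame_children(frames)
  todo <- 1L
  Rs[[1]] <- R_root; cs[[1]] <- c0; ps[[1]] <- conf$position
  while (length(todo)) {
    f <- todo[1]; todo <- c(todo[-1], kids[[f]])
    Rf <- Rs[[f]]; cf <- cs[[f]]; pf <- ps[[f]]
    idx <- frames[[f]]$atoms
    coords[idx, ] <- sweep(sweep(x0[idx, , drop = FALSE], 2, cf) %*% t(Rf),
                           2, pf, "+")
    for (g in kids[[f]]) {
      ai <- frames[[g]]$axis_idx
      b0 <- x0[ai[2], ]                       # axis child atom, original
      pb <- Rf %*% (b0 - cf) + pf             # its new position (parent move)
      u0 <- x0[ai[2], ] - x0[ai[1], ]
      u <- Rf %*% (u0 / sqrt(sum(u0^2)))      # new axis direction
      phi <- angle_of[[as.character(g)]]
      Rg <- quat_to_matrix(quat_from_axis_angle(as.numeric(u), phi)) %*% Rf
      Rs[[g]] <- Rg; cs[[g]] <- b0; ps[[g]] <- as.numeric(pb)
    }
  }
  coords
}

#' Randomly perturb a conformation
#'
#' Perturbs exactly one randomly chosen degree-of-freedom class: the position
#' (uniform step in a ball of the position amplitude), the orientation
#' (rotation about a random axis by an angle uniform in `[0, angle
#' amplitude]`), or one randomly chosen torsion (reset uniform in
#' `(-pi, pi)`).  Reproducible under a fixed RNG state.
#'
#' @param conf A `conformation`.
#' @param amplitudes Named list: `position` (Angstrom, default 2),
#'   `angle` (radians, default pi/6).
#' @return A new `conformation`.
#' @export
mutate_conformation <- function(conf, amplitudes = list(position = 2,
                                                        angle = pi / 6)) {
  n_tor <- length(conf$torsions)
  choice <- sample.int(if (n_tor > 0) 3L else 2L, 1L)
  if (choice == 1L) {
    step <- stats::rnorm(3)
    step <- step / sqrt(sum(step^2)) * stats::runif(1) * amplitudes$position
    conf$position <- conf$position + step
  } else if (choice == 2L) {
    axis <- stats::rnorm(3)
    dq <- quat_from_axis_angle(axis, stats::runif(1) * amplitudes$angle)
    conf$orientation <- quat_normalize(quat_multiply(dq, conf$orientation))
  } else {
    k <- sample.int(n_tor, 1L)
    conf$torsions[k] <- stats::runif(1, -pi, pi)
  }
  conf
}

#' Root mean square deviation between two poses
#'
#' RMSD over corresponding atoms (heavy atoms in practice), with no
#' superposition: docked poses share the receptor frame.
#'
#' @param coords_a,coords_b n x 3 matrices with identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("coordinate sets differ in size", call. = FALSE)
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Heavy-atom RMSD between two realized poses of one template
#' @param template A `ligand_template`.
#' @param coords_a,coords_b Full-atom coordinate matrices.
#' @return RMSD over heavy atoms, Angstrom.
#' @export
heavy_rmsd <- function(template, coords_a, coords_b) {
  h <- which(!template$atoms$is_hydrogen)
  rmsd(coords_a[h, , drop = FALSE], coords_b[h, , drop = FALSE])
}
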