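# Benchmark machinery: automatic search-box definition, redocking
# success-rate tables, correlation metrics, descriptor filtering, and
# stratified success rates.

#' Automatic search-box definition around a ligand
#'
#' Finds the smallest cube covering the ligand and extends it by the margin:
#' edge = largest axis span + margin, centered on the bounding-box center.
#'
#' @param ligand_coords n x 3 matrix of (heavy-atom) coordinates.
#' @param margin Extension, Angstrom (default 10; read as +10 on the cube
#'   edge, i.e. 5 per face).
#' @param granularity Lattice spacing passed through to [search_box()].
#' @return A `search_box` containing every ligand atom.
#' @export
auto_search_box <- function(ligand_coords, margin = 10,
                            granularity = 0.15625) {
  ligand_coords <- as.matrix(ligand_coords)
  if (!nrow(ligand_coords)) stop("no ligand coordinates", call. = FALSE)
  rngs <- apply(ligand_coords, 2, range)
  center <- colMeans(rngs)
  edge <- max(rngs[2, ] - rngs[1, ]) + margin
  search_box(center, edge, granularity)
}

#' A redocking record
#'
#' @param case Case identifier.
#' @param rmsd_by_rank RMSDs of the ranked docked poses to the crystal pose
#'   (up to 9 values), Angstrom.
#' @param n_rotatable Rotatable-bond count of the ligand (optional).
#' @param n_metals_in_site Metal ions in the binding site (optional).
#' @return Named list of class `redock_record` with `rmsd_min` derived.
#' @export
redock_record <- function(case, rmsd_by_rank, n_rotatable = NA_integer_,
                          n_metals_in_site = NA_integer_) {
  stopifnot(length(rmsd_by_rank) >= 1, all(rmsd_by_rank >= 0))
  structure(list(case = case, rmsd_by_rank = as.numeric(rmsd_by_rank),
                 rmsd_min = min(rmsd_by_rank),
                 n_rotatable = n_rotatable,
                 n_metals_in_site = n_metals_in_site),
            class = "redock_record")
}

#' Redocking success-rate table
#'
#' For a set of redocking records, reports (as fractions of cases):
#' for each rank i, the fraction whose rank-i pose is the closest one
#' (ties resolved to the smallest rank, so these fractions partition);
#' and for each threshold, the fraction with `RMSD1 < theta` (top pose
#' correct) and with `RMSDmin < theta` (some pose correct).  `RMSD < 2.0`
#' Angstrom is the conventional positive control for a correct bound
#' structure.
#'
#' @param records List of `redock_record`s.
#' @param thresholds RMSD thresholds, Angstrom.
#' @return A data.frame with columns `condition` and `rate`.
#' @export
success_table <- function(records, thresholds = c(0.5, 1.0, 1.5, 2.0, 2.5)) {
  stopifnot(length(records) > 0)
  n <- length(records)
  max_rank <- max(vapply(records, function(r) length(r$rmsd_by_rank),
                         integer(1)))
  rows <- list()
  first_attaining <- vapply(records, function(r) {
    which(r$rmsd_by_rank == r$rmsd_min)[1]
  }, numeric(1))
  for (i in seq_len(max_rank)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = sprintf("RMSD%d=RMSDmin", i),
      rate = mean(first_attaining == i))
  }
  r1 <- vapply(records, function(r) r$rmsd_by_rank[1], numeric(1))
  rmin <- vapply(records, function(r) r$rmsd_min, numeric(1))
  for (th in thresholds) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = sprintf("RMSD1<%.1f", th), rate = mean(r1 < th))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = sprintf("RMSDmin<%.1f", th), rate = mean(rmin < th))
  }
  do.call(rbind, rows)
}

#' Correlation metrics between predicted and experimental affinities
#'
#' Pearson's r, Spearman's rho (average ranks on ties), the standard
#' deviation of the prediction errors, and the root mean squared error.
#' `sd_convention = "residual"` instead reports the residual standard
#' deviation about the least-squares regression line, the convention some
#' benchmarks use.
#'
#' @param predicted,experimental Equal-length numeric vectors (n >= 3), pKd.
#' @param sd_convention `"difference"` (default) or `"residual"`.
#' @return Named list with `Rp`, `Rs`, `SD`, `RMSE`.
#' @export
correlation_metrics <- function(predicted, experimental,
                                sd_convention = c("difference", "residual")) {
  sd_convention <- match.arg(sd_convention)
  stopifnot(length(predicted) == length(experimental), length(predicted) >= 3)
  if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  diffs <- predicted - experimental
  sd_val <- if (sd_convention == "difference") {
    stats::sd(diffs)
  } else {
    fit <- stats::lm(experimental ~ predicted)
    sqrt(sum(stats::residuals(fit)^2) / (length(predicted) - 2))
  }
  list(Rp = stats::cor(predicted, experimental, method = "pearson"),
       Rs = stats::cor(predicted, experimental, method = "spearman"),
       SD = sd_val,
       RMSE = sqrt(mean(diffs^2)))
}

#' The nine descriptor names used for ligand filtering
#' @return Character vector of length 9.
#' @export
property_names <- function() {
  c("mwt", "xlogp", "apolar_desolv", "polar_desolv", "hbd", "hba",
    "tpsa", "charge", "rotatable_bonds")
}

#' Filter ligands by nine closed descriptor intervals
#'
#' A ligand is kept iff every one of its nine descriptors (molecular weight,
#' xlogP, apolar and polar desolvation, H-bond donors and acceptors, tPSA,
#' net charge, rotatable bonds) lies inside its closed interval -- a logical
#' AND over conditions with closed endpoints, so widening any interval can
#' only keep more ligands, and a full-range interval nullifies its condition.
#'
#' @param records Data.frame with the columns of [property_names()] (plus
#'   any id columns, passed through).
#' @param intervals Named list mapping descriptor name to `c(lo, hi)`;
#'   descriptors not named are unconstrained.
#' @return List with `kept` (the surviving rows) and `count`.
#' @export
filter_ligands <- function(records, intervals = list()) {
  stopifnot(is.data.frame(records))
  keep <- rep(TRUE, nrow(records))
  for (nm in names(intervals)) {
    if (!nm %in% names(records)) {
      stop(sprintf("unknown descriptor '%s'", nm), call. = FALSE)
    }
    iv <- intervals[[nm]]
    stopifnot(length(iv) == 2, iv[1] <= iv[2])
    keep <- keep & records[[nm]] >= iv[1] & records[[nm]] <= iv[2]
  }
  list(kept = records[keep, , drop = FALSE], count = sum(keep))
}

#' Success rates stratified by a ligand/site covariate
#'
#' Groups redocking records by rotatable-bond count or by the number of metal
#' ions in the binding site and reports the success rate (`RMSD1 <
#' threshold`) per stratum, plus the mean covariate among successes and
#' failures.
#'
#' @param records List of `redock_record`s carrying the stratification field.
#' @param by `"rotatable"` or `"metals"`.
#' @param threshold Success threshold, Angstrom (default 2).
#' @return List with `per_stratum` (data.frame: value, n, success_rate) and
#'   `mean_covariate` (success/failure group means).
#' @export
stratify_success <- function(records, by = c("rotatable", "metals"),
                             threshold = 2.0) {
  by <- match.arg(by)
  field <- if (by == "rotatable") "n_rotatable" else "n_metals_in_site"
  cov <- vapply(records, function(r) as.numeric(r[[field]]), numeric(1))
  if (anyNA(cov)) stop("records lack the stratification field", call. = FALSE)
  succ <- vapply(records, function(r) r$rmsd_by_rank[1] < threshold,
                 logical(1))
  vals <- sort(unique(cov))
  per <- data.frame(value = vals,
                    n = vapply(vals, function(v) sum(cov == v), numeric(1)),
                    success_rate = vapply(vals, function(v) {
                      mean(succ[cov == v])
                    }, numeric(1)))
  list(per_stratum = per,
       mean_covariate = c(success = mean(cov[succ]),
                          failure = mean(cov[!succ])))
}
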