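#' Default scoring weights
#'
#' Weights of the five empirical terms (gauss1, gauss2, repulsion, hydrophobic,
#' hydrogen bond) plus the flexibility-penalty coefficient.  The defaults are
#' the published Vina-family regression values (fit on the PDBbind v2007
#' refined set); every weight can be overridden.
#'
#' @param gauss1,gauss2,repulsion,hydrophobic,hbond Term weights
#'   (dimensionless).
#' @param flex Flexibility-penalty coefficient of the conformation-independent
#'   part of the score.
#' @return A named list of class `scoring_weights`.
#' @export
scoring_weights <- function(gauss1 = -0.035579, gauss2 = -0.005156,
                            repulsion = 0.840245, hydrophobic = -0.035069,
                            hbond = -0.587439, flex = 0.05846) {
  w <- list(gauss1 = gauss1, gauss2 = gauss2, repulsion = repulsion,
            hydrophobic = hydrophobic, hbond = hbond, flex = flex)
  stopifnot(all(vapply(w, is.finite, logical(1))), repulsion > 0)
  structure(w, class = "scoring_weights")
}

#' Thermodynamic constants for free-energy / pKd conversion
#'
#' @param gas_constant Gas constant in kcal mol^-1 K^-1.
#' @param temperature Absolute temperature in K (room temperature).
#' @return Named list of class `thermo_constants`.
#' @export
thermo_constants <- function(gas_constant = 1.9872e-3, temperature = 298.15) {
  stopifnot(gas_constant > 0, temperature > 0)
  structure(list(gas_constant = gas_constant, temperature = temperature),
            class = "thermo_constants")
}

#' Engine configuration defaults
#'
#' Collects the tunable numeric knobs of the engine in one place: pair-table
#' sampling (16,384 points over [0, 8] Angstrom), grid granularity (0.15625
#' Angstrom), the hydrogen-bond REMARK distance threshold, and the
#' thermodynamic constants.  All values are overridable per call.
#'
#' @param n_samples Number of uniformly spaced distance samples of the
#'   pair-potential table.
#' @param r_cutoff Interatomic distance cutoff in Angstrom.
#' @param granularity Grid-map spacing in Angstrom.
#' @param hbond_distance Donor-acceptor heavy-atom distance threshold in
#'   Angstrom for putative hydrogen bonds.
#' @param weights A [scoring_weights()] object.
#' @param thermo A [thermo_constants()] object.
#' @return Named list of class `engine_config`.
#' @export
engine_config <- function(n_samples = 16384L, r_cutoff = 8,
                          granularity = 0.15625, hbond_distance = 3.5,
                          weights = scoring_weights(),
                          thermo = thermo_constants()) {
  stopifnot(n_samples >= 2, r_cutoff > 0, granularity > 0, hbond_distance > 0)
  structure(list(n_samples = as.integer(n_samples), r_cutoff = r_cutoff,
                 granularity = granularity, hbond_distance = hbond_distance,
                 weights = weights, thermo = thermo),
            class = "engine_config")
}
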