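#' Heavy-atom type taxonomy
#'
#' The engine distinguishes 15 heavy-atom types, the functional split the
#' scoring terms require: carbons by hydrophobicity, nitrogens and oxygens by
#' hydrogen-bonding role, the heavier elements by identity, and a single metal
#' class.  Metal ions are treated as hydrogen-bond donors.  With 15 types an
#' unordered pair of types has 120 (= 15*16/2) combinations, the number of
#' pair-potential curves precalculated by [precalculate_table()].
#'
#' @return A data.frame with one row per type and columns `code`,
#'   `vdw_radius` (van der Waals radius, Angstrom), `is_hydrophobic`,
#'   `is_hbond_donor`, `is_hbond_acceptor`.
#' @export
#' @examples
#' nrow(atom_type_table())  # 15
atom_type_table <- function() {
  tab <- data.frame(
    code = c("C_H", "C_P",
             "N", "N_D", "N_A", "N_DA",
             "O_A", "O_DA",
             "S", "P", "F", "Cl", "Br", "I", "Met"),
    vdw_radius = c(1.9, 1.9,
                   1.8, 1.8, 1.8, 1.8,
                   1.7, 1.7,
                   2.0, 2.1, 1.5, 1.8, 2.0, 2.2, 1.2),
    is_hydrophobic = c(TRUE, FALSE,
                       FALSE, FALSE, FALSE, FALSE,
                       FALSE, FALSE,
                       FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    is_hbond_donor = c(FALSE, FALSE,
                       FALSE, TRUE, FALSE, TRUE,
                       FALSE, TRUE,
                       FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    is_hbond_acceptor = c(FALSE, FALSE,
                          FALSE, FALSE, TRUE, TRUE,
                          TRUE, TRUE,
                          FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$code
  tab
}

#' @rdname atom_type_table
#' @format NULL
#' @keywords internal
ATOM_TYPES <- NULL  # populated in .onLoad for fast repeated access

.pd_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .pd_env$atom_types <- atom_type_table()
  .pd_env$type_index <- stats::setNames(seq_len(15), .pd_env$atom_types$code)
  invisible()
}

atom_types <- function() {
  if (is.null(.pd_env$atom_types)) .onLoad()
  .pd_env$atom_types
}

#' Number of heavy-atom types and unordered type pairs
#' @return Integer scalar.
#' @export
n_atom_types <- function() nrow(atom_types())

#' @rdname n_atom_types
#' @export
n_type_pairs <- function() {
  k <- n_atom_types()
  k * (k + 1L) / 2L
}

type_code_to_index <- function(code) {
  idx <- .pd_env$type_index[code]
  if (anyNA(idx)) {
    bad <- unique(code[is.na(idx)])
    stop("unknown heavy-atom type code(s): ", paste(bad, collapse = ", "))
  }
  unname(idx)
}

# canonical index of the unordered pair (i, j), 1..120, row-compacted
pair_index <- function(i, j) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  # pairs (1,1),(1,2)...(1,15),(2,2)... : offset of row lo plus column
  as.integer((lo - 1L) * 15L - (lo - 1L) * lo / 2 + hi)
}

vdw_radius_of <- function(code) {
  atom_types()$vdw_radius[type_code_to_index(code)]
}

# elements that map to the single metal class
METAL_ELEMENTS <- c("ZN", "FE", "MG", "CA", "MN", "CU", "NA", "K", "HG",
                    "NI", "CO", "CD", "SR", "CS", "LI", "AL", "BA", "MO")

# covalent radii (Angstrom) used for distance-threshold bond perception
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39,
                    B = 0.84, SI = 1.11, SE = 1.20, MET = 1.40)

covalent_radius_of_element <- function(element) {
  el <- toupper(element)
  r <- COVALENT_RADII[el]
  r[is.na(r) & el %in% METAL_ELEMENTS] <- COVALENT_RADII[["MET"]]
  r[is.na(r)] <- 1.0
  unname(r)
}
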