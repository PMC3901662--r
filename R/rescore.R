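# Random-forest rescoring of docked poses.
#
# Each protein-ligand complex is summarized as 36 occurrence counts of
# element pairs -- 4 protein elements (C, N, O, S) crossed with 9 ligand
# elements (C, N, O, F, P, S, Cl, Br, I) -- within a 12 Angstrom cutoff; the
# generous cutoff implicitly captures solvation effects.  A random-forest
# regression (500 unpruned CART trees grown on bootstrap samples, best split
# among mtry randomly chosen features, nodes with <= 5 samples become
# leaves; each prediction is the mean over trees of the traversed leaf mean)
# maps the counts to binding affinity in pKd units.

RF_PROTEIN_ELEMENTS <- c("C", "N", "O", "S")
RF_LIGAND_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

rf_feature_names <- function() {
  as.vector(outer(RF_PROTEIN_ELEMENTS, RF_LIGAND_ELEMENTS,
                  function(p, l) paste0(p, ".", l)))
}

#' Extract the 36 element-pair contact counts
#'
#' Counts protein-ligand atom pairs within the distance cutoff for each of
#' the 4 x 9 element combinations.  Element symbols outside the two sets
#' (including hydrogens) are ignored.  The counts depend only on interatomic
#' distances, so they are invariant to atom order and to rigid motions of the
#' complex.
#'
#' @param receptor A `receptor`.
#' @param ligand_coords m x 3 matrix of ligand atom coordinates.
#' @param ligand_elements Character vector of their element symbols.
#' @param cutoff Distance cutoff, Angstrom (default 12); pairs at exactly the
#'   cutoff are counted.
#' @return Named integer vector of length 36 (protein element . ligand
#'   element), class `rf_features`.
#' @export
extract_features <- function(receptor, ligand_coords, ligand_elements,
                             cutoff = 12) {
  counts <- stats::setNames(integer(36), rf_feature_names())
  ratoms <- receptor$atoms
  pk <- which(ratoms$element %in% RF_PROTEIN_ELEMENTS)
  lk <- which(ligand_elements %in% RF_LIGAND_ELEMENTS)
  if (length(pk) && length(lk)) {
    rc <- as.matrix(ratoms[pk, c("x", "y", "z")])
    lc <- ligand_coords[lk, , drop = FALSE]
    d2 <- outer(rowSums(rc^2), rowSums(lc^2), "+") - 2 * rc %*% t(lc)
    hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
    if (nrow(hit)) {
      key <- paste0(ratoms$element[pk[hit[, 1]]], ".",
                    ligand_elements[lk[hit[, 2]]])
      tab <- table(key)
      counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    }
  }
  structure(counts, class = c("rf_features", "integer"))
}

#' Train the random-forest rescoring model
#'
#' Breiman-Cutler random forest regression: `n_trees` unpruned CART trees,
#' each grown on an independent bootstrap sample, best split chosen among
#' `mtry` randomly selected features, splitting stopped at nodes holding no
#' more than `min_node` samples.  Deterministic under the seed.
#'
#' @param features Numeric matrix, one row per complex, 36 columns.
#' @param pkd Numeric vector of experimental affinities (pKd units).
#' @param n_trees Number of trees (default 500).
#' @param min_node Leaf-size stopping threshold (default 5).
#' @param mtry Features tried per split (default 12, about p/3).
#' @param seed Integer seed.
#' @param bootstrap Draw each tree's sample with replacement (the forest
#'   default).  `FALSE` grows every tree on the full data -- with
#'   `n_trees = 1` and `mtry = p` that is a single deterministic CART fit.
#' @return Object of class `rf_model` wrapping the fitted forest.
#' @export
train_rf <- function(features, pkd, n_trees = 500L, min_node = 5L,
                     mtry = 12L, seed = 1L, bootstrap = TRUE) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(pkd))
  if (nrow(features) < 2 * min_node) {
    warning("very small training set: trees will be single leaves")
  }
  colnames(features) <- rf_feature_names()[seq_len(ncol(features))]
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = features, y = pkd, ntree = n_trees, mtry = mtry, nodesize = min_node,
    replace = bootstrap,
    sampsize = if (bootstrap) nrow(features) else nrow(features))
  structure(list(fit = fit, n_trees = as.integer(n_trees),
                 min_node = as.integer(min_node), mtry = as.integer(mtry),
                 seed = as.integer(seed), p = ncol(features),
                 y_range = range(pkd)),
            class = "rf_model")
}

#' Predict binding affinity from contact counts
#'
#' @param model An `rf_model`.
#' @param features A length-36 count vector or a matrix with 36 columns.
#' @return Predicted affinity(ies), pKd units.
#' @export
predict_rf <- function(model, features) {
  if (is.null(dim(features))) {
    if (length(features) != model$p) {
      stop(sprintf("feature vector has length %d, expected %d",
                   length(features), model$p), call. = FALSE)
    }
    features <- matrix(as.numeric(features), 1)
  }
  colnames(features) <- rf_feature_names()[seq_len(ncol(features))]
  unname(stats::predict(model$fit, features))
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, mtry %d, min node %d (seed %d)\n",
              x$n_trees, x$mtry, x$min_node, x$seed))
  invisible(x)
}

#' Save / load a fitted rescoring model
#'
#' Serializes the forest with base R serialization (portable across
#' platforms) together with its hyperparameters.
#' @param model An `rf_model`.
#' @param path File path.
#' @export
save_rf_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_rf_model
#' @export
load_rf_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "rf_model"))
  model
}

#' Re-score docked poses with the random forest
#'
#' Fills each pose's `rf_pkd` (random-forest affinity from its contact
#' counts) and `consensus_pkd` (mean of the engine's energy converted to pKd
#' and the forest's prediction).  Also reports the two pose-selection rules
#' used in screening practice: the first-pose prediction and the maximum
#' prediction over poses.
#'
#' @param poses A `docked_poses` list.
#' @param receptor A `receptor`.
#' @param template The `ligand_template` the poses realize.
#' @param model An `rf_model`.
#' @param constants [thermo_constants()] for the kcal/mol to pKd conversion.
#' @param cutoff Feature cutoff, Angstrom.
#' @return The pose list with `rf_pkd` / `consensus_pkd` filled, plus
#'   attributes `rf_pkd_first` and `rf_pkd_max`.
#' @export
rescore_poses <- function(poses, receptor, template, model,
                          constants = thermo_constants(), cutoff = 12) {
  if (!length(poses)) return(poses)
  rf <- numeric(length(poses))
  for (i in seq_along(poses)) {
    fv <- extract_features(receptor, poses[[i]]$coords,
                           template$atoms$element, cutoff)
    rf[i] <- predict_rf(model, as.integer(fv))
    poses[[i]]$rf_pkd <- rf[i]
    poses[[i]]$consensus_pkd <- consensus_score(
      kcal_to_pkd(poses[[i]]$energy_kcal, constants), rf[i])
  }
  attr(poses, "rf_pkd_first") <- rf[1]
  attr(poses, "rf_pkd_max") <- max(rf)
  poses
}
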