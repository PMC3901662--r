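# Contact-count features and random-forest rescoring.

test_that("feature vectors have the 4 x 9 layout with the 12 A cutoff semantics", {
  rec <- parse_receptor(pdbqt_atom(1, "C1", 0, 0, 0, "C", "REC"))
  fv <- extract_features(rec, matrix(c(4, 0, 0), 1), "C")
  expect_length(fv, 36)
  expect_equal(sum(fv), 1)
  expect_equal(unname(fv["C.C"]), 1L)
  # pair at exactly the cutoff counts; just beyond does not
  expect_equal(sum(extract_features(rec, matrix(c(12, 0, 0), 1), "C")), 1)
  expect_equal(sum(extract_features(rec, matrix(c(12.5, 0, 0), 1), "C")), 0)
  # hydrogens and out-of-set elements are ignored
  expect_equal(sum(extract_features(rec, matrix(c(4, 0, 0), 1), "H")), 0)
})

test_that("feature extraction equals the brute-force double loop and is invariant to rigid motion", {
  set.seed(53)
  n_rec <- 120
  rec_elements <- sample(c("C", "N", "O", "S"), n_rec, TRUE)
  rec_ad <- ifelse(rec_elements == "O", "OA", rec_elements)
  rec_lines <- vapply(seq_len(n_rec), function(i) {
    p <- rnorm(3, 0, 6)
    pdbqt_atom(i, paste0(rec_elements[i], i), p[1], p[2], p[3], rec_ad[i],
               "REC")
  }, character(1))
  rec <- parse_receptor(paste(rec_lines, collapse = "\n"))
  m <- 60
  lig_el <- sample(c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "H"),
                   m, TRUE)
  lig_xyz <- matrix(rnorm(3 * m, 0, 6), m, 3)
  fv <- extract_features(rec, lig_xyz, lig_el)
  # brute force, written independently
  brute <- stats::setNames(integer(36), names(fv))
  for (i in seq_len(n_rec)) {
    for (j in seq_len(m)) {
      if (!lig_el[j] %in% c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I"))
        next
      d <- sqrt(sum((c(rec$atoms$x[i], rec$atoms$y[i], rec$atoms$z[i]) -
                       lig_xyz[j, ])^2))
      if (d <= 12) {
        key <- paste0(rec$atoms$element[i], ".", lig_el[j])
        brute[key] <- brute[key] + 1L
      }
    }
  }
  expect_equal(as.integer(fv), as.integer(brute))
  # permutation invariance in ligand atom order
  perm <- sample(m)
  fv_p <- extract_features(rec, lig_xyz[perm, , drop = FALSE], lig_el[perm])
  expect_equal(as.integer(fv_p), as.integer(fv))
  # translation invariance requires moving both partners
  shift <- c(5, -3, 2)
  rec_shift <- rec
  rec_shift$atoms$x <- rec$atoms$x + shift[1]
  rec_shift$atoms$y <- rec$atoms$y + shift[2]
  rec_shift$atoms$z <- rec$atoms$z + shift[3]
  fv_s <- extract_features(rec_shift, lig_xyz +
                             rep(shift, each = m), lig_el)
  expect_equal(as.integer(fv_s), as.integer(fv))
})

test_that("the forest respects its structural hyperparameters and label bounds", {
  dat <- make_rf_training_set(n = 120, sigma = 0.1, seed = 2)
  model <- train_rf(dat$features, dat$pkd, n_trees = 25, seed = 9)
  expect_equal(model$min_node, 5L)
  expect_equal(model$p, 36L)
  # engine defaults advertise the full-size forest
  expect_equal(formals(train_rf)$n_trees, 500L)
  expect_equal(formals(train_rf)$min_node, 5L)
  preds <- predict_rf(model, dat$features)
  expect_true(all(preds >= min(dat$pkd) - 1e-9))
  expect_true(all(preds <= max(dat$pkd) + 1e-9))
  # constant labels -> constant prediction
  const <- suppressWarnings(train_rf(dat$features[1:30, ], rep(6.2, 30),
                                     n_trees = 10, seed = 1))
  expect_equal(unique(round(predict_rf(const, dat$features[31:40, ]), 9)),
               6.2)
})

test_that("a single full-mtry tree agrees with an exhaustive CART oracle on clustered data", {
  # three clusters separated on two features, constant label per cluster:
  # any correct CART with leaf threshold 5 recovers the cluster partition
  X <- matrix(0, 20, 36)
  X[, 1] <- c(rep(0, 6), rep(10, 6), rep(10, 8))
  X[, 2] <- c(rep(0, 6), rep(0, 6), rep(10, 8))
  X[, 3:36] <- matrix(rep(seq_len(34), each = 20), 20)  # constant columns
  y <- c(rep(4, 6), rep(6, 6), rep(9, 8))
  model <- suppressWarnings(
    train_rf(X, y, n_trees = 1, mtry = 36, min_node = 5, seed = 7,
             bootstrap = FALSE))
  got <- predict_rf(model, X)

  # exhaustive CART oracle: best variance-reducing split over all features
  # and midpoints, recursion stops at <= 5 samples or no improvement
  cart_fit <- function(X, y) {
    n <- length(y)
    if (n <= 5) return(list(leaf = TRUE, value = mean(y)))
    best <- list(gain = 0)
    sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2) next
      cuts <- (xs[-1] + xs[-length(xs)]) / 2
      for (cut in cuts) {
        l <- X[, j] <= cut
        gain <- sse(y) - sse(y[l]) - sse(y[!l])
        if (gain > best$gain + 1e-12) {
          best <- list(gain = gain, j = j, cut = cut)
        }
      }
    }
    if (best$gain == 0) return(list(leaf = TRUE, value = mean(y)))
    l <- X[, best$j] <= best$cut
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = cart_fit(X[l, , drop = FALSE], y[l]),
         right = cart_fit(X[!l, , drop = FALSE], y[!l]))
  }
  cart_predict <- function(tree, x) {
    while (!tree$leaf) {
      tree <- if (x[tree$j] <= tree$cut) tree$left else tree$right
    }
    tree$value
  }
  oracle <- cart_fit(X, y)
  expected <- vapply(seq_len(nrow(X)), function(i) cart_predict(oracle, X[i, ]),
                     numeric(1))
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("the forest recovers a synthetic count-feature signal (held-out r > 0.9)", {
  train_set <- make_rf_training_set(n = 500, sigma = 0.1, seed = 4)
  test_set <- make_rf_training_set(n = 150, sigma = 0.1, seed = 204)
  model <- train_rf(train_set$features, train_set$pkd, n_trees = 200,
                    seed = 6)
  preds <- predict_rf(model, test_set$features)
  expect_gt(cor(preds, test_set$pkd), 0.9)
  # deterministic under the seed
  model2 <- train_rf(train_set$features, train_set$pkd, n_trees = 200,
                     seed = 6)
  expect_equal(predict_rf(model2, test_set$features), preds)
})

test_that("rescoring fills per-pose and selection-rule predictions compositionally", {
  fx <- funnel_rigid()
  cfg <- search_config(n_runs = 6, iterations_base = 3, seed = 2,
                       bfgs_max_iter = 40)
  poses <- monte_carlo_dock(fx$receptor, fx$template, fx$box, cfg,
                            table = small_table(), maps = funnel_maps())
  dat <- make_rf_training_set(n = 80, sigma = 0.1, seed = 3)
  model <- train_rf(dat$features, dat$pkd, n_trees = 20, seed = 5)
  scored <- rescore_poses(poses, fx$receptor, fx$template, model)
  rf <- vapply(scored, `[[`, numeric(1), "rf_pkd")
  expect_equal(attr(scored, "rf_pkd_first"), rf[1])
  expect_equal(attr(scored, "rf_pkd_max"), max(rf))
  for (i in seq_along(scored)) {
    fv <- extract_features(fx$receptor, scored[[i]]$coords,
                           fx$template$atoms$element)
    expect_equal(scored[[i]]$rf_pkd, predict_rf(model, as.integer(fv)))
    expect_equal(scored[[i]]$consensus_pkd,
                 consensus_score(kcal_to_pkd(scored[[i]]$energy_kcal),
                                 scored[[i]]$rf_pkd))
  }
  expect_error(predict_rf(model, numeric(10)), "length 10")
})
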