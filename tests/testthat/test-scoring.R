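# The five-term scoring function, pair-potential table, and unit conversions.

test_that("surface distance is r minus the summed vdW radii", {
  expect_equal(surface_distance(3.8, "C_H", "C_H"), 0)
  expect_equal(surface_distance(0, "C_H", "C_H"), -3.8)
  expect_equal(surface_distance(4.0, "C_H", "N"), 0.3)
})

test_that("term shapes: gaussian peaks, one-sided repulsion, ramp supports", {
  tv0 <- term_values(0)
  expect_equal(unname(tv0["gauss1"]), 1.0)
  expect_equal(unname(tv0["repulsion"]), 0)
  tv2 <- term_values(2.0)
  expect_equal(unname(tv2["hydrophobic"]), 0)
  expect_equal(unname(tv2["hbond"]), 0)
  tvm1 <- term_values(-1.0)
  expect_equal(unname(tvm1["repulsion"]), 1.0)
  expect_equal(unname(tvm1["hbond"]), 1.0)
  # hydrophobic ramp midpoint
  expect_equal(unname(term_values(1.0)["hydrophobic"]), 0.5)
})

test_that("pair score vanishes at and beyond the 8 A cutoff", {
  expect_equal(pair_score(8.0, "C_H", "C_H"), 0)
  expect_equal(pair_score(9.3, "O_A", "N_D"), 0)
  tab <- small_table()
  expect_equal(lookup_score(tab, 8.0, "C_H", "C_H"), 0)
  expect_equal(lookup_score(tab, 11, "Met", "O_A"), 0)
  # last stored sample sits at the cutoff and is zero for every pair
  expect_true(all(tab$values[tab$n_samples, ] == 0))
})

test_that("pair score equals an independent straight-line reimplementation", {
  w <- scoring_weights()
  tt <- atom_type_table()
  straight <- function(r, a, b) {
    if (r >= 8) return(0)
    d <- r - (tt[a, "vdw_radius"] + tt[b, "vdw_radius"])
    s <- w$gauss1 * exp(-(d / 0.5)^2) +
      w$gauss2 * exp(-((d - 3) / 2)^2) +
      w$repulsion * (if (d < 0) d^2 else 0)
    if (tt[a, "is_hydrophobic"] && tt[b, "is_hydrophobic"]) {
      s <- s + w$hydrophobic *
        (if (d <= 0.5) 1 else if (d >= 1.5) 0 else 1.5 - d)
    }
    if ((tt[a, "is_hbond_donor"] && tt[b, "is_hbond_acceptor"]) ||
        (tt[b, "is_hbond_donor"] && tt[a, "is_hbond_acceptor"])) {
      s <- s + w$hbond * (if (d <= -0.7) 1 else if (d >= 0) 0 else -d / 0.7)
    }
    s
  }
  set.seed(11)
  for (k in 1:200) {
    a <- sample(tt$code, 1)
    b <- sample(tt$code, 1)
    r <- runif(1, 0, 10)
    expect_equal(pair_score(r, a, b), straight(r, a, b), tolerance = 1e-12)
  }
})

test_that("the precalculated table has 120 pair curves and exact on-grid lookups", {
  expect_equal(n_atom_types(), 15)
  expect_equal(n_type_pairs(), 120)
  tab <- small_table()
  expect_equal(ncol(tab$values), 120)
  expect_equal(dim(tab$values), dim(tab$derivatives))
  # default sampling advertises 16,384 points over [0, 8]
  cfg <- engine_config()
  expect_identical(cfg$n_samples, 16384L)
  expect_equal(cfg$r_cutoff, 8)
  # degenerate two-point table: samples exactly at 0 and the cutoff
  t2 <- precalculate_table(n_samples = 2)
  expect_equal(t2$dr, 8)
  expect_equal(t2$values[1, pocketdock:::pair_index(1, 1)],
               pair_score(0, "C_H", "C_H"))
  expect_true(all(t2$values[2, ] == 0))
  # on-grid identity
  k <- c(1, 57, 500, 2048)
  r <- (k - 1) * tab$dr
  for (ri in r[r < 8]) {
    expect_equal(lookup_score(tab, ri, "O_A", "N_D"),
                 pair_score(ri, "O_A", "N_D"), tolerance = 1e-12)
  }
  expect_error(lookup_score(tab, -0.1, "C_H", "C_H"), "negative")
})

test_that("nearest-sample lookup error is bounded by bin width times curve slope and converges", {
  codes <- atom_type_table()$code
  set.seed(21)
  # 100 draws per unordered type pair, inside the cutoff (the curve jumps to
  # its hard zero at r = 8; cutoff behaviour is asserted separately above)
  grid <- expand.grid(a = codes, b = codes, stringsAsFactors = FALSE)
  grid <- grid[match(grid$a, codes) <= match(grid$b, codes), ]
  rs <- lapply(seq_len(nrow(grid)), function(i) runif(100, 0, 7.98))
  sup_err <- function(tab) {
    max(vapply(seq_len(nrow(grid)), function(i) {
      max(abs(lookup_score(tab, rs[[i]], grid$a[i], grid$b[i]) -
                pair_score(rs[[i]], grid$a[i], grid$b[i])))
    }, numeric(1)))
  }
  errs <- vapply(c(2^10, 2^12, 2^14), function(n) {
    sup_err(precalculate_table(n_samples = n))
  }, numeric(1))
  # empirical Lipschitz bound of the steepest curve (fine sampling of the
  # stored analytic derivative)
  tabf <- precalculate_table(n_samples = 2^14)
  L <- max(abs(tabf$derivatives))
  for (j in seq_along(errs)) {
    dr <- 8 / (c(2^10, 2^12, 2^14)[j] - 1)
    expect_lt(errs[j], L * dr)
  }
  # error shrinks as sampling doubles (quartering the bin twice)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})

test_that("intra score is zero for rigid ligands and excludes 1-4 pairs", {
  tab <- small_table()
  rigid <- parse_ligand(paste(c("ROOT", pdbqt_atom(1, "C1", 0, 0, 0, "C"),
                                pdbqt_atom(2, "C2", 1.5, 0, 0, "C"),
                                pdbqt_atom(3, "C3", 3.0, 0, 0, "C"),
                                "ENDROOT", "TORSDOF 0"), collapse = "\n"))
  expect_equal(intra_score(rigid, rigid$coords0, tab), 0)

  # chain with an active torsion: C1-C2-C3-Cl are all within 3 bonds, so
  # every movable pair is 1-4-excluded and the intra score is still 0
  cl <- parse_ligand(chloro_ligand_text())
  expect_equal(intra_score(cl, cl$coords0, tab), 0)

  # biphenyl: far-ring atoms are > 3 bonds from the root ring -> nonzero sum
  # matching a brute-force O(n^2) pair enumeration
  bi <- parse_ligand(biphenyl_ligand_text())
  conf <- identity_conformation(bi)
  conf$torsions <- pi / 5
  coords <- realize(bi, conf)
  got <- intra_score(bi, coords, tab)
  pairs <- bi$intra_pairs
  brute <- 0
  for (k in seq_len(nrow(pairs))) {
    r <- sqrt(sum((coords[pairs[k, 1], ] - coords[pairs[k, 2], ])^2))
    brute <- brute + lookup_score(tab, r, bi$atoms$type[pairs[k, 1]],
                                  bi$atoms$type[pairs[k, 2]])
  }
  expect_equal(got, brute, tolerance = 1e-12)
  expect_gt(nrow(pairs), 0)
})

test_that("flexibility penalty reduces to the difference for rigid ligands and preserves ranking", {
  expect_equal(flexibility_penalized_energy(-5, -1, 0, 0), -4)
  w0 <- scoring_weights(flex = 0)
  expect_equal(flexibility_penalized_energy(-5, -1, 4, 2, w0), -4)
  set.seed(3)
  e_intra_1 <- -0.7
  for (k in 1:50) {
    e <- sort(rnorm(2))
    out <- flexibility_penalized_energy(e, e_intra_1, 5, 2)
    expect_lt(out[1], out[2])
  }
})

test_that("free energy converts to pKd by -dG/(RT ln 10) and round-trips", {
  expect_equal(kcal_to_pkd(0), 0)
  rtln10 <- 1.9872e-3 * 298.15 * log(10)
  expect_equal(kcal_to_pkd(-rtln10), 1.0)
  expect_equal(kcal_to_pkd(-6.82), 6.82 / rtln10)
  expect_equal(kcal_to_pkd(-6.82), 5.0, tolerance = 0.01)
  set.seed(5)
  x <- rnorm(20, 0, 5)
  expect_equal(pkd_to_kcal(kcal_to_pkd(x)), x, tolerance = 1e-12)
  # linearity
  expect_equal(kcal_to_pkd(2 * x), 2 * kcal_to_pkd(x), tolerance = 1e-12)
})

test_that("consensus is the symmetric mean and ligand efficiency is per heavy atom", {
  expect_equal(consensus_score(5, 7), 6)
  expect_equal(consensus_score(4.2, 4.2), 4.2)
  expect_equal(consensus_score(3, 9), consensus_score(9, 3))
  expect_equal(ligand_efficiency(-8, 20), -0.4)
  expect_equal(ligand_efficiency(-3.3, 1), -3.3)
  expect_error(ligand_efficiency(-8, 0), "n_heavy")
})

test_that("putative hydrogen bonds obey the donor-acceptor geometry rule", {
  rec <- parse_receptor(paste(c(
    pdbqt_atom(1, "N1", 0, 0, 0, "N", "REC"),
    pdbqt_atom(2, "H1", 0.9, 0.2, 0, "HD", "REC"),   # makes N1 a donor
    pdbqt_atom(3, "C1", 5, 5, 5, "C", "REC")), collapse = "\n"))
  lig <- data.frame(serial = 1:2, type = c("O_A", "C_H"),
                    x = c(2.9, 2.9), y = c(0, 5), z = c(0, 5))
  hb <- detect_hbonds(rec, lig)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$receptor_serial, 1)
  expect_equal(hb$ligand_serial, 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-9)
  # beyond threshold
  lig_far <- transform(lig, x = c(5.0, 2.9))
  expect_equal(nrow(detect_hbonds(rec, lig_far)), 0)
  # hydrophobic pair at 2.9 A is not a hydrogen bond
  lig_c <- data.frame(serial = 9, type = "C_H", x = 2.9, y = 0, z = 0)
  expect_equal(nrow(detect_hbonds(rec, lig_c)), 0)
})
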