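# PDBQT parsing, atom typing, torsion-tree construction, writing.

test_that("receptor parsing assigns the 15-type taxonomy and keeps hydrogens flagged", {
  rec <- parse_receptor(toy_receptor_text())
  expect_s3_class(rec, "receptor")
  expect_equal(nrow(rec$atoms), 3)
  expect_length(rec$heavy, 3)
  expect_equal(rec$atoms$type, c("C_H", "N", "O_A"))

  tab <- atom_type_table()
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$vdw_radius > 0))
  # metal ions are hydrogen-bond donors
  expect_true(tab["Met", "is_hbond_donor"])
})

test_that("a metal ion is typed as the donor metal class", {
  rec <- parse_receptor(metal_receptor_text())
  zn <- rec$atoms[rec$atoms$name == "ZN", ]
  expect_equal(zn$type, "Met")
  expect_true(atom_type_table()[zn$type, "is_hbond_donor"])
})

test_that("malformed records raise typed errors citing the line", {
  bad_coord <- sub("   0.000   0.000", "  xx.yyy   0.000",
                   pdbqt_atom(1, "C1", 0, 0, 0, "C"), fixed = TRUE)
  expect_error(parse_receptor(bad_coord), "line 1.*coordinate")
  bad_type <- pdbqt_atom(1, "Q1", 0, 0, 0, "Qq")
  expect_error(parse_receptor(bad_type), "unknown atom type 'Qq'")
  expect_error(parse_receptor("REMARK nothing here"), "no ATOM")
})

test_that("ligand parsing mirrors BRANCH nesting and counts torsions", {
  lig <- parse_ligand(paste(c("ROOT", pdbqt_atom(1, "C1", 0, 0, 0, "C"),
                              pdbqt_atom(2, "C2", 1.5, 0, 0, "C"),
                              "ENDROOT", "TORSDOF 0"), collapse = "\n"))
  expect_equal(lig$n_active, 0)
  expect_equal(lig$n_inactive, 0)
  expect_length(lig$frames, 1)

  bi <- parse_ligand(biphenyl_ligand_text())
  expect_equal(bi$n_active, 1)
  expect_equal(bi$n_inactive, 0)
  expect_equal(bi$n_heavy, 12)
})

test_that("structural errors are rejected", {
  expect_error(parse_ligand(paste(c(pdbqt_atom(1, "C1", 0, 0, 0, "C"),
                                    "TORSDOF 0"), collapse = "\n")),
               "ROOT")
  unmatched <- paste(c("ROOT", pdbqt_atom(1, "C1", 0, 0, 0, "C"), "ENDROOT",
                       "BRANCH 1 2", pdbqt_atom(2, "C2", 1.5, 0, 0, "C"),
                       "TORSDOF 1"), collapse = "\n")
  expect_error(parse_ligand(unmatched), "unmatched BRANCH")
})

test_that("hydrogen-only torsions are deactivated; heavy-moving ones stay active", {
  # hydroxyl branch: O on the rotor axis, only H moves
  oh <- parse_ligand(hydroxyl_axis_ligand_text())
  expect_equal(oh$n_active, 0)
  expect_equal(oh$n_inactive, 1)

  # methyl branch: axis carbon plus three hydrogens
  me <- parse_ligand(methyl_ligand_text())
  expect_equal(me$n_active, 0)
  expect_equal(me$n_inactive, 1)

  # chlorine in the branch: a heavy atom moves
  cl <- parse_ligand(chloro_ligand_text())
  expect_equal(cl$n_active, 1)
  expect_equal(cl$n_inactive, 0)

  # idempotence
  again <- detect_inactive_torsions(me)
  expect_equal(again$n_active, me$n_active)
  expect_equal(again$n_inactive, me$n_inactive)
  expect_equal(vapply(again$frames, function(f) isTRUE(f$active), logical(1)),
               vapply(me$frames, function(f) isTRUE(f$active), logical(1)))
})

test_that("inactive-torsion classification matches the brute-force rotation oracle", {
  for (txt in list(hydroxyl_axis_ligand_text(), methyl_ligand_text(),
                   chloro_ligand_text(), biphenyl_ligand_text())) {
    tpl <- parse_ligand(txt)
    heavy <- which(!tpl$atoms$is_hydrogen)
    branch_frames <- which(!vapply(tpl$frames, function(f) is.na(f$parent),
                                   logical(1)))
    for (f in branch_frames) {
      # oracle: force the torsion active, rotate by several angles, ask
      # whether any heavy atom actually moves
      tf <- tpl
      tf$frames[[f]]$active <- TRUE
      tf$n_active <- sum(vapply(tf$frames, function(fr) isTRUE(fr$active),
                                logical(1)))
      base <- realize(tf, identity_conformation(tf))
      act_ids <- which(vapply(tf$frames, function(fr) isTRUE(fr$active),
                              logical(1)))
      k <- match(f, act_ids)
      moved <- FALSE
      for (ang in c(pi / 3, pi / 2, pi)) {
        conf <- identity_conformation(tf)
        conf$torsions[k] <- ang
        delta <- realize(tf, conf)[heavy, , drop = FALSE] -
          base[heavy, , drop = FALSE]
        if (max(abs(delta)) > 1e-9) moved <- TRUE
      }
      expect_identical(isTRUE(tpl$frames[[f]]$active), moved)
    }
  }
})

test_that("every atom belongs to exactly one torsion-tree frame", {
  for (txt in list(ethanol_ligand_text(), biphenyl_ligand_text(),
                   funnel_rigid()$ligand_pdbqt)) {
    tpl <- parse_ligand(txt)
    membership <- unlist(lapply(tpl$frames, `[[`, "atoms"))
    expect_setequal(membership, seq_len(nrow(tpl$atoms)))
    expect_equal(length(membership), nrow(tpl$atoms))
  }
})

test_that("1-4 exclusions contain bonded-path pairs up to three bonds", {
  tpl <- parse_ligand(chloro_ligand_text())
  ex <- tpl$one_four_exclusions
  key <- paste(ex[, 1], ex[, 2])
  # chain C1-C2-C3-Cl: 1-2 (1 bond), 1-3 (2), 1-4 (3 bonds) all excluded
  expect_true("1 2" %in% key)
  expect_true("1 3" %in% key)
  expect_true("1 4" %in% key)
  # symmetric storage convention: first index < second
  expect_true(all(ex[, 1] < ex[, 2]))
})

test_that("docked PDBQT output prints per-atom energies in columns 71-76", {
  tpl <- parse_ligand(paste(c("ROOT", pdbqt_atom(1, "C1", 0, 0, 0, "C"),
                              pdbqt_atom(2, "C2", 1.5, 0, 0, "C"),
                              "ENDROOT", "TORSDOF 0"), collapse = "\n"))
  pose <- list(conf = identity_conformation(tpl), coords = tpl$coords0,
               energy_kcal = -1.5,
               breakdown = list(per_atom_inter = c(-0.5, 1.25)),
               hbonds = NULL)
  txt <- write_docked_pdbqt(tpl, list(pose))
  atom_lines <- grep("^ATOM", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_equal(substr(atom_lines[1], 71, 76), " -0.50")
  expect_equal(substr(atom_lines[2], 71, 76), "  1.25")
})

test_that("zero poses give header REMARKs only, and atom-count mismatch errors", {
  tpl <- parse_ligand(ethanol_ligand_text())
  txt <- write_docked_pdbqt(tpl, list(),
                            metadata = list(properties = c(mwt = 46.07)))
  expect_false(grepl("MODEL", txt))
  expect_true(grepl("REMARK 901", txt))

  bad <- list(conf = identity_conformation(tpl),
              coords = tpl$coords0[1:2, , drop = FALSE], energy_kcal = 0,
              breakdown = list(per_atom_inter = numeric(2)))
  expect_error(write_docked_pdbqt(tpl, list(bad)), "template has")
})

test_that("write -> parse round trip preserves coordinates, types and topology", {
  fx <- funnel_rigid()
  for (txt in list(ethanol_ligand_text(), chloro_ligand_text(),
                   fx$ligand_pdbqt)) {
    tpl <- parse_ligand(txt)
    heavy <- which(!tpl$atoms$is_hydrogen)
    pose <- list(conf = identity_conformation(tpl), coords = tpl$coords0,
                 energy_kcal = -1,
                 breakdown = list(per_atom_inter = numeric(length(heavy))))
    out <- write_docked_pdbqt(tpl, list(pose))
    body <- strsplit(out, "\n")[[1]]
    body <- body[(grep("^MODEL", body) + 1):(grep("^ENDMDL", body) - 1)]
    back <- parse_ligand(paste(body, collapse = "\n"))
    expect_equal(back$coords0, tpl$coords0, tolerance = 1e-3)
    expect_equal(back$atoms$type, tpl$atoms$type)
    expect_equal(back$n_active, tpl$n_active)
    expect_equal(back$n_inactive, tpl$n_inactive)
    expect_equal(vapply(back$frames, `[[`, integer(1) * NA_integer_, "parent"),
                 vapply(tpl$frames, `[[`, integer(1) * NA_integer_, "parent"))
  }
})
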