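# PDBQT input/output and the torsion-tree ligand model.
#
# PDBQT is the AutoDock-family dialect of PDB: fixed-column ATOM/HETATM
# records carrying a partial charge and an AutoDock atom type, and -- for
# ligands -- a ROOT/BRANCH/ENDBRANCH skeleton that decomposes the molecule
# into rigid frames connected by rotatable bonds, closed by a TORSDOF record.

parse_float <- function(s, what, line_no) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) {
    stop(sprintf("parse error at line %d: malformed %s field '%s'",
                 line_no, what, trimws(s)), call. = FALSE)
  }
  v
}

# one ATOM/HETATM record -> named list (PDB fixed columns, 1-based text)
parse_atom_record <- function(line, line_no) {
  pad <- function(x, n) formatC(x, width = n, flag = "-")
  line <- pad(line, 80)
  serial <- suppressWarnings(as.integer(trimws(substr(line, 7, 11))))
  if (is.na(serial)) {
    stop(sprintf("parse error at line %d: malformed serial field", line_no),
         call. = FALSE)
  }
  name <- trimws(substr(line, 13, 16))
  x <- parse_float(substr(line, 31, 38), "x-coordinate", line_no)
  y <- parse_float(substr(line, 39, 46), "y-coordinate", line_no)
  z <- parse_float(substr(line, 47, 54), "z-coordinate", line_no)
  charge <- suppressWarnings(as.numeric(trimws(substr(line, 67, 76))))
  if (is.na(charge)) charge <- 0
  ad_type <- trimws(substr(line, 78, 80))
  if (ad_type == "") ad_type <- trimws(substr(line, 77, 80))
  list(serial = serial, name = name, x = x, y = y, z = z,
       charge = charge, ad_type = ad_type, line_no = line_no)
}

# AutoDock atom-type code -> chemical element
ad_type_element <- function(ad_type, name) {
  t <- toupper(ad_type)
  el <- switch(t,
    "C" = "C", "A" = "C", "CG0" = "C", "CG1" = "C",
    "N" = "N", "NA" = "N", "NS" = "N",
    "O" = "O", "OA" = "O", "OS" = "O",
    "H" = "H", "HD" = "H", "HS" = "H",
    "S" = "S", "SA" = "S",
    "P" = "P", "F" = "F", "CL" = "Cl", "BR" = "Br", "I" = "I",
    NULL)
  if (!is.null(el)) return(el)
  if (t %in% METAL_ELEMENTS) {
    return(paste0(substr(t, 1, 1), tolower(substr(t, 2, nchar(t)))))
  }
  stop(sprintf("unknown atom type '%s' (atom '%s')", ad_type, name),
       call. = FALSE)
}

# distance-threshold bond perception: bonded iff r < 1.15 * (rcov_i + rcov_j).
# Returns a list of integer vectors (neighbours per atom).
perceive_bonds <- function(coords, elements) {
  n <- nrow(coords)
  nb <- vector("list", n)
  if (n < 2) return(nb)
  rcov <- covalent_radius_of_element(elements)
  block <- 512L
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    idx <- s:e
    d2 <- outer(rowSums(coords[idx, , drop = FALSE]^2),
                rowSums(coords^2), "+") -
      2 * coords[idx, , drop = FALSE] %*% t(coords)
    thr2 <- (1.15 * outer(rcov[idx], rcov, "+"))^2
    hit <- which(d2 < thr2 & d2 > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      ii <- idx[hit[, 1]]
      jj <- hit[, 2]
      for (k in seq_along(ii)) nb[[ii[k]]] <- c(nb[[ii[k]]], jj[k])
    }
  }
  lapply(nb, function(v) sort(unique(v)))
}

# assign one of the 15 heavy-atom type codes (or "H") per atom
assign_atom_types <- function(atoms, neighbours) {
  n <- nrow(atoms)
  elements <- atoms$element
  has_h <- vapply(seq_len(n), function(i) {
    any(elements[neighbours[[i]]] == "H")
  }, logical(1))
  hetero_nb <- vapply(seq_len(n), function(i) {
    any(!elements[neighbours[[i]]] %in% c("C", "H"))
  }, logical(1))
  vapply(seq_len(n), function(i) {
    el <- elements[i]
    t <- toupper(atoms$ad_type[i])
    if (el == "H") return("H")
    if (el == "C") return(if (hetero_nb[i]) "C_P" else "C_H")
    if (el == "N") {
      acc <- t %in% c("NA", "NS")
      if (acc && has_h[i]) return("N_DA")
      if (acc) return("N_A")
      if (has_h[i]) return("N_D")
      return("N")
    }
    if (el == "O") return(if (has_h[i]) "O_DA" else "O_A")
    if (el == "S") return("S")
    if (el %in% c("P", "F", "Cl", "Br", "I")) return(el)
    if (toupper(el) %in% METAL_ELEMENTS) return("Met")
    stop(sprintf("unknown atom type '%s' (atom '%s')",
                 atoms$ad_type[i], atoms$name[i]), call. = FALSE)
  }, character(1))
}

atoms_data_frame <- function(records) {
  data.frame(
    serial = vapply(records, `[[`, integer(1) * 1L, "serial"),
    name = vapply(records, `[[`, character(1), "name"),
    ad_type = vapply(records, `[[`, character(1), "ad_type"),
    x = vapply(records, `[[`, numeric(1), "x"),
    y = vapply(records, `[[`, numeric(1), "y"),
    z = vapply(records, `[[`, numeric(1), "z"),
    charge = vapply(records, `[[`, numeric(1), "charge"),
    stringsAsFactors = FALSE
  )
}

#' Parse a PDBQT receptor
#'
#' Reads ATOM/HETATM records, assigns each heavy atom one of the 15
#' heavy-atom types of [atom_type_table()] (hydrogens are kept but flagged),
#' and perceives covalent bonds by a distance threshold so carbons bonded to
#' heteroatoms become polar and nitrogens/oxygens carrying a hydrogen become
#' donors.  Metal ions are typed `Met` and treated as hydrogen-bond donors.
#'
#' @param pdbqt Character: either a path to a `.pdbqt` file or the file
#'   content as a single string / character vector of lines.
#' @return An object of class `receptor`: list with `atoms` (data.frame with
#'   serial, name, element, type, coordinates, charge, `is_hydrogen`) and
#'   `heavy` (row indices of heavy atoms).
#' @export
parse_receptor <- function(pdbqt) {
  lines <- as_pdbqt_lines(pdbqt)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records found", call. = FALSE)
  records <- lapply(which(is_atom), function(i) parse_atom_record(lines[i], i))
  atoms <- atoms_data_frame(records)
  if (anyDuplicated(atoms$serial)) {
    stop("duplicate atom serial numbers in receptor", call. = FALSE)
  }
  atoms$element <- mapply(ad_type_element, atoms$ad_type, atoms$name,
                          USE.NAMES = FALSE)
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  nb <- perceive_bonds(coords, atoms$element)
  atoms$type <- assign_atom_types(atoms, nb)
  atoms$is_hydrogen <- atoms$element == "H"
  structure(list(atoms = atoms, heavy = which(!atoms$is_hydrogen)),
            class = "receptor")
}

as_pdbqt_lines <- function(pdbqt) {
  if (length(pdbqt) == 1 && !grepl("\n", pdbqt) && file.exists(pdbqt)) {
    return(readLines(pdbqt, warn = FALSE))
  }
  unlist(strsplit(pdbqt, "\n", fixed = TRUE), use.names = FALSE)
}

#' @export
print.receptor <- function(x, ...) {
  cat(sprintf("<receptor> %d atoms (%d heavy)\n",
              nrow(x$atoms), length(x$heavy)))
  invisible(x)
}

#' Parse a PDBQT ligand into a torsion-tree template
#'
#' Builds the rigid-frame tree mirroring the ROOT/BRANCH nesting, perceives
#' covalent bonds, classifies each torsion active or inactive (a torsion that
#' moves no heavy atom -- hydroxyl, amine, methyl rotors -- is deactivated so
#' it never enters the optimization variables), and precomputes the
#' intra-molecular interacting heavy-atom pairs: pairs in different frames
#' separated by at least one active torsion and by more than three consecutive
#' covalent bonds (1-4 interactions and closer are excluded).
#'
#' @param pdbqt Path, single string, or character vector of PDBQT lines.
#' @return Object of class `ligand_template`: atoms data.frame, `coords0`
#'   matrix of input coordinates, `frames` list (atom indices, parent, rotor
#'   axis, active flag), torsion counts, `torsdof`, bond list, intra pair
#'   matrix.
#' @export
parse_ligand <- function(pdbqt) {
  lines <- as_pdbqt_lines(pdbqt)
  records <- list()
  frame_of <- integer(0)
  frames <- list()
  stack <- integer(0)
  torsdof <- NA_integer_
  seen_root <- FALSE
  in_root <- FALSE
  serial_to_idx <- function(serial, atoms) match(serial, atoms$serial)

  for (i in seq_along(lines)) {
    line <- lines[i]
    key <- sub("\\s.*$", "", line)
    if (key %in% c("ATOM", "HETATM")) {
      if (length(stack) == 0) {
        stop(sprintf("structural error at line %d: atom outside ROOT/BRANCH",
                     i), call. = FALSE)
      }
      records[[length(records) + 1L]] <- parse_atom_record(line, i)
      frame_of[length(records)] <- stack[length(stack)]
    } else if (key == "ROOT") {
      seen_root <- TRUE
      frames[[1L]] <- list(parent = NA_integer_, axis_serial = NULL)
      stack <- 1L
    } else if (key == "ENDROOT") {
      if (length(stack) != 1) {
        stop("structural error: ENDROOT inside BRANCH", call. = FALSE)
      }
      # root frame stays on the stack conceptually; BRANCHes re-attach below
    } else if (key == "BRANCH") {
      ab <- suppressWarnings(as.integer(strsplit(trimws(line), "\\s+")[[1]][2:3]))
      if (anyNA(ab)) {
        stop(sprintf("structural error at line %d: malformed BRANCH record", i),
             call. = FALSE)
      }
      parent <- stack[length(stack)]
      frames[[length(frames) + 1L]] <- list(parent = parent, axis_serial = ab)
      stack <- c(stack, length(frames))
    } else if (key == "ENDBRANCH") {
      if (length(stack) <= 1) {
        stop(sprintf("structural error at line %d: unmatched ENDBRANCH", i),
             call. = FALSE)
      }
      stack <- stack[-length(stack)]
    } else if (key == "TORSDOF") {
      torsdof <- suppressWarnings(as.integer(strsplit(trimws(line), "\\s+")[[1]][2]))
    }
  }
  if (!seen_root) stop("structural error: missing ROOT record", call. = FALSE)
  if (length(stack) != 1) {
    stop("structural error: unmatched BRANCH record(s)", call. = FALSE)
  }
  if (length(records) == 0) stop("ligand has no atoms", call. = FALSE)

  atoms <- atoms_data_frame(records)
  atoms$element <- mapply(ad_type_element, atoms$ad_type, atoms$name,
                          USE.NAMES = FALSE)
  atoms$frame <- frame_of
  coords0 <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(coords0) <- NULL
  nb <- perceive_bonds(coords0, atoms$element)
  atoms$type <- assign_atom_types(atoms, nb)
  atoms$is_hydrogen <- atoms$element == "H"

  for (f in seq_along(frames)) {
    frames[[f]]$atoms <- which(frame_of == f)
    ab <- frames[[f]]$axis_serial
    if (!is.null(ab)) {
      ai <- match(ab, atoms$serial)
      if (anyNA(ai)) {
        stop(sprintf("structural error: BRANCH %d %d names unknown serial",
                     ab[1], ab[2]), call. = FALSE)
      }
      frames[[f]]$axis_idx <- ai
    }
  }

  tpl <- structure(
    list(atoms = atoms, coords0 = coords0, frames = frames,
         bonds = nb, torsdof = torsdof,
         n_heavy = sum(!atoms$is_hydrogen)),
    class = "ligand_template")
  tpl <- detect_inactive_torsions(tpl)
  tpl$one_four_exclusions <- build_one_four_exclusions(tpl)
  tpl$intra_pairs <- build_intra_pairs(tpl)
  tpl <- cache_template_statics(tpl)
  tpl
}

# precompute everything the search loop needs per evaluation: heavy-atom
# indices and type columns, the root anchor, per-active-frame subtree atoms
cache_template_statics <- function(tpl) {
  heavy <- which(!tpl$atoms$is_hydrogen)
  tpl$heavy_idx <- heavy
  tpl$heavy_types <- tpl$atoms$type[heavy]
  tpl$heavy_type_idx <- type_code_to_index(tpl$heavy_types)
  tpl$root_anchor <- {
    ra <- tpl$frames[[1]]$atoms
    h <- ra[!tpl$atoms$is_hydrogen[ra]]
    if (!length(h)) h <- ra
    colMeans(tpl$coords0[h, , drop = FALSE])
  }
  act <- which(vapply(tpl$frames, function(f) isTRUE(f$active), logical(1)))
  tpl$active_ids <- act
  tpl$active_sub_heavy <- lapply(act, function(f) {
    sub_atoms <- unlist(lapply(frame_subtree(tpl$frames, f),
                               function(g) tpl$frames[[g]]$atoms))
    match(intersect(sub_atoms, heavy), heavy)
  })
  if (nrow(tpl$intra_pairs)) {
    pr <- tpl$intra_pairs
    ti <- type_code_to_index(tpl$atoms$type[pr[, 1]])
    tj <- type_code_to_index(tpl$atoms$type[pr[, 2]])
    tpl$intra_pair_idx <- pair_index(ti, tj)
    tpl$intra_hpos <- cbind(match(pr[, 1], heavy), match(pr[, 2], heavy))
  }
  tpl
}

frame_children <- function(frames) {
  kids <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    p <- frames[[f]]$parent
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], f)
  }
  kids
}

frame_subtree <- function(frames, f) {
  kids <- frame_children(frames)
  out <- integer(0)
  todo <- f
  while (length(todo)) {
    cur <- todo[1]
    todo <- todo[-1]
    out <- c(out, cur)
    todo <- c(todo, kids[[cur]])
  }
  out
}

#' Deactivate torsions that move no heavy atom
#'
#' A torsion whose whole subtree contains no heavy atom other than the axis
#' atom itself (which lies on the rotation axis and therefore does not move)
#' only rotates hydrogens and has no effect on the score; it is reclassified
#' inactive during parsing so the optimizer never sees it.  The operation is
#' pure and idempotent.
#'
#' @param template A `ligand_template`.
#' @return The template with `active` flags and `n_active` / `n_inactive`
#'   counts set.
#' @export
detect_inactive_torsions <- function(template) {
  frames <- template$frames
  heavy <- !template$atoms$is_hydrogen
  for (f in seq_along(frames)) {
    if (is.na(frames[[f]]$parent)) {
      frames[[f]]$active <- NA
      next
    }
    sub_atoms <- unlist(lapply(frame_subtree(frames, f),
                               function(g) frames[[g]]$atoms))
    movers <- setdiff(sub_atoms[heavy[sub_atoms]], frames[[f]]$axis_idx[2])
    frames[[f]]$active <- length(movers) > 0
  }
  template$frames <- frames
  act <- vapply(frames, function(fr) isTRUE(fr$active), logical(1))
  inact <- vapply(frames, function(fr) isFALSE(fr$active), logical(1))
  template$n_active <- sum(act)
  template$n_inactive <- sum(inact)
  template
}

# heavy-atom pairs separated by <= 3 consecutive covalent bonds (1-4 and
# closer); stored as a symmetric logical via a sorted two-column matrix
build_one_four_exclusions <- function(template) {
  nb <- template$bonds
  n <- length(nb)
  heavy <- which(!template$atoms$is_hydrogen)
  excl <- list()
  for (a in heavy) {
    # BFS to depth 3
    depth <- rep.int(NA_integer_, n)
    depth[a] <- 0L
    frontier <- a
    for (d in 1:3) {
      nxt <- setdiff(unique(unlist(nb[frontier])), which(!is.na(depth)))
      if (!length(nxt)) break
      depth[nxt] <- d
      frontier <- nxt
    }
    near <- which(!is.na(depth) & depth > 0L)
    near <- near[near %in% heavy & near > a]
    if (length(near)) excl[[length(excl) + 1L]] <- cbind(a, near)
  }
  if (!length(excl)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, excl)
  dimnames(m) <- NULL
  m
}

# frames separated by at least one ACTIVE torsion can move relative to each
# other; build the heavy-atom pair list used by the intra-molecular score
build_intra_pairs <- function(template) {
  frames <- template$frames
  nf <- length(frames)
  # ancestor chains with activity flags
  chain <- lapply(seq_len(nf), function(f) {
    path <- integer(0)
    while (!is.na(f)) {
      path <- c(path, f)
      f <- frames[[f]]$parent
    }
    path
  })
  movable <- matrix(FALSE, nf, nf)
  for (f in seq_len(nf)) {
    for (g in seq_len(nf)) {
      if (f >= g) next
      cf <- chain[[f]]
      cg <- chain[[g]]
      common <- max(intersect(cf, cg))
      edges <- c(cf[seq_len(which(cf == common) - 1L)],
                 cg[seq_len(which(cg == common) - 1L)])
      movable[f, g] <- movable[g, f] <-
        any(vapply(edges, function(e) isTRUE(frames[[e]]$active), logical(1)))
    }
  }
  heavy <- which(!template$atoms$is_hydrogen)
  fr <- template$atoms$frame
  pairs <- list()
  excl <- template$one_four_exclusions
  excl_key <- if (nrow(excl)) excl[, 1] * 1e6 + excl[, 2] else numeric(0)
  for (i in seq_along(heavy)) {
    for (j in seq_along(heavy)) {
      if (j <= i) next
      a <- heavy[i]; b <- heavy[j]
      if (fr[a] == fr[b]) next
      if (!movable[fr[a], fr[b]]) next
      if ((a * 1e6 + b) %in% excl_key) next
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf(
    "<ligand_template> %d atoms (%d heavy), %d torsions (%d active, %d inactive), TORSDOF %s\n",
    nrow(x$atoms), x$n_heavy, length(x$frames) - 1L,
    x$n_active, x$n_inactive, x$torsdof))
  invisible(x)
}

format_atom_line <- function(record, x, y, z, energy = NA, charge = 0) {
  base <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  "ATOM", record$serial,
                  formatC(substr(record$name, 1, 4), width = 4, flag = "-"),
                  "", "LIG", "A", 1L, x, y, z, 1.00, 0.00)
  if (is.na(energy)) {
    line <- sprintf("%s%10.3f", base, charge)      # charge in 67-76
  } else {
    e <- max(min(energy, 999.99), -99.99)          # clamp to printable range
    line <- sprintf("%s    %6.2f", base, e)        # energy right-aligned 71-76
  }
  sprintf("%-76s %-2s", line, record$ad_type)
}

#' Write docked poses as multi-MODEL PDBQT
#'
#' Emits one MODEL block per pose with the torsion-tree skeleton preserved.
#' REMARK lines come first: the nine-descriptor property line, SMILES and
#' supplier pass-through metadata when given, then per-pose REMARKs with the
#' predicted free energy (kcal/mol), ligand efficiency (kcal/mol per heavy
#' atom), putative hydrogen bonds, the random-forest rescored affinity and the
#' consensus score (pKd units) when present.  Columns 71-76 of each ATOM line
#' carry that atom's inter-molecular free-energy contribution, right-aligned,
#' clamped to the printable F6.2 range.
#'
#' @param template A `ligand_template`.
#' @param poses List of poses as returned by [monte_carlo_dock()]; each has
#'   `coords`, `energy_kcal`, a `breakdown` with `per_atom_inter`, optional
#'   `rf_pkd`, `consensus_pkd`, `hbonds`.
#' @param metadata Optional named list: `properties` (named numeric vector of
#'   the nine descriptors), `smiles`, `suppliers` (character vector).
#' @return The PDBQT text as a single string.
#' @export
write_docked_pdbqt <- function(template, poses, metadata = NULL) {
  out <- character(0)
  if (!is.null(metadata$properties)) {
    p <- metadata$properties
    out <- c(out, paste("REMARK 901 PROPERTIES",
                        paste(names(p), format(unname(p), trim = TRUE),
                              collapse = " ")))
  }
  if (!is.null(metadata$smiles)) {
    out <- c(out, paste("REMARK 902 SMILES", metadata$smiles))
  }
  if (!is.null(metadata$suppliers)) {
    out <- c(out, paste("REMARK 903 SUPPLIERS", length(metadata$suppliers),
                        paste(metadata$suppliers, collapse = " ")))
  }
  atoms <- template$atoms
  n_atoms <- nrow(atoms)
  records <- lapply(seq_len(n_atoms), function(i) {
    list(serial = atoms$serial[i], name = atoms$name[i],
         ad_type = atoms$ad_type[i])
  })

  for (m in seq_along(poses)) {
    pose <- poses[[m]]
    if (nrow(pose$coords) != n_atoms) {
      stop(sprintf("pose %d has %d atoms but template has %d",
                   m, nrow(pose$coords), n_atoms), call. = FALSE)
    }
    out <- c(out, sprintf("MODEL %8d", m))
    out <- c(out, sprintf("REMARK 911 FREE ENERGY PREDICTED: %8.3f KCAL/MOL",
                          pose$energy_kcal))
    le <- pose$energy_kcal / template$n_heavy
    out <- c(out, sprintf(
      "REMARK 912 LIGAND EFFICIENCY PREDICTED: %8.3f KCAL/MOL/HEAVYATOM", le))
    if (!is.null(pose$hbonds) && nrow(pose$hbonds)) {
      hb <- apply(pose$hbonds, 1, function(r) {
        sprintf("%s:%s=%.2f", r[["receptor_serial"]], r[["ligand_serial"]],
                as.numeric(r[["distance"]]))
      })
      out <- c(out, paste("REMARK 913 PUTATIVE HYDROGEN BONDS:",
                          paste(hb, collapse = " ")))
    } else {
      out <- c(out, "REMARK 913 PUTATIVE HYDROGEN BONDS: NONE")
    }
    if (!is.null(pose$rf_pkd)) {
      out <- c(out, sprintf(
        "REMARK 914 BINDING AFFINITY PREDICTED BY RF-SCORE: %8.3f PKD", pose$rf_pkd))
    }
    if (!is.null(pose$consensus_pkd)) {
      out <- c(out, sprintf("REMARK 915 CONSENSUS SCORE: %8.3f PKD",
                            pose$consensus_pkd))
    }
    per_atom <- rep(NA_real_, n_atoms)
    if (!is.null(pose$breakdown$per_atom_inter)) {
      heavy_idx <- which(!atoms$is_hydrogen)
      per_atom[heavy_idx] <- pose$breakdown$per_atom_inter
    }
    # re-emit the torsion-tree skeleton around the atoms of each frame
    out <- c(out, emit_tree_lines(template, pose$coords, records, per_atom))
    out <- c(out, "ENDMDL")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

emit_tree_lines <- function(template, coords, records, per_atom) {
  frames <- template$frames
  kids <- frame_children(frames)
  lines <- character(0)
  emit_frame <- function(f) {
    fr <- frames[[f]]
    if (is.na(fr$parent)) {
      lines <<- c(lines, "ROOT")
    } else {
      lines <<- c(lines, sprintf("BRANCH %3d %3d",
                                 fr$axis_serial[1], fr$axis_serial[2]))
    }
    for (i in fr$atoms) {
      lines <<- c(lines, format_atom_line(records[[i]], coords[i, 1],
                                          coords[i, 2], coords[i, 3],
                                          energy = per_atom[i],
                                          charge = template$atoms$charge[i]))
    }
    if (is.na(fr$parent)) lines <<- c(lines, "ENDROOT")
    for (k in kids[[f]]) emit_frame(k)
    if (!is.na(fr$parent)) {
      lines <<- c(lines, sprintf("ENDBRANCH %3d %3d",
                                 fr$axis_serial[1], fr$axis_serial[2]))
    }
  }
  emit_frame(1L)
  c(lines, sprintf("TORSDOF %d",
                   if (is.na(template$torsdof)) template$n_active + template$n_inactive
                   else template$torsdof))
}
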