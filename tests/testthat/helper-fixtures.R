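# Shared in-code fixtures: tiny PDBQT texts and lazily cached heavy objects.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

small_table <- function() {
  cached("table2k", function() precalculate_table(n_samples = 2048L))
}

funnel_rigid <- function() {
  cached("funnel_rigid", function() make_funnel_complex(fixture_spec(seed = 1)))
}

funnel_maps <- function() {
  cached("funnel_maps", function() {
    fx <- funnel_rigid()
    build_grid_maps(fx$receptor, fx$box, small_table(),
                    unique(fx$template$atoms$type))
  })
}

pdbqt_atom <- function(serial, name, x, y, z, ad_type, res = "LIG") {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          "ATOM", serial, substr(name, 1, 4), res, "A", 1L,
          x, y, z, 1.00, 0.00, 0.000, ad_type)
}

# three heavy atoms: C, N, O
toy_receptor_text <- function() {
  paste(c(pdbqt_atom(1, "C1", 0, 0, 0, "C", "REC"),
          pdbqt_atom(2, "N1", 3, 0, 0, "N", "REC"),
          pdbqt_atom(3, "O1", 0, 3, 0, "OA", "REC")),
        collapse = "\n")
}

# receptor containing a zinc ion
metal_receptor_text <- function() {
  paste(c(pdbqt_atom(1, "C1", 0, 0, 0, "C", "REC"),
          pdbqt_atom(2, "ZN", 4, 0, 0, "Zn", "REC")),
        collapse = "\n")
}

# ethanol-like ligand: C-C-O(-H), single BRANCH rotating only the hydroxyl H
ethanol_ligand_text <- function() {
  paste(c(
    "ROOT",
    pdbqt_atom(1, "C1", 0, 0, 0, "C"),
    pdbqt_atom(2, "C2", 1.54, 0, 0, "C"),
    pdbqt_atom(3, "O1", 2.25, 1.21, 0, "OA"),
    "ENDROOT",
    "BRANCH 3 4",
    pdbqt_atom(4, "HO", 3.21, 1.10, 0, "HD"),
    "ENDBRANCH 3 4",
    "TORSDOF 1"), collapse = "\n")
}

# a BRANCH whose hydroxyl hydrogen hangs off the in-branch oxygen: the
# oxygen sits on the rotor axis, so the torsion moves hydrogens only
hydroxyl_axis_ligand_text <- function() {
  paste(c(
    "ROOT",
    pdbqt_atom(1, "C1", 0, 0, 0, "C"),
    pdbqt_atom(2, "C2", 1.54, 0, 0, "C"),
    "ENDROOT",
    "BRANCH 2 3",
    pdbqt_atom(3, "O1", 2.25, 1.21, 0, "OA"),
    pdbqt_atom(4, "HO", 3.19, 1.15, 0.1, "HD"),
    "ENDBRANCH 2 3",
    "TORSDOF 1"), collapse = "\n")
}

# methyl branch: three hydrogens around an axis carbon
methyl_ligand_text <- function() {
  paste(c(
    "ROOT",
    pdbqt_atom(1, "C1", 0, 0, 0, "C"),
    pdbqt_atom(2, "C2", 1.54, 0, 0, "C"),
    "ENDROOT",
    "BRANCH 2 3",
    pdbqt_atom(3, "C3", 2.31, 1.33, 0, "C"),
    pdbqt_atom(4, "H1", 3.01, 1.33, 0.89, "H"),
    pdbqt_atom(5, "H2", 3.01, 1.33, -0.89, "H"),
    pdbqt_atom(6, "H3", 1.61, 2.22, 0, "H"),
    "ENDBRANCH 2 3",
    "TORSDOF 1"), collapse = "\n")
}

# branch carrying one heavy chlorine: must stay active
chloro_ligand_text <- function() {
  paste(c(
    "ROOT",
    pdbqt_atom(1, "C1", 0, 0, 0, "C"),
    pdbqt_atom(2, "C2", 1.54, 0, 0, "C"),
    "ENDROOT",
    "BRANCH 2 3",
    pdbqt_atom(3, "C3", 2.31, 1.33, 0, "C"),
    pdbqt_atom(4, "CL1", 3.55, 2.40, 0, "Cl"),
    "ENDBRANCH 2 3",
    "TORSDOF 1"), collapse = "\n")
}

# biphenyl-like: BRANCH moving a 6-heavy-atom ring (planar hexagon)
biphenyl_ligand_text <- function() {
  ring <- function(cx, start_serial, start_deg = 0) {
    ang <- (start_deg + seq(0, 300, by = 60)) * pi / 180
    vapply(seq_along(ang), function(k) {
      pdbqt_atom(start_serial + k - 1L, sprintf("C%d", start_serial + k - 1L),
                 cx + 1.4 * cos(ang[k]), 1.4 * sin(ang[k]), 0, "A")
    }, character(1))
  }
  paste(c("ROOT", ring(0, 1), "ENDROOT",
          "BRANCH 1 7",
          ring(4.2, 7, 180),
          "ENDBRANCH 1 7",
          "TORSDOF 1"), collapse = "\n")
}
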