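# Reading, altloc resolution, sequence extraction and PDB round-trips.

make_pdb_lines <- function() {
  c("HEADER    HYDROLASE                               01-JAN-20   2GKG",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.00 ANGSTROMS.",
    sprintf("ATOM  %5d  CA  ALA A%4d       %5.3f   0.000   0.000  1.00 10.00           C",
            1:10, 1:10, (1:10) * 3.8),
    "HETATM   11  O   HOH A 101       9.000   9.000   9.000  1.00 20.00           O",
    "HETATM   12  S   SO4 A 102       5.000   5.000   5.000  1.00 20.00           S",
    "END")
}

test_that("PDB files parse with metadata, polymer/het partition and waters separated", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(), f)
  m <- read_structure(f)
  expect_equal(m$metadata$entry_id, "2GKG")
  expect_equal(m$metadata$method, "X-RAY DIFFRACTION")
  expect_equal(m$metadata$resolution, 1.0)
  expect_equal(sum(m$atoms$is_polymer), 10)
  expect_equal(sum(m$atoms$is_water), 1)
  het <- residue_table(m$atoms)
  expect_equal(sum(!het$is_polymer & !het$is_water), 1)  # SO4 only
  # atom count oracle: ATOM/HETATM line count
  n_lines <- sum(grepl("^(ATOM|HETATM)", readLines(f)))
  expect_equal(nrow(m$atoms), n_lines)
})

test_that("refinement resolution is preferred over REMARK 2 when both exist", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
               "REMARK   3   RESOLUTION RANGE HIGH (ANGSTROMS) : 1.60",
               make_pdb_lines()[4:13]), f)
  expect_equal(read_structure(f)$metadata$resolution, 1.6)
})

test_that("a file with only waters raises an empty-structure error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00 20.00           O",
               "END"), f)
  expect_error(read_structure(f), "no polymer residues")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("mmCIF files parse with refine resolution and method", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TST1",
    "_entry.id TST1",
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_d_res_high 1.25",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d C CA . GLY A 1 %d ? %.3f 0.000 0.000 1.00 15.00 ? %d GLY A CA 1",
            1:4, 1:4, (1:4) * 3.8, 1:4)), f)
  m <- read_structure(f)
  expect_equal(m$metadata$resolution, 1.25)
  expect_equal(sum(m$atoms$is_polymer), 4)
  expect_equal(polymer_sequence(get_chain(m, "A")), "GGGG")
})

test_that("altloc resolution keeps the highest occupancy and breaks ties by altloc order", {
  df <- data.frame(chain = "A", resno = c(1, 1, 1, 2), resname = "ALA",
                   name = c("CA", "CA", "CB", "CA"), element = "C",
                   x = c(0, 0.5, 1, 3.8), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  m <- points_model(df)
  m$atoms$altloc <- c("A", "B", "", "")
  m$atoms$occ <- c(0.4, 0.6, 1, 1)
  r <- resolve_altlocs(m)
  expect_equal(nrow(r$atoms), 3)
  expect_equal(r$atoms$x[r$atoms$name == "CA" & r$atoms$resno == 1], 0.5)
  # tie at equal occupancy -> altloc 'A' wins
  m$atoms$occ <- c(0.5, 0.5, 1, 1)
  r2 <- resolve_altlocs(m)
  expect_equal(r2$atoms$x[r2$atoms$name == "CA" & r2$atoms$resno == 1], 0)
  # no altlocs -> identity
  m2 <- points_model(df)
  expect_identical(resolve_altlocs(m2)$atoms, m2$atoms)
})

test_that("polymer sequence maps standard, modified and unknown residues", {
  df <- data.frame(chain = "A", resno = 1:3,
                   resname = c("ALA", "MSE", "XYZ"), name = "CA",
                   element = "C", x = (1:3) * 3.8, y = 0, z = 0,
                   stringsAsFactors = FALSE)
  m <- points_model(df)
  m$atoms$is_polymer <- TRUE
  expect_equal(polymer_sequence(get_chain(m, "A")), "AMX")
  h <- make_ideal_helix(10)
  expect_equal(polymer_sequence(get_chain(h, "A")), "AAAAAAAAAA")
})

test_that("write/read PDB round-trip preserves counts and coordinates to 3 decimals", {
  m <- make_compact_bundle(25, 6.3, seed = 11, sequence = "random")
  m <- add_het_ligand(add_water(plant_disulfide(m, 4, 12)), "GOL")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(residue_table(m2$atoms)$resname, residue_table(m$atoms)$resname)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(m2$atoms$y, m$atoms$y, tolerance = 1e-3)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 1e-3)
  expect_equal(m2$metadata$resolution, m$metadata$resolution)
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, f2)
  expect_identical(readLines(f), readLines(f2))
})
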