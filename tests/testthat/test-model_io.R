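test_that("mmCIF write/read round trip preserves coordinates to 1e-3 A", {
  r <- asymmetric_ring()
  dna <- make_bdna(dna_spec(strrep("ACTG", 5), melted_5prime = 2))
  comb <- combine_models(r$model, dna)
  f <- tempfile(fileext = ".cif")
  write_structure_cif(comb, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(comb$atoms))
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(comb$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  ch <- structure_chains(m2)
  expect_setequal(ch$polymer_kind[ch$chain %in% LETTERS[1:6]], "protein")
  expect_setequal(ch$polymer_kind[ch$chain %in% c("X", "Y")], "dna")
  # identical models give byte-identical files
  f2 <- tempfile(fileext = ".cif")
  write_structure_cif(comb, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("PDB format parses through the same interface", {
  # write a tiny PDB by hand and read it back
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A 105      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  PRO A 330      12.500   1.250  -3.125  1.00  0.00           C",
    "HETATM    3  P    DA B   1       1.000   2.000   3.000  1.00  0.00           P",
    "END"), f)
  m <- read_structure(f)
  expect_equal(m$source_format, "pdb")
  expect_equal(get_calpha(m, "A", 330), c(12.5, 1.25, -3.125))
  expect_true(m$atoms$het[m$atoms$chain == "B"])
})

test_that("multi-model files use the first model with a warning", {
  r <- make_ring(ring_spec(seed = 3L))
  f <- tempfile(fileext = ".cif")
  write_structure_cif(r$model, f)
  lines <- readLines(f)
  body <- grep("^(ATOM|HETATM)", lines, value = TRUE)
  hdr <- lines[seq_len(length(lines) - length(body) - 1L)]
  body2 <- sub(" 1$", " 2", body)
  # second model: same atoms shifted in x by editing the x field
  writeLines(c(hdr, body, body2, "#"), f)
  expect_warning(m <- read_structure(f), "models")
  expect_equal(nrow(m$atoms), length(body))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_x", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA A ALA A 1 5 ? 1.0 0.0 0.0 0.40 0.00 5 A 1",
    "ATOM 2 C CA B ALA A 1 5 ? 2.0 0.0 0.0 0.60 0.00 5 A 1",
    "ATOM 3 C CA A ALA A 1 6 ? 3.0 0.0 0.0 0.50 0.00 6 A 1",
    "ATOM 4 C CA B ALA A 1 6 ? 4.0 0.0 0.0 0.50 0.00 6 A 1"), f)
  m <- read_structure(f)
  expect_equal(get_calpha(m, "A", 5)[1], 2.0)  # higher occupancy wins
  expect_equal(get_calpha(m, "A", 6)[1], 3.0)  # tie -> first in file
})

test_that("lookup errors distinguish absent chains from disordered residues", {
  r <- make_ring(ring_spec(seed = 2L))
  m <- r$model
  expect_equal(get_calpha(m, "A", 1330),
               as.numeric(unlist(m$atoms[m$atoms$chain == "A" &
                                           m$atoms$resno == 1330 &
                                           m$atoms$elety == "CA",
                                         c("x", "y", "z")])))
  expect_error(get_calpha(m, "Q", 1330), "chain 'Q' absent")
  expect_error(get_calpha(m, "A", 9999), "not modeled")
  # drop the ATPase-domain residues of one chain: anchors become unresolvable
  m2 <- m
  m2$atoms <- m2$atoms[!(m2$atoms$chain == "D" & m2$atoms$resno >= 1319), ]
  expect_error(get_calpha(m2, "D", 1330), "not modeled")
  expect_error(read_structure(tempfile(fileext = ".cif")), "not found")
})

test_that("chimera construct numbering maps to deposited numbers injectively", {
  expect_equal(map_chimera_numbering(330, "Pf"), 1330)
  expect_equal(map_chimera_numbering(824, "Pf"), 1824)
  expect_equal(map_chimera_numbering(755, "Pf"), 1755)
  expect_equal(map_chimera_numbering(201, "Sso"), 201)
  expect_equal(map_chimera_numbering(c(257, 361, 729, 966), "Pf"),
               c(1257, 1361, 1729, 1966))
  expect_error(map_chimera_numbering(270, "Sso"), "outside")
  expect_error(map_chimera_numbering(400, "Pf"), "outside")
  expect_error(map_chimera_numbering(0, "Sso"), "outside")
  # injectivity over the full declared domain
  dep <- c(map_chimera_numbering(1:269, "Sso"),
           map_chimera_numbering(c(257:361, 729:966), "Pf"))
  expect_false(anyDuplicated(dep) > 0)
})

test_that("insertion codes are rejected", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  10A     10.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "insertion")
})
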