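test_that("a minimal one-residue PDB parses into one residue of five atoms", {
  s <- read_pdb(minimal_ala_pdb())
  expect_s3_class(s, "protein_structure")
  rt <- residue_table(s)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$aa, "A")
  expect_equal(nrow(s$atoms), 5)
  expect_setequal(s$atoms$elety, c("N", "CA", "C", "O", "CB"))
})

test_that("write/read round-trip preserves atoms, names and coordinates", {
  hx <- helix15()
  p <- tempfile(fileext = ".pdb")
  write_pdb(hx, p)
  back <- read_pdb(p)
  expect_equal(nrow(back$atoms), nrow(hx$atoms))
  expect_equal(back$atoms$elety, hx$atoms$elety)
  expect_equal(back$atoms$resno, hx$atoms$resno)
  expect_equal(round(back$atoms$x, 3), round(hx$atoms$x, 3))
  expect_equal(round(back$atoms$y, 3), round(hx$atoms$y, 3))
  expect_equal(round(back$atoms$z, 3), round(hx$atoms$z, 3))

  ## second round trip is exact: ordering is total and deterministic
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(back, p2)
  again <- read_pdb(p2)
  expect_equal(again$atoms[, c("x", "y", "z")], back$atoms[, c("x", "y", "z")])
})

test_that("altloc conformers resolve to highest occupancy, ties to label A", {
  lines <- c(
    pdb_atom_line(1, "N",  "SER", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C",  "SER", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(4, "O",  "SER", "A", 1, 1.25, 2.4, 0),
    pdb_atom_line(5, "CB", "SER", "A", 1, 2.0, -0.8, -1.2, occ = 0.4, alt = "A"),
    pdb_atom_line(6, "CB", "SER", "A", 1, 2.1, -0.7, -1.3, occ = 0.6, alt = "B"),
    pdb_atom_line(7, "OG", "SER", "A", 1, 1.4, -1.9, -1.4, occ = 0.5, alt = "A"),
    pdb_atom_line(8, "OG", "SER", "A", 1, 1.5, -2.0, -1.5, occ = 0.5, alt = "B")
  )
  s <- read_pdb(write_pdb_text(lines))
  expect_equal(nrow(s$atoms), 6)  # exactly one conformer per atom retained
  cb <- s$atoms[s$atoms$elety == "CB", ]
  expect_equal(cb$x, 2.1)   # occupancy 0.6 conformer B wins
  og <- s$atoms[s$atoms$elety == "OG", ]
  expect_equal(og$x, 1.4)   # tie broken toward altloc A
})

test_that("stripping removes waters and ligands, maps MSE to MET, idempotent", {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 1.25, 2.4, 0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, -1.2),
    pdb_atom_line(6, "N",  "MSE", "A", 2, 3.3, 1.5, 0.1, record = "HETATM"),
    pdb_atom_line(7, "CA", "MSE", "A", 2, 4.3, 2.5, 0.2, record = "HETATM"),
    pdb_atom_line(8, "C",  "MSE", "A", 2, 5.6, 1.8, 0.3, record = "HETATM"),
    pdb_atom_line(9, "O",  "MSE", "A", 2, 5.7, 0.6, 0.4, record = "HETATM"),
    pdb_atom_line(10, "CB", "MSE", "A", 2, 4.4, 3.4, -1.0, record = "HETATM"),
    pdb_atom_line(11, "SE", "MSE", "A", 2, 5.0, 5.0, -1.2, record = "HETATM",
                  element = "SE"),
    pdb_atom_line(12, "O",  "HOH", "A", 101, 8, 8, 8, record = "HETATM"),
    pdb_atom_line(13, "O",  "HOH", "A", 102, 9, 9, 9, record = "HETATM"),
    pdb_atom_line(14, "P",  "GMP", "A", 201, -5, -5, -5, record = "HETATM",
                  element = "P")
  )
  s <- read_pdb(write_pdb_text(lines))
  st <- strip_non_protein(s)
  rt <- residue_table(st)
  expect_equal(nrow(rt), 2)                  # waters and GMP gone
  expect_equal(rt$resid, c("ALA", "MET"))    # MSE retained as MET
  se_row <- st$atoms[st$atoms$resno == 2 & st$atoms$elety == "SD", ]
  expect_equal(nrow(se_row), 1)
  expect_equal(se_row$element, "S")

  ## idempotent
  st2 <- strip_non_protein(st)
  expect_equal(st2$atoms, st$atoms)
})

test_that("stripping a structure with no protein residues errors", {
  ## waters recorded as ATOM so the file itself parses
  lines <- c(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "O", "HOH", "A", 2, 3, 3, 3))
  s <- read_pdb(write_pdb_text(lines))
  expect_error(strip_non_protein(s), "no protein content")
  ## and a file with zero ATOM records is rejected at parse time
  het <- c(pdb_atom_line(1, "O", "HOH", "A", 1, 0, 0, 0, record = "HETATM"))
  expect_error(read_pdb(write_pdb_text(het)), "no ATOM records")
})

test_that("residue ordering is deterministic for shuffled record order", {
  hx <- helix15()
  shuffled <- hx$atoms[sample(nrow(hx$atoms)), ]
  s2 <- thermoforest:::new_structure(shuffled, id = "shuffled")
  expect_equal(residue_table(s2)$resno, residue_table(hx)$resno)
  expect_equal(s2$atoms$resno, hx$atoms$resno)
})

test_that("wild-type validation errors on mismatching residue identity", {
  hx <- helix15()
  expect_true(validate_mutant_residue(hx, "A", 5, "A"))
  expect_error(validate_mutant_residue(hx, "A", 5, "W"), "mismatch")
  expect_error(validate_mutant_residue(hx, "A", 99, "A"), "not found")
})
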