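test_that("a minimal PDB parses into the expected hierarchy", {
  s <- read_structure(mini_pdb())
  expect_s3_class(s, "rna_structure")
  expect_length(residue_keys(s), 1L)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$elety, c("P", "C1'", "O5'"))
  expect_equal(s$atoms$x, c(1, 2.5, 3))
})

test_that("legacy star atom names are normalized to primes", {
  s <- read_structure(mini_pdb(names = c("P", "C1*", "O5'")))
  expect_true("C1'" %in% s$atoms$elety)
  expect_false(any(grepl("*", s$atoms$elety, fixed = TRUE)))
})

test_that("altLoc duplicates resolve to the highest occupancy, ties alphabetically", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "C1'", "G", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 5, 5, 5, o = 0.6, alt = "A",
                  elesy = "O"),
    pdb_atom_line(4, "O5'", "G", "A", 1, 6, 6, 6, o = 0.4, alt = "B",
                  elesy = "O")))
  s <- read_structure(p)
  expect_equal(sum(s$atoms$elety == "O5'"), 1L)
  expect_equal(s$atoms$x[s$atoms$elety == "O5'"], 5)

  p2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "O5'", "G", "A", 1, 9, 9, 9, o = 0.5, alt = "B",
                  elesy = "O"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 5, 5, 5, o = 0.5, alt = "A",
                  elesy = "O")))
  s2 <- read_structure(p2)
  expect_equal(s2$atoms$x[s2$atoms$elety == "O5'"], 5)
})

test_that("hydrogen and HETATM filters default off and nest monotonically", {
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "C1'", "G", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "H5'", "G", "A", 1, 2, 2, 2, elesy = "H"),
    pdb_atom_line(4, "O", "HOH", "A", 90, 8, 8, 8, elesy = "O",
                  record = "HETATM")))
  s0 <- read_structure(p)
  expect_equal(nrow(s0$atoms), 2L)
  sh <- read_structure(p, include_hydrogens = TRUE)
  sx <- read_structure(p, include_hydrogens = TRUE, include_hetero = TRUE)
  expect_true(all(s0$atoms$atom_key %in% sh$atoms$atom_key))
  expect_true(all(sh$atoms$atom_key %in% sx$atoms$atom_key))
  expect_equal(nrow(sx$atoms), 4L)
})

test_that("only the requested MODEL block is read", {
  p <- write_pdb_fixture(c(
    "MODEL        1",
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "C1'", "G", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 2, 2, 2, elesy = "O"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "P", "G", "A", 1, 10, 10, 10, elesy = "P"),
    pdb_atom_line(2, "C1'", "G", "A", 1, 11, 11, 11, elesy = "C"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 12, 12, 12, elesy = "O"),
    "ENDMDL"))
  expect_equal(read_structure(p)$atoms$x[1], 0)
  expect_equal(read_structure(p, model_index = 2)$atoms$x[1], 10)
  expect_error(read_structure(p, model_index = 5), "out of range",
               class = "rnasphere_data_error")
})

test_that("unreadable, empty and malformed files raise classed errors", {
  expect_error(read_structure(tempfile()), class = "rnasphere_io_error")
  p <- write_pdb_fixture("REMARK nothing here")
  expect_error(read_structure(p), class = "rnasphere_empty_structure")
  bad <- pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P")
  substr(bad, 34, 38) <- "xx.yy"   # corrupt the x coordinate field
  pb <- write_pdb_fixture(c(
    bad,
    pdb_atom_line(2, "C1'", "G", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 2, 2, 2, elesy = "O")))
  expect_error(read_structure(pb), "coordinate",
               class = "rnasphere_data_error")
})

test_that("validation is clean on a well-formed helix and flags known defects", {
  h <- generate_helix(8, seed = 4)
  expect_true(is_clean(validate_structure(h)))

  ## duplicate residue identity -> error
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "P", "G", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "C1'", "G", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "P", "C", "A", 2, 5, 5, 5, elesy = "P"),
    pdb_atom_line(4, "P", "U", "A", 1, 9, 9, 9, elesy = "P")))
  rep <- validate_structure(read_structure(p))
  expect_gte(sum(rep$severity == "error" & rep$code == "duplicate_residue"), 1L)

  ## 5'-terminal residue without P -> exactly one warning
  h5 <- perturb_structure(h, "atom_deletion", target = 1, atoms = "P")
  rep5 <- validate_structure(h5)
  expect_equal(nrow(rep5), 1L)
  expect_equal(rep5$severity, "warning")
  expect_equal(rep5$code, "missing_center_atom")

  ## non-nucleotide name and chain break -> warnings
  p2 <- write_pdb_fixture(c(
    pdb_atom_line(1, "P", "XYZ", "A", 1, 0, 0, 0, elesy = "P"),
    pdb_atom_line(2, "C1'", "XYZ", "A", 1, 1, 1, 1, elesy = "C"),
    pdb_atom_line(3, "O5'", "XYZ", "A", 1, 1, 2, 1, elesy = "O"),
    pdb_atom_line(4, "O3'", "XYZ", "A", 1, 2, 1, 1, elesy = "O"),
    pdb_atom_line(5, "P", "G", "A", 5, 5, 5, 5, elesy = "P"),
    pdb_atom_line(6, "C1'", "G", "A", 5, 6, 6, 6, elesy = "C"),
    pdb_atom_line(7, "O5'", "G", "A", 5, 6, 7, 6, elesy = "O"),
    pdb_atom_line(8, "O3'", "G", "A", 5, 7, 6, 6, elesy = "O")))
  rep2 <- validate_structure(read_structure(p2))
  expect_true(any(rep2$code == "non_nucleotide"))
  expect_true(any(rep2$code == "chain_break"))
  expect_false(any(rep2$severity == "error"))
})

test_that("write/parse round-trip preserves keys, names and coordinates", {
  h <- generate_helix(6, seed = 9)
  tmp <- tempfile(fileext = ".pdb")
  write_structure(h, tmp)
  h2 <- read_structure(tmp)
  expect_identical(h2$atoms$atom_key, h$atoms$atom_key)
  expect_identical(residue_keys(h2), residue_keys(h))
  expect_lt(max(abs(as.matrix(h2$atoms[, c("x", "y", "z")]) -
                    as.matrix(h$atoms[, c("x", "y", "z")]))), 0.001)

  ## idempotence: a second round-trip is exact
  tmp2 <- tempfile(fileext = ".pdb")
  write_structure(h2, tmp2)
  h3 <- read_structure(tmp2)
  expect_identical(h3$atoms$atom_key, h2$atoms$atom_key)
  expect_equal(h3$atoms$x, h2$atoms$x, tolerance = 0)

  empty <- h
  empty$atoms <- h$atoms[0, ]
  expect_error(write_structure(empty, tempfile()),
               class = "rnasphere_empty_structure")
})
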