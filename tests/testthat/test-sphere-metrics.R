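test_that("atom correspondence pairs identical keys and lists the rest", {
  h <- generate_helix(6, seed = 1)
  self <- match_atoms(h, h)
  expect_equal(nrow(self$pairs), nrow(h$atoms))
  expect_length(self$unmatched_reference, 0L)
  expect_length(self$unmatched_model, 0L)

  ## model missing one atom: that key lands in unmatched_reference
  m <- perturb_structure(h, "atom_deletion", target = 3, atoms = "O2'")
  corr <- match_atoms(h, m)
  expect_equal(nrow(corr$pairs), nrow(h$atoms) - 1L)
  expect_equal(corr$unmatched_reference, "A|3||O2'")

  ## disjoint chain IDs: no pairs at all
  other <- generate_helix(6, seed = 1, chain_id = "B")
  expect_error(match_atoms(h, other),
               class = "rnasphere_correspondence_error")
})

test_that("sphere membership follows the closed-ball distance rule", {
  ## hand-placed coordinates: atoms at 2.9, 3.0 and 3.1 A from the center
  p <- write_pdb_fixture(c(
    pdb_atom_line(1, "C1'", "G", "A", 1, 0, 0, 0, elesy = "C"),
    pdb_atom_line(2, "P", "G", "A", 1, 2.9, 0, 0, elesy = "P"),
    pdb_atom_line(3, "O5'", "G", "A", 1, 0, 3.0, 0, elesy = "O"),
    pdb_atom_line(4, "O3'", "G", "A", 1, 0, 0, 3.1, elesy = "O")))
  s <- read_structure(p)
  sph <- extract_sphere(s, "A:1", 3.0)
  expect_setequal(s$atoms$elety[sph$member_idx], c("C1'", "P", "O5'"))

  ## radius below any interatomic distance: the ball still holds its center
  tiny <- extract_sphere(s, "A:1", 0.5)
  expect_equal(s$atoms$elety[tiny$member_idx], "C1'")

  ## radius covering the molecule: every eligible atom is a member
  all_in <- extract_sphere(s, "A:1", 100)
  expect_equal(sort(all_in$member_idx), seq_len(nrow(s$atoms)))

  ## center-atoms-only mode restricts membership to the chosen name
  h <- generate_helix(8, seed = 2)
  co <- extract_sphere(h, "A:4", 300, center_atom = "C1'",
                       mode = "center_atoms_only")
  expect_true(all(h$atoms$elety[co$member_idx] == "C1'"))
  expect_equal(length(co$member_idx), 8L)
})

test_that("sphere membership is monotone in the radius", {
  h <- generate_helix(10, seed = 3)
  for (rk in residue_keys(h)[c(1, 5, 10)]) {
    prev <- integer(0)
    for (r in c(2, 5, 9, 15, 40, 300)) {
      mem <- extract_sphere(h, rk, r)$member_idx
      expect_true(all(prev %in% mem))
      prev <- mem
    }
  }
})

test_that("sphere RMSD is zero for self and rigid-motion comparisons", {
  h <- generate_helix(10, seed = 5)
  corr <- match_atoms(h, h)
  for (rk in residue_keys(h)[c(1, 6)])
    for (r in c(3, 20))
      expect_equal(sphere_rmsd(h, h, corr, rk, r)$rmsd, 0,
                   tolerance = 1e-12)
  mv <- perturb_structure(h, "rigid_motion", 12, seed = 6)
  corr2 <- match_atoms(h, mv)
  for (rk in residue_keys(h))
    expect_lt(sphere_rmsd(h, mv, corr2, rk, 8)$rmsd, 1e-6)
})

test_that("a localized displacement is scored only by spheres that reach it", {
  h <- generate_helix(10, seed = 7)
  m <- perturb_structure(h, "residue_displacement", 2, target = 5,
                         seed = 8)
  corr <- match_atoms(h, m)
  moved_keys <- h$atoms$atom_key[h$atoms$resno == 5]
  hits <- expected_hit_rows(h, 6, moved_keys)
  for (i in seq_along(residue_keys(h))) {
    res <- sphere_rmsd(h, m, corr, residue_keys(h)[i], 6)
    if (hits[i]) expect_gt(res$rmsd, 1e-6) else
      expect_lt(res$rmsd, 1e-9)
  }

  ## a sphere holding only center + displaced atoms agrees with the
  ## brute-force oracle
  at <- h$atoms
  ci <- which(at$res_key == "A:5" & at$elety == "C1'")
  d <- sqrt((at$x - at$x[ci])^2 + (at$y - at$y[ci])^2 +
            (at$z - at$z[ci])^2)
  r_small <- 4
  idx <- which(d <= r_small)
  mo <- corr$model_of_ref[idx]
  fit <- sphere_rmsd(h, m, corr, "A:5", r_small)
  expect_equal(fit$rmsd,
               oracle_min_rmsd(as.matrix(at[idx, c("x", "y", "z")]),
                               as.matrix(m$atoms[mo, c("x", "y", "z")])),
               tolerance = 1e-3)
})

test_that("gap markers cover missing centers and starved spheres", {
  h <- generate_helix(6, seed = 9)
  noP <- perturb_structure(h, "atom_deletion", target = 2, atoms = "C1'")
  expect_true(is_gap(extract_sphere(noP, "A:2", 5)))
  corr <- match_atoms(h, noP)

  ## reference keeps its center: model-side deletions lower coverage
  res <- sphere_rmsd(h, noP, corr, "A:2", 3)
  if (!is_gap(res)) expect_lt(res$coverage, 1)

  ## starve a sphere below 3 pairs: delete all but two atom types
  skinny <- perturb_structure(h, "atom_deletion",
                              atoms = setdiff(unique(h$atoms$elety),
                                              c("C1'", "P")))
  corr2 <- match_atoms(h, skinny)
  g <- sphere_rmsd(h, skinny, corr2, "A:1", 1.5)
  expect_true(is_gap(g))
  expect_equal(g$reason, "too_few_pairs")
  expect_lt(g$coverage, 1)
})

test_that("a molecule-covering sphere reproduces the global RMSD bit for bit", {
  pair <- helix_pair(n = 9, sigma = 1.2, seed = 21)
  corr <- match_atoms(pair$ref, pair$mod)
  g <- global_rmsd(pair$ref, pair$mod, corr)
  for (rk in residue_keys(pair$ref)) {
    s <- sphere_rmsd(pair$ref, pair$mod, corr, rk, 300)
    expect_identical(s$rmsd, g$rmsd)
  }
  ## and in center-atoms-only mode as well
  gc <- global_rmsd(pair$ref, pair$mod, corr, mode = "center_atoms_only")
  sc <- sphere_rmsd(pair$ref, pair$mod, corr, "A:4", 300,
                    mode = "center_atoms_only")
  expect_identical(sc$rmsd, gc$rmsd)
  expect_equal(gc$n_atoms, 9L)
})

test_that("global RMSD against itself is zero and matches the grid oracle when perturbed", {
  h <- generate_helix(7, seed = 13)
  corr <- match_atoms(h, h)
  expect_equal(global_rmsd(h, h, corr)$rmsd, 0, tolerance = 1e-12)

  pair <- helix_pair(n = 7, sigma = 0.6, seed = 22)
  corr2 <- match_atoms(pair$ref, pair$mod)
  g <- global_rmsd(pair$ref, pair$mod, corr2)
  expect_equal(g$rmsd,
               oracle_min_rmsd(coords_matrix(pair$ref),
                               coords_matrix(pair$mod)),
               tolerance = 1e-3)
})
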