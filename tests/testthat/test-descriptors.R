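test_that("center of mass is mass-weighted with table masses", {
  expect_equal(unname(center_of_mass(atoms_tbl("N", 1, 2, 3))), c(1, 2, 3))
  two_o <- atoms_tbl(c("O", "O"), c(0, 2), c(0, 0), c(0, 0))
  expect_equal(unname(center_of_mass(two_o)), c(1, 0, 0))
  hc <- atoms_tbl(c("H", "C"), c(0, 1), c(0, 0), c(0, 0))
  expect_equal(unname(center_of_mass(hc))[1], 12 / (12 + 1.007825032),
               tolerance = 1e-9)
})

test_that("max distance from COM matches brute force and conventions", {
  expect_equal(max_distance_from_com(atoms_tbl("C", 3, -1, 2)), 0)
  chain <- atoms_tbl(rep("C", 4), 0:3, rep(0, 4), rep(0, 4))
  expect_equal(max_distance_from_com(chain, heteroatoms_only = TRUE), 0)

  at <- fixture_bent_molecule()
  com <- center_of_mass(at)
  d_all <- apply(as.matrix(at[, 2:4]), 1, function(p) sqrt(sum((p - com)^2)))
  expect_equal(max_distance_from_com(at), max(d_all))
  expect_equal(max_distance_from_com(at, heteroatoms_only = TRUE), d_all[1])
})

test_that("anion m/z follows monoisotopic arithmetic", {
  ch4 <- atoms_tbl(c("C", "H", "H", "H", "H"), 0:4, rep(0, 5), rep(0, 5))
  expect_equal(mz_anion(ch4, geometry_is_neutral = TRUE), 15.0240,
               tolerance = 1e-4)
  # oleate anion (C18H33O2-), neutral oleic acid C18H34O2
  n_c <- 18; n_h <- 33
  oleate <- atoms_tbl(c(rep("C", n_c), rep("H", n_h), "O", "O"),
                      seq_len(n_c + n_h + 2), rep(0, n_c + n_h + 2),
                      rep(0, n_c + n_h + 2))
  expect_equal(mz_anion(oleate), 281.2486, tolerance = 1e-4)
  # additivity: one more 12C raises m/z by exactly 12
  plus_c <- dplyr::bind_rows(oleate, atoms_tbl("C", 99, 0, 0))
  expect_equal(mz_anion(plus_c) - mz_anion(oleate), 12)
})

test_that("heteroatom count excludes exactly C and H", {
  oleate <- atoms_tbl(c(rep("C", 18), rep("H", 33), "O", "O"),
                      seq_len(53), rep(0, 53), rep(0, 53))
  expect_equal(count_heteroatoms(oleate), 2)
  expect_equal(count_heteroatoms(atoms_tbl(rep("C", 6), 1:6, rep(0, 6),
                                           rep(0, 6))), 0)
  # glutarylcarnitine-like C12H21NO6 -> 7 heteroatoms
  gc <- atoms_tbl(c(rep("C", 12), rep("H", 21), "N", rep("O", 6)),
                  seq_len(40), rep(0, 40), rep(0, 40))
  expect_equal(count_heteroatoms(gc), 7)
})

test_that("surface area matches closed forms", {
  one_c <- atoms_tbl("C", 0, 0, 0)
  expect_equal(molecular_surface_area(one_c), 4 * pi * 3.1^2,
               tolerance = 0.005)
  far <- atoms_tbl(c("C", "C"), c(0, 100), c(0, 0), c(0, 0))
  expect_equal(molecular_surface_area(far), 2 * 4 * pi * 3.1^2,
               tolerance = 0.005)
  # two intersecting spheres vs the analytic cap formula
  d <- 1.5
  near <- atoms_tbl(c("C", "C"), c(0, d), c(0, 0), c(0, 0))
  expect_equal(molecular_surface_area(near), two_sphere_sasa(3.1, 3.1, d),
               tolerance = 0.01)
})

test_that("surface area converges with sampling density", {
  ens <- random_ensemble(5, seed = 31)
  for (i in seq_len(5)) {
    a960 <- molecular_surface_area(ens$atoms[[i]], points_per_atom = 960)
    a1920 <- molecular_surface_area(ens$atoms[[i]], points_per_atom = 1920)
    expect_lt(abs(a1920 - a960) / a960, 0.005)
  }
})

test_that("the five descriptors are rigid-motion invariant", {
  at <- fixture_mixed_conformer()
  base <- featurize(at)
  shifted <- featurize(transform_atoms(at, shift = c(5, 5, 5)))
  expect_equal(shifted[feature_names()], base[feature_names()],
               tolerance = 1e-10)
  rotated <- featurize(transform_atoms(at, random_rotation_matrix(7)))
  expect_equal(rotated$mz, base$mz)
  expect_equal(rotated$n_het, base$n_het)
  expect_equal(rotated$d_het_max, base$d_het_max, tolerance = 1e-10)
  expect_equal(rotated$d_atom_max, base$d_atom_max, tolerance = 1e-10)
  expect_equal(rotated$msa, base$msa, tolerance = 0.02)
})

test_that("featurize agrees with per-component values and orders features", {
  ens <- random_ensemble(3, seed = 41)
  f <- featurize(ens)
  expect_equal(names(f), c("id", feature_names(), "label_ccs"))
  for (i in seq_len(3)) {
    at <- ens$atoms[[i]]
    expect_equal(f$mz[i], mz_anion(at))
    expect_equal(f$d_het_max[i], max_distance_from_com(at, TRUE))
    expect_equal(f$d_atom_max[i], max_distance_from_com(at, FALSE))
    expect_equal(f$n_het[i], count_heteroatoms(at))
    expect_equal(f$msa[i], molecular_surface_area(at))
  }
  expect_true(all(f$d_het_max <= f$d_atom_max))
})

test_that("feature shift survey reports signed percent differences", {
  ref <- tibble::tibble(d_het_max = c(9, 11), d_atom_max = c(18, 22),
                        msa = c(90, 110))
  idm <- feature_shift_survey(ref, ref)
  expect_equal(idm$percent_difference, c(0, 0, 0))
  dbl <- feature_shift_survey(ref, dplyr::mutate(ref,
                                                 dplyr::across(dplyr::everything(), ~ 2 * .x)))
  expect_equal(dbl$percent_difference, c(100, 100, 100))
  ref2 <- tibble::tibble(d_het_max = 10, d_atom_max = 20, msa = 100)
  qry2 <- tibble::tibble(d_het_max = 11, d_atom_max = 25, msa = 90)
  expect_equal(feature_shift_survey(ref2, qry2)$percent_difference,
               c(10, 25, -10))
  expect_error(feature_shift_survey(ref2[0, ], qry2), "non-empty")
  ref0 <- tibble::tibble(d_het_max = 0, d_atom_max = 20, msa = 100)
  expect_error(feature_shift_survey(ref0, qry2), "zero")
})
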