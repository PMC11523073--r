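test_that("Kabsch RMSD is zero for rigid-motion images and symmetric", {
  a <- fixture_mixed_conformer()
  expect_equal(kabsch_rmsd(a, a), 0)
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- transform_atoms(a, rot90z, shift = c(3, -2, 7))
  expect_lt(kabsch_rmsd(a, b), 1e-8)
  c1 <- transform_atoms(a, random_rotation_matrix(71), shift = c(1, 2, 3))
  c1$x[2] <- c1$x[2] + 0.8
  expect_equal(kabsch_rmsd(a, c1), kabsch_rmsd(c1, a), tolerance = 1e-12)
  expect_error(kabsch_rmsd(a, a[1:3, ]), "atom count")
})

test_that("Kabsch RMSD matches a rotation-search oracle", {
  sq <- atoms_tbl(rep("C", 4), c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 0, 0, 0))
  sq_bent <- sq; sq_bent$z[3] <- 1  # one corner displaced 1 A
  expect_equal(kabsch_rmsd(sq, sq_bent), rmsd_rotation_oracle(sq, sq_bent),
               tolerance = 1e-3)
  a <- fixture_mixed_conformer()
  set.seed(72)
  b <- transform_atoms(a, random_rotation_matrix(73), shift = c(1, 0, -2))
  b$y <- b$y + rnorm(nrow(b), sd = 0.4)
  expect_equal(kabsch_rmsd(a, b), rmsd_rotation_oracle(a, b),
               tolerance = 1e-3)
})

test_that("greedy leader clustering matches an independent reimplementation", {
  base <- fixture_mixed_conformer()
  ens <- conformer_ensemble(rep(list(base), 10))
  expect_equal(nrow(cluster_representatives(ens, 1.0)), 1)

  stretched <- base
  stretched$x <- stretched$x * 4
  two <- conformer_ensemble(list(base, stretched))
  expect_gt(kabsch_rmsd(base, stretched), 1.0)
  expect_equal(nrow(cluster_representatives(two, 1.0)), 2)

  ens50 <- random_ensemble(50, seed = 74)
  thr <- 0.45
  reps <- cluster_representatives(ens50, thr)
  # oracle: direct loop over input order
  picked <- integer(0)
  for (i in 1:50) {
    if (all(vapply(picked, function(r) {
      kabsch_rmsd(ens50$atoms[[i]], ens50$atoms[[r]]) > thr
    }, logical(1)))) picked <- c(picked, i)
  }
  expect_identical(reps$id, ens50$id[picked])
  # separation and coverage
  if (nrow(reps) > 1) {
    for (i in seq_len(nrow(reps) - 1)) {
      for (j in seq(i + 1, nrow(reps))) {
        expect_gt(kabsch_rmsd(reps$atoms[[i]], reps$atoms[[j]]), thr)
      }
    }
  }
  cover <- vapply(seq_len(50), function(i) {
    any(vapply(seq_len(nrow(reps)), function(r) {
      kabsch_rmsd(ens50$atoms[[i]], reps$atoms[[r]]) <= thr
    }, logical(1)))
  }, logical(1))
  expect_true(all(cover))
})

test_that("Boltzmann weights follow the closed form", {
  expect_equal(boltzmann_weights(rep(2.5, 4)), rep(0.25, 4))
  expect_equal(boltzmann_weights(7.3), 1)
  # Delta E = RT ln 2 at 298.15 K -> 2:1 population
  rtln2 <- 0.0019872 * 298.15 * log(2)
  expect_equal(rtln2, 0.41068, tolerance = 1e-4)
  expect_equal(boltzmann_weights(c(0, rtln2)), c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  # invariance to a constant shift and normalization
  set.seed(75)
  e <- runif(20, 0, 10)
  expect_equal(sum(boltzmann_weights(e)), 1, tolerance = 1e-12)
  expect_equal(boltzmann_weights(e + 123.4), boltzmann_weights(e),
               tolerance = 1e-12)
  expect_error(boltzmann_weights(c(1, Inf)), "finite")
  # hartree input converts with 627.5095
  expect_equal(boltzmann_weights(c(0, rtln2 / 627.5095), units = "hartree"),
               c(2 / 3, 1 / 3), tolerance = 1e-6)
})

test_that("Boltzmann-averaged CCS is a proper weighted mean", {
  expect_equal(boltzmann_ccs(c(180, 190), c(1, 1)), 185)
  expect_equal(boltzmann_ccs(c(180, 240), c(0, 10)), 180, tolerance = 1e-4)
  e3 <- c(0, 0.5, 1.2); c3 <- c(170, 181, 196)
  w <- exp(-(e3 - min(e3)) / (0.0019872 * 298.15)); w <- w / sum(w)
  expect_equal(boltzmann_ccs(c3, e3), sum(w * c3), tolerance = 1e-12)
  set.seed(76)
  cv <- runif(15, 160, 210); ev <- runif(15, 0, 5)
  bc <- boltzmann_ccs(cv, ev)
  expect_gte(bc, min(cv)); expect_lte(bc, max(cv))
})

test_that("candidate selection takes the lowest energy, first on ties", {
  ens <- random_ensemble(3, seed = 77)
  ens$energy <- c(3, 1, 2)
  expect_equal(select_candidate(ens)$id, ens$id[2])
  ens$energy <- c(1, 1, 5)
  expect_equal(select_candidate(ens)$id, ens$id[1])
  ens100 <- random_ensemble(100, seed = 78)
  set.seed(79)
  ens100$energy <- runif(100, 0, 20)
  expect_equal(select_candidate(ens100)$id,
               ens100$id[which.min(ens100$energy)])
  ens$energy[2] <- NA
  expect_error(select_candidate(ens), "energy")
})

test_that("percent CCS error uses the experimental denominator", {
  expect_equal(round(percent_ccs_error(235.72, 174.95), 2), 34.74)
  expect_equal(round(percent_ccs_error(189.75, 190.17), 2), 0.22)
  expect_equal(percent_ccs_error(182.2, 182.2), 0)
  expect_error(percent_ccs_error(180, 0), "positive")
})

test_that("evaluation tables round rows to 2 decimals and flag 3%", {
  one <- evaluate_candidates(tibble::tibble(species = "x", exp_ccs = 180,
                                            calc_ccs = 180))
  expect_equal(one$percent_error, 0)
  expect_true(one$pass_3pct)
  s <- summarize_evaluation(one)
  expect_equal(s$mean_pct_error, 0)
  expect_equal(s$n_pass_3pct, 1L)

  tbl <- evaluate_candidates(tibble::tibble(
    species = c("a", "b"), exp_ccs = c(100, 200), calc_ccs = c(103.004, 206.8)
  ))
  expect_equal(tbl$percent_error, c(3.00, 3.40))
  expect_equal(tbl$pass_3pct, c(TRUE, FALSE))
})
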