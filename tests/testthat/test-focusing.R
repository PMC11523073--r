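# independent two-pass oracle for the batch error statistics
naive_error_stats <- function(pred, lab) {
  e <- numeric(length(pred))
  for (i in seq_along(pred)) e[i] <- abs(pred[i] - lab[i]) / lab[i]
  m <- sum(e) / length(e)
  s <- if (length(e) == 1) 0 else sqrt(sum((e - m)^2) / (length(e) - 1)) /
    sqrt(length(e))
  list(mean = m, sem = s)
}

test_that("error statistics follow the reconstructed definitions", {
  s <- error_statistics(c(102, 98), c(100, 100))
  expect_equal(s$per_item_errors, c(0.02, 0.02))
  expect_equal(s$mean_error, 0.02)
  expect_equal(s$sem_error, 0)

  s <- error_statistics(c(110, 100), c(100, 100))
  expect_equal(s$per_item_errors, c(0.10, 0))
  expect_equal(s$mean_error, 0.05)
  expect_equal(s$sem_error, 0.05)

  s <- error_statistics(c(181.5, 170.2), c(181.5, 170.2))
  expect_equal(s$mean_error, 0)
  expect_equal(s$sem_error, 0)
  expect_error(error_statistics(c(1, 2), c(1, -1)), "positive")
})

test_that("error statistics agree with a naive two-pass oracle to 1e-12", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(1:60, 1)
    lab <- runif(n, 150, 220)
    pred <- lab * (1 + rnorm(n, sd = 0.05))
    s <- error_statistics(pred, lab)
    o <- naive_error_stats(pred, lab)
    expect_equal(s$mean_error, o$mean, tolerance = 1e-12)
    expect_equal(s$sem_error, o$sem, tolerance = 1e-12)
    expect_equal(s$n, n)
  }
})

test_that("filter bounds are symmetric multiplicative bands", {
  b <- filter_bounds(180, summary_error_stats(0, 0))
  expect_equal(c(b$lower, b$upper), c(180, 180))

  b <- filter_bounds(180, summary_error_stats(0.02, 0.005))
  expect_equal(b$lower, 175.5)
  expect_equal(b$upper, 184.5)

  b <- filter_bounds(174.95, summary_error_stats(0.02, 0.005))
  expect_equal(b$upper - b$lower, 2 * 0.025 * 174.95)

  expect_error(filter_bounds(-5, summary_error_stats(0.02)), "positive")
  expect_error(filter_bounds(180, summary_error_stats(0.7, 0.4)),
               "lower bound")
})

test_that("band width scales linearly in mean_error + sem_error", {
  widths <- vapply(c(0.01, 0.02, 0.04), function(h) {
    b <- filter_bounds(200, summary_error_stats(h / 2, h / 2))
    b$upper - b$lower
  }, numeric(1))
  expect_equal(widths, 2 * 200 * c(0.01, 0.02, 0.04))
})

test_that("apply_ccs_filter retains exactly the in-band conformers", {
  ens <- random_ensemble(3, seed = 51)
  band <- filter_bounds(180, summary_error_stats(0.025, 0.003))  # ~[175,185]
  out <- apply_ccs_filter(ens, c(170, 180, 190),
                          filter_bounds(180, summary_error_stats(0.0278, 0)))
  expect_equal(out$id, ens$id[2])
  expect_equal(out$pred_ccs, 180)

  wide <- filter_bounds(180, summary_error_stats(0.9, 0))
  out <- apply_ccs_filter(ens, c(170, 180, 190), wide)
  expect_equal(out$id, ens$id)

  expect_error(apply_ccs_filter(ens, c(1, 2), band), "one prediction")
})

test_that("capacity keeps the predictions nearest the user CCS", {
  ens <- random_ensemble(4, seed = 52)
  band <- filter_bounds(180, summary_error_stats(0.05, 0))  # [171, 189]
  out <- apply_ccs_filter(ens, c(176, 179, 181, 184), band, capacity = 2)
  expect_equal(out$pred_ccs, c(179, 181))
  expect_equal(out$id, ens$id[2:3])
  # ties resolved by input order
  out <- apply_ccs_filter(ens, c(178, 182, 178, 185), band, capacity = 2)
  expect_equal(out$pred_ccs, c(178, 182))
})

test_that("filtering equals the brute-force set on randomized ensembles", {
  ens <- random_ensemble(50, seed = 53)
  set.seed(54)
  for (trial in 1:200) {
    preds <- runif(50, 150, 220)
    stats <- summary_error_stats(runif(1, 0, 0.1), runif(1, 0, 0.02))
    band <- filter_bounds(runif(1, 160, 210), stats)
    out <- apply_ccs_filter(ens, preds, band)
    brute <- which(preds >= band$lower & preds <= band$upper)
    expect_identical(out$id, ens$id[brute])
  }
})

test_that("widening the band never drops a retained conformer", {
  ens <- random_ensemble(40, seed = 55)
  set.seed(56)
  preds <- runif(40, 150, 220)
  kept_prev <- character(0)
  for (h in seq(0.005, 0.15, by = 0.005)) {
    out <- apply_ccs_filter(ens, preds,
                            filter_bounds(185, summary_error_stats(h, 0)))
    expect_true(all(kept_prev %in% out$id))
    kept_prev <- out$id
  }
})

test_that("capacity output is nested in the uncapacitated output", {
  ens <- random_ensemble(30, seed = 57)
  set.seed(58)
  preds <- runif(30, 150, 220)
  band <- filter_bounds(185, summary_error_stats(0.08, 0.01))
  full <- apply_ccs_filter(ens, preds, band)
  for (k in c(1, 3, 10, 100)) {
    capped <- apply_ccs_filter(ens, preds, band, capacity = k)
    expect_true(all(capped$id %in% full$id))
    expect_equal(nrow(capped), min(k, nrow(full)))
  }
})

test_that("focus_ensemble composes featurize, predict and filter", {
  spec <- synthetic_spec(18, 9L, n_conformers = 120, seed = 61)
  ens <- generate_ensemble(spec)
  tr <- featurize(ens)
  # single species: mz and n_het are constant, so mask them out
  m <- train_ccs_regressor(
    tr, tr$label_ccs,
    ccs_regressor_config(epochs = 60, patience = 15, seed = 62,
                         feature_mask = c("d_het_max", "d_atom_max", "msa"))
  )
  ccs_user <- stats::median(tr$label_ccs)
  out <- focus_ensemble(ens, m, ccs_user)
  rep <- focus_report(out)
  expect_equal(rep$n_in, 120)
  expect_equal(rep$n_out, nrow(out))
  # every retained conformer's prediction lies inside the band (brute force)
  preds <- attr(out, "predictions")
  band <- attr(out, "band")
  inside <- which(preds >= band$lower & preds <= band$upper)
  expect_identical(out$id, ens$id[inside])
  expect_equal(out$pred_ccs, preds[inside])

  # a band far outside the predictions captures nothing, without error
  empty <- focus_ensemble(ens, m, ccs_user * 3,
                          stats = summary_error_stats(0.01, 0))
  expect_equal(nrow(empty), 0)
  expect_equal(focus_report(empty)$n_out, 0)
})
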