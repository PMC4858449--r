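make_county <- function(n_tracts = 30, n = 1200, miss = TRUE, seed = 1) {
  geo <- sim_geography(n_tracts, max(2, n_tracts %/% 6), 3,
                       seed = sub_seed(seed, 1))
  truth <- sim_truth(geo, qlogis(0.15), 0.3, 0.15, seed = sub_seed(seed, 2))
  r <- sim_survey(truth, geo, n, seed = sub_seed(seed, 3))
  if (miss) r <- apply_missingness(r, seed = sub_seed(seed, 4))
  list(geo = geo, truth = truth, r = r)
}

test_that("the imputation run keeps a ledger of distinct sub-seeds", {
  cc <- make_county()
  run <- run_mi_smoothing(cc$r, cc$geo$crosswalk, cc$geo$nb,
                          fast_spec(iterations = 600, burn_in = 100),
                          M = 4, seed = 99, areas = cc$geo$tract_ids)
  expect_equal(run$M, 4)
  expect_length(unique(c(run$alloc_seeds, run$fit_seeds)), 8)
  expect_false(any(vapply(run$tracts, anyNA, TRUE)))
  # every fit covers every tract
  for (f in run$fits)
    expect_identical(as.character(f$area_id), cc$geo$tract_ids)
})

test_that("with M = 1 pooling is the identity on the single fit", {
  cc <- make_county()
  run <- run_mi_smoothing(cc$r, cc$geo$crosswalk, cc$geo$nb,
                          fast_spec(iterations = 1500, burn_in = 500),
                          M = 1, seed = 5, areas = cc$geo$tract_ids)
  pooled <- pool_estimates(run, level = 0.9)
  single <- summarize_fit(run$fits[[1]], level = 0.9)
  expect_equal(pooled$median, single$median, tolerance = 1e-12)
  expect_equal(pooled$lower, single$lower, tolerance = 1e-12)
  expect_equal(pooled$upper, single$upper, tolerance = 1e-12)
})

test_that("zero missingness gives identical completed tables", {
  cc <- make_county(miss = FALSE)
  run <- run_mi_smoothing(cc$r, cc$geo$crosswalk, cc$geo$nb,
                          fast_spec(iterations = 600, burn_in = 100),
                          M = 3, seed = 7, areas = cc$geo$tract_ids)
  expect_identical(run$tracts[[1]], run$tracts[[2]])
  expect_identical(run$tracts[[1]], run$tracts[[3]])
  expect_identical(run$tracts[[1]], cc$r$tract)
})

test_that("pooling mixes draws: shifted components widen the interval", {
  spec <- fast_spec()
  fake_fit <- function(shift) {
    set.seed(400 + round(100 * shift))
    eta <- matrix(rnorm(4000, -2 + shift, 0.2), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
    structure(list(eta = eta, area_id = c("a", "b"), spec = spec),
              class = "sae_fit")
  }
  run <- structure(list(fits = list(fake_fit(-0.3), fake_fit(0.3)), M = 2L),
                   class = "sae_mi_run")
  pooled <- pool_estimates(run, 0.9)
  for (f in run$fits) {
    comp <- summarize_fit(f, 0.9)
    expect_gt(pooled$ci_half_width[1], comp$ci_half_width[1] * 0.99)
  }
  # mixture must be genuinely wider than each equal-width component
  expect_gt(pooled$ci_half_width[1],
            summarize_fit(run$fits[[1]], 0.9)$ci_half_width[1] * 1.2)
})

test_that("law of total variance holds for the pooled draw mixture", {
  cc <- make_county()
  run <- run_mi_smoothing(cc$r, cc$geo$crosswalk, cc$geo$nb,
                          fast_spec(iterations = 1000, burn_in = 200),
                          M = 4, seed = 13, areas = cc$geo$tract_ids)
  p_list <- lapply(run$fits, function(f) plogis(f$eta))
  pooled <- do.call(rbind, p_list)
  pvar <- function(x) mean((x - mean(x))^2)
  for (j in seq_len(ncol(pooled))) {
    within <- mean(vapply(p_list, function(p) pvar(p[, j]), numeric(1)))
    expect_gte(pvar(pooled[, j]), within - 1e-12)
  }
})

test_that("imputation failures identify the offending sub-seed", {
  cc <- make_county()
  bad_cw <- cc$geo$crosswalk[cc$geo$crosswalk$zip != cc$r$zip[1], ]
  r <- cc$r
  r$tract[r$zip == r$zip[1]] <- NA  # force allocation through a missing zip
  expect_error(
    run_mi_smoothing(r, bad_cw, cc$geo$nb, fast_spec(), M = 2, seed = 3,
                     areas = cc$geo$tract_ids),
    "imputation 1")
})
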