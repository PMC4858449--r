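test_that("smoothing_spec validates its settings", {
  expect_error(smoothing_spec(iterations = 100, burn_in = 100), "burn_in")
  expect_error(smoothing_spec(level = 1), "level")
  expect_error(smoothing_spec(level = 0), "level")
  s <- smoothing_spec("iid_only", iterations = 1000, burn_in = 200, thin = 4)
  expect_equal((s$iterations - s$burn_in) / s$thin, 200)
})

test_that("with tiny working variances the posterior tracks the data", {
  d <- direct_table(theta = c(-2, -1), V = c(1e-4, 1e-4))
  fit <- fit_smoothing_model(d, chain_nb(2), fast_spec("iid_only"))
  expect_equal(nrow(fit$eta), 2500)
  expect_lt(abs(mean(fit$eta[, 1]) - (-2)), 3 * mc_se(fit$eta[, 1]))
  expect_lt(abs(mean(fit$eta[, 2]) - (-1)), 3 * mc_se(fit$eta[, 2]))
})

test_that("the two-area posterior matches the conjugate closed form", {
  theta <- c(-2.0, -1.2)
  V <- c(0.30, 0.15)
  sig2 <- 0.5  # 1 / tau_v, held fixed
  d <- direct_table(theta, V)
  fit <- fit_smoothing_model(
    d, chain_nb(2),
    fast_spec("iid_only", iterations = 21000, burn_in = 1000,
              tau_v_fixed = 1 / sig2))
  # closed form: integrating the flat-prior mu out, mu | data is normal with
  # precision sum 1/(V_i + sig2); eta_i | mu shrinks theta_i toward mu
  prec_mu <- sum(1 / (V + sig2))
  m_mu <- sum(theta / (V + sig2)) / prec_mu
  prec_i <- 1 / V + 1 / sig2
  m_eta <- (theta / V + m_mu / sig2) / prec_i
  v_eta <- 1 / prec_i + (1 / (sig2 * prec_i))^2 / prec_mu
  for (i in 1:2) {
    expect_lt(abs(mean(fit$eta[, i]) - m_eta[i]), 3 * mc_se(fit$eta[, i]))
    # second moment: sample variance within 10% of the closed form
    expect_lt(abs(var(fit$eta[, i]) - v_eta[i]) / v_eta[i], 0.10)
  }
  # posterior mean of mu itself
  expect_lt(abs(mean(fit$mu) - m_mu), 3 * mc_se(fit$mu))
})

test_that("seeded sampler runs are reproducible draw for draw", {
  d <- direct_table(theta = c(-2, -1.5, -1), V = rep(0.2, 3))
  f1 <- fit_smoothing_model(d, chain_nb(3), fast_spec(seed = 11))
  f2 <- fit_smoothing_model(d, chain_nb(3), fast_spec(seed = 11))
  expect_identical(f1$eta, f2$eta)
  f3 <- fit_smoothing_model(d, chain_nb(3), fast_spec(seed = 12))
  expect_false(identical(f1$eta, f3$eta))
})

test_that("retained ICAR draws satisfy the sum-to-zero constraint", {
  d <- direct_table(theta = seq(-2.5, -1, length.out = 6), V = rep(0.2, 6))
  fit <- fit_smoothing_model(d, chain_nb(6), fast_spec("icar_plus_iid"))
  expect_true(all(abs(rowSums(fit$u)) < 1e-6))
  expect_true(all(fit$tau_u > 0) && all(fit$tau_v > 0))
})

test_that("degenerate areas are predicted from the prior with valid summaries", {
  theta <- c(-2, -1.8, -2.2, 0, -1.9)
  d <- direct_table(theta, V = rep(0.1, 5),
                    degenerate = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  fit <- fit_smoothing_model(d, chain_nb(5), fast_spec("icar_plus_iid"))
  sm <- summarize_fit(fit, 0.9)
  expect_true(all(sm$median > 0 & sm$median < 1))
  expect_true(all(sm$lower <= sm$median & sm$median <= sm$upper))
  # the no-data area is pulled toward its neighbours, not to 0.5
  expect_lt(sm$median[4], 0.4)
  expect_gt(sm$ci_half_width[4], median(sm$ci_half_width[-4]))
})

test_that("fit preconditions are enforced", {
  d <- direct_table(theta = c(-2, -1), V = c(0.1, 0.1),
                    degenerate = c(FALSE, TRUE))
  expect_error(fit_smoothing_model(d, chain_nb(2), fast_spec()),
               "at least 2")
  d2 <- direct_table(theta = c(-2, -1), V = c(0.1, -0.1))
  expect_error(fit_smoothing_model(d2, chain_nb(2), fast_spec()),
               "var_theta")
  d3 <- direct_table(theta = c(-2, -1, -1.5), V = rep(0.1, 3))
  nb_disc <- list(2L, 1L, integer(0))
  expect_error(fit_smoothing_model(d3, nb_disc, fast_spec("icar_only")),
               "connected")
})

test_that("CPO is symmetric for exchangeable areas and monotone in variance", {
  d <- direct_table(theta = rep(-1.5, 4), V = rep(0.2, 4))
  fit <- fit_smoothing_model(d, chain_nb(4), fast_spec("iid_only"))
  cpo <- compute_cpo(fit, d)
  expect_true(all(is.finite(cpo$cpo)))
  expect_lt(max(cpo$cpo) - min(cpo$cpo), 0.15 * mean(cpo$cpo))
  expect_equal(cpo$sum_log_cpo, sum(log(cpo$cpo)))

  # two outlying areas at the same residual from the bulk: when the residual
  # exceeds the working SD, the larger-variance area has the larger
  # leave-one-out predictive density
  d2 <- direct_table(theta = c(-1, -1, -2.5, -2.5),
                     V = c(0.1, 0.1, 0.1, 0.9))
  fit2 <- fit_smoothing_model(d2, chain_nb(4),
                              fast_spec("iid_only", tau_v_fixed = 16))
  cpo2 <- compute_cpo(fit2, d2)
  expect_gt(cpo2$cpo[4], cpo2$cpo[3])
})

test_that("harmonic-mean CPO matches a leave-one-out refit oracle", {
  # working variances are kept above twice the posterior spread of eta so
  # the harmonic-mean importance ratios are square-integrable and the
  # estimator actually converges
  theta <- c(-2.1, -1.6, -1.9, -1.2, -1.4)
  V <- c(0.5, 0.45, 0.55, 0.4, 0.5)
  d <- direct_table(theta, V)
  spec <- fast_spec("iid_only", iterations = 41000, burn_in = 1000,
                    thin = 4, tau_v_fixed = 1 / 0.15)
  fit <- fit_smoothing_model(d, chain_nb(5), spec)
  cpo <- compute_cpo(fit, d)
  for (i in 1:5) {
    d_loo <- d
    d_loo$degenerate[i] <- TRUE  # drop area i's likelihood term
    fit_loo <- fit_smoothing_model(d_loo, chain_nb(5), spec)
    oracle <- mean(dnorm(theta[i], mean = fit_loo$eta[, i],
                         sd = sqrt(V[i])))
    expect_lt(abs(cpo$cpo[i] - oracle) / oracle, 0.06)
  }
})

test_that("model selection takes the argmax with a simplicity tie-break", {
  expect_equal(saeprev:::pick_best(c("icar_only", "iid_only"),
                                   c(-10.2, -12.1)), 1L)
  expect_equal(saeprev:::pick_best(c("icar_plus_iid", "iid_only"),
                                   c(-10, -10)), 2L)
  expect_equal(saeprev:::pick_best(c("icar_plus_iid", "icar_only"),
                                   c(-10, -10)), 2L)
})

test_that("strong spatial signal leads CPO selection to an ICAR model", {
  geo <- sim_geography(64, 9, 4, seed = 21)
  wins <- 0L
  for (rep in 1:5) {
    truth <- sim_truth(geo, qlogis(0.15), 1.2, 0.05, seed = 100 + rep)
    r <- sim_survey(truth, geo, 64 * 60, uniform_selection(),
                    seed = 200 + rep)
    d <- saeprev:::with_logits(
      direct_estimate(r, r$base_weight, "tract", areas = geo$tract_ids))
    fits <- list(
      fit_smoothing_model(d, geo$nb, fast_spec("iid_only", seed = rep)),
      fit_smoothing_model(d, geo$nb, fast_spec("icar_plus_iid", seed = rep)))
    sel <- select_model(fits, d)
    if (sel$chosen$spec$effect_structure != "iid_only") wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("selection refuses candidates fit to different data", {
  d1 <- direct_table(theta = c(-2, -1), V = c(0.1, 0.1))
  d2 <- direct_table(theta = c(-2, -0.5), V = c(0.1, 0.1))
  f1 <- fit_smoothing_model(d1, chain_nb(2), fast_spec("iid_only"))
  f2 <- fit_smoothing_model(d2, chain_nb(2), fast_spec("icar_plus_iid"))
  expect_error(select_model(list(f1, f2), d1), "identical data")
})

test_that("prevalence-scale summaries have correct symmetry and quantiles", {
  spec <- fast_spec()
  mk_fit <- function(eta_draws) {
    structure(list(eta = eta_draws, area_id = colnames(eta_draws),
                   obs = rep(TRUE, ncol(eta_draws)), spec = spec),
              class = "sae_fit")
  }
  set.seed(8)
  # symmetric logit draws => median prevalence 1/2
  sym <- matrix(rnorm(20000, 0, 1.3), ncol = 1,
                dimnames = list(NULL, "a"))
  sym[, 1] <- sym[, 1] - median(sym[, 1])
  s <- summarize_fit(mk_fit(sym), 0.9)
  expect_equal(s$median, 0.5, tolerance = 1e-9)

  # normal draws pushed through the inverse logit match analytic quantiles
  dr <- matrix(rnorm(40000, -2.197, 0.25), ncol = 1,
               dimnames = list(NULL, "a"))
  s9 <- summarize_fit(mk_fit(dr), 0.9)
  expect_equal(s9$lower, plogis(-2.197 + qnorm(0.05) * 0.25),
               tolerance = 0.01)
  expect_equal(s9$upper, plogis(-2.197 + qnorm(0.95) * 0.25),
               tolerance = 0.01)
  # nested intervals
  s8 <- summarize_fit(mk_fit(dr), 0.8)
  expect_gt(s8$lower, s9$lower)
  expect_lt(s8$upper, s9$upper)

  # too few draws refused
  tiny <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "a"))
  expect_error(summarize_fit(mk_fit(tiny), 0.9), "100")
})
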