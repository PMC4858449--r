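# Shared fixtures: tiny geographies and fast sampler settings.

fast_spec <- function(..., iterations = 3000, burn_in = 500, thin = 1,
                      seed = 42) {
  smoothing_spec(..., iterations = iterations, burn_in = burn_in,
                 thin = thin, seed = seed)
}

# A one-cell demographic structure: equal inclusion, no outcome effect,
# so the survey design is non-informative and weights are flat.
uniform_selection <- function() {
  list(cells = data.frame(age = "all", sex = "all", race = "all",
                          pop_share = 1, intensity = 1, outcome_logit = 0,
                          stringsAsFactors = FALSE))
}

# Hand-built direct-estimate table for smoothing tests (bypasses survey
# machinery): theta/V given directly.
direct_table <- function(theta, V, degenerate = rep(FALSE, length(theta))) {
  p <- plogis(theta)
  out <- data.frame(
    area_id = sprintf("A%02d", seq_along(theta)),
    n = ifelse(degenerate, 0L, 30L),
    p_hat = ifelse(degenerate, NA_real_, p),
    var_p = ifelse(degenerate, NA_real_, V * (p * (1 - p))^2),
    theta_hat = ifelse(degenerate, NA_real_, theta),
    var_theta = ifelse(degenerate, NA_real_, V),
    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("sae_direct", "data.frame")
  out
}

# Neighbor list for a simple chain graph 1-2-...-n.
chain_nb <- function(n) {
  lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1L, if (i < n) i + 1L)))
}

rmse <- function(a, b) sqrt(mean((a - b)^2, na.rm = TRUE))

# Monte-Carlo standard error of a mean of (possibly autocorrelated) draws,
# using the lag-1 autocorrelation effective-size correction.
mc_se <- function(x) {
  r1 <- suppressWarnings(stats::cor(x[-1], x[-length(x)]))
  if (!is.finite(r1)) r1 <- 0
  ess <- max(1, length(x) * (1 - r1) / (1 + r1))
  stats::sd(x) / sqrt(ess)
}
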