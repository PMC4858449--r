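#' Specify the hierarchical smoothing model
#'
#' Settings for the three-stage area-level model: the random-effect
#' structure in the linear predictor \eqn{\eta_i = \mu + u_i + v_i}
#' (ICAR \eqn{u}, iid \eqn{v}, or both — the BYM convolution), Gamma
#' hyperpriors on the precisions \eqn{\tau_u, \tau_v}, Gibbs sampler
#' settings, and the credible-interval level.
#'
#' @param effect_structure one of \code{"icar_plus_iid"} (BYM, default),
#'   \code{"icar_only"}, \code{"iid_only"}
#' @param prior_u,prior_v Gamma (shape, rate) hyperprior on the spatial /
#'   unstructured precision. The default Gamma(0.5, 0.05) is weakly
#'   informative on the scale relevant to prevalence smoothing: its prior
#'   median corresponds to a logit-scale standard deviation of about 0.5,
#'   with 90% prior mass on SDs from roughly 0.15 to 5. The
#'   Gamma(0.5, 0.0005) convention inherited from disease mapping puts its
#'   prior median at an SD of about 0.05 — effectively asserting no
#'   between-area variation — and badly overshrinks weakly identified
#'   variance components here (see the vignette)
#' @param iterations,burn_in,thin Gibbs chain settings; retained draws are
#'   \code{(iterations - burn_in) / thin}
#' @param seed integer seed for the sampler
#' @param level credible-interval level in (0, 1)
#' @param tau_u_fixed,tau_v_fixed optional fixed precision values (mainly
#'   for closed-form validation); \code{NULL} samples them
#' @return list of class \code{sae_spec}
#' @export
smoothing_spec <- function(effect_structure = c("icar_plus_iid", "icar_only",
                                                "iid_only"),
                           prior_u = c(0.5, 0.05),
                           prior_v = c(0.5, 0.05),
                           iterations = 20000, burn_in = 5000, thin = 5,
                           seed = 1, level = 0.9,
                           tau_u_fixed = NULL, tau_v_fixed = NULL) {
  effect_structure <- match.arg(effect_structure)
  if (!(iterations > burn_in && burn_in >= 0))
    stop("need iterations > burn_in >= 0")
  if (!(level > 0 && level < 1)) stop("level must be strictly inside (0, 1)")
  stopifnot(length(prior_u) == 2, all(prior_u > 0),
            length(prior_v) == 2, all(prior_v > 0))
  structure(list(effect_structure = effect_structure,
                 prior_u = prior_u, prior_v = prior_v,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), level = level,
                 tau_u_fixed = tau_u_fixed, tau_v_fixed = tau_v_fixed),
            class = "sae_spec")
}

structure_rank <- function(s)
  match(s, c("iid_only", "icar_only", "icar_plus_iid"))

## Normalize adjacency input (neighbor list or 0/1 matrix) to a neighbor list.
as_nblist <- function(adjacency) {
  if (is.matrix(adjacency)) return(adjacency_to_nblist(adjacency))
  if (inherits(adjacency, "sae_geography")) return(adjacency$nb)
  stopifnot(is.list(adjacency))
  adjacency
}

#' Fit the spatial smoothing model by Gibbs sampling
#'
#' Stage 1 takes each non-degenerate area's empirical logit as a Gaussian
#' working observation with known variance,
#' \eqn{\hat\theta_i \sim N(\eta_i, V_i)}; stage 2 decomposes
#' \eqn{\eta_i = \mu + u_i + v_i} with an ICAR prior on \eqn{u} (sum-to-zero
#' enforced by re-centering every sweep) and iid normal \eqn{v}; stage 3
#' places Gamma hyperpriors on the precisions and a flat prior on \eqn{\mu}.
#' All full conditionals are conjugate, so the sampler is a plain Gibbs
#' scheme (no tuning). Degenerate areas (zero or unit prevalence, or no
#' respondents) carry no likelihood term: their \eqn{\eta_i} draws come from
#' the prior conditional on the neighbouring effects, which is exactly how
#' the model produces strictly positive smoothed prevalences for areas whose
#' direct estimate is 0.
#'
#' @param directs an \code{sae_direct} table covering every area (degenerate
#'   rows included); non-degenerate rows must have \code{theta_hat} and
#'   \code{var_theta} filled (see [empirical_logit()]), or they are filled
#'   here
#' @param adjacency neighbor index list over the areas (in table order), a
#'   0/1 adjacency matrix, or an \code{sae_geography} (its tract graph)
#' @param spec an \code{sae_spec}
#' @return object of class \code{sae_fit}: retained draws of \code{mu},
#'   \code{tau_u}, \code{tau_v}, matrices \code{u}, \code{v} and
#'   \code{eta} (draws x areas), plus \code{area_id}, \code{obs} flags, the
#'   working observations and the spec
#' @export
fit_smoothing_model <- function(directs, adjacency, spec = smoothing_spec()) {
  stopifnot(inherits(spec, "sae_spec"))
  directs <- with_logits(directs)
  n <- nrow(directs)
  obs <- !directs$degenerate
  if (sum(obs) < 2)
    stop("need at least 2 non-degenerate areas to identify the model")
  if (any(obs & !(directs$var_theta > 0)))
    stop("non-degenerate areas must have strictly positive var_theta")

  nb <- as_nblist(adjacency)
  if (length(nb) != n) stop("adjacency does not match the number of areas")
  if (spec$effect_structure != "iid_only" && !graph_connected(nb))
    stop("adjacency graph must be connected for ICAR structures")

  nb0 <- lapply(nb, function(x) as.integer(x) - 1L)
  nb_len <- lengths(nb0)
  nb_start <- c(0L, cumsum(nb_len))[seq_len(n)]
  theta <- ifelse(obs, directs$theta_hat, 0)
  V <- ifelse(obs, directs$var_theta, 1)

  set.seed(spec$seed)
  draws <- gibbs_bym_cpp(
    theta, V, as.integer(obs), unlist(nb0) %||% integer(0),
    as.integer(nb_start), as.integer(nb_len),
    spec$iterations, spec$burn_in, spec$thin,
    structure_rank(spec$effect_structure) - 1L,
    spec$prior_u[1], spec$prior_u[2], spec$prior_v[1], spec$prior_v[2],
    spec$tau_u_fixed %||% NA_real_, spec$tau_v_fixed %||% NA_real_)

  eta <- draws$mu + draws$u + draws$v
  colnames(eta) <- directs$area_id
  structure(list(mu = draws$mu, tau_u = draws$tau_u, tau_v = draws$tau_v,
                 u = draws$u, v = draws$v, eta = eta,
                 area_id = directs$area_id, obs = obs,
                 theta_hat = directs$theta_hat,
                 var_theta = directs$var_theta, spec = spec),
            class = "sae_fit")
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf(
    "Smoothing fit (%s): %d areas (%d with data), %d retained draws\n",
    x$spec$effect_structure, length(x$area_id), sum(x$obs), nrow(x$eta)))
  cat(sprintf("  posterior median mu = %.3f; min ESS(eta) = %.0f\n",
              median(x$mu), min(effective_size(x))))
  invisible(x)
}

## Crude effective sample size per area from the lag-1 autocorrelation.
effective_size <- function(fit) {
  apply(fit$eta, 2, function(e) {
    r1 <- suppressWarnings(stats::cor(e[-1], e[-length(e)]))
    if (!is.finite(r1)) return(length(e))
    max(1, length(e) * (1 - r1) / (1 + r1))
  })
}

#' Conditional predictive ordinates
#'
#' Estimates each non-degenerate area's leave-one-out predictive density by
#' the harmonic-mean identity,
#' \eqn{CPO_i = [\,\mathrm{mean}_s\; 1 / N(\hat\theta_i \mid \eta_i^{(s)},
#' V_i)\,]^{-1}}, over the retained posterior draws, and the model-comparison
#' score \eqn{\sum_i \log CPO_i}. Draws at which the density underflows to
#' zero are excluded with a count.
#'
#' @param fit an \code{sae_fit}
#' @param directs the \code{sae_direct} table the fit was computed from
#' @return list of class \code{sae_cpo}: per-area \code{cpo} (NA for
#'   degenerate areas), \code{sum_log_cpo}, \code{n_excluded} draws
#' @export
compute_cpo <- function(fit, directs) {
  stopifnot(inherits(fit, "sae_fit"),
            identical(as.character(directs$area_id),
                      as.character(fit$area_id)))
  directs <- with_logits(directs)
  n <- length(fit$area_id)
  cpo <- rep(NA_real_, n)
  excluded <- 0L
  for (i in which(!directs$degenerate)) {
    d <- dnorm(directs$theta_hat[i], mean = fit$eta[, i],
               sd = sqrt(directs$var_theta[i]))
    bad <- !is.finite(d) | d <= 0
    excluded <- excluded + sum(bad)
    if (all(bad)) stop("all draws excluded for area ", fit$area_id[i])
    cpo[i] <- 1 / mean(1 / d[!bad])
  }
  structure(list(cpo = cpo, sum_log_cpo = sum(log(cpo), na.rm = TRUE),
                 n_excluded = excluded, area_id = fit$area_id),
            class = "sae_cpo")
}

#' Select among candidate random-effect structures by CPO
#'
#' Returns the fit whose sum of log conditional predictive ordinates is
#' highest; exact ties break toward the simpler structure
#' (iid < icar < icar+iid). All candidates must have been fit to the same
#' working observations.
#'
#' @param fits list of \code{sae_fit} objects on identical data
#' @param directs the shared \code{sae_direct} table
#' @return list: \code{chosen} (the winning \code{sae_fit}),
#'   \code{scores} data.frame of structure and sum_log_cpo
#' @export
select_model <- function(fits, directs) {
  stopifnot(length(fits) >= 2)
  ref <- fits[[1]]
  for (f in fits[-1]) {
    if (!identical(as.character(f$area_id), as.character(ref$area_id)) ||
        !isTRUE(all.equal(f$theta_hat, ref$theta_hat)) ||
        !isTRUE(all.equal(f$var_theta, ref$var_theta)))
      stop("candidate fits were not computed on identical data")
  }
  scores <- data.frame(
    structure = vapply(fits, function(f) f$spec$effect_structure, ""),
    sum_log_cpo = vapply(fits, function(f)
      compute_cpo(f, directs)$sum_log_cpo, numeric(1)))
  best <- pick_best(scores$structure, scores$sum_log_cpo)
  list(chosen = fits[[best]], scores = scores)
}

## Argmax of the CPO score; exact ties break toward the simpler structure.
pick_best <- function(structures, sums) {
  best <- which(sums == max(sums))
  if (length(best) > 1)
    best <- best[order(structure_rank(structures[best]))][1]
  best
}

#' Summarize a fit on the prevalence scale
#'
#' Applies the inverse logit to every retained draw of each area's linear
#' predictor and reports the posterior median and the equal-tailed credible
#' interval at the requested level. Because the transform is applied
#' draw-wise, every summary lies strictly inside (0, 1) — including for
#' areas whose direct estimate was 0 or 1.
#'
#' @param fit an \code{sae_fit}
#' @param level interval level in (0, 1); default from the fit's spec
#' @return data.frame of class \code{sae_smoothed}: area_id, median, lower,
#'   upper, ci_half_width, level
#' @export
summarize_fit <- function(fit, level = fit$spec$level) {
  stopifnot(inherits(fit, "sae_fit"), level > 0, level < 1)
  if (nrow(fit$eta) < 100)
    stop("fewer than 100 retained draws: quantiles would be unstable")
  p <- plogis(fit$eta)
  qs <- t(apply(p, 2, interval_from_draws, level = level))
  out <- data.frame(area_id = fit$area_id, median = qs[, "median"],
                    lower = qs[, "lower"], upper = qs[, "upper"],
                    ci_half_width = (qs[, "upper"] - qs[, "lower"]) / 2,
                    level = level, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("sae_smoothed", "data.frame")
  out
}

#' @export
summary.sae_fit <- function(object, level = object$spec$level, ...)
  summarize_fit(object, level)
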