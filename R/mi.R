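#' Multiple imputation of missing tracts with re-smoothing
#'
#' For each of M imputations, respondents with missing tracts are completed
#' by crosswalk-ratio random allocation under a distinct sub-seed, the
#' direct estimates and empirical logits are recomputed on the completed
#' data, and the smoothing model is refit. Raking weights are held fixed
#' across imputations (they depend only on demographics, which are fully
#' observed). All M fits are retained so that pooling can mix their
#' posterior draws.
#'
#' @param respondents respondent data.frame (may contain missing tracts)
#' @param crosswalk zip-tract residential-ratio table
#' @param adjacency tract adjacency (neighbor list, matrix or
#'   \code{sae_geography})
#' @param spec an \code{sae_spec}
#' @param M number of imputations (>= 1); the reference analysis uses 100
#' @param seed master seed; imputation m uses \code{sub_seed(seed, m)} for
#'   the allocation and \code{sub_seed(seed, M + m)} for the sampler
#' @param weights per-respondent analysis weights; default base weights
#' @param areas character vector of all tract ids (areas with no
#'   respondents are kept for prediction)
#' @return object of class \code{sae_mi_run}: list with \code{fits} (M
#'   \code{sae_fit}s), \code{tracts} (M completed tract vectors),
#'   \code{alloc_seeds}, \code{fit_seeds}, \code{M}, \code{area_id}
#' @export
run_mi_smoothing <- function(respondents, crosswalk, adjacency, spec, M,
                             seed, weights = respondents$base_weight,
                             areas = NULL) {
  if (!(is.numeric(M) && M >= 1)) stop("M must be >= 1")
  M <- as.integer(M)
  areas <- areas %||% sort(unique(c(respondents$tract, crosswalk$tract)))
  areas <- areas[!is.na(areas)]
  alloc_seeds <- vapply(seq_len(M), function(m) sub_seed(seed, m), 1L)
  fit_seeds <- vapply(seq_len(M), function(m) sub_seed(seed, M + m), 1L)
  if (anyDuplicated(c(alloc_seeds, fit_seeds)))
    stop("sub-seed collision; choose a different master seed")

  fits <- vector("list", M)
  tracts <- vector("list", M)
  for (m in seq_len(M)) {
    completed <- tryCatch(
      allocate_missing(respondents, crosswalk, seed = alloc_seeds[m]),
      error = function(e)
        stop("imputation ", m, " (seed ", alloc_seeds[m], ") failed: ",
             conditionMessage(e)))
    directs <- direct_estimate(completed, weights, "tract", areas = areas)
    spec_m <- spec
    spec_m$seed <- fit_seeds[m]
    fits[[m]] <- tryCatch(
      fit_smoothing_model(with_logits(directs), adjacency, spec_m),
      error = function(e)
        stop("imputation ", m, " (seed ", fit_seeds[m], ") failed: ",
             conditionMessage(e)))
    tracts[[m]] <- completed$tract
  }
  structure(list(fits = fits, tracts = tracts, alloc_seeds = alloc_seeds,
                 fit_seeds = fit_seeds, M = M, area_id = areas),
            class = "sae_mi_run")
}

#' @export
print.sae_mi_run <- function(x, ...) {
  cat(sprintf("Multiple-imputation smoothing run: M = %d, %d areas\n",
              x$M, length(x$area_id)))
  invisible(x)
}

#' Pool smoothed estimates across imputations
#'
#' The retained prevalence-scale posterior draws of all M fits are pooled
#' into one equally-weighted mixture per area; the reported median and
#' equal-tailed interval are quantiles of that mixture. Between-imputation
#' spread therefore widens the intervals automatically, which is how
#' imputation uncertainty propagates into the final estimates; with M = 1
#' pooling is the identity.
#'
#' @param run an \code{sae_mi_run}
#' @param level interval level in (0, 1)
#' @return data.frame of class \code{sae_smoothed} with an extra \code{M}
#'   column
#' @export
pool_estimates <- function(run, level = 0.9) {
  stopifnot(inherits(run, "sae_mi_run"), level > 0, level < 1)
  ids <- lapply(run$fits, function(f) as.character(f$area_id))
  if (length(unique(ids)) != 1)
    stop("imputation fits do not cover identical areas")
  p_all <- do.call(rbind, lapply(run$fits, function(f) plogis(f$eta)))
  qs <- t(apply(p_all, 2, interval_from_draws, level = level))
  out <- data.frame(area_id = run$fits[[1]]$area_id,
                    median = qs[, "median"], lower = qs[, "lower"],
                    upper = qs[, "upper"],
                    ci_half_width = (qs[, "upper"] - qs[, "lower"]) / 2,
                    level = level, M = run$M,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sae_smoothed", "data.frame")
  out
}
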