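#' Rake survey weights to population margins
#'
#' Iterative proportional fitting (IPF): starting from the base design
#' weights, weights are scaled within the categories of each margin in turn
#' so the weighted sample totals match the known population totals, and the
#' cycle repeats until every margin is reproduced within \code{tol}
#' (maximum absolute relative deviation).
#'
#' @param respondents respondent data.frame; each margin name must be a
#'   column
#' @param margins named list of margins, in raking order; each element is a
#'   named numeric vector mapping category to population total (> 0). All
#'   margins must share the same grand total to within 1e-6 relative.
#' @param max_iter maximum IPF cycles
#' @param tol convergence tolerance on the relative margin deviation
#' @return list of class \code{sae_raking}: \code{weights} (per respondent),
#'   \code{iterations}, \code{max_dev}, \code{converged}
#' @examples
#' r <- data.frame(sex = c("F", "F", "M"), y = c(1, 0, 1),
#'                 base_weight = c(1, 1, 1))
#' rk <- rake_weights(r, list(sex = c(F = 60, M = 40)))
#' sum(rk$weights)  # 100
#' @export
rake_weights <- function(respondents, margins, max_iter = 100, tol = 1e-10) {
  stopifnot(is.list(margins), length(margins) >= 1,
            !is.null(names(margins)), all(names(margins) != ""))
  if (is.null(respondents$base_weight) || any(respondents$base_weight <= 0))
    stop("respondents must carry positive base_weight")

  totals <- vapply(margins, sum, numeric(1))
  if (max(abs(totals - totals[1])) > 1e-6 * abs(totals[1]))
    stop("margins disagree on the grand population total")

  idx <- list()
  for (mname in names(margins)) {
    m <- margins[[mname]]
    if (any(m <= 0)) stop("margin '", mname, "' has non-positive totals")
    obs <- respondents[[mname]]
    if (is.null(obs)) stop("respondents lack margin column '", mname, "'")
    if (!all(obs %in% names(m)))
      stop("margin '", mname, "' is missing categories present in the ",
           "sample: ", paste(setdiff(unique(obs), names(m)), collapse = ", "))
    empty <- setdiff(names(m), unique(obs))
    if (length(empty))
      stop("no respondents in category '", empty[1], "' of margin '",
           mname, "' but its population total is nonzero")
    idx[[mname]] <- split(seq_len(nrow(respondents)), obs)
  }

  w <- respondents$base_weight
  max_dev <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (mname in names(margins)) {
      m <- margins[[mname]]
      for (cat in names(m)) {
        rows <- idx[[mname]][[cat]]
        s <- sum(w[rows])
        w[rows] <- w[rows] * (m[[cat]] / s)
      }
    }
    max_dev <- 0
    for (mname in names(margins)) {
      m <- margins[[mname]]
      for (cat in names(m)) {
        s <- sum(w[idx[[mname]][[cat]]])
        max_dev <- max(max_dev, abs(s - m[[cat]]) / m[[cat]])
      }
    }
    if (max_dev < tol) break
  }
  if (max_dev >= tol)
    stop(sprintf(
      "raking did not converge in %d iterations (residual %.3g > tol %.3g)",
      max_iter, max_dev, tol))
  structure(list(weights = w, iterations = it, max_dev = max_dev,
                 converged = TRUE), class = "sae_raking")
}

#' @export
print.sae_raking <- function(x, ...) {
  cat(sprintf("Raked weights: %d respondents, %d IPF cycles, residual %.2g\n",
              length(x$weights), x$iterations, x$max_dev))
  invisible(x)
}
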