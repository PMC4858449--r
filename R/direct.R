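#' Design-based direct estimates of area prevalence
#'
#' The Horvitz–Thompson style weighted prevalence per area,
#' \eqn{\hat p = \sum w_i y_i / \sum w_i}, with the single-stage
#' with-replacement design variance
#' \eqn{\widehat{var}(\hat p) = \sum w_i^2 (y_i - \hat p)^2 / (\sum w_i)^2}.
#' Areas where \eqn{\hat p \in \{0, 1\}} (or with no respondents) are flagged
#' degenerate: their design variance is zero or undefined, so they
#' contribute no working-likelihood term downstream and are estimated from
#' the spatial prior alone. Such areas are kept in the output so the
#' smoothing model can predict them.
#'
#' @param respondents respondent data.frame with binary column \code{y}
#' @param weights positive per-respondent weights (e.g. raked)
#' @param area_field name of the column holding the area id (\code{"tract"}
#'   or \code{"hra"})
#' @param areas optional character vector of all area ids; areas with no
#'   respondents are emitted with \code{n = 0} and \code{degenerate = TRUE}
#' @return data.frame of class \code{sae_direct}: area_id, n, p_hat, var_p,
#'   theta_hat, var_theta (NA until [empirical_logit()]), degenerate
#' @examples
#' r <- data.frame(tract = c("a", "a", "b"), y = c(1, 0, 1))
#' direct_estimate(r, weights = c(1, 1, 1), area_field = "tract")
#' @export
direct_estimate <- function(respondents, weights, area_field,
                            areas = NULL) {
  if (length(weights) != nrow(respondents))
    stop("weights must have one entry per respondent")
  if (any(weights <= 0)) stop("weights must be positive")
  a <- respondents[[area_field]]
  if (is.null(a)) stop("no such area field: ", area_field)
  if (anyNA(a)) stop("respondents with missing ", area_field,
                     " cannot enter direct estimation")
  areas <- areas %||% sort(unique(a))

  out <- data.frame(area_id = areas, n = 0L, p_hat = NA_real_,
                    var_p = NA_real_, theta_hat = NA_real_,
                    var_theta = NA_real_, degenerate = TRUE,
                    stringsAsFactors = FALSE)
  rows <- split(seq_len(nrow(respondents)), factor(a, levels = areas))
  for (k in seq_along(areas)) {
    i <- rows[[k]]
    if (!length(i)) next
    w <- weights[i]; y <- respondents$y[i]
    W <- sum(w)
    p <- sum(w * y) / W
    v <- sum(w^2 * (y - p)^2) / W^2
    out$n[k] <- length(i)
    out$p_hat[k] <- p
    out$var_p[k] <- v
    out$degenerate[k] <- (p <= 0 || p >= 1 || v == 0)
  }
  class(out) <- c("sae_direct", "data.frame")
  out
}

#' Empirical-logit transform of direct estimates
#'
#' Fills \eqn{\hat\theta = \log(\hat p / (1 - \hat p))} and its delta-method
#' variance \eqn{\widehat{var}(\hat\theta) = \widehat{var}(\hat p) /
#' (\hat p (1 - \hat p))^2}, the Gaussian working observation used by the
#' smoothing model. Refuses degenerate rows (\eqn{\hat p \in \{0,1\}} or
#' zero variance): those areas must be routed to prediction-only handling.
#'
#' @param direct an \code{sae_direct} table (or subset of rows)
#' @return the table with \code{theta_hat} and \code{var_theta} filled
#' @export
empirical_logit <- function(direct) {
  if (any(direct$degenerate))
    stop("empirical logit undefined for degenerate areas (p_hat in {0,1} ",
         "or zero variance); filter them out first")
  p <- direct$p_hat
  direct$theta_hat <- log(p / (1 - p))
  direct$var_theta <- direct$var_p / (p * (1 - p))^2
  direct
}

## Fill logits on the non-degenerate rows, keep degenerate rows NA.
with_logits <- function(direct) {
  ok <- !direct$degenerate
  if (any(ok)) direct[ok, ] <- empirical_logit(direct[ok, ])
  direct
}

#' Write direct estimates as a delimited table
#'
#' @param direct an \code{sae_direct}
#' @param path file path
#' @export
write_direct <- function(direct, path) {
  write.table(direct, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
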