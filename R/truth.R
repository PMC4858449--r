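#' Simulate a true prevalence surface
#'
#' Draws tract-level true prevalences from the same structure the smoothing
#' model assumes: on the logit scale, an intercept plus an intrinsic
#' conditional autoregressive (ICAR) spatial effect plus an independent
#' unstructured effect. The ICAR draw uses the eigendecomposition of the graph
#' Laplacian with the null space removed — for Laplacian eigenpairs
#' \eqn{(\lambda_k, e_k)} with \eqn{\lambda_k > 0}, \eqn{u = \sigma_u \sum_k
#' \lambda_k^{-1/2} z_k e_k}, \eqn{z_k} iid standard normal — then re-centered
#' to sum to zero, so \code{sigma_u} scales the pairwise-difference precision
#' (\eqn{\tau_u = \sigma_u^{-2}}), not the marginal standard deviation.
#'
#' @param geo an \code{sae_geography} with a connected tract graph
#' @param mu intercept on the logit scale
#' @param sigma_u ICAR scale (>= 0); 0 disables the spatial effect
#' @param sigma_v standard deviation of the iid effect (>= 0)
#' @param seed integer seed
#' @return an object of class \code{sae_truth}: list with \code{mu},
#'   per-tract \code{u}, \code{v}, and \code{p_true =
#'   plogis(mu + u + v)}
#' @examples
#' geo <- sim_geography(16, 4, 2, seed = 1)
#' truth <- sim_truth(geo, mu = qlogis(0.12), sigma_u = 0.4,
#'                    sigma_v = 0.2, seed = 2)
#' range(truth$p_true)
#' @export
sim_truth <- function(geo, mu, sigma_u, sigma_v, seed) {
  stopifnot(inherits(geo, "sae_geography"))
  if (sigma_u < 0 || sigma_v < 0) stop("sigma_u and sigma_v must be >= 0")
  n <- length(geo$tract_ids)
  if (n > 1 && !graph_connected(geo$nb))
    stop("ICAR draw undefined: tract graph is disconnected")
  set.seed(as.integer(seed))

  u <- rep(0, n)
  if (sigma_u > 0 && n > 1) {
    deg <- lengths(geo$nb)
    L <- diag(deg)
    for (i in seq_len(n)) L[i, geo$nb[[i]]] <- -1
    e <- eigen(L, symmetric = TRUE)
    keep <- seq_len(n - 1)  # drop the constant null eigenvector
    z <- rnorm(n - 1)
    u <- as.numeric(e$vectors[, keep] %*% (z / sqrt(e$values[keep]))) * sigma_u
    u <- u - mean(u)
  }
  v <- if (sigma_v > 0) rnorm(n, 0, sigma_v) else rep(0, n)
  eta <- mu + u + v
  structure(list(mu = mu, u = u, v = v, p_true = plogis(eta),
                 sigma_u = sigma_u, sigma_v = sigma_v),
            class = "sae_truth")
}

#' @export
print.sae_truth <- function(x, ...) {
  cat(sprintf(
    "True prevalence surface: %d tracts, median %.3f, range [%.3f, %.3f]\n",
    length(x$p_true), median(x$p_true), min(x$p_true), max(x$p_true)))
  invisible(x)
}
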