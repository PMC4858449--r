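## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed
#'
#' Sub-seeds for independent stages (imputations, replicates) are derived from
#' the master seed by a fixed counter scheme so each stage is independently
#' reproducible. Kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param counter positive integer stage index
#' @return an integer seed
#' @export
sub_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(counter), counter >= 1)
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483587)
}

## Draw from a Dirichlet(alpha) via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

## Breadth-first connectivity check on a neighbor list.
graph_connected <- function(nb) {
  n <- length(nb)
  if (n == 0L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in nb[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  all(seen)
}

## Adjacency matrix (0/1) -> neighbor index list.
adjacency_to_nblist <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
  if (any(diag(adj) != 0)) stop("adjacency must be irreflexive")
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] != 0))
}

## Quantile-based equal-tailed interval of draws on the prevalence scale.
interval_from_draws <- function(draws, level) {
  alpha <- (1 - level) / 2
  qs <- quantile(draws, probs = c(alpha, 0.5, 1 - alpha), names = FALSE,
                 type = 7)
  c(lower = qs[1], median = qs[2], upper = qs[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
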