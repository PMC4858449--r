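#' Simulate a synthetic county geography
#'
#' Builds a toy county on a rectangular grid of census tracts with shared-edge
#' (rook) adjacency. Zip codes and health reporting areas (HRAs) are contiguous
#' blocks of tracts taken along a boustrophedon (snake) ordering of the grid,
#' so both are connected but their boundaries do not coincide: a zip can
#' straddle several HRAs, which is what makes population-share assignment of
#' zip-only respondents to HRAs non-trivial. Residential-address shares of the
#' tracts within each zip (the crosswalk ratios used to impute missing tract
#' geocodes) are drawn from a symmetric Dirichlet and renormalized; HRA
#' population shares per zip are derived from those same ratios, so both sets
#' of shares sum to one within each zip by construction.
#'
#' @param n_tracts number of census tracts (grid cells)
#' @param n_zips number of zip codes; must satisfy
#'   \code{n_tracts >= n_zips >= 1}
#' @param n_hras number of health reporting areas; must satisfy
#'   \code{n_tracts >= n_hras >= 1}
#' @param seed integer seed; identical seeds give identical geographies
#' @param concentration Dirichlet concentration for the within-zip
#'   residential-address shares (1 = uniform on the simplex)
#' @return an object of class \code{sae_geography}: a list with
#'   \code{tract_ids}, \code{zip_ids}, \code{hra_ids}, \code{nb} (neighbor
#'   index list), \code{crosswalk} (zip, tract, res_ratio), \code{hra_share}
#'   (zip, hra, pop_share), \code{tract_to_hra}, \code{tract_to_zip},
#'   \code{tract_region} (north/south split of the grid) and \code{grid_dim}.
#' @examples
#' geo <- sim_geography(n_tracts = 9, n_zips = 3, n_hras = 2, seed = 1)
#' geo
#' @export
sim_geography <- function(n_tracts, n_zips, n_hras, seed,
                          concentration = 1) {
  if (!is.numeric(n_tracts) || n_tracts < 1)
    stop("n_tracts must be >= 1")
  if (!is.numeric(n_zips) || n_zips < 1 || n_zips > n_tracts)
    stop("need n_tracts >= n_zips >= 1 (got n_zips = ", n_zips, ")")
  if (!is.numeric(n_hras) || n_hras < 1 || n_hras > n_tracts)
    stop("need n_tracts >= n_hras >= 1 (got n_hras = ", n_hras, ")")
  n_tracts <- as.integer(n_tracts)
  n_zips <- as.integer(n_zips)
  n_hras <- as.integer(n_hras)
  set.seed(as.integer(seed))

  nc <- as.integer(ceiling(sqrt(n_tracts)))
  idx <- seq_len(n_tracts) - 1L
  row <- idx %/% nc + 1L
  col <- idx %% nc + 1L

  ## rook adjacency on the (possibly ragged) grid
  nb <- vector("list", n_tracts)
  cell <- matrix(NA_integer_, nrow = max(row), ncol = nc)
  cell[cbind(row, col)] <- seq_len(n_tracts)
  for (i in seq_len(n_tracts)) {
    r <- row[i]; c <- col[i]
    cand <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    keep <- cand[, 1] >= 1 & cand[, 1] <= nrow(cell) &
      cand[, 2] >= 1 & cand[, 2] <= nc
    nbs <- cell[cand[keep, , drop = FALSE]]
    nb[[i]] <- sort(nbs[!is.na(nbs)])
  }

  ## snake ordering: consecutive positions are always grid-adjacent, so
  ## consecutive blocks form connected zips/HRAs. When the last row is
  ## partial, row directions are chosen so the path enters it at column 1.
  rem <- n_tracts %% nc
  nr_full <- n_tracts %/% nc
  off <- if (rem > 0) nr_full %% 2 else 1L
  snake <- unlist(lapply(seq_len(max(row)), function(r) {
    ids <- cell[r, !is.na(cell[r, ])]
    if ((r + off) %% 2 == 1) ids else rev(ids)
  }), use.names = FALSE)

  block_cut <- function(n, k) sort((seq_len(n) - 1L) %% k + 1L)
  zip_of <- integer(n_tracts); zip_of[snake] <- block_cut(n_tracts, n_zips)
  hra_of <- integer(n_tracts); hra_of[snake] <- block_cut(n_tracts, n_hras)

  tract_ids <- sprintf("T%03d", seq_len(n_tracts))
  zip_ids <- sprintf("Z%02d", seq_len(n_zips))
  hra_ids <- sprintf("H%02d", seq_len(n_hras))

  cw <- do.call(rbind, lapply(seq_len(n_zips), function(z) {
    tr <- which(zip_of == z)
    shares <- rdirichlet1(rep(concentration, length(tr)))
    shares <- shares / sum(shares)
    data.frame(zip = zip_ids[z], tract = tract_ids[tr],
               res_ratio = shares, stringsAsFactors = FALSE)
  }))
  rownames(cw) <- NULL

  ## HRA population shares within a zip follow the residential-address shares
  tract_hra <- hra_ids[hra_of]
  names(tract_hra) <- tract_ids
  hs <- do.call(rbind, lapply(seq_len(n_zips), function(z) {
    rows <- cw[cw$zip == zip_ids[z], ]
    agg <- tapply(rows$res_ratio, tract_hra[rows$tract], sum)
    data.frame(zip = zip_ids[z], hra = names(agg),
               pop_share = as.numeric(agg) / sum(agg),
               stringsAsFactors = FALSE)
  }))
  rownames(hs) <- NULL

  tract_zip <- zip_ids[zip_of]
  names(tract_zip) <- tract_ids

  region <- ifelse(row <= max(row) / 2, "north", "south")
  names(region) <- tract_ids

  geo <- structure(list(
    tract_ids = tract_ids, zip_ids = zip_ids, hra_ids = hra_ids,
    nb = nb, crosswalk = cw, hra_share = hs,
    tract_to_hra = tract_hra, tract_to_zip = tract_zip,
    tract_region = region, grid_dim = c(rows = max(row), cols = nc)
  ), class = "sae_geography")
  validate_geography(geo)
  geo
}

#' Validate a county geography
#'
#' Checks the structural invariants: crosswalk residential ratios and HRA
#' population shares sum to one within each zip (to 1e-9), adjacency is
#' symmetric and irreflexive, the tract graph is connected, and every tract
#' appears in at least one crosswalk row.
#'
#' @param geo an \code{sae_geography}
#' @return \code{geo}, invisibly; errors describe the violated invariant
#' @export
validate_geography <- function(geo) {
  stopifnot(inherits(geo, "sae_geography"))
  n <- length(geo$tract_ids)
  cw_sums <- tapply(geo$crosswalk$res_ratio, geo$crosswalk$zip, sum)
  if (any(abs(cw_sums - 1) > 1e-9))
    stop("crosswalk res_ratio does not sum to 1 within every zip")
  hs_sums <- tapply(geo$hra_share$pop_share, geo$hra_share$zip, sum)
  if (any(abs(hs_sums - 1) > 1e-9))
    stop("hra_share pop_share does not sum to 1 within every zip")
  for (i in seq_len(n)) {
    if (i %in% geo$nb[[i]]) stop("adjacency is not irreflexive at tract ", i)
    for (j in geo$nb[[i]])
      if (!(i %in% geo$nb[[j]])) stop("adjacency is not symmetric")
  }
  if (n > 1 && !graph_connected(geo$nb))
    stop("tract adjacency graph is not connected")
  if (!all(geo$tract_ids %in% geo$crosswalk$tract))
    stop("some tracts appear in no crosswalk row")
  invisible(geo)
}

#' @export
print.sae_geography <- function(x, ...) {
  cat("Synthetic county geography\n")
  cat(sprintf("  %d tracts on a %d x %d grid, %d zips, %d HRAs\n",
              length(x$tract_ids), x$grid_dim[1], x$grid_dim[2],
              length(x$zip_ids), length(x$hra_ids)))
  cat(sprintf("  mean tracts per zip: %.1f\n",
              length(x$tract_ids) / length(x$zip_ids)))
  invisible(x)
}

#' Derive reporting-area adjacency from tract adjacency
#'
#' Two HRAs are neighbors when any of their member tracts share a grid edge.
#'
#' @param geo an \code{sae_geography}
#' @return neighbor index list over \code{geo$hra_ids}
#' @export
hra_adjacency <- function(geo) {
  h <- match(geo$tract_to_hra, geo$hra_ids)
  nh <- length(geo$hra_ids)
  nb <- lapply(seq_len(nh), function(k) integer(0))
  for (i in seq_along(geo$nb)) {
    for (j in geo$nb[[i]]) {
      if (h[i] != h[j]) nb[[h[i]]] <- union(nb[[h[i]]], h[j])
    }
  }
  lapply(nb, sort)
}

#' Write or read geography tables
#'
#' The crosswalk (zip, tract, res_ratio), HRA share table (zip, hra,
#' pop_share) and tract adjacency edge list (tract_a, tract_b) are stored as
#' headered tab-delimited text, one file each, under \code{dir}.
#'
#' @param geo an \code{sae_geography}
#' @param dir output directory, created if needed
#' @return \code{write_geography} returns the file paths invisibly
#' @export
write_geography <- function(geo, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_cw <- file.path(dir, "crosswalk.tsv")
  f_hs <- file.path(dir, "hra_share.tsv")
  f_ad <- file.path(dir, "adjacency.tsv")
  write.table(geo$crosswalk, f_cw, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(geo$hra_share, f_hs, sep = "\t", row.names = FALSE,
              quote = FALSE)
  edges <- do.call(rbind, lapply(seq_along(geo$nb), function(i) {
    j <- geo$nb[[i]][geo$nb[[i]] > i]
    if (length(j)) data.frame(tract_a = geo$tract_ids[i],
                              tract_b = geo$tract_ids[j]) else NULL
  }))
  write.table(edges, f_ad, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(crosswalk = f_cw, hra_share = f_hs, adjacency = f_ad))
}

#' @rdname write_geography
#' @return \code{read_crosswalk} returns the crosswalk data frame
#' @param path file path
#' @export
read_crosswalk <- function(path) {
  cw <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"))
  stopifnot(identical(names(cw), c("zip", "tract", "res_ratio")))
  cw
}
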