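#' Randomly allocate missing tracts from crosswalk ratios
#'
#' Each respondent with a missing tract is assigned one independently at
#' random among the tracts of their zip, with probabilities equal to the
#' zip's residential-address ratios. Observed tracts are never altered, and
#' no other field is touched.
#'
#' @param respondents respondent data.frame (column \code{tract} may hold
#'   \code{NA})
#' @param crosswalk data.frame (zip, tract, res_ratio); ratios must sum to 1
#'   within each zip
#' @param seed integer seed; same seed, same assignment
#' @return the completed respondent table (zero missing tracts)
#' @examples
#' cw <- data.frame(zip = "Z1", tract = c("a", "b", "c"),
#'                  res_ratio = c(0.705, 0.208, 0.087))
#' r <- data.frame(id = 1:4, zip = "Z1", tract = NA_character_)
#' table(allocate_missing(r, cw, seed = 1)$tract)
#' @export
allocate_missing <- function(respondents, crosswalk, seed) {
  miss <- which(is.na(respondents$tract))
  if (!length(miss)) return(respondents)
  zips <- unique(respondents$zip[miss])
  absent <- setdiff(zips, unique(crosswalk$zip))
  if (length(absent))
    stop("zip(s) absent from the crosswalk: ", paste(absent, collapse = ", "))
  set.seed(as.integer(seed))
  for (z in zips) {
    rows <- crosswalk[crosswalk$zip == z, ]
    who <- miss[respondents$zip[miss] == z]
    pick <- sample.int(nrow(rows), length(who), replace = TRUE,
                       prob = rows$res_ratio)
    respondents$tract[who] <- rows$tract[pick]
  }
  respondents
}

#' Assign respondents to health reporting areas
#'
#' Respondents with a geocoded tract take that tract's HRA deterministically.
#' For the rest, a zip whose population lies at least \code{threshold}
#' (default 95%) within a single HRA sends all its respondents to that HRA;
#' otherwise the HRA is drawn at random with the zip's population shares.
#'
#' @param respondents respondent data.frame (columns \code{zip},
#'   \code{tract})
#' @param hra_share data.frame (zip, hra, pop_share)
#' @param tract_to_hra named character vector mapping tract to its HRA
#' @param threshold deterministic-assignment share in (0.5, 1]
#' @param seed integer seed
#' @return the respondents with an \code{hra} column filled for every row
#' @export
assign_hra <- function(respondents, hra_share, tract_to_hra,
                       threshold = 0.95, seed = 1) {
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must lie in (0.5, 1]")
  respondents$hra <- NA_character_
  geocoded <- !is.na(respondents$tract)
  respondents$hra[geocoded] <-
    unname(tract_to_hra[respondents$tract[geocoded]])

  set.seed(as.integer(seed))
  for (z in unique(respondents$zip[!geocoded])) {
    rows <- hra_share[hra_share$zip == z, ]
    if (!nrow(rows)) stop("zip ", z, " has no rows in hra_share")
    who <- which(!geocoded & respondents$zip == z)
    if (max(rows$pop_share) >= threshold) {
      respondents$hra[who] <- rows$hra[which.max(rows$pop_share)]
    } else {
      pick <- sample.int(nrow(rows), length(who), replace = TRUE,
                         prob = rows$pop_share)
      respondents$hra[who] <- rows$hra[pick]
    }
  }
  if (anyNA(respondents$hra)) stop("internal error: unassigned HRAs remain")
  respondents
}
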