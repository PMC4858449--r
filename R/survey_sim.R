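#' Default demographic structure for the synthetic survey
#'
#' Three demographic axes (age band, sex, race group) crossed into 12 cells.
#' \code{pop_share} is each cell's share of the adult population;
#' \code{intensity} is the cell's relative inclusion intensity (a telephone
#' survey over-represents older respondents), and \code{outcome_logit} shifts
#' the smoking log-odds by cell so that weighting genuinely matters. Shares
#' need not be calibrated to any real county; they only have to make the
#' design informative.
#'
#' @return a list with \code{cells} (data.frame: age, sex, race, pop_share,
#'   intensity, outcome_logit)
#' @export
default_selection_config <- function() {
  cells <- expand.grid(
    age = c("18-34", "35-64", "65+"),
    sex = c("F", "M"),
    race = c("white", "nonwhite"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  age_share <- c("18-34" = 0.30, "35-64" = 0.52, "65+" = 0.18)
  race_share <- c(white = 0.68, nonwhite = 0.32)
  cells$pop_share <- age_share[cells$age] * 0.5 * race_share[cells$race]
  ## older and white respondents answer more often
  age_int <- c("18-34" = 0.5, "35-64" = 1.0, "65+" = 1.8)
  race_int <- c(white = 1.2, nonwhite = 0.7)
  cells$intensity <- age_int[cells$age] * race_int[cells$race]
  ## young and male respondents smoke more, on the logit scale
  cells$outcome_logit <- ifelse(cells$age == "18-34", 0.35, 0) +
    ifelse(cells$age == "65+", -0.40, 0) +
    ifelse(cells$sex == "M", 0.25, 0)
  rownames(cells) <- NULL
  list(cells = cells)
}

cell_key <- function(df) paste(df$age, df$sex, df$race, sep = "|")

#' Simulate survey respondents
#'
#' Respondents are drawn cell-by-tract: the demographic cell with probability
#' proportional to population share times inclusion intensity, the tract with
#' probability proportional to tract population (zip population split by
#' residential-address share). The binary outcome is Bernoulli with
#' tract-level true prevalence shifted on the logit scale by the cell's
#' outcome effect, and the base weight is the inverse inclusion intensity, so
#' weighted means are design-consistent while unweighted means are biased
#' under informative selection.
#'
#' @param truth an \code{sae_truth}
#' @param geo an \code{sae_geography}
#' @param n number of respondents (>= 1)
#' @param selection_config as returned by [default_selection_config()];
#'   \code{NULL} uses the default
#' @param seed integer seed
#' @return data.frame with one row per respondent: id, zip, tract, age, sex,
#'   race, region, y, base_weight
#' @export
sim_survey <- function(truth, geo, n, selection_config = NULL, seed = 1) {
  stopifnot(inherits(truth, "sae_truth"), inherits(geo, "sae_geography"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  cfg <- selection_config %||% default_selection_config()
  cells <- cfg$cells
  if (any(cells$intensity <= 0) || any(cells$pop_share <= 0))
    stop("selection_config intensities and pop_shares must be positive")
  set.seed(as.integer(seed))

  sel_prob <- cells$pop_share * cells$intensity
  ci <- sample.int(nrow(cells), n, replace = TRUE,
                   prob = sel_prob / sum(sel_prob))

  ## tract population = zip population (proportional to zip tract count)
  ## split by residential share; equivalently res_ratio * n_tracts_in_zip
  zsize <- table(geo$crosswalk$zip)[geo$crosswalk$zip]
  tract_pop <- geo$crosswalk$res_ratio * as.numeric(zsize)
  tpop <- tapply(tract_pop, geo$crosswalk$tract, sum)[geo$tract_ids]
  ti <- sample.int(length(geo$tract_ids), n, replace = TRUE,
                   prob = as.numeric(tpop) / sum(tpop))

  eta <- qlogis(truth$p_true)[ti] + cells$outcome_logit[ci]
  y <- rbinom(n, 1, plogis(eta))

  data.frame(
    id = seq_len(n),
    zip = unname(geo$tract_to_zip[ti]),
    tract = geo$tract_ids[ti],
    age = cells$age[ci], sex = cells$sex[ci], race = cells$race[ci],
    region = unname(geo$tract_region[ti]),
    y = y,
    base_weight = 1 / cells$intensity[ci],
    stringsAsFactors = FALSE)
}

#' Population-level true prevalence implied by the generator
#'
#' Averages the cell-shifted tract prevalences over the demographic
#' population shares and tract populations; the design-weighted survey mean
#' is consistent for this quantity. With \code{by = "tract"} returns the
#' per-tract population prevalence.
#'
#' @inheritParams sim_survey
#' @param by \code{"county"} or \code{"tract"}
#' @return a single number, or a named per-tract vector
#' @export
true_prevalence <- function(truth, geo, selection_config = NULL,
                            by = c("county", "tract")) {
  by <- match.arg(by)
  cfg <- selection_config %||% default_selection_config()
  cells <- cfg$cells
  share <- cells$pop_share / sum(cells$pop_share)
  per_tract <- vapply(qlogis(truth$p_true), function(l)
    sum(share * plogis(l + cells$outcome_logit)), numeric(1))
  names(per_tract) <- geo$tract_ids
  if (by == "tract") return(per_tract)
  zsize <- table(geo$crosswalk$zip)[geo$crosswalk$zip]
  tract_pop <- geo$crosswalk$res_ratio * as.numeric(zsize)
  tpop <- tapply(tract_pop, geo$crosswalk$tract, sum)[geo$tract_ids]
  sum(per_tract * as.numeric(tpop)) / sum(tpop)
}

#' Blank census tracts under a covariate-dependent missingness model
#'
#' The probability that a respondent's tract geocode is missing follows a
#' logistic model on respondent covariates; zip codes are never blanked. The
#' default configuration makes missingness more likely for younger, nonwhite
#' and southern respondents, with the intercept calibrated (by
#' [calibrate_missingness()]) so the overall missing fraction is about 26%.
#'
#' @param respondents data.frame from [sim_survey()]
#' @param miss_config list with \code{intercept} (logit scale) and
#'   \code{coef}, a named vector whose names are \code{"column=level"} terms,
#'   e.g. \code{c("age=18-34" = 0.8)}; \code{NULL} uses the default
#'   calibrated configuration
#' @param seed integer seed
#' @return the respondents with \code{tract} set to \code{NA} where blanked
#' @export
apply_missingness <- function(respondents, miss_config = NULL, seed = 1) {
  cfg <- miss_config %||% calibrate_missingness(respondents)
  p <- missingness_prob(respondents, cfg)
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("missingness probabilities fall outside [0, 1]")
  set.seed(as.integer(seed))
  drop <- runif(nrow(respondents)) < p
  respondents$tract[drop] <- NA_character_
  respondents
}

missingness_prob <- function(respondents, cfg) {
  lp <- rep(cfg$intercept, nrow(respondents))
  for (term in names(cfg$coef)) {
    kv <- strsplit(term, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[1] %in% names(respondents))
      stop("malformed missingness term: ", term)
    lp <- lp + ifelse(respondents[[kv[1]]] == kv[2], cfg$coef[[term]], 0)
  }
  plogis(lp)
}

#' Calibrate the missingness intercept to a target overall rate
#'
#' Solves for the logistic intercept so the expected missing fraction over
#' the given respondents equals \code{target}, holding the covariate
#' coefficients fixed.
#'
#' @inheritParams apply_missingness
#' @param coef named coefficient vector (see [apply_missingness()])
#' @param target overall expected missing fraction in (0, 1)
#' @return a miss_config list with the calibrated \code{intercept}
#' @export
calibrate_missingness <- function(respondents,
                                  coef = c("age=18-34" = 0.8,
                                           "race=nonwhite" = 0.6,
                                           "region=south" = 0.5),
                                  target = 0.26) {
  stopifnot(target > 0, target < 1)
  f <- function(b0) mean(missingness_prob(respondents,
                                          list(intercept = b0, coef = coef))) -
    target
  b0 <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  list(intercept = b0, coef = coef)
}

#' Write or read respondent tables
#'
#' Respondents are stored as headered tab-delimited text; a missing tract is
#' an empty field.
#'
#' @param respondents respondent data.frame
#' @param path file path
#' @export
write_respondents <- function(respondents, path) {
  out <- respondents
  out$tract[is.na(out$tract)] <- ""
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_respondents
#' @export
read_respondents <- function(path) {
  r <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = list(tract = "character", zip = "character"))
  r$tract[!is.na(r$tract) & r$tract == ""] <- NA_character_
  r
}
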