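test_that("a single-tract zip absorbs all of its missing respondents", {
  cw <- data.frame(zip = "Z1", tract = "T1", res_ratio = 1)
  r <- data.frame(id = 1:5, zip = "Z1", tract = NA_character_)
  out <- allocate_missing(r, cw, seed = 1)
  expect_true(all(out$tract == "T1"))
})

test_that("allocation frequencies track the crosswalk ratios", {
  shares <- c(0.705, 0.208, 0.087)
  cw <- data.frame(zip = "98001", tract = c("EFW", "NA1", "CFW"),
                   res_ratio = shares)
  r <- data.frame(id = 1:10000, zip = "98001", tract = NA_character_)
  out <- allocate_missing(r, cw, seed = 3)
  frac <- as.numeric(table(factor(out$tract, c("EFW", "NA1", "CFW")))) / 1e4
  se <- sqrt(shares * (1 - shares) / 1e4)
  expect_true(all(abs(frac - shares) < 3 * se))
})

test_that("allocation is seed-deterministic and leaves observed tracts alone", {
  geo <- sim_geography(30, 5, 3, seed = 2)
  truth <- sim_truth(geo, qlogis(0.15), 0.3, 0.1, seed = 3)
  r <- apply_missingness(sim_survey(truth, geo, 800, seed = 4), seed = 5)
  a1 <- allocate_missing(r, geo$crosswalk, seed = 10)
  a2 <- allocate_missing(r, geo$crosswalk, seed = 10)
  a3 <- allocate_missing(r, geo$crosswalk, seed = 11)
  expect_identical(a1, a2)
  expect_false(identical(a1$tract, a3$tract))
  obs <- !is.na(r$tract)
  expect_identical(a1$tract[obs], r$tract[obs])
  expect_identical(a1[names(a1) != "tract"], r[names(r) != "tract"])
  expect_false(anyNA(a1$tract))
  # imputed tracts are always consistent with the respondent's zip
  expect_identical(unname(geo$tract_to_zip[a1$tract]), a1$zip)
})

test_that("allocation fails when a zip is absent from the crosswalk", {
  cw <- data.frame(zip = "Z1", tract = "T1", res_ratio = 1)
  r <- data.frame(id = 1:2, zip = c("Z1", "Z9"), tract = NA_character_)
  expect_error(allocate_missing(r, cw, seed = 1), "Z9")
})

test_that("allocation draws pass a chi-square goodness-of-fit sweep", {
  shares <- c(0.5, 0.3, 0.15, 0.05)
  cw <- data.frame(zip = "Z1", tract = paste0("T", 1:4), res_ratio = shares)
  r <- data.frame(id = 1:10000, zip = "Z1", tract = NA_character_)
  rejections <- 0L
  for (s in 1:50) {
    out <- allocate_missing(r, cw, seed = 1000 + s)
    counts <- as.numeric(table(factor(out$tract, paste0("T", 1:4))))
    pval <- suppressWarnings(
      stats::chisq.test(counts, p = shares)$p.value)
    if (pval < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("concentrated zips are assigned deterministically to their HRA", {
  hs <- data.frame(zip = "Z1", hra = c("H1", "H2"),
                   pop_share = c(0.96, 0.04))
  r <- data.frame(id = 1:50, zip = "Z1", tract = NA_character_)
  out <- assign_hra(r, hs, tract_to_hra = character(0), threshold = 0.95,
                    seed = 1)
  expect_true(all(out$hra == "H1"))
})

test_that("split zips are assigned by population share", {
  hs <- data.frame(zip = "98001", hra = c("EFW", "NAu", "CFW"),
                   pop_share = c(0.705, 0.208, 0.087))
  r <- data.frame(id = 1:20000, zip = "98001", tract = NA_character_)
  out <- assign_hra(r, hs, tract_to_hra = character(0), seed = 2)
  frac <- as.numeric(table(factor(out$hra, hs$hra))) / 2e4
  se <- sqrt(hs$pop_share * (1 - hs$pop_share) / 2e4)
  expect_true(all(abs(frac - hs$pop_share) < 3 * se))
})

test_that("geocoded respondents take their tract's HRA regardless of shares", {
  hs <- data.frame(zip = "Z1", hra = c("H1", "H2"),
                   pop_share = c(0.99, 0.01))
  t2h <- c(Ta = "H2")
  r <- data.frame(id = 1:3, zip = "Z1", tract = c("Ta", NA, "Ta"))
  out <- assign_hra(r, hs, t2h, seed = 1)
  expect_identical(out$hra, c("H2", "H1", "H2"))
})

test_that("assign_hra validates threshold and share coverage", {
  hs <- data.frame(zip = "Z1", hra = "H1", pop_share = 1)
  r <- data.frame(id = 1, zip = "Z2", tract = NA_character_)
  expect_error(assign_hra(r, hs, character(0), threshold = 0.4), "threshold")
  expect_error(assign_hra(r, hs, character(0)), "hra_share")
})
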