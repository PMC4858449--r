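---
title: "Small-area prevalence estimation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area prevalence estimation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saeprev)
```

# The problem

County-level health surveys (telephone surveys with complex design weights,
a few thousand respondents per year) are routinely asked to produce
estimates for much smaller geographies — census tracts with a median of a
few dozen respondents each, many with none at all. Direct design-based
estimation at that scale is unusable: confidence intervals span tens of
percentage points and a substantial fraction of tracts report a prevalence
of exactly 0% or 100%. On top of that, the geocode that places a respondent
in a tract is often missing (typically for a quarter of the sample, and not
at random — younger and nonwhite respondents are less likely to be
geocoded), while the zip code is almost always observed.

`saeprev` implements the full estimation pipeline for this situation:

1. **raking** of design weights to known population margins,
2. **design-based direct estimation** per area with a with-replacement
   variance,
3. an **empirical-logit working model** feeding a three-stage hierarchical
   Bayesian spatial smoother (BYM: ICAR + iid random effects) fit by Gibbs
   sampling,
4. **CPO-based comparison** of random-effect structures,
5. **multiple imputation** of missing tract geocodes from zip-to-tract
   residential-address crosswalk ratios, pooled by mixing posterior draws,
6. **population-share assignment** of respondents to larger reporting
   areas (HRAs),

plus a synthetic-county generator so all of it can be exercised, tested and
calibrated without access to restricted survey microdata.

# The model

For area $i$, let $\hat p_i$ be the weighted (Horvitz–Thompson style)
prevalence and $\widehat{\mathrm{var}}(\hat p_i)$ its design-based
variance. The area-level data summary is the empirical logit
$$\hat\theta_i = \log\frac{\hat p_i}{1-\hat p_i}, \qquad
V_i = \frac{\widehat{\mathrm{var}}(\hat p_i)}{\big(\hat p_i(1-\hat p_i)\big)^2},$$
treated as a Gaussian working observation. The three stages are
$$\hat\theta_i \mid \eta_i \sim N(\eta_i, V_i), \qquad
\eta_i = \mu + u_i + v_i,$$
with $u$ an intrinsic conditional autoregressive (ICAR) field on the
area adjacency graph with precision $\tau_u$ scaling the pairwise
differences, $v_i \stackrel{iid}{\sim} N(0, 1/\tau_v)$, a flat prior on
$\mu$, and Gamma hyperpriors on both precisions. Every full conditional is
Gaussian or Gamma, so posterior sampling is plain Gibbs (implemented in
C++); the ICAR sum-to-zero constraint is enforced by re-centering $u$ each
sweep, with the removed mean absorbed into $\mu$.

Estimates are reported on the prevalence scale by applying the inverse
logit to each retained draw of $\eta_i$ and taking the median and
equal-tailed interval. This guarantees every reported estimate and interval
endpoint lies strictly inside $(0,1)$.

**Degenerate areas.** Areas with $\hat p_i \in \{0, 1\}$, zero variance or
no respondents have no usable working observation: they contribute no
stage-1 term and their $\eta_i$ is drawn from the prior conditional on the
neighbouring effects. This is how a tract whose direct estimate is 0%
receives a strictly positive smoothed estimate with an honest (wide)
interval.

**Model comparison.** Candidate random-effect structures (`iid_only`,
`icar_only`, `icar_plus_iid`) are compared by the sum of log conditional
predictive ordinates, each CPO estimated from the single posterior run by
the harmonic-mean identity
$\mathrm{CPO}_i^{-1} = \mathrm{E}_{\text{post}}\big[1/N(\hat\theta_i \mid \eta_i, V_i)\big]$;
the highest sum wins, ties going to the simpler structure.

# Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `effect_structure` | `icar_plus_iid` | BYM convolution; the other two structures are for CPO comparison |
| `prior_u`, `prior_v` | Gamma(0.5, 0.05) | see below |
| `iterations`, `burn_in`, `thin` | 20000 / 5000 / 5 | 3000 retained draws; effective sizes are logged |
| `level` | 0.90 | reporting choice for credible intervals, configurable per run |
| `M` | 100 | imputations for missing geocodes |
| `hra_threshold` | 0.95 | population share above which a zip is deterministically assigned to one HRA |
| raking `tol` | 1e-10 | maximum relative margin deviation |

**Why Gamma(0.5, 0.05) and not the disease-mapping convention.** The
Gamma(0.5, 0.0005) precision prior often called "vague" in the BYM
literature has its prior median at $\tau \approx 455$, i.e. a logit-scale
standard deviation of about 0.05 — it effectively asserts that between-area
variation is negligible. In this setting the variance components are weakly
identified (per-area noise $V_i \approx 0.3$–$1$ easily dominates a
logit-scale signal variance of $0.1$–$0.2$), so that prior wins and the
model over-shrinks: in our calibration experiments nominal 90% intervals
covered only ~76% *even when the data were generated exactly from the
model*. Gamma(0.5, 0.05) places its prior median near a logit SD of 0.5
with 90% prior mass on SDs of roughly 0.15–5 — weakly informative on the
scale that matters for prevalence smoothing — and restores nominal
calibration in the same experiment. Both priors remain configurable.

# The synthetic county

The generator builds the conditions of a large-county surveillance survey:

- **Geography**: `n_tracts` cells on a rectangular grid with shared-edge
  adjacency; zips and HRAs are contiguous blocks along a snake ordering of
  the grid (zips average ~7 tracts, mirroring the real ratio), so zip
  boundaries straddle HRA boundaries and population-share assignment is
  non-trivial. Residential-address shares within each zip are Dirichlet
  draws; HRA population shares are derived from them, so all share tables
  are exactly normalized.
- **Truth**: logit-scale BYM surface, $\mathrm{logit}(p) = \mu + u + v$
  with $u$ an ICAR draw (via the graph-Laplacian eigendecomposition with
  the null space removed, then re-centred) and $v$ iid. Defaults
  $\mu = \mathrm{logit}(0.12)$, $\sigma_u = 0.4$, $\sigma_v = 0.2$ give
  county-wide tract prevalences of roughly 4%–35%, matching the dynamic
  range a smoking indicator shows at tract level.
- **Survey**: 16,000 respondents (a five-year pooled sample), allocated to
  demographic cells with inclusion intensities that over-represent older
  and white respondents, and to tracts by population; outcomes are
  Bernoulli with cell-level logit shifts (younger/male respondents smoke
  more), so the design is informative and raking genuinely matters. Base
  weights are inverse inclusion intensities. The resulting geocoded median
  tract sample is ~28.
- **Missingness**: the tract geocode is blanked by a logistic model on age,
  race and region, with the intercept calibrated so the overall missing
  fraction is 26%; zips are never blanked.

What it deliberately does *not* emulate: real tract shapes (topology, not
geometry, drives the model), population pyramids of any real county,
tracts split across HRAs, string-intersection geocoding, or
cluster/telephone-frame design features beyond unequal selection. Passing
tests on this generator therefore validate the statistical machinery and
its self-consistency, not the realism of any particular county's data.

# Numerical choices

- ICAR simulation uses the dense eigendecomposition of the graph Laplacian;
  fine to a few thousand areas, not meant for national-scale graphs.
- The Gibbs sampler re-centres $u$ every sweep and transfers the mean to
  $\mu$, which keeps $\mu$ identified and the retained $u$ draws summing to
  zero to machine precision. $\tau_u$ uses rank $n-1$ in its Gamma shape.
- Degenerate working observations are detected as $\hat p \in \{0,1\}$ or
  zero variance; the empirical logit refuses them, and the model routes
  them to prediction-only handling.
- The harmonic-mean CPO estimator is only square-integrable when the
  posterior spread of $\eta_i$ is below $V_i/2$; draws where the density
  underflows are dropped and counted. Comparisons across models use the
  same data by construction.
- Raking margins must agree on the grand total to 1e-6 relative; an empty
  sample category with a nonzero target is an error naming the category,
  not a silent skip.
- Sub-seeds for imputations and sampler runs are derived from the master
  seed by a fixed integer counter scheme, so any single imputation can be
  reproduced in isolation and full runs are byte-reproducible.
- MI pooling mixes the prevalence-scale posterior draws of all $M$ fits
  with equal weights and summarizes the mixture. This propagates
  between-imputation spread into the intervals automatically, reduces to
  the single-fit summary at $M = 1$, and never narrows an interval below
  the law-of-total-variance bound. (Normal-theory combining rules on point
  estimates are a cruder approximation to the same thing and are not
  used.)
- HRA-level analysis uses single-pass assignment (deterministic above the
  95% share threshold, categorical below), not multiple imputation:
  reporting-area estimation needs a fixed assignment, and HRA samples are
  large enough that imputation uncertainty is second-order.
- Raking weights are computed once and held fixed across imputations; they
  depend only on demographics, which are fully observed.

# Problem sizes used in the test suite

The shipped tests validate the pipeline at deliberately reduced sizes
chosen to keep the full suite around a minute while leaving Monte-Carlo
error well below the tolerances asserted: interval calibration uses a
200-tract county with 50 replicates and 1,750 retained draws per fit;
the survey-scale comparison uses the full 396-tract county with 50
replicates, 3 imputations and 1,200-draw chains; oracle equivalences use
2–6 area toys with fixed hyperparameters where closed forms exist. The
package defaults (20,000 iterations, $M = 100$) are sized for real
analyses, not for the tests.

# Known limitations

- **Small-count working observations.** The Gaussian working likelihood
  takes $V_i$ as known. With tract samples around $n \approx 30$ and
  prevalences near 10%, $V_i = 1/(n \hat p(1-\hat p))$ is noisy and
  anti-correlated with $\hat p$: low-prevalence areas get huge working
  variances and are shrunk hardest, which biases their smoothed estimates
  upward. In our experiments, binomially sampled counties at this scale
  show ~77% coverage for nominal 90% intervals, with the shortfall
  concentrated in the lowest-prevalence quintile — a property of the
  empirical-logit area-level method itself, not of the sampler (which
  calibrates to nominal coverage when the working model is exact). Treat
  tract-level intervals at such sample sizes as approximate.
- The with-replacement variance ignores finite-population corrections and
  clustering; replicate-weight variances are out of scope.
- The imputation model conditions only on zip (through the crosswalk
  ratios), not on respondent covariates.
- CPO via the harmonic mean is noisy for very precise observations; for
  final model choices on real data, longer chains are advisable.

# A worked run

```{r example, eval = FALSE}
res <- run_tract_pipeline(list(
  seed = 1,
  smoothing = list(iterations = 4000, burn_in = 1000, thin = 2),
  M = 10))
res$summaries
res$correlations$pearson
write_report(res, "tract_run")
```

The summaries table mirrors the standard reporting layout for this kind of
analysis: per method (A direct, B smoothed, C smoothed + multiple
imputation), the min/median/max of the point estimates and of the
credible- or confidence-interval half-widths, with method A's half-width
summary excluding its degenerate zero-prevalence areas. The qualitative
signature of successful smoothing is a compressed prevalence range (no
impossible 0% or 50%+ tracts), halved median interval widths, and
correlation between B and C well above their correlations with A.
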