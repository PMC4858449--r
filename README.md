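# saeprev

Small-area estimation of survey prevalence: design-based direct estimation,
hierarchical Bayesian spatial smoothing, and multiple imputation of missing
small-area geography.

## Who this is for

Public-health analysts and biostatisticians who need subcounty (census
tract / reporting area) prevalence estimates from a complex survey whose
per-area samples are far too small for direct estimation — tens of
respondents per tract, many tracts with zero observed cases, and a quarter
of respondents missing the tract geocode entirely while retaining a zip
code. The package implements the complete pipeline and a synthetic-county
generator so every stage is testable without restricted survey microdata.

## The method

For area *i*, the design-weighted prevalence and its with-replacement
design variance are

&nbsp;&nbsp;p̂ᵢ = Σ wⱼyⱼ / Σ wⱼ,&nbsp;&nbsp;
v̂ᵢ = Σ wⱼ²(yⱼ − p̂ᵢ)² / (Σ wⱼ)²,

with weights raked (iterative proportional fitting) to known population
margins. The empirical logit θ̂ᵢ = logit(p̂ᵢ) with delta-method variance
Vᵢ = v̂ᵢ / (p̂ᵢ(1−p̂ᵢ))² becomes a Gaussian working observation in a
three-stage model:

1. θ̂ᵢ | ηᵢ ~ N(ηᵢ, Vᵢ)
2. ηᵢ = μ + uᵢ + vᵢ, with **u** an ICAR spatial field on the area
   adjacency graph (precision τᵤ, sum-to-zero constrained) and vᵢ iid
   N(0, 1/τᵥ) — the BYM convolution
3. Gamma hyperpriors on τᵤ, τᵥ; flat prior on μ.

All full conditionals are conjugate; inference is Gibbs sampling (C++
inner loop). Areas with p̂ᵢ ∈ {0, 1} or no respondents carry no likelihood
term and are predicted from the spatial prior, which is how a 0% direct
estimate becomes a strictly positive smoothed estimate with a wide
interval. Random-effect structures are compared by the sum of log
conditional predictive ordinates (harmonic-mean estimator). Estimates are
reported as posterior medians and equal-tailed credible intervals of the
inverse-logit draws, so everything lies in (0, 1).

Missing tract geocodes are multiply imputed: each missing tract is drawn
from the respondent's zip with probabilities equal to the zip's
residential-address crosswalk ratios, the model is refit per imputation
(M = 100 by default), and the prevalence-scale posterior draws of all fits
are pooled into one mixture, so imputation uncertainty widens the final
intervals. Respondents are assigned to larger reporting areas (HRAs)
deterministically when a zip is ≥95% inside one HRA and by
population-share draw otherwise.

## Worked example

```r
library(saeprev)
res <- run_tract_pipeline(list(
  seed = 1,
  smoothing = list(iterations = 4000, burn_in = 1000, thin = 2),
  M = 10))
res
```

```
Tract-level pipeline (A direct / B smoothed / C smoothed + MI)
         method prev_min prev_max prev_median hw_min hw_max hw_median
1      A_direct   0.0000    0.761       0.124 0.0202 0.4110    0.1167
2    B_smoothed   0.0782    0.329       0.155 0.0345 0.1207    0.0624
3 C_smoothed_mi   0.0842    0.298       0.160 0.0333 0.0994    0.0555
  areas_reported areas_excluded
1            390             73
2            396            0
3            396            0
Pearson correlations of point estimates:
      A     B     C
A 1.000 0.551 0.512
B 0.551 1.000 0.978
C 0.512 0.978 1.000
```

Reading this: method A (direct) produces impossible extremes — 73 of 396
tracts are degenerate (0% observed prevalence) and the median 90% interval
half-width is 12 percentage points. Smoothing (B) compresses the tract
prevalences into a plausible 8–33% range and halves the interval widths;
adding multiple imputation (C) uses all respondents, tightening intervals
further (median half-width 5.6 points). B and C agree strongly with each
other (r = 0.98) but only moderately with the noisy direct estimates —
exactly the signature expected when per-area samples average ~28.

At the reporting-area level, samples are large (median ≈ 330) and direct
and smoothed estimation should, and do, agree:

```r
run_hra_pipeline(list(seed = 1,
  smoothing = list(iterations = 4000, burn_in = 1000, thin = 2)))
#> HRA pipeline: 48 areas, direct vs smoothed r = 0.973
```

`write_report(res, "out_dir")` writes the per-area tables, summaries,
correlations and a run log (seed ledger, sampler diagnostics, respondent
accounting) as deterministic tab-delimited text.

See the vignette (`vignettes/small-area-smoothing.Rmd`) for the model in
full, the synthetic-county design, hyperprior rationale, and known
limitations.

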