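# unimodalMRDS

Abundance estimation from **double-observer aerial line-transect surveys
whose detection curve is unimodal** — rising from a blind strip under the
aircraft to an apex at intermediate distance, then decaying.

Conventional distance sampling assumes detection is perfect at the line and
decreases monotonically; aerial surveys violate both. `unimodalMRDS` fits a
**two-piece (split) normal detection function** — two half-normal curves
sharing a mode μ with different scales σ₁, σ₂ — so the detection apex stays
at the *same* distance for every covariate level:

```
g(y, z) = exp{ -[(y - μ) / 2σ₁(z)]² }   for w_b ≤ y < μ
        = exp{ -[(y - μ) / 2σ₂(z)]² }   for y ≥ μ
σ₁(z) = exp(β₀ + Σ shared + Σ left-only),  σ₂(z) = exp(β₀ + Σ shared + Σ right-only)
```

That single fixed apex is what makes the model compatible with the **point
independence (PI)** assumption of mark-recapture distance sampling (MRDS):
the two observers need to be independent only at the apex y = μ, not at
every distance (the "full independence" assumption known to bias abundance
low under unmodeled sighting heterogeneity). Detection *at* the apex is
estimated from the capture histories with a conditional (Huggins-type)
logistic model — observer effect, polynomial B-spline of distance,
covariates — and abundance follows from a Horvitz–Thompson-like estimator

```
N̂_c = Σ s_i / π̂_i ,   π̂_i = p̂•(μ̂) · p̂(z_i)
```

with `p̂•(μ̂)` the covariate-averaged combined apex detection and `p̂(z_i)`
the strip-averaged relative detection from the distance model (closed-form
erf integrals). Inclusion probabilities are screened (all > 0.1, fewer than
5% in (0.1, 0.2]), fit is assessed by binned χ², Kolmogorov–Smirnov and q-q
diagnostics, variances come from a delta method or a transect bootstrap,
and full-independence and perfect-apex-detection comparators are computed
side by side. A survey simulator with an optional shared visibility frailty
(heterogeneity that biases FI low but leaves PI valid) supports calibration
and recovery studies; everything is seeded and reproducible.

## Worked example

Simulate a survey at the default study conditions (~300 detections, strip
22–350 m, true apex 102.6 m, true combined apex detection 0.926) and run
the full pipeline:

```r
library(unimodalMRDS)
geom <- survey_geometry(w_b = 22, w = 350)
sim  <- simulate_survey(sim_config(seed = 7))

est <- mrds_estimate(sim$observations, sim$transects, geom,
                     shared = ~ flat + cover20,
                     mr_formula = mr_candidate_formulas())  # AIC-selected
est <- analytic_variance(est)
est
#> Point-independence MRDS estimate
#>   MCDS: apex mu = 106.11 m, AIC = 3142.5
#>   MR:   AIC = 482.5, averaged apex detection = 0.931
#> Abundance estimate (PI_averaged mode, 288 detected groups)
#>   covered strips: N_c = 945.4 over 1476.0 km^2
#>   study area:     N   = 945.4 over 1476.0 km^2 (density 640.54 / 1000 km^2)
#>   se = 65.88, CV = 6.97%, 95% CI (824.9, 1083.6)
#>   screening: pass

mcds_gof_chisq(est$mcds, n_bins = 15)
#> Chi-square goodness of fit: statistic = 14.150, df = 9, p = 0.117
#>   (1 bin-pooling merge applied)
mcds_ks(est$mcds)$p_value
#> [1] 0.881

sim$truth$n_individuals_strip   # known truth for this simulated survey
#> [1] 975
```

Reading the output: the estimated apex (106.1 m) and averaged apex
detection (0.931) recover the generating values within their standard
errors; the point estimate 945.4 individuals in the covered strips carries
a 6.97% CV and its 95% interval covers the simulated truth of 975. Both
goodness-of-fit tests are comfortably non-significant. `comparator_estimates()`
reports the same survey under per-record PI, full-independence and
perfect-detection assumptions, and `bootstrap_variance()` replaces the
delta-method SE with a transect bootstrap.

Real surveys enter through `read_observations()` / `read_transects()`
(CSV, arbitrary headers via a schema map, standard covariate transforms
applied), or through the command-line tool in `inst/exec/`:

```sh
unimodal-mrds estimate --obs obs.csv --transects tr.csv \
    --blind 22 --trunc 350 --shared '~ flat + cover20' --out results/
```

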