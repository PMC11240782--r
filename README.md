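# indirectRI

Indirect reference-interval estimation from mixed clinical data, built
around the canonical use case of canine rectal temperature: given a clinic
database of healthy *and* diseased patients, isolate the non-pathological
core of the distribution and report the central-95% reference interval with
bootstrap confidence limits and CLSI transference validation.

## Who this is for

Clinical pathologists and veterinary epidemiologists who want to derive (or
verify) reference intervals by data mining routine records instead of
recruiting a vetted healthy cohort, and who need every screening and
modelling step to be auditable and reproducible.

## The method

For screened measurements `x_1..x_n` (one per patient, initial
presentation, implausible values excluded):

1. **Tukey truncation** — remove values outside
   `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`; the downstream fit assumes only
   *moderate* contamination.
2. **Truncated-Gaussian fit** — over a grid of power transforms
   `λ ∈ {0, ½, 1}` and truncation windows `[t1, t2]` (empirical-quantile
   pairs, `p1 ∈ [0.05, 0.30]`, `p2 ∈ [0.70, 0.95]`), maximise the
   truncated-normal likelihood of the transformed in-window data and score
   each candidate by the Kolmogorov–Smirnov distance between the model's
   window-conditional CDF and a kernel-smoothed empirical CDF on the same
   window; select among near-optimal candidates the most identifiable
   (largest-mass) window.
3. **Reference interval** — `μ ± 1.959964·σ`, back-transformed, with 90%
   percentile bootstrap CIs (B = 200, re-running truncation and fitting on
   each resample).
4. **CLSI validation** — 20 fresh healthy-subject samples: ≤ 2 outside
   accepts, 3–4 extends, > 4 rejects.

Because such databases are typically available only on request, the package
includes a calibrated synthetic-cohort generator with exact ground truth;
the analysis scripts and all tests run against it. See the methods
vignette (`vignettes/indirect-reference-intervals.Rmd`) for the model,
numerical choices, and limitations.

## Worked example

```r
library(indirectRI)

cohort <- synthetic_config(n_patients = 12051L, rng_seed = 20240703L)
est    <- estimator_config(bootstrap_reps = 200L, rng_seed = 20240703L)
report <- run_pipeline(synthetic = cohort, estimator = est)
print(report)
```

```
== Indirect reference-interval run ==
Exclusion tally
  input measurements : 23981
  repeat visits      : 11930
  missing age        : 48
  juvenile           : 2214
  out-of-range       : 7
  retained           : 9782
Tukey fences: Q1 = 38.3, Q3 = 38.9, IQR = 0.6, fences [37.4, 39.8]
Tukey outliers removed: 560 (n for fitting: 9222)
Truncated-Gaussian reference model (lambda = 1)
  window [37.85, 39.45], mu = 38.6022, sigma = 0.4680 (transformed scale)
  KS distance = 0.00224, n = 9222
Reference interval (central 95%, n = 9222)
  mean : 38.6 (90% CI: 38.6-38.6)
  lower: 37.7 (90% CI: 37.7-37.7)
  upper: 39.5 (90% CI: 39.5-39.5)
  Fahrenheit: mean 101.5, interval 99.9-103.1
Normality (Anderson-Darling): before A2 = 182.85 (p = 3.7e-24); after A2 = 18.54 (p = 3.7e-24)
```

Reading the output: of 23,981 simulated visit records, screening keeps one
measurement for each of 9,782 adult dogs; the fence rule removes 560
outliers; the KS-optimised fit on the remaining 9,222 values selects the
identity transform and a central window, and the back-transformed central
95% of the fitted Gaussian — 37.7–39.5 °C around a mean of 38.6 °C — is the
reference interval, with 90% bootstrap CIs so tight at this sample size
that they collapse onto the point estimates at one-decimal reporting
precision. (The generator's true healthy component was calibrated to span
exactly 37.70–39.50 °C, so the recovery error here is ~0.02 °C.) The
Anderson–Darling statistic shows the gross non-normality of the untruncated
mixture; after truncation the diagnostic of record is the Q–Q plot, since
heaped one-decimal data always fail tail-weighted normality tests at this n.

The same analysis, step by step with intermediate tables written under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cohort -> scratch/cohort.csv
Rscript analysis/02_screen_records.R       # exclusion tally
Rscript analysis/03_fit_reference_interval.R   # fit, interval, figure data
Rscript analysis/04_validate_clsi.R        # CLSI transference check
```

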