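#!/usr/bin/env Rscript
# CLSI 20-sample transference validation of the fitted reference interval
# and, for comparison, of the published textbook interval (Merck: 37.5 to
# 39.2 degrees C), using a fresh batch of 20 apparently healthy dogs
# drawn from the generator's healthy component.
#
# Writes: results/validation.json

suppressPackageStartupMessages(library(indirectRI))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(n_patients = 12051L, rng_seed = 20240703L)
est <- estimator_config(bootstrap_reps = 0L, rng_seed = 20240703L)
report <- run_pipeline(synthetic = cfg, estimator = est)

# an independent batch of 20 healthy dogs, one-decimal thermometer readout
set.seed(20240704L)
batch <- round(rnorm(20L, cfg$healthy_mu, cfg$healthy_sigma), 1L)

fitted <- clsi_validate(report$interval, batch)
published <- validate_against_published(batch, 37.5, 39.2)

cat("Validation batch:", paste(sprintf("%.1f", batch), collapse = " "), "\n")
print(fitted)
print(published)

jsonlite::write_json(list(
  batch = batch,
  fitted_interval = list(lower = report$interval$lower,
                         upper = report$interval$upper,
                         n_outside = fitted$n_outside,
                         decision = fitted$decision),
  published_interval = list(lower = 37.5, upper = 39.2,
                            n_outside = published$n_outside,
                            decision = published$decision)),
  "results/validation.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("-> results/validation.json\n")
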