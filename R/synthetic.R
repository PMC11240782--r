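# Synthetic clinic cohorts with known ground truth.
#
# The raw hospital database behind an indirect reference-interval study is
# rarely public, so every pipeline stage here is exercised on generated
# cohorts that emulate its statistical structure: a dominant Gaussian
# "healthy" temperature component, hypothermic and febrile contamination,
# repeat visits per patient, juvenile and missing-age records, rare gross
# data-entry errors, and temperatures rounded to the thermometer's
# one-decimal display.

#' Calibrate a Gaussian to target reference limits
#'
#' Given the limits an interval should reproduce, returns the mean and
#' standard deviation of the Gaussian whose central `central_fraction`
#' spans exactly those limits: `mu = (lower + upper) / 2`,
#' `sigma = (upper - lower) / (2 z)` with
#' `z = qnorm((1 + central_fraction) / 2)`.
#'
#' @param lower,upper Target limits, `lower < upper`.
#' @param central_fraction Central coverage (default 0.95).
#' @return List with `mu` and `sigma`.
#' @export
#' @examples
#' calibrate_sigma(37.7, 39.5) # mu 38.6, sigma ~0.4592
calibrate_sigma <- function(lower, upper, central_fraction = 0.95) {
  if (!(central_fraction > 0 && central_fraction < 1))
    stop("central_fraction must be in (0, 1)")
  if (!(lower < upper)) stop("need lower < upper")
  z <- stats::qnorm((1 + central_fraction) / 2)
  list(mu = (lower + upper) / 2, sigma = (upper - lower) / (2 * z))
}

#' Synthetic-cohort configuration
#'
#' Defaults describe a university-clinic canine rectal-temperature
#' database: healthy component calibrated so its central 95% spans
#' 37.7-39.5 degrees C; 7% contamination split 40% hypothermic
#' N(36.5, 1.0) / 60% febrile N(40.3, 0.7); roughly one repeat visit per
#' patient on average; 18.4% juveniles and 0.4% missing ages among
#' patients; 7 gross data-entry errors; one-decimal rounding.
#'
#' @param n_patients Number of distinct patients.
#' @param healthy_mu,healthy_sigma Healthy (non-pathological) Gaussian.
#' @param contamination_fraction Share of measurements from the diseased
#'   components, in \[0, 1).
#' @param hypo_component,hyper_component Numeric `c(mu, sigma, weight)`;
#'   the weights are within-contamination shares and must sum to 1.
#' @param rounding_decimals Decimals the thermometer displays.
#' @param duplicate_visit_rate Expected number of repeat visits per
#'   patient (Poisson mean across the cohort; planted as an exact count).
#' @param juvenile_fraction,missing_age_fraction Patient shares planted
#'   with age below one year / without an age (exact counts after
#'   rounding).
#' @param gross_error_count Number of planted documentation errors:
#'   temperatures outside the plausible 30-43 degree C range.
#' @param rng_seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 9782L,
                             healthy_mu = 38.6,
                             healthy_sigma = calibrate_sigma(37.7, 39.5)$sigma,
                             contamination_fraction = 0.07,
                             hypo_component = c(mu = 36.5, sigma = 1.0, weight = 0.4),
                             hyper_component = c(mu = 40.3, sigma = 0.7, weight = 0.6),
                             rounding_decimals = 1L,
                             duplicate_visit_rate = 0.99,
                             juvenile_fraction = 2214 / 12051,
                             missing_age_fraction = 48 / 12051,
                             gross_error_count = 7L,
                             rng_seed = 1L) {
  stopifnot(n_patients >= 1, healthy_sigma > 0,
            contamination_fraction >= 0, contamination_fraction < 1,
            length(hypo_component) == 3L, length(hyper_component) == 3L,
            hypo_component[2] > 0, hyper_component[2] > 0,
            abs(hypo_component[3] + hyper_component[3] - 1) < 1e-12,
            rounding_decimals >= 0,
            duplicate_visit_rate >= 0,
            juvenile_fraction >= 0, juvenile_fraction < 1,
            missing_age_fraction >= 0, missing_age_fraction < 1,
            gross_error_count >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 healthy_mu = healthy_mu, healthy_sigma = healthy_sigma,
                 contamination_fraction = contamination_fraction,
                 hypo_component = hypo_component,
                 hyper_component = hyper_component,
                 rounding_decimals = as.integer(rounding_decimals),
                 duplicate_visit_rate = duplicate_visit_rate,
                 juvenile_fraction = juvenile_fraction,
                 missing_age_fraction = missing_age_fraction,
                 gross_error_count = as.integer(gross_error_count),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

# Mixture draw with component labels. Draws landing where the instrument
# could not record them (rounding outside [30, 43]) are redrawn, so only
# deliberately planted gross errors ever violate the plausibility range.
.draw_mixture <- function(n, config) {
  cf <- config$contamination_fraction
  probs <- c(healthy = 1 - cf,
             hypo = cf * unname(config$hypo_component[3]),
             hyper = cf * unname(config$hyper_component[3]))
  comp <- sample(names(probs), n, replace = TRUE, prob = probs)
  draw1 <- function(k, m) {
    if (k == 0L) return(numeric())
    switch(m,
           healthy = stats::rnorm(k, config$healthy_mu, config$healthy_sigma),
           hypo = stats::rnorm(k, config$hypo_component[1], config$hypo_component[2]),
           hyper = stats::rnorm(k, config$hyper_component[1], config$hyper_component[2]))
  }
  x <- numeric(n)
  for (m in names(probs)) {
    idx <- which(comp == m)
    v <- draw1(length(idx), m)
    eps <- 0.5 / 10^config$rounding_decimals
    bad <- v < 30 + eps | v > 43 - eps
    while (any(bad)) {
      v[bad] <- draw1(sum(bad), m)
      bad <- v < 30 + eps | v > 43 - eps
    }
    x[idx] <- v
  }
  list(values = x, component = comp)
}

#' Generate a mixed temperature sample with ground truth
#'
#' Draws `n_patients` measurements from the healthy/hypothermic/febrile
#' mixture, rounds them to the configured display precision, and records
#' per-value component labels plus the healthy component's true central-95%
#' quantiles.
#'
#' @param config A [synthetic_config()].
#' @return List with `values` (rounded temperatures) and `truth`
#'   (`true_lower`, `true_upper`, per-value `component` labels, and the
#'   unrounded draws as `raw`).
#' @export
generate_temperatures <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  mix <- .draw_mixture(config$n_patients, config)
  z <- stats::qnorm(0.975)
  list(values = round(mix$values, config$rounding_decimals),
       truth = list(true_lower = config$healthy_mu - z * config$healthy_sigma,
                    true_upper = config$healthy_mu + z * config$healthy_sigma,
                    component = mix$component,
                    raw = mix$values))
}

#' Generate a full patient-record table with planted artifacts
#'
#' Builds a visit-level record table for `n_patients` patients with
#' exactly-counted planted artifacts: repeat visits (later timestamps for
#' sampled patients), juvenile ages, missing ages, and gross out-of-range
#' temperature entries (planted on adult, known-age patients so each is
#' tallied under its own exclusion reason). The planted counts are exact,
#' so the records module's exclusion tally must recover them identically.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a record table as read by
#'   [read_records()]) and `truth` (planted counts, component labels for
#'   each patient's initial presentation, true limits).
#' @export
generate_record_table <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  n <- config$n_patients
  n_missing <- round(config$missing_age_fraction * n)
  n_juv <- round(config$juvenile_fraction * n)
  n_gross <- config$gross_error_count
  n_dup <- round(config$duplicate_visit_rate * n)
  if (n_missing + n_juv + n_gross > n)
    stop("planted artifact counts exceed n_patients")

  ids <- sprintf("P%06d", seq_len(n))
  pool <- sample(n)  # disjoint planting
  idx_missing <- pool[seq_len(n_missing)]
  idx_juv <- pool[n_missing + seq_len(n_juv)]
  idx_gross <- pool[n_missing + n_juv + seq_len(n_gross)]

  # ages: adults 1 + lognormal with median 5.8 extra years (cohort median
  # ~6.8 y); juveniles uniform below one year; missing ages NA
  age <- 1 + stats::rlnorm(n, meanlog = log(5.8), sdlog = 0.6)
  age <- round(pmin(age, 23.7), 1)
  age[idx_juv] <- round(stats::runif(n_juv, 0.1, 0.95), 1)
  age[idx_missing] <- NA_real_

  sex <- sample(c("female-intact", "female-spayed", "male-intact",
                  "male-neutered", "unknown"),
                n, replace = TRUE,
                prob = c(2281, 2479, 2883, 2124, 15))
  breeds <- c("Mixed breed", "Labrador Retriever", "German Shepherd",
              "French Bulldog", "Beagle", "Dachshund", "Golden Retriever",
              "Border Collie", "Chihuahua", "Rottweiler")
  breed <- sample(breeds, n, replace = TRUE,
                  prob = c(0.27, rep(0.73 / 9, 9)))
  t0 <- as.POSIXct("2008-01-01 08:00:00", tz = "UTC")
  first_ts <- t0 + stats::runif(n, 0, 8.4 * 365.25 * 86400)

  mix <- .draw_mixture(n, config)
  temp <- mix$values
  if (n_gross > 0L) {
    lo <- stats::runif(n_gross, 25, 29.4)
    hi <- stats::runif(n_gross, 43.6, 45)
    pick_hi <- stats::runif(n_gross) < 0.5
    temp[idx_gross] <- ifelse(pick_hi, hi, lo)
  }
  temp <- round(temp, config$rounding_decimals)

  records <- data.frame(patient_id = ids, timestamp = first_ts,
                        age_years = age, sex = sex, breed = breed,
                        temperature_c = temp, stringsAsFactors = FALSE)

  if (n_dup > 0L) {
    who <- sample(n, n_dup, replace = TRUE)
    rep_mix <- .draw_mixture(n_dup, config)
    extra <- data.frame(patient_id = ids[who],
                        timestamp = first_ts[who] +
                          stats::runif(n_dup, 3600, 2 * 365.25 * 86400),
                        age_years = age[who], sex = sex[who],
                        breed = breed[who],
                        temperature_c = round(rep_mix$values,
                                              config$rounding_decimals),
                        stringsAsFactors = FALSE)
    records <- rbind(records, extra)
  }
  records <- records[sample(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL

  z <- stats::qnorm(0.975)
  truth <- list(
    true_lower = config$healthy_mu - z * config$healthy_sigma,
    true_upper = config$healthy_mu + z * config$healthy_sigma,
    component = stats::setNames(mix$component, ids),
    planted = list(n_input_measurements = n + n_dup,
                   n_duplicates_removed = n_dup,
                   n_missing_age = n_missing,
                   n_juvenile = n_juv,
                   n_out_of_range = n_gross,
                   n_retained = n - n_missing - n_juv - n_gross))
  list(records = records, truth = truth)
}

#' Write a record table as CSV
#'
#' Emits the same dialect [read_records()] consumes (comma-delimited,
#' header, UTF-8, timestamps as `YYYY-MM-DD HH:MM:SS`).
#'
#' @param records A record table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
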