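# One-call orchestration: ingest -> dedup -> exclusions -> Tukey
# truncation -> truncated-Gaussian fit -> reference interval ->
# normality diagnostics -> optional CLSI validation, collected into a
# machine-readable run report.

#' Box-and-whisker summary
#'
#' Quartiles, median, mean, and whiskers at the most extreme data points
#' still within 1.5 IQR of the quartiles (the conventional Tukey
#' box-plot definition).
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Named numeric vector `c(q1, median, q3, mean, whisker_low,
#'   whisker_high)`.
#' @export
boxwhisker_stats <- function(values) {
  values <- values[is.finite(values)]
  q <- sample_quartiles(values)
  f <- tukey_fences(values)
  inside <- values[values >= f$lower_fence & values <= f$upper_fence]
  c(q1 = unname(q["q1"]), median = unname(q["median"]), q3 = unname(q["q3"]),
    mean = mean(values), whisker_low = min(inside),
    whisker_high = max(inside))
}

.histogram_bins <- function(values, bin_width = 0.1) {
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(bin_start = utils::head(h$breaks, -1),
             bin_end = utils::tail(h$breaks, -1),
             count = h$counts)
}

#' Run the full indirect reference-interval pipeline
#'
#' Executes every stage on a record table (read from CSV, passed as a
#' data.frame, or generated synthetically): reduction to initial
#' presentation, exclusion screening, Tukey truncation, the KS-optimised
#' truncated-Gaussian fit, reference limits with bootstrap CIs,
#' Anderson-Darling / Q-Q normality diagnostics before and after
#' truncation, and (optionally) CLSI transference validation of the new
#' and/or a published interval. Deterministic given the input and seeds.
#'
#' @param input Path to a record CSV, or a record table data.frame;
#'   ignored when `synthetic` is given.
#' @param synthetic A [synthetic_config()]; when supplied the cohort is
#'   generated instead of read.
#' @param filter A [filter_config()].
#' @param estimator An [estimator_config()].
#' @param validate Optional numeric vector of 20 healthy-subject values;
#'   validated against the newly fitted interval.
#' @param validate_published Optional `c(lower, upper)` literature limits
#'   validated on the same batch.
#' @param column_map Passed to [read_records()] when `input` is a path.
#' @param histogram_bin_width Bin width (data units) for the reported
#'   histogram (default 0.1, the thermometer display resolution).
#' @return A `run_report` list: `tally`, `fences`, `model`, `interval`
#'   (data units), `interval_f` (Fahrenheit twin, one-decimal),
#'   `normality_before`, `normality_after`, `validation`,
#'   `validation_published`, `histogram_before`, `histogram_after`,
#'   `boxwhisker`, `n_outliers`, `config`, `seed`, `version`.
#' @export
run_pipeline <- function(input = NULL, synthetic = NULL,
                         filter = filter_config(),
                         estimator = estimator_config(),
                         validate = NULL, validate_published = NULL,
                         column_map = NULL, histogram_bin_width = 0.1) {
  truth <- NULL
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    gen <- generate_record_table(synthetic)
    records <- gen$records
    truth <- gen$truth
  } else if (is.data.frame(input)) {
    records <- input
  } else if (is.character(input)) {
    records <- read_records(input, column_map = column_map)
  } else {
    stop("provide `input` (path or data.frame) or `synthetic`")
  }

  dedup <- select_first_per_patient(records)
  scr <- apply_exclusions(dedup, filter,
                          attr(dedup, "n_duplicates_removed"))
  values <- scr$retained$temperature_c

  trunc <- remove_tukey_outliers(values)
  model <- fit_reference_model(trunc$retained, estimator)
  interval <- reference_interval(model, values, estimator)

  norm_before <- anderson_darling(values)
  norm_after <- anderson_darling(trunc$retained)

  validation <- validation_published <- NULL
  if (!is.null(validate)) {
    validation <- clsi_validate(interval, validate)
    if (!is.null(validate_published))
      validation_published <- validate_against_published(
        validate, validate_published[1], validate_published[2])
  }

  # Fahrenheit twins are conversions of the *reported* (one-decimal)
  # Celsius values, so the printed pair stays self-consistent
  f_twin <- function(c) round_half_up(celsius_to_fahrenheit(round_half_up(c)))
  interval_f <- list(lower = f_twin(interval$lower),
                     upper = f_twin(interval$upper),
                     mean = f_twin(interval$mean))

  structure(list(
    tally = scr$tally,
    fences = trunc$fences,
    n_outliers = length(trunc$outliers),
    model = model,
    interval = interval,
    interval_f = interval_f,
    normality_before = norm_before[c("a2_statistic", "p_value")],
    normality_after = norm_after[c("a2_statistic", "p_value")],
    qq_after = norm_after$qq_points,
    validation = validation,
    validation_published = validation_published,
    histogram_before = .histogram_bins(values, histogram_bin_width),
    histogram_after = .histogram_bins(trunc$retained, histogram_bin_width),
    boxwhisker = boxwhisker_stats(trunc$retained),
    truth = truth,
    config = list(filter = unclass(filter), estimator = unclass(estimator),
                  synthetic = if (!is.null(synthetic)) unclass(synthetic)),
    seed = estimator$rng_seed,
    version = as.character(utils::packageVersion("indirectRI"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== Indirect reference-interval run ==\n")
  print(x$tally)
  print(x$fences)
  cat(sprintf("Tukey outliers removed: %d (n for fitting: %d)\n",
              x$n_outliers, x$model$n_used))
  print(x$model)
  print(x$interval)
  cat(sprintf("  Fahrenheit: mean %.1f, interval %.1f-%.1f\n",
              x$interval_f$mean, x$interval_f$lower, x$interval_f$upper))
  cat(sprintf("Normality (Anderson-Darling): before A2 = %.2f (p = %.3g); after A2 = %.2f (p = %.3g)\n",
              x$normality_before$a2_statistic, x$normality_before$p_value,
              x$normality_after$a2_statistic, x$normality_after$p_value))
  if (!is.null(x$validation)) print(x$validation)
  if (!is.null(x$validation_published)) print(x$validation_published)
  invisible(x)
}

#' Write a run report to disk
#'
#' Serialises the report as JSON (`report.json`) plus tab-separated
#' figure data: histogram bins before/after truncation, Q-Q pairs of the
#' truncated sample, and the box-whisker six-tuple.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json <- report[c("tally", "fences", "n_outliers", "model", "interval",
                   "interval_f", "normality_before", "normality_after",
                   "validation", "validation_published", "boxwhisker",
                   "config", "seed", "version")]
  json <- lapply(json, function(el)
    if (is.object(el)) unclass(el) else el)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  tsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  tsv(report$histogram_before, "histogram_before.tsv")
  tsv(report$histogram_after, "histogram_after.tsv")
  qq <- report$qq_after
  if (nrow(qq) > 512L)   # thin evenly for plotting
    qq <- qq[unique(round(seq(1L, nrow(qq), length.out = 512L))), ]
  tsv(qq, "qq_after.tsv")
  tsv(data.frame(statistic = names(report$boxwhisker),
                 value = unname(report$boxwhisker)), "boxwhisker.tsv")
  invisible(dir)
}
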