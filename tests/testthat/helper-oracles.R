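# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: direct index formulas on sorted copies and
# explicit comparisons.

# linear interpolation between order statistics at 1 + (n - 1) * p,
# written out longhand
oracle_quantile <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_tukey <- function(values) {
  q1 <- oracle_quantile(values, 0.25)
  q3 <- oracle_quantile(values, 0.75)
  iqr <- q3 - q1
  lf <- q1 - 1.5 * iqr
  uf <- q3 + 1.5 * iqr
  keep <- logical(length(values))
  for (i in seq_along(values))
    keep[i] <- values[i] >= lf && values[i] <= uf
  list(q1 = q1, q3 = q3, lower = lf, upper = uf,
       retained = values[keep], outliers = values[!keep])
}

oracle_boxwhisker <- function(values) {
  o <- oracle_tukey(values)
  c(q1 = o$q1, median = oracle_quantile(values, 0.5), q3 = o$q3,
    mean = sum(values) / length(values),
    whisker_low = min(o$retained), whisker_high = max(o$retained))
}

# a small literal record table used across records-module tests
make_record_df <- function() {
  data.frame(
    patient_id = c("A", "B", "A", "C", "B"),
    timestamp = as.POSIXct(c("2010-01-05", "2010-02-01", "2010-01-01",
                             "2010-03-01", "2010-02-02"), tz = "UTC"),
    age_years = c(3, 0.5, 3, NA, 0.5),
    sex = c("female-intact", "male-intact", "female-intact",
            "unknown", "male-intact"),
    breed = c("Beagle", "Mixed breed", "Beagle", NA, "Mixed breed"),
    temperature_c = c(38.5, 38.2, 39.0, 38.7, 40.1),
    stringsAsFactors = FALSE)
}
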