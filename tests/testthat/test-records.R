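test_that("read_records parses well-formed rows in order and honours the column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,seen,age,gender,race,temp",
    "A,2010-01-05 09:00:00,3.0,female-intact,Beagle,38.5",
    "B,2010-02-01,,male-intact,,38.2",
    "C,2010-03-01 14:30:00,7.5,unknown,Mixed breed,39.1"), path)
  map <- c(patient_id = "id", timestamp = "seen", age_years = "age",
           sex = "gender", breed = "race", temperature_c = "temp")
  rec <- read_records(path, column_map = map)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$patient_id, c("A", "B", "C"))
  expect_equal(rec$temperature_c, c(38.5, 38.2, 39.1))
  expect_true(is.na(rec$age_years[2]))       # blank age cell -> missing
  expect_true(is.na(rec$breed[2]))
  expect_equal(attr(rec, "n_rejected"), 0L)
})

test_that("read_records handles empty input, bad temperatures, and bad maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,timestamp,age_years,sex,breed,temperature_c", path)
  expect_equal(nrow(read_records(path)), 0L)

  writeLines(c(
    "patient_id,timestamp,age_years,sex,breed,temperature_c",
    "A,2010-01-05,3.0,unknown,Beagle,38.5",
    "B,2010-01-06,2.0,unknown,Beagle,not-a-number"), path)
  expect_warning(rec <- read_records(path), "unparseable temperature")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_rejected"), 1L)

  expect_error(read_records(path, column_map = c(temperature_c = "nope")),
               "not found")
  expect_error(read_records(path, column_map = c(bogus_role = "temp")),
               "unknown roles")
})

test_that("select_first_per_patient keeps the earliest visit, ties by input order", {
  df <- make_record_df()
  out <- select_first_per_patient(df)
  expect_equal(nrow(out), 3L)
  expect_equal(attr(out, "n_duplicates_removed"), 2L)
  # A's day-1 visit wins over day-5; B's first-listed row wins its near-tie
  expect_equal(out$temperature_c[out$patient_id == "A"], 39.0)
  expect_equal(out$temperature_c[out$patient_id == "B"], 38.2)

  one <- df[1, , drop = FALSE]
  expect_equal(select_first_per_patient(one)$temperature_c, 38.5)

  # exact-tie: file order decides
  tie <- data.frame(patient_id = c("X", "X"),
                    timestamp = as.POSIXct(rep("2010-01-01", 2), tz = "UTC"),
                    age_years = c(2, 2), sex = "unknown", breed = "a",
                    temperature_c = c(38.0, 39.9))
  expect_equal(select_first_per_patient(tie)$temperature_c, 38.0)
})

test_that("deduplication is invariant to row shuffling when timestamps are strict", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 60
    df <- data.frame(
      patient_id = sample(sprintf("P%02d", 1:20), n, replace = TRUE),
      timestamp = as.POSIXct("2010-01-01", tz = "UTC") +
        sample.int(1e6, n),   # distinct seconds -> strict order per patient
      age_years = runif(n, 1, 12), sex = "unknown", breed = "b",
      temperature_c = round(rnorm(n, 38.6, 0.5), 1))
    a <- select_first_per_patient(df)
    b <- select_first_per_patient(df[sample(n), , drop = FALSE])
    a <- a[order(a$patient_id), ]
    b <- b[order(b$patient_id), ]
    expect_equal(a$temperature_c, b$temperature_c)
    expect_equal(a$timestamp, b$timestamp)
  }
})

test_that("exclusion screening applies age and range rules with exact tallies", {
  cfg <- filter_config()
  df <- data.frame(
    patient_id = sprintf("P%d", 1:7),
    timestamp = as.POSIXct("2012-06-01", tz = "UTC") + 1:7,
    age_years = c(0.5, 3, NA, 4, 2, 5, NA),
    sex = "unknown", breed = "x",
    temperature_c = c(38.5, 29.9, 38.0, 30.0, 43.0, 43.1, 50.0))
  res <- apply_exclusions(df, cfg, n_duplicates_removed = 4L)
  expect_s3_class(res$tally, "exclusion_tally")
  expect_equal(res$tally$n_juvenile, 1L)        # age 0.5
  expect_equal(res$tally$n_missing_age, 2L)     # NA age wins precedence over range
  expect_equal(res$tally$n_out_of_range, 2L)    # 29.9 and 43.1; 30.0 & 43.0 inclusive
  expect_equal(res$tally$n_retained, 2L)
  expect_equal(res$tally$n_input_measurements, 7L + 4L)
  with(res$tally, expect_identical(
    n_input_measurements,
    n_duplicates_removed + n_missing_age + n_juvenile + n_out_of_range + n_retained))
  expect_setequal(res$retained$temperature_c, c(30.0, 43.0))
})

test_that("exclusions are conservative and idempotent on random tables", {
  set.seed(21)
  cfg <- filter_config()
  for (rep in 1:20) {
    n <- sample(5:80, 1)
    df <- data.frame(
      patient_id = sprintf("P%d", seq_len(n)),
      timestamp = as.POSIXct("2012-06-01", tz = "UTC") + seq_len(n),
      age_years = ifelse(runif(n) < 0.1, NA, runif(n, 0, 15)),
      sex = "unknown", breed = "x",
      temperature_c = round(runif(n, 25, 46), 1))
    res <- apply_exclusions(df, cfg)
    with(res$tally, expect_identical(
      n_input_measurements,
      n_duplicates_removed + n_missing_age + n_juvenile + n_out_of_range + n_retained))
    again <- apply_exclusions(res$retained, cfg)
    expect_equal(again$tally$n_retained, nrow(res$retained))
    expect_equal(again$tally$n_missing_age + again$tally$n_juvenile +
                   again$tally$n_out_of_range, 0L)
  }
})

test_that("temperature conversions are exact and invertible", {
  expect_equal(celsius_to_fahrenheit(0), 32)
  expect_equal(round_half_up(celsius_to_fahrenheit(38.6)), 101.5)
  expect_equal(round_half_up(celsius_to_fahrenheit(37.7)), 99.9)
  expect_equal(round_half_up(celsius_to_fahrenheit(39.5)), 103.1)
  t <- seq(25, 45, by = 0.173)
  expect_equal(fahrenheit_to_celsius(celsius_to_fahrenheit(t)), t,
               tolerance = 1e-9)
})

test_that("filter_config rejects inverted bounds and negative ages", {
  expect_error(filter_config(temp_min_c = 44, temp_max_c = 30))
  expect_error(filter_config(min_age_years = -1))
})
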