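# Patient-record ingestion and exclusion screening.
#
# A "record table" is a plain data.frame with one row per patient visit and
# the columns patient_id, timestamp, age_years, sex, breed, temperature_c.

.record_roles <- c("patient_id", "timestamp", "age_years", "sex", "breed",
                   "temperature_c")

#' Filter configuration for exclusion screening
#'
#' Holds the plausibility bounds applied to deduplicated patient records:
#' the minimum adult age and the temperature range outside which a value is
#' treated as a documentation error. Defaults follow common veterinary
#' practice for rectal temperature: adults are at least one year old, and
#' values below 30.0 or above 43.0 degrees Celsius are physiologically
#' implausible for a live animal presenting for care.
#'
#' @param min_age_years Minimum age (years) for inclusion; records with
#'   `age_years < min_age_years` are excluded as juvenile.
#' @param temp_min_c,temp_max_c Inclusive plausibility bounds in degrees
#'   Celsius; records strictly outside are excluded as out-of-range.
#' @return An object of class `filter_config`.
#' @export
#' @examples
#' filter_config()
filter_config <- function(min_age_years = 1.0, temp_min_c = 30.0,
                          temp_max_c = 43.0) {
  stopifnot(is.numeric(min_age_years), min_age_years >= 0,
            is.numeric(temp_min_c), is.numeric(temp_max_c),
            temp_min_c < temp_max_c)
  structure(list(min_age_years = min_age_years, temp_min_c = temp_min_c,
                 temp_max_c = temp_max_c),
            class = "filter_config")
}

#' Read patient-visit temperature records from delimited text
#'
#' Reads a header-carrying delimited file and returns one row per
#' well-formed visit record, in file order. Rows whose temperature cannot
#' be parsed to a finite number are rejected with a warning naming their
#' line numbers (never silently dropped); blank age cells become `NA`.
#'
#' @param path Path to the file (or a connection).
#' @param column_map Named character vector binding the six roles
#'   `patient_id`, `timestamp`, `age_years`, `sex`, `breed`,
#'   `temperature_c` to the column names used in the file. Roles omitted
#'   from the map are looked up under their own names.
#' @param sep Field delimiter (default comma).
#' @param tz Time zone used to parse timestamps (default UTC).
#' @return A data.frame of records; the number of rejected rows is attached
#'   as attribute `n_rejected`.
#' @export
read_records <- function(path, column_map = NULL, sep = ",", tz = "UTC") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           encoding = "UTF-8", quote = "\"",
                           comment.char = "", na.strings = character())
  map <- stats::setNames(.record_roles, .record_roles)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .record_roles)
    if (length(bad) > 0L)
      stop("unknown roles in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0L)
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  blank <- function(x) !nzchar(trimws(x)) | toupper(trimws(x)) == "NA"
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.frame(patient_id = character(), timestamp = as.POSIXct(character(), tz = tz),
                      age_years = numeric(), sex = character(),
                      breed = character(), temperature_c = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  temp_chr <- raw[[map[["temperature_c"]]]]
  temp <- suppressWarnings(as.numeric(temp_chr))
  ok <- is.finite(temp) & !blank(temp_chr)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) rejected for unparseable temperature (lines ",
            paste(utils::head(which(!ok) + 1L, 10L), collapse = ", "),
            if (sum(!ok) > 10L) ", ..." else "", ")")
  }
  age_chr <- raw[[map[["age_years"]]]]
  age <- suppressWarnings(as.numeric(age_chr))
  age[blank(age_chr)] <- NA_real_
  ts <- as.POSIXct(raw[[map[["timestamp"]]]], tz = tz,
                   tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  sex <- trimws(raw[[map[["sex"]]]])
  sex[blank(sex)] <- "unknown"
  breed <- trimws(raw[[map[["breed"]]]])
  breed[blank(breed)] <- NA_character_
  out <- data.frame(patient_id = raw[[map[["patient_id"]]]],
                    timestamp = ts, age_years = age, sex = sex,
                    breed = breed, temperature_c = temp,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Reduce repeat visits to the initial presentation
#'
#' Keeps, for every distinct patient id, the record with the earliest
#' timestamp (ties broken by input order), so each patient contributes a
#' single measurement — the one taken on initial presentation. Diseased
#' patients are re-examined more often, so later visits would bias an
#' indirect reference estimate toward pathology.
#'
#' @param records A record table (see [read_records()]).
#' @return The deduplicated table, in order of first appearance of each
#'   patient; the number of removed rows is attached as attribute
#'   `n_duplicates_removed`.
#' @export
select_first_per_patient <- function(records) {
  n <- nrow(records)
  if (n == 0L) {
    attr(records, "n_duplicates_removed") <- 0L
    return(records)
  }
  o <- order(xtfrm(records$timestamp), seq_len(n))  # stable: ties keep file order
  first_idx <- o[!duplicated(records$patient_id[o])]
  keep <- sort(first_idx)  # original file order == order of first appearance
  # order by first appearance of the patient id in the input
  appearance <- match(records$patient_id[keep],
                      unique(records$patient_id))
  out <- records[keep[order(appearance)], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates_removed") <- n - length(keep)
  out
}

#' Apply exclusion rules to deduplicated records
#'
#' Screens a deduplicated record table against a [filter_config()]:
#' records with missing age, juvenile age, or an out-of-range temperature
#' are removed. Each record is tallied under exactly one reason, with the
#' fixed precedence missing age, then juvenile, then out-of-range (the
#' duplicate count having been determined upstream), so the tally is an
#' exact partition of the input.
#'
#' @param records A deduplicated record table.
#' @param config A [filter_config()].
#' @param n_duplicates_removed Number of repeat-visit rows removed before
#'   this call (from [select_first_per_patient()]); folded into the tally's
#'   conservation identity.
#' @return A list with elements `retained` (the surviving records) and
#'   `tally`, an `exclusion_tally` whose components sum exactly to
#'   `n_input_measurements`.
#' @export
apply_exclusions <- function(records, config = filter_config(),
                             n_duplicates_removed = 0L) {
  stopifnot(inherits(config, "filter_config"))
  if (is.null(n_duplicates_removed))
    n_duplicates_removed <- 0L
  age <- records$age_years
  temp <- records$temperature_c
  miss <- is.na(age)
  juv <- !miss & age < config$min_age_years
  oor <- !miss & !juv &
    (temp < config$temp_min_c | temp > config$temp_max_c)
  keep <- !miss & !juv & !oor
  tally <- structure(list(
    n_input_measurements = nrow(records) + as.integer(n_duplicates_removed),
    n_duplicates_removed = as.integer(n_duplicates_removed),
    n_missing_age = sum(miss),
    n_juvenile = sum(juv),
    n_out_of_range = sum(oor),
    n_retained = sum(keep)), class = "exclusion_tally")
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusion tally\n")
  cat(sprintf("  input measurements : %d\n", x$n_input_measurements))
  cat(sprintf("  repeat visits      : %d\n", x$n_duplicates_removed))
  cat(sprintf("  missing age        : %d\n", x$n_missing_age))
  cat(sprintf("  juvenile           : %d\n", x$n_juvenile))
  cat(sprintf("  out-of-range       : %d\n", x$n_out_of_range))
  cat(sprintf("  retained           : %d\n", x$n_retained))
  invisible(x)
}

#' Temperature unit conversions
#'
#' Exact affine conversion between Celsius and Fahrenheit; rounding to the
#' reporting precision is left to the reporting layer.
#'
#' @param t Temperature(s), finite numeric.
#' @return Converted temperature(s).
#' @export
#' @examples
#' celsius_to_fahrenheit(38.6) # 101.48
celsius_to_fahrenheit <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  t * 9 / 5 + 32
}

#' @rdname celsius_to_fahrenheit
#' @export
fahrenheit_to_celsius <- function(t) {
  stopifnot(is.numeric(t), all(is.finite(t)))
  (t - 32) * 5 / 9
}

#' Round half away from zero
#'
#' Conventional half-up rounding used for reported temperatures (R's
#' `round()` rounds half to even). A tiny epsilon absorbs binary
#' representation error so values printed as x.x5 round up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
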