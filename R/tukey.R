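# Tukey fence truncation: the outlier-removal pass applied before the
# reference model is fitted. An indirect estimate from mixed data is biased
# when many pathological values are present, so values beyond 1.5 IQR from
# the quartiles are removed in a single pass.

#' Sample quartiles
#'
#' First quartile, median and third quartile by linear interpolation
#' between order statistics at positions `1 + (n - 1) * p` (the common
#' statistical-software default, `quantile()` type 7). The convention is
#' centralised here so every fence, whisker and truncation window in the
#' package uses the same one.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @export
sample_quartiles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4L)
    stop("sample_quartiles() needs at least 4 finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Tukey fences
#'
#' Lower and upper fences at Q1 - 1.5 IQR and Q3 + 1.5 IQR.
#'
#' @inheritParams sample_quartiles
#' @return An object of class `tukey_fences` with fields `q1`, `q3`,
#'   `iqr`, `lower_fence`, `upper_fence`.
#' @export
tukey_fences <- function(values) {
  q <- sample_quartiles(values)
  iqr <- unname(q["q3"] - q["q1"])
  structure(list(q1 = unname(q["q1"]), q3 = unname(q["q3"]), iqr = iqr,
                 lower_fence = unname(q["q1"]) - 1.5 * iqr,
                 upper_fence = unname(q["q3"]) + 1.5 * iqr),
            class = "tukey_fences")
}

#' @export
print.tukey_fences <- function(x, ...) {
  cat(sprintf("Tukey fences: Q1 = %.4g, Q3 = %.4g, IQR = %.4g, fences [%.4g, %.4g]\n",
              x$q1, x$q3, x$iqr, x$lower_fence, x$upper_fence))
  invisible(x)
}

#' Remove Tukey outliers
#'
#' Partitions the input into values inside the fences (retained; a value
#' exactly on a fence counts as inside) and values strictly outside
#' (outliers). Multiplicities are preserved: `retained` and `outliers`
#' together are exactly the input.
#'
#' @inheritParams sample_quartiles
#' @return List with `retained`, `outliers` and the `fences` used.
#' @export
remove_tukey_outliers <- function(values) {
  f <- tukey_fences(values)
  inside <- values >= f$lower_fence & values <= f$upper_fence
  list(retained = values[inside], outliers = values[!inside], fences = f)
}
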