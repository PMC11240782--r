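# CLSI 20-sample transference validation: a proposed reference interval is
# checked against a fresh batch of reference-subject measurements. With 20
# samples, at most 2 outside is acceptance; 3-4 calls for a further batch;
# more than 4 rejects the interval.

#' Validation policy
#'
#' @param batch_size Required number of validation samples (20).
#' @param accept_max_outside Largest outside-count still accepted (2).
#' @param extend_max_outside Largest outside-count for which a further
#'   batch is collected (4); above it the interval is rejected.
#' @return An object of class `validation_policy`.
#' @export
validation_policy <- function(batch_size = 20L, accept_max_outside = 2L,
                              extend_max_outside = 4L) {
  stopifnot(accept_max_outside < extend_max_outside,
            extend_max_outside < batch_size)
  structure(list(batch_size = as.integer(batch_size),
                 accept_max_outside = as.integer(accept_max_outside),
                 extend_max_outside = as.integer(extend_max_outside)),
            class = "validation_policy")
}

.clsi_decide <- function(samples, lower, upper, policy) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), lower < upper)
  if (length(samples) != policy$batch_size)
    stop("validation needs exactly ", policy$batch_size, " samples (got ",
         length(samples), "); collect a full batch of ", policy$batch_size)
  outside <- samples < lower | samples > upper  # boundary values count inside
  n_outside <- sum(outside)
  decision <- if (n_outside <= policy$accept_max_outside) "accepted"
  else if (n_outside <= policy$extend_max_outside) "extend"
  else "rejected"
  structure(list(n_outside = n_outside, decision = decision,
                 values_outside = samples[outside],
                 lower = lower, upper = upper),
            class = "validation_result")
}

#' Validate a fitted reference interval on a 20-sample batch
#'
#' Counts validation samples strictly below the lower or strictly above
#' the upper reference limit and applies the transference decision rule:
#' `accepted` when at most `accept_max_outside` fall outside, `extend`
#' (collect another batch) up to `extend_max_outside`, `rejected` beyond.
#' Orchestrating the follow-up batch after `extend` is the caller's job.
#'
#' @param interval A [reference_interval()].
#' @param samples Numeric vector of exactly `policy$batch_size` values
#'   from apparently healthy subjects.
#' @param policy A [validation_policy()].
#' @return A `validation_result` with `n_outside`, `decision`,
#'   `values_outside`.
#' @export
clsi_validate <- function(interval, samples, policy = validation_policy()) {
  stopifnot(inherits(interval, "reference_interval"),
            inherits(policy, "validation_policy"))
  .clsi_decide(samples, interval$lower, interval$upper, policy)
}

#' Validate an externally published interval
#'
#' Same decision rule as [clsi_validate()], with literature limits
#' supplied directly (e.g. a textbook interval being transferred to the
#' local population).
#'
#' @param samples Numeric vector of exactly `policy$batch_size` values.
#' @param published_lower,published_upper Literature reference limits.
#' @inheritParams clsi_validate
#' @return A `validation_result`.
#' @export
validate_against_published <- function(samples, published_lower,
                                       published_upper,
                                       policy = validation_policy()) {
  stopifnot(inherits(policy, "validation_policy"))
  .clsi_decide(samples, published_lower, published_upper, policy)
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("CLSI transference check vs [%.4g, %.4g]: %d outside -> %s\n",
              x$lower, x$upper, x$n_outside, x$decision))
  invisible(x)
}
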