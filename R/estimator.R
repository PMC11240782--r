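# Indirect reference-interval estimator.
#
# The working assumption of the indirect method: in a mixed
# healthy/diseased population the central bulk of the distribution (the
# highest histogram peak) is dominated by non-pathological values. The
# estimator therefore fits a Gaussian — optionally after a power
# transform — to the data restricted to a truncation window, conditioning
# the likelihood and the model CDF on that window, and selects the
# transform/window pair whose window-conditional CDF is closest (in
# Kolmogorov-Smirnov distance) to a kernel-smoothed empirical CDF
# restricted to the same window.

#' Estimator configuration
#'
#' @param min_n Minimum sample size the estimator accepts; the indirect
#'   approach needs more than 1000 points to isolate the non-pathological
#'   core reliably.
#' @param central_fraction Fraction of the fitted healthy distribution the
#'   reference interval covers (default 0.95, the conventional central 95%).
#' @param ci_level Level of the bootstrap confidence intervals (default 0.90).
#' @param bootstrap_reps Number of nonparametric bootstrap resamples
#'   (default 200); 0 skips the bootstrap.
#' @param rng_seed Integer seed driving the bootstrap.
#' @param transform_lambdas Grid of power-transform exponents searched;
#'   must include 1 (identity). 0 means log.
#' @param trunc_lower_probs,trunc_upper_probs Empirical-quantile
#'   probabilities defining the candidate truncation windows; every
#'   (lower, upper) pair with lower < upper is searched.
#' @param grid_points Number of equispaced points used for the KS objective
#'   within each window.
#' @param allow_small_n Permit fitting below `min_n` (testing at reduced n).
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(min_n = 1000L,
                             central_fraction = 0.95,
                             ci_level = 0.90,
                             bootstrap_reps = 200L,
                             rng_seed = 1L,
                             transform_lambdas = c(0, 0.5, 1),
                             trunc_lower_probs = seq(0.05, 0.30, by = 0.05),
                             trunc_upper_probs = seq(0.70, 0.95, by = 0.05),
                             grid_points = 512L,
                             allow_small_n = FALSE) {
  stopifnot(min_n >= 4L,
            central_fraction > 0, central_fraction < 1,
            ci_level > 0, ci_level < 1,
            bootstrap_reps >= 0,
            1 %in% transform_lambdas,
            all(trunc_lower_probs > 0), all(trunc_upper_probs < 1),
            max(trunc_lower_probs) < min(trunc_upper_probs),
            grid_points >= 16L)
  structure(list(min_n = as.integer(min_n),
                 central_fraction = central_fraction,
                 ci_level = ci_level,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 rng_seed = as.integer(rng_seed),
                 transform_lambdas = transform_lambdas,
                 trunc_lower_probs = trunc_lower_probs,
                 trunc_upper_probs = trunc_upper_probs,
                 grid_points = as.integer(grid_points),
                 allow_small_n = isTRUE(allow_small_n)),
            class = "estimator_config")
}

# Box-Cox-type power transform; x must be positive unless lambda == 1.
bc_transform <- function(x, lambda) {
  if (lambda == 1) return(x)
  if (lambda == 0) return(log(x))
  (x^lambda - 1) / lambda
}

bc_inverse <- function(y, lambda) {
  if (lambda == 1) return(y)
  if (lambda == 0) return(exp(y))
  (lambda * y + 1)^(1 / lambda)
}

# d/dx of the power transform (used to map a data-scale kernel bandwidth
# onto the transformed scale)
.bc_deriv <- function(x, lambda) {
  if (lambda == 1) return(rep(1, length(x)))
  x^(lambda - 1)
}

#' Kernel-smoothed empirical CDF
#'
#' Gaussian-kernel estimate of the cumulative distribution, obtained by
#' trapezoid integration of a kernel density estimate on a fine grid and
#' renormalised to run from 0 to 1 across the grid. Bandwidth defaults to
#' Silverman's rule of thumb ([stats::bw.nrd0()]).
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @param bandwidth Kernel bandwidth; `NULL` for Silverman's rule.
#' @param n_grid Grid resolution (default 2048).
#' @return An object of class `smoothed_cdf` with fields `x` (grid),
#'   `F` (nondecreasing, 0 to 1) and `bandwidth`; evaluate it with
#'   [eval_cdf()].
#' @export
smoothed_cdf <- function(values, bandwidth = NULL, n_grid = 2048L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    stop("smoothed_cdf() needs at least 2 distinct values (zero variance)")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  stopifnot(bandwidth > 0)
  d <- stats::density(values, bw = bandwidth, n = n_grid, kernel = "gaussian")
  dx <- diff(d$x)
  FF <- c(0, cumsum(dx * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2))
  FF <- FF / FF[length(FF)]
  structure(list(x = d$x, F = FF, bandwidth = bandwidth),
            class = "smoothed_cdf")
}

#' Evaluate a smoothed CDF
#'
#' Linear interpolation on the stored grid, clamped to 0/1 beyond it.
#'
#' @param cdf A `smoothed_cdf`.
#' @param q Points at which to evaluate.
#' @return Probabilities in \[0, 1\].
#' @export
eval_cdf <- function(cdf, q) {
  stopifnot(inherits(cdf, "smoothed_cdf"))
  stats::approx(cdf$x, cdf$F, xout = q, rule = 2, ties = "ordered")$y
}

.as_cdf_fun <- function(f) {
  if (inherits(f, "smoothed_cdf")) return(function(q) eval_cdf(f, q))
  if (is.function(f)) return(f)
  stop("expected a function or a smoothed_cdf")
}

#' Kolmogorov-Smirnov distance on a grid
#'
#' Supremum over the grid of the absolute difference between two
#' cumulative functions (each a function of one argument or a
#' [smoothed_cdf()]).
#'
#' @param cdf_a,cdf_b Cumulative functions.
#' @param grid Nonempty numeric vector of evaluation points.
#' @return The KS distance, in \[0, 1\].
#' @export
ks_distance <- function(cdf_a, cdf_b, grid) {
  if (length(grid) == 0L) stop("ks_distance() needs a nonempty grid")
  fa <- .as_cdf_fun(cdf_a)
  fb <- .as_cdf_fun(cdf_b)
  max(abs(fa(grid) - fb(grid)))
}

# Truncated-normal ML fit on window [a, b] via sufficient statistics
# (n, sum y, sum y^2), so each likelihood evaluation is O(1). Optimised
# over (mu, log sigma) by box-constrained L-BFGS-B, initialised at the
# window's sample mean/SD. The box encodes the indirect method's own
# assumption — the non-pathological peak lies in or near the truncation
# window and its spread is commensurate with the window width — and keeps
# the optimiser off the flat ridge (sigma >> b - a) where a truncated
# normal degenerates to a uniform on the window and the likelihood stops
# identifying the parameters.
.fit_truncnorm <- function(s1, s2, n, a, b, init_mu, init_sigma) {
  w <- b - a
  nll <- function(p) {
    mu <- p[1]
    sigma <- exp(p[2])
    z <- stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma)
    if (!is.finite(z) || z < 1e-300) return(1e12)
    n * log(sigma) + (s2 - 2 * mu * s1 + n * mu^2) / (2 * sigma^2) + n * log(z)
  }
  lo <- c(a - w / 2, log(w / 30))
  hi <- c(b + w / 2, log(2.5 * w))
  init <- pmin(pmax(c(init_mu, log(init_sigma)), lo), hi)
  opt <- stats::optim(init, nll, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(factr = 1e7, maxit = 500L))
  list(mu = opt$par[1], sigma = exp(opt$par[2]), value = opt$value)
}

# Measurement resolution of gridded data: the lattice spacing when all
# values are (numerically) integer multiples of the smallest positive gap
# between distinct values, else 0. Rounded instrument readings heap on a
# lattice; truncation bounds are widened to half a lattice step so a
# boundary atom's whole rounding bin lies inside the model window.
.data_resolution <- function(values) {
  u <- sort(unique(values))
  if (length(u) < 2L) return(0)
  g <- min(diff(u))
  if (g <= 0) return(0)
  on_lattice <- all(abs(u / g - round(u / g)) < 1e-6)
  if (on_lattice && length(u) <= length(values) / 4) g else 0
}

#' Fit the truncated-Gaussian reference model
#'
#' Searches the grid of power transforms times truncation windows
#' (windows given by empirical-quantile pairs of the input). For each
#' candidate, the power-transformed data inside the window are fitted by
#' truncated-normal maximum likelihood, and the candidate is scored by the
#' KS distance between the model's window-conditional CDF and the
#' kernel-smoothed empirical CDF restricted and renormalised to the same
#' window, both evaluated on an equispaced grid spanning the window. The
#' minimiser is returned. Deterministic: identical values and config give
#' an identical model.
#'
#' @param values Numeric vector; the Tukey-truncated sample. Must exceed
#'   `config$min_n` unless `config$allow_small_n`.
#' @param config An [estimator_config()].
#' @return An object of class `reference_model` with fields `lambda`,
#'   `t1`, `t2` (window bounds, data units), `p1`, `p2` (the quantile
#'   probabilities that produced them), `mu`, `sigma` (transformed
#'   scale), `ks_distance`, `n_used`.
#' @export
fit_reference_model <- function(values, config = estimator_config()) {
  stopifnot(inherits(config, "estimator_config"))
  values <- values[is.finite(values)]
  n <- length(values)
  if (n <= config$min_n && !config$allow_small_n)
    stop("fit_reference_model() requires more than ", config$min_n,
         " data points (got ", n, "); the indirect method is unreliable ",
         "below that size. Set allow_small_n = TRUE to override.")
  if (n < 4L) stop("fit_reference_model() needs at least 4 values")
  if (stats::sd(values) == 0)
    stop("degenerate data: zero variance")
  scdf <- smoothed_cdf(values)
  res <- .data_resolution(values)
  probs <- sort(unique(c(config$trunc_lower_probs, config$trunc_upper_probs)))
  qs <- stats::quantile(values, probs, names = FALSE, type = 7)
  qlookup <- function(p) qs[[which.min(abs(probs - p))]]
  cand <- list()
  for (p1 in config$trunc_lower_probs) {
    t1 <- qlookup(p1)
    for (p2 in config$trunc_upper_probs) {
      t2 <- qlookup(p2)
      if (!(t1 < t2)) next
      inside <- values >= t1 & values <= t2
      xw <- values[inside]
      if (length(xw) < 4L || stats::sd(xw) == 0) next
      # model window widened to the rounding-bin edges of the boundary atoms
      w1 <- t1 - res / 2
      w2 <- t2 + res / 2
      grid <- seq(w1, w2, length.out = config$grid_points)
      Fe <- eval_cdf(scdf, grid)
      F1 <- eval_cdf(scdf, w1)
      F2 <- eval_cdf(scdf, w2)
      if (F2 - F1 < 1e-12) next
      Fe <- (Fe - F1) / (F2 - F1)
      for (lambda in config$transform_lambdas) {
        if (lambda != 1 && any(values <= 0)) next
        yw <- bc_transform(xw, lambda)
        a <- bc_transform(w1, lambda)
        b <- bc_transform(w2, lambda)
        fit <- .fit_truncnorm(sum(yw), sum(yw^2), length(yw), a, b,
                              mean(yw), stats::sd(yw))
        # score against the *kernel-convolved* model: the smoothed empirical
        # CDF is the data CDF convolved with the kernel, so comparing it to
        # a raw model CDF would systematically reward sigma inflated by the
        # bandwidth. Bandwidth mapped to the transformed scale through the
        # local derivative at the window centre.
        h_t <- scdf$bandwidth * abs(.bc_deriv((w1 + w2) / 2, lambda))
        sig_s <- sqrt(fit$sigma^2 + h_t^2)
        zden <- stats::pnorm(b, fit$mu, sig_s) -
          stats::pnorm(a, fit$mu, sig_s)
        if (!is.finite(zden) || zden < 1e-12) next
        Gm <- (stats::pnorm(bc_transform(grid, lambda), fit$mu, sig_s) -
                 stats::pnorm(a, fit$mu, sig_s)) / zden
        ks <- max(abs(Gm - Fe))
        cand[[length(cand) + 1L]] <- list(
          lambda = lambda, t1 = w1, t2 = w2, p1 = p1, p2 = p2,
          mu = fit$mu, sigma = fit$sigma,
          ks_distance = ks, mass = F2 - F1, n_used = n)
      }
    }
  }
  if (length(cand) == 0L)
    stop("degenerate data: no truncation window with positive variance")
  # Near its minimum the KS landscape over overlapping windows is noise
  # dominated (kernel-smoothing and rounding wiggles are of the same order
  # as the differences between well-fitting candidates), while the
  # identifiability of sigma grows with the mass the window covers. Among
  # candidates within a fixed smoothing-noise allowance (0.003) of the
  # smallest KS distance, take the one covering the largest empirical
  # mass; ties broken toward the identity transform, then by grid order.
  ksv <- vapply(cand, `[[`, numeric(1), "ks_distance")
  near <- which(ksv <= min(ksv) + 0.003)
  mass <- vapply(cand, `[[`, numeric(1), "mass")[near]
  lam_pen <- abs(vapply(cand, `[[`, numeric(1), "lambda")[near] - 1)
  best <- cand[[near[order(-mass, lam_pen, near)[1L]]]]
  best$mass <- NULL
  structure(best, class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf(
    "Truncated-Gaussian reference model (lambda = %g)\n  window [%.4g, %.4g], mu = %.4f, sigma = %.4f (transformed scale)\n  KS distance = %.5f, n = %d\n",
    x$lambda, x$t1, x$t2, x$mu, x$sigma, x$ks_distance, x$n_used))
  invisible(x)
}

# Re-estimate (mu, sigma) on a sample with the model's hyperparameters
# (transform and window quantile probabilities) held fixed: window bounds
# are re-derived from the sample's own quantiles, widened to the rounding
# lattice, and the truncated-normal MLE re-run. Used by the bootstrap.
.refit_model <- function(values, model) {
  t1 <- stats::quantile(values, model$p1, names = FALSE, type = 7)
  t2 <- stats::quantile(values, model$p2, names = FALSE, type = 7)
  if (!(t1 < t2)) return(NULL)
  res <- .data_resolution(values)
  w1 <- t1 - res / 2
  w2 <- t2 + res / 2
  xw <- values[values >= t1 & values <= t2]
  if (length(xw) < 4L || stats::sd(xw) == 0) return(NULL)
  yw <- bc_transform(xw, model$lambda)
  a <- bc_transform(w1, model$lambda)
  b <- bc_transform(w2, model$lambda)
  fit <- .fit_truncnorm(sum(yw), sum(yw^2), length(yw), a, b,
                        mean(yw), stats::sd(yw))
  list(lambda = model$lambda, mu = fit$mu, sigma = fit$sigma)
}

#' Reference interval with bootstrap confidence intervals
#'
#' The reference limits are the central-`central_fraction` quantiles of
#' the fitted Gaussian, back-transformed to data units:
#' `mu +/- z * sigma` with `z = qnorm((1 + central_fraction) / 2)`
#' (1.959964 for 0.95). Confidence intervals come from a seeded
#' nonparametric bootstrap: each resample of `values` is re-truncated by
#' the Tukey fence rule and refitted — with the selected transform and
#' window quantile probabilities held fixed while the window bounds and
#' Gaussian parameters are re-estimated from the resample — and the
#' percentile interval at `ci_level` is taken for each quantity.
#' (Conditioning on the selected model keeps the interval from being
#' dominated by discrete window-selection flips, which would otherwise
#' badly overstate the uncertainty of the reported limits.)
#'
#' @param model A fitted [fit_reference_model()] result.
#' @param values The sample the pipeline fed to Tukey truncation (i.e. the
#'   cleaned, deduplicated measurements *before* outlier removal); each
#'   bootstrap replicate re-runs truncation and fitting on a resample.
#'   With `config$bootstrap_reps = 0` the CIs are `NA` and `values` may be
#'   omitted.
#' @param config The [estimator_config()] used for the fit.
#' @return An object of class `reference_interval`: `lower`, `upper`,
#'   `mean` (data units), `ci_lower`, `ci_upper`, `ci_mean` (each a
#'   2-vector), `central_fraction`, `ci_level`, `n_used`.
#' @export
reference_interval <- function(model, values = NULL,
                               config = estimator_config()) {
  stopifnot(inherits(model, "reference_model"),
            inherits(config, "estimator_config"))
  z <- stats::qnorm((1 + config$central_fraction) / 2)
  lim <- function(m) {
    c(lower = bc_inverse(m$mu - z * m$sigma, m$lambda),
      mean = bc_inverse(m$mu, m$lambda),
      upper = bc_inverse(m$mu + z * m$sigma, m$lambda))
  }
  pt <- lim(model)
  ci_lower <- ci_upper <- ci_mean <- c(NA_real_, NA_real_)
  if (config$bootstrap_reps > 0L) {
    if (is.null(values))
      stop("bootstrap CIs need the pre-truncation sample in `values`")
    values <- values[is.finite(values)]
    set.seed(config$rng_seed)
    boot <- matrix(NA_real_, nrow = config$bootstrap_reps, ncol = 3L)
    for (b in seq_len(config$bootstrap_reps)) {
      xb <- sample(values, replace = TRUE)
      tb <- remove_tukey_outliers(xb)$retained
      mb <- .refit_model(tb, model)
      if (!is.null(mb)) boot[b, ] <- lim(mb)
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) < 2L)
      stop("bootstrap failed: fewer than 2 successful replicates")
    pr <- c((1 - config$ci_level) / 2, (1 + config$ci_level) / 2)
    qb <- function(j) unname(stats::quantile(boot[, j], pr, type = 7))
    ci_lower <- qb(1)
    ci_mean <- qb(2)
    ci_upper <- qb(3)
  }
  structure(list(lower = unname(pt["lower"]), upper = unname(pt["upper"]),
                 mean = unname(pt["mean"]),
                 ci_lower = ci_lower, ci_upper = ci_upper, ci_mean = ci_mean,
                 central_fraction = config$central_fraction,
                 ci_level = config$ci_level, n_used = model$n_used),
            class = "reference_interval")
}

#' @export
print.reference_interval <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (anyNA(ci)) "" else sprintf(" (%.0f%% CI: %.1f-%.1f)",
                                   100 * x$ci_level, ci[1], ci[2])
  }
  cat(sprintf("Reference interval (central %.0f%%, n = %d)\n",
              100 * x$central_fraction, x$n_used))
  cat(sprintf("  mean : %.1f%s\n", round_half_up(x$mean), fmt_ci(x$ci_mean)))
  cat(sprintf("  lower: %.1f%s\n", round_half_up(x$lower), fmt_ci(x$ci_lower)))
  cat(sprintf("  upper: %.1f%s\n", round_half_up(x$upper), fmt_ci(x$ci_upper)))
  invisible(x)
}

#' Anderson-Darling normality test with Q-Q diagnostics
#'
#' Case-3 (estimated mean and variance) Anderson-Darling test with the
#' small-sample correction, plus the standard-normal Q-Q pairs used for
#' visual inspection: theoretical quantiles `qnorm(ppoints(n))` against
#' the order statistics.
#'
#' @param values Numeric vector, at least 8 values with nonzero variance.
#' @return List with `a2_statistic`, `p_value` and `qq_points` (a
#'   data.frame with columns `theoretical`, `sample`).
#' @export
anderson_darling <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8L)
    stop("anderson_darling() needs at least 8 values")
  if (stats::sd(values) == 0)
    stop("degenerate data: zero variance")
  at <- nortest::ad.test(values)
  list(a2_statistic = unname(at$statistic),
       p_value = unname(at$p.value),
       qq_points = data.frame(theoretical = stats::qnorm(stats::ppoints(length(values))),
                              sample = sort(values)))
}
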