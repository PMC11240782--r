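test_that("smoothed CDF is a proper nondecreasing cumulative estimate", {
  set.seed(31)
  x <- rnorm(501, 10, 2)
  sc <- smoothed_cdf(x)
  expect_true(all(diff(sc$F) >= 0))
  expect_equal(sc$F[1], 0)
  expect_equal(sc$F[length(sc$F)], 1)
  expect_equal(eval_cdf(sc, median(x)), 0.5, tolerance = 0.02)

  expect_equal(eval_cdf(smoothed_cdf(c(0, 1), bandwidth = 0.3), 0.5), 0.5,
               tolerance = 1e-6)

  set.seed(32)
  z <- rnorm(10000)
  sz <- smoothed_cdf(z)
  grid <- seq(-3, 3, length.out = 400)
  expect_lt(max(abs(eval_cdf(sz, grid) - pnorm(grid))), 0.02)

  expect_error(smoothed_cdf(rep(4, 10)), "zero variance|distinct")
})

test_that("KS distance behaves like a sup-norm metric on the grid", {
  grid <- seq(-1, 2, length.out = 1000)
  f <- function(q) punif(q)
  expect_equal(ks_distance(f, f, grid), 0)
  g <- function(q) punif(q, 0.5, 1.5)
  expect_equal(ks_distance(f, g, grid), 0.5, tolerance = 1e-3)
  s0 <- function(q) as.numeric(q >= 0)
  s10 <- function(q) as.numeric(q >= 10)
  expect_equal(ks_distance(s0, s10, seq(-5, 15, 0.1)), 1)
  expect_error(ks_distance(f, g, numeric()), "nonempty")

  # symmetry and triangle inequality on random cdf triples
  set.seed(33)
  for (rep in 1:10) {
    ms <- rnorm(3)
    cdfs <- lapply(ms, function(m) function(q) pnorm(q, m, 1))
    d12 <- ks_distance(cdfs[[1]], cdfs[[2]], grid)
    d21 <- ks_distance(cdfs[[2]], cdfs[[1]], grid)
    d13 <- ks_distance(cdfs[[1]], cdfs[[3]], grid)
    d32 <- ks_distance(cdfs[[3]], cdfs[[2]], grid)
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d32 + 1e-12)
  }
})

test_that("the reference model recovers a pure Gaussian and is deterministic", {
  set.seed(42)
  x <- rnorm(5000, 38.6, 0.4592)
  m1 <- fit_reference_model(x)
  expect_lt(abs(m1$mu - 38.6), 0.02)
  expect_lt(abs(m1$sigma - 0.4592), 0.02)
  expect_identical(m1$lambda, 1)
  expect_true(m1$ks_distance >= 0 && m1$ks_distance <= 1)
  expect_true(m1$t1 < m1$t2)

  m2 <- fit_reference_model(x)
  expect_identical(m1, m2)   # bit-identical rerun
})

test_that("the location estimate survives heavy two-sided contamination", {
  set.seed(55)
  n <- 9782
  comp <- sample(c("healthy", "hypo", "febrile"), n, TRUE, c(0.8, 0.08, 0.12))
  x <- numeric(n)
  x[comp == "healthy"] <- rnorm(sum(comp == "healthy"), 38.6, 0.459)
  x[comp == "hypo"] <- rnorm(sum(comp == "hypo"), 36.0, 1)
  x[comp == "febrile"] <- rnorm(sum(comp == "febrile"), 40.8, 0.8)
  tr <- remove_tukey_outliers(x)
  m <- fit_reference_model(tr$retained)
  expect_lt(abs(m$mu - 38.6), 0.05)
})

test_that("transform selection tracks the data scale", {
  # strongly log-normal data: the log transform must win
  set.seed(44)
  xl <- exp(rnorm(3000, 2, 0.6))
  ml <- fit_reference_model(xl)
  expect_identical(ml$lambda, 0)
  # back-transformed limits are positive and ordered
  lo <- exp(ml$mu - 1.959964 * ml$sigma)
  hi <- exp(ml$mu + 1.959964 * ml$sigma)
  expect_true(0 < lo && lo < hi)
})

test_that("sample-size guard names the requirement and can be overridden", {
  set.seed(45)
  x <- rnorm(500, 38.6, 0.46)
  expect_error(fit_reference_model(x), "1000")
  cfg <- estimator_config(allow_small_n = TRUE, bootstrap_reps = 0L)
  m <- fit_reference_model(x, cfg)
  expect_lt(abs(m$mu - 38.6), 0.15)
  expect_error(fit_reference_model(rep(38.6, 2000)), "zero variance|degenerate")
})

test_that("reference limits equal mu +/- z sigma under the identity transform", {
  set.seed(46)
  x <- rnorm(2000, 38.6, 0.46)
  cfg <- estimator_config(allow_small_n = TRUE, bootstrap_reps = 0L)
  m <- fit_reference_model(x, cfg)
  ri <- reference_interval(m, config = cfg)
  z <- qnorm(0.975)
  expect_equal(ri$upper - ri$lower, 2 * z * m$sigma, tolerance = 1e-12)
  expect_equal(ri$mean, m$mu, tolerance = 1e-12)
  expect_true(ri$lower < ri$mean && ri$mean < ri$upper)
  expect_equal(ri$n_used, m$n_used)
})

test_that("a vanishing sigma collapses the interval onto the mean", {
  m <- structure(list(lambda = 1, t1 = 38, t2 = 39, p1 = 0.05, p2 = 0.95,
                      mu = 38.6, sigma = 1e-12, ks_distance = 0,
                      n_used = 5000L),
                 class = "reference_model")
  ri <- reference_interval(m, config = estimator_config(bootstrap_reps = 0L))
  expect_equal(ri$lower, 38.6, tolerance = 1e-9)
  expect_equal(ri$upper, 38.6, tolerance = 1e-9)
})

test_that("bootstrap confidence intervals bracket their point estimates", {
  cfg <- estimator_config(allow_small_n = TRUE, bootstrap_reps = 60L,
                          rng_seed = 1L)
  braks <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    x <- round(rnorm(2000, 38.6, 0.46), 1)
    tr <- remove_tukey_outliers(x)
    cfg$rng_seed <- s
    m <- fit_reference_model(tr$retained, cfg)
    ri <- reference_interval(m, x, cfg)
    expect_true(ri$ci_lower[1] <= ri$ci_lower[2])
    expect_true(ri$ci_upper[1] <= ri$ci_upper[2])
    braks <- braks +
      (ri$ci_lower[1] <= ri$lower && ri$lower <= ri$ci_lower[2]) +
      (ri$ci_upper[1] <= ri$upper && ri$upper <= ri$ci_upper[2]) +
      (ri$ci_mean[1] <= ri$mean && ri$mean <= ri$ci_mean[2])
  }
  expect_gte(braks, 14L)   # 15 quantity/seed pairs, allow one edge case
})

test_that("reference_interval demands the sample when bootstrapping", {
  m <- structure(list(lambda = 1, t1 = 38, t2 = 39, p1 = 0.05, p2 = 0.95,
                      mu = 38.6, sigma = 0.46, ks_distance = 0.01,
                      n_used = 2000L),
                 class = "reference_model")
  expect_error(reference_interval(m, config = estimator_config()),
               "pre-truncation sample")
})

test_that("Anderson-Darling diagnostics are affine invariant with sane Q-Q pairs", {
  set.seed(47)
  x <- rnorm(300, 5, 2)
  a <- anderson_darling(x)
  b <- anderson_darling(3.7 * x - 11)
  expect_equal(a$a2_statistic, b$a2_statistic, tolerance = 1e-8)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
  expect_true(all(diff(a$qq_points$sample) >= 0))
  expect_true(all(diff(a$qq_points$theoretical) > 0))

  bimodal <- c(rnorm(1000, 36.5, 0.3), rnorm(1000, 40.3, 0.3))
  expect_lt(anderson_darling(bimodal)$p_value, 1e-4)

  expect_error(anderson_darling(rnorm(5)), "at least 8")
  expect_error(anderson_darling(rep(1, 20)), "zero variance")
})
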