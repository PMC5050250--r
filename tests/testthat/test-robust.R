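test_that("identical populations give a difference near zero covering zero", {
  set.seed(9)
  x <- rnorm(40)
  y <- rnorm(40)
  ps <- robust_difference(x, y, n_samples = 10000, seed = 4)
  expect_lt(abs(ps$median), 0.5)
  expect_true(ps$ci_low < 0 && ps$ci_high > 0)
  expect_s3_class(ps, "posterior_summary")
  expect_true(is.finite(ps$diagnostics$rhat))
})

test_that("the true difference is recovered on generated data", {
  set.seed(42)
  x <- rnorm(50, 0.5)
  y <- rnorm(50)
  ps <- robust_difference(x, y, n_samples = 20000, seed = 3,
                          keep_draws = TRUE)
  post_sd <- sd(ps$draws)
  expect_lt(abs(ps$median - 0.5), 3 * post_sd)
})

test_that("with nu forced to near-normality the posterior matches the Welch oracle", {
  set.seed(7)
  x <- rnorm(60, 1, 1)
  y <- rnorm(45, 0, 1.4)
  # a huge nu prior mean pins the likelihood at (near) normal
  ps <- robust_difference(x, y, n_samples = 30000, seed = 11,
                          nu_prior_mean = 1e5, interval = "percentile")
  w <- t.test(x, y)
  est <- unname(w$estimate[1] - w$estimate[2])
  se <- w$stderr
  expect_equal(ps$median, est, tolerance = 0.35 * se)
  expect_equal(ps$ci_low, w$conf.int[1], tolerance = 0.5 * se)
  expect_equal(ps$ci_high, w$conf.int[2], tolerance = 0.5 * se)
})

test_that("the sampler is reproducible under a fixed seed", {
  set.seed(2)
  x <- rt(30, 5) + 0.3
  y <- rt(30, 5)
  a <- robust_difference(x, y, n_samples = 2000, seed = 99)
  b <- robust_difference(x, y, n_samples = 2000, seed = 99)
  expect_identical(a$median, b$median)
  expect_identical(a$diagnostics$rhat, b$diagnostics$rhat)
})

test_that("heavy-tailed contamination does not drag the robust estimate", {
  set.seed(13)
  x <- c(rnorm(48, 0.5), 25, -20)
  y <- rnorm(50)
  ps <- robust_difference(x, y, n_samples = 15000, seed = 5)
  # the ordinary mean difference is pulled toward the outliers' average,
  # the robust posterior should stay near 0.5
  expect_lt(abs(ps$median - 0.5), 0.4)
})
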