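test_that("a single look keeps the false-positive rate at alpha", {
  d <- optional_stopping_design(n_min = 30, n_max = 30, n_sims = 10000,
                                seed = 101)
  s <- simulate_optional_stopping(d)
  se <- mc_se(0.05, d$n_sims)
  expect_lt(abs(s$false_positive_rate - 0.05), 2.5 * se)
})

test_that("two looks match an independent brute-force oracle", {
  d <- optional_stopping_design(n_min = 20, n_max = 40, step = 20,
                                n_sims = 8000, seed = 55)
  s <- simulate_optional_stopping(d)
  set.seed(777)  # oracle runs on its own RNG stream
  oracle <- two_look_rate_oracle(20, 4000)
  se <- sqrt(mc_se(oracle, 4000)^2 + mc_se(oracle, 8000)^2)
  expect_lt(abs(s$false_positive_rate - oracle), 2.5 * se)
})

test_that("peeking after every observation inflates false positives far above alpha", {
  d <- optional_stopping_design(n_min = 10, n_max = 50, step = 1,
                                n_sims = 5000, seed = 7)
  s <- simulate_optional_stopping(d)
  expect_gt(s$false_positive_rate, 0.12)
  expect_lt(s$false_positive_rate, 0.40)
})

test_that("false-positive rate is non-decreasing in the number of peeks (common random numbers)", {
  rates <- vapply(c(40, 10, 1), function(step) {
    d <- optional_stopping_design(n_min = 10, n_max = 50, step = step,
                                  n_sims = 4000, seed = 202)
    simulate_optional_stopping(d)$false_positive_rate
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("results are bit-reproducible under a fixed seed", {
  d <- optional_stopping_design(n_sims = 500, seed = 99)
  a <- simulate_optional_stopping(d)
  b <- simulate_optional_stopping(d)
  expect_identical(a$p_values, b$p_values)
  expect_identical(a$estimates, b$estimates)
})

test_that("publication filter: identity at 1, significant-only at 0, inflation oracle", {
  p <- c(0.01, 0.2, 0.04, 0.8)
  d <- c(0.5, 0.1, -0.4, 0.02)
  all_in <- apply_publication_bias(p, d, 1)
  expect_identical(all_in$published, rep(TRUE, 4))
  only_sig <- apply_publication_bias(p, d, 0)
  expect_identical(only_sig$published, p < 0.05)
  expect_identical(only_sig$estimates, d[p < 0.05])

  # selection-for-significance inflates |d|: compare the pipeline's mean
  # published |d| with E[|d| given significance] from a brute-force oracle
  des <- optional_stopping_design(n_min = 20, n_max = 20, n_sims = 20000,
                                  seed = 31)
  s <- simulate_optional_stopping(des)
  pub <- apply_publication_bias(s$p_values, s$estimates, 0)
  set.seed(888)
  oracle <- selected_d_oracle(20, 60000)
  n_sig <- sum(pub$published)
  se <- 0.3 / sqrt(n_sig)  # sd of |d| given selection is well under 0.3
  expect_gt(mean(abs(pub$estimates)), oracle$mean_abs_all)
  expect_lt(abs(mean(abs(pub$estimates)) - oracle$mean_abs_sig), 3 * se)
})

test_that("HARKing folds signs, preserves order, and matches the folded-mean oracle", {
  expect_identical(apply_harking(c(-0.3, 0.2)), c(0.3, 0.2))
  x <- c(0.1, 0.5, 0.2)
  expect_identical(apply_harking(x), x)

  des <- optional_stopping_design(n_min = 25, n_max = 25, n_sims = 20000,
                                  seed = 63)
  s <- simulate_optional_stopping(des)
  harked <- apply_harking(s$estimates)
  set.seed(999)
  oracle <- selected_d_oracle(25, 60000)
  expect_gt(mean(harked), 0)
  expect_lt(abs(mean(harked) - oracle$mean_abs_all),
            3 * 0.2 / sqrt(length(harked)))
})

test_that("publication records: binomial-tail oracle with all QRPs off", {
  world <- qrp_world_config(n_candidates = 4, optional_stopping = FALSE,
                            n_fixed = 25, prob_report_nonsignificant = 1,
                            harking = FALSE)
  rec <- simulate_publication_record(world, 4000, seed = 17)
  expect_true(all(rec$n_published == 4L))  # filter = 1 publishes all
  expect_false(any(rec$truth))
  p_exp <- pbinom(1, 4, 0.05, lower.tail = FALSE)
  se <- mc_se(p_exp, 4000)
  expect_lt(abs(mean(rec$internally_replicated) - p_exp), 3 * se)
})

test_that("QRPs make internal replications of null effects much more likely", {
  off <- qrp_world_config(n_candidates = 4, optional_stopping = FALSE,
                          n_fixed = 30, prob_report_nonsignificant = 1,
                          harking = FALSE)
  on <- qrp_world_config(n_candidates = 4, optional_stopping = TRUE,
                         prob_report_nonsignificant = 0, harking = TRUE)
  rec_off <- simulate_publication_record(off, 2000, seed = 23)
  rec_on <- simulate_publication_record(on, 2000, seed = 23)
  expect_gt(mean(rec_on$internal_replication_count >= 1),
            mean(rec_off$internal_replication_count >= 1))
  # published effects of null phenomena are inflated and sign-aligned
  expect_gt(mean(rec_on$mean_published_effect, na.rm = TRUE), 0.3)
})
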