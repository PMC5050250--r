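test_that("Dirichlet-multinomial evidence matches closed forms and quadrature", {
  # int p (1-p) dp = 1/6
  expect_equal(dm_log_evidence(c(1, 1)), log(1 / 6))
  # a uniform prior makes every count equally likely: 1 / (n + 1)
  for (n in c(1, 5, 17)) {
    expect_equal(dm_log_evidence(c(0, n)), log(1 / (n + 1)))
  }
  # dense-grid quadrature oracle, 6 decimals
  expect_equal(dm_log_evidence(c(12, 30)),
               log(dm_evidence_quad(12, 30)), tolerance = 1e-6)
  expect_error(dm_log_evidence(c(1, 1), a = 0), "positive")
})

test_that("two-sided BF: Occam factor, symmetry, quadrature agreement", {
  tab_eq <- contingency_2x2(c(10, 10), c(20, 20))
  expect_lt(contingency_bf(tab_eq)$bf10, 1)

  tab <- contingency_2x2(c(12, 22), c(42, 54))
  tab_sw <- contingency_2x2(c(22, 12), c(54, 42), rev(tab$labels))
  expect_equal(contingency_bf(tab)$bf10, contingency_bf(tab_sw)$bf10)

  expect_equal(contingency_bf(tab)$bf10,
               contingency_bf_quad(12, 42, 22, 54), tolerance = 1e-4)
})

test_that("one-sided BF by posterior restriction", {
  tab <- contingency_2x2(c(12, 22), c(42, 54),
                         c("internally replicated",
                           "internally unreplicated"))
  # sampling and deterministic integration agree at 100k draws
  bs <- contingency_bf(tab, direction = "internally replicated",
                       n_samples = 1e5, seed = 42)
  bi <- contingency_bf(tab, direction = "internally replicated",
                       method = "integration")
  expect_equal(bs$bf_plus0, bi$bf_plus0, tolerance = 0.02)
  expect_equal(bs$bf_0plus * bs$bf_plus0, 1)
  # the two opposite direction probabilities sum to one
  bo <- contingency_bf(tab, direction = "internally unreplicated",
                       method = "integration")
  expect_equal(bi$posterior_prob_direction + bo$posterior_prob_direction,
               1, tolerance = 1e-8)
  # perfectly balanced table: direction carries no information
  tb <- contingency_2x2(c(15, 15), c(40, 40))
  bb <- contingency_bf(tb, direction = tb$labels[1], method = "integration")
  expect_equal(bb$posterior_prob_direction, 0.5, tolerance = 1e-8)
  expect_equal(bb$bf_plus0, bb$bf10, tolerance = 1e-8)
  expect_error(contingency_bf(tab, direction = "nope"), "must name")
})

test_that("stronger prior concentration erodes evidence for a real difference", {
  # as a dominates the counts, both models shrink to p = 1/2 and the
  # alternative's evidence advantage drains away monotonically
  tab <- contingency_2x2(c(30, 10), c(40, 40))
  bfs <- vapply(c(1, 10, 100),
                function(a) contingency_bf(tab, a = a)$bf10, 0)
  expect_true(all(diff(bfs) < 0))
  expect_gt(bfs[1] / bfs[3], 100)
})

test_that("posterior contrast: symmetry, oracle median, reproducibility", {
  tb <- contingency_2x2(c(20, 20), c(50, 50))
  ps <- posterior_contrast(tb, "log_odds_ratio", n_samples = 2e5, seed = 1)
  expect_equal(ps$median, 0, tolerance = 0.02)
  expect_true(ps$ci_low <= ps$median && ps$median <= ps$ci_high)

  tab <- contingency_2x2(c(50, 25), c(100, 100))
  ps2 <- posterior_contrast(tab, "log_odds_ratio", n_samples = 2e5,
                            seed = 2)
  expect_equal(ps2$median, grid_logodds_median(50, 100, 25, 100),
               tolerance = 0.02)

  a <- posterior_contrast(tab, "proportion_difference", seed = 7,
                          n_samples = 1e4)
  b <- posterior_contrast(tab, "proportion_difference", seed = 7,
                          n_samples = 1e4)
  expect_identical(a$median, b$median)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
})

test_that("results serialize to JSON with a full config echo", {
  tab <- contingency_2x2(c(12, 22), c(42, 54))
  bf <- contingency_bf(tab, direction = tab$labels[1], seed = 5,
                       n_samples = 1000)
  parsed <- jsonlite::fromJSON(result_json(bf))
  expect_equal(parsed$bf10, bf$bf10)
  expect_equal(parsed$config$a, 1)
  expect_equal(parsed$config$seed, 5)
  expect_equal(parsed$config$table$successes, c(12, 22))
})
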