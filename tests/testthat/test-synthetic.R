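test_that("generated tables pass study-table validation with the right shape", {
  tab <- generate_dataset(world_config("qrp_world", n_studies = 300),
                          seed = 5)
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 300L)
  expect_equal(nrow(validate_study_table(as.data.frame(tab))), 0L)
  expect_equal(sum(is.na(tab$p_replication)), round(0.04 * 300))
})

test_that("generation is reproducible and coupling = 0 reduces the moderator world to the QRP world", {
  cq <- world_config("qrp_world", n_studies = 150)
  cm0 <- world_config("moderator_world", n_studies = 150, coupling = 0)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "provenance") <- NULL
    x
  }
  a <- generate_dataset(cq, seed = 77)
  b <- generate_dataset(cq, seed = 77)
  m <- generate_dataset(cm0, seed = 77)
  expect_identical(strip(a), strip(b))
  expect_identical(strip(a), strip(m))  # worlds differ only in coupling
  expect_error(world_config("qrp_world", coupling = 0.5), "moderator")
})

test_that("the internally replicated fraction and replication power hit their targets", {
  tab <- generate_dataset(world_config("qrp_world", n_studies = 2000),
                          seed = 31)
  frac <- mean(tab$internal_replication_count > 0)
  expect_lt(abs(frac - 0.44), 3 * mc_se(0.44, 2000))
  expect_lt(abs(mean(tab$replication_power) - 0.92), 0.03)
})

test_that("QRP world: success proportions are equal in expectation across groups", {
  diffs <- vapply(1:6, function(i) {
    tab <- generate_dataset(world_config("qrp_world", n_studies = 2000),
                            seed = 400 + i)
    suc <- replication_success_flag(tab$p_replication)
    ir <- tab$internal_replication_count > 0
    mean(suc[ir], na.rm = TRUE) - mean(suc[!ir], na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(diffs)), 0.03)
  expect_true(all(abs(diffs) < 0.06))
})

test_that("moderator world with strong coupling separates the groups by a clear margin", {
  tab <- generate_dataset(world_config("moderator_world",
                                       n_studies = 2000), seed = 8)
  suc <- replication_success_flag(tab$p_replication)
  ir <- tab$internal_replication_count > 0
  expect_gt(mean(suc[ir], na.rm = TRUE) - mean(suc[!ir], na.rm = TRUE),
            0.08)
})

test_that("effect-size inflation of originals is stable across seeds", {
  m <- vapply(1:2, function(i) {
    tab <- generate_dataset(world_config("qrp_world", n_studies = 2000),
                            seed = 600 + i)
    mean(es_reduction_simple(tab$r_original, tab$r_replication),
         na.rm = TRUE)
  }, 0)
  # originals are QRP-inflated, so the reduction is clearly positive and
  # two independent replicates agree within Monte-Carlo error
  expect_true(all(m > 0.1))
  expect_lt(abs(diff(m)), 0.03)
})

test_that("correlation / standardized-difference conversions invert each other", {
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(d_to_r(r_to_d(r)), r)
  expect_equal(r_to_d(0.4472136), 1, tolerance = 1e-6)
})

test_that("world configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("world: moderator_world", "n_studies: 50",
               "coupling: 0.8", "seed: 4"), path)
  cfg <- world_config_from_yaml(path)
  expect_equal(cfg$world, "moderator_world")
  expect_equal(cfg$n_studies, 50L)
  expect_equal(cfg$coupling, 0.8)
})
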