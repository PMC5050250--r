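test_that("CSV write/read round trip is the identity, including missing values", {
  tab <- synthetic_osc_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_table(tab, path)
  back <- read_study_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab),
               ignore_attr = TRUE)
  expect_identical(is.na(back$p_replication), is.na(tab$p_replication))
  expect_identical(is.na(back$effect_type), is.na(tab$effect_type))
})

test_that("column mapping adapts foreign headers without editing the file", {
  tab <- synthetic_osc_fixture()
  df <- as.data.frame(tab)
  names(df)[names(df) == "p_replication"] <- "T_pval_USE"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  back <- read_study_table(path, columns = c(p_replication = "T_pval_USE"))
  expect_equal(back$p_replication, tab$p_replication)
  expect_error(read_study_table(path),
               class = "bayesrep_schema_error")
})

test_that("validation names the offending field and row", {
  df <- as.data.frame(synthetic_osc_fixture())
  df$p_original[3] <- 1.5
  df$r_original[7] <- -1.2
  report <- validate_study_table(df)
  expect_setequal(report$row, c(3L, 7L))
  expect_setequal(report$field, c("p_original", "r_original"))
  err <- tryCatch(study_table(df), error = identity)
  expect_s3_class(err, "bayesrep_validation_error")
  expect_match(conditionMessage(err), "row 3, p_original")
})

test_that("replication success uses a strict threshold and propagates NA", {
  expect_true(replication_success_flag(0.0017))
  expect_false(replication_success_flag(0.05))
  expect_true(is.na(replication_success_flag(NA_real_)))
  expect_identical(replication_success_flag(c(0.01, 0.9, NA)),
                   c(TRUE, FALSE, NA))
  # on a table where every replication p is significant, both groups have
  # success proportion 1
  tab <- as.data.frame(synthetic_osc_fixture())
  tab$p_replication[!is.na(tab$p_replication)] <- 0.001
  suc <- replication_success_flag(tab$p_replication)
  ir <- tab$internal_replication_count > 0
  expect_equal(mean(suc[ir], na.rm = TRUE), 1)
  expect_equal(mean(suc[!ir], na.rm = TRUE), 1)
})

test_that("effect-size reductions: arithmetic, Fisher-z, antisymmetry", {
  expect_equal(es_reduction_simple(0.4, 0.4), 0)
  expect_equal(es_reduction_simple(0.5, 0.3), 0.2)
  expect_equal(es_reduction_q(0.5, 0.3), 0.2397865401, tolerance = 1e-9)
  rs <- seq(-0.9, 0.9, by = 0.15)
  expect_equal(es_reduction_q(rs, rs), rep(0, length(rs)))
  expect_equal(es_reduction_q(rs, rev(rs)), -es_reduction_q(rev(rs), rs))
  expect_error(es_reduction_q(1, 0.3), "undefined")
})

test_that("log sample size flags (not drops) the unusually large study", {
  tab <- synthetic_osc_fixture()
  ls <- log_sample_size(tab)
  expect_equal(nrow(ls), nrow(tab))
  expect_identical(which(ls$excluded), which(tab$n_original == 230025))
  expect_equal(exp(ls$log_n[!ls$excluded]),
               tab$n_original[!ls$excluded])
  expect_equal(log_sample_size(data.frame(n_original = 1))$log_n, 0)
})

test_that("packaged fixture reproduces the documented marginals", {
  tab <- synthetic_osc_fixture()
  expect_equal(nrow(tab), 100L)
  expect_equal(sum(tab$internal_replication_count > 0), 44L)
  expect_equal(as.vector(table(factor(
    tab$internal_replication_count[tab$internal_replication_count > 0],
    levels = 1:4))), c(20L, 10L, 9L, 5L))
  usable <- !is.na(tab$p_replication)
  ir <- tab$internal_replication_count > 0
  expect_equal(sum(usable & ir), 42L)
  expect_equal(sum(usable & !ir), 54L)
  suc <- replication_success_flag(tab$p_replication)
  expect_equal(sum(suc[usable & ir]), 12L)
  expect_equal(sum(suc[usable & !ir]), 22L)
  expect_equal(sum(tab$discipline[usable & ir] == "cognitive"), 13L)
  expect_equal(sum(tab$discipline[usable & !ir] == "cognitive"), 29L)
  expect_equal(sum(tab$effect_type[usable & ir] == "main", na.rm = TRUE), 20L)
  expect_equal(sum(!is.na(tab$effect_type[usable & ir])), 36L)
  expect_equal(sum(!is.na(tab$effect_type[usable & !ir])), 50L)
  expect_equal(sum(tab$power_analysis_present[usable & ir]), 0L)
  expect_equal(sum(tab$power_analysis_present[usable & !ir]), 2L)
  # the shipped CSV is this same table
  csv <- system.file("extdata", "synthetic_osc100.csv",
                     package = "bayesrep")
  expect_equal(as.data.frame(read_study_table(csv)), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("internal-replication grouping partitions every table", {
  for (seed in 1:3) {
    tab <- generate_dataset(world_config("qrp_world", n_studies = 60),
                            seed = seed)
    ir <- tab$internal_replication_count > 0
    expect_equal(sum(ir) + sum(!ir), nrow(tab))
  }
})
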