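# A deterministic synthetic stand-in for the reproducibility-project
# study table. The real per-study dataset is external; this table is
# constructed (no RNG) to reproduce the documented marginals exactly --
# 100 effects, 44 internally replicated (counts 20x1, 10x2, 9x3, 5x4),
# 96 usable replication outcomes (42 + 54), success counts 12/42 and
# 22/54, field counts 13/29 vs 29/25 with subgroup successes 5/29, 8/25
# (social) and 7/13, 14/29 (cognitive), effect-type counts 20/36 vs
# 29/50, power-analysis counts 0/42 vs 2/54, and one unusually large
# original sample (N = 230,025). Continuous covariates are plausible
# deterministic sequences; they are NOT fit to the external data.

# evenly spaced sequence with an exact mean
.seq_mean <- function(n, mean, half_range) {
  if (n == 1L) return(mean)
  mean + seq(-half_range, half_range, length.out = n)
}

#' Deterministic synthetic fixture table
#'
#' Builds the packaged 100-row synthetic study table whose categorical
#' marginals match the documented contingency tables of the emulated
#' analysis (see the package vignette). Fully deterministic: no RNG.
#'
#' @return A validated [study_table()].
#' @export
synthetic_osc_fixture <- function() {
  n <- 100L
  ir <- c(rep(TRUE, 44L), rep(FALSE, 56L))
  internal_count <- c(rep(1L, 20L), rep(2L, 10L), rep(3L, 9L),
                      rep(4L, 5L), rep(0L, 56L))

  # usable replication outcome: all but rows 43, 44 (internally
  # replicated) and 99, 100 (not internally replicated)
  usable <- rep(TRUE, n)
  usable[c(43L, 44L, 99L, 100L)] <- FALSE

  # field of study among usable rows: 13/29 (IR), 29/25 (not IR)
  discipline <- rep("social", n)
  discipline[1:13] <- "cognitive"        # IR cognitive
  discipline[45:73] <- "cognitive"       # non-IR cognitive
  discipline[c(99L, 100L)] <- "cognitive"

  # successes: cognitive 7/13 and 14/29, social 5/29 and 8/25
  success <- rep(FALSE, n)
  success[1:7] <- TRUE       # IR cognitive
  success[14:18] <- TRUE     # IR social
  success[45:58] <- TRUE     # non-IR cognitive
  success[74:81] <- TRUE     # non-IR social

  p_replication <- rep(NA_real_, n)
  n_succ <- sum(success & usable)
  p_replication[success & usable] <- .seq_mean(n_succ, 0.02, 0.018)
  fail <- !success & usable
  p_replication[fail] <- .seq_mean(sum(fail), 0.5, 0.44)
  p_replication[74L] <- 0.0017  # lower-quartile landmark, non-IR group

  # effect type: 20 main / 16 interaction / 6 missing among usable IR;
  # 29 / 21 / 4 among usable non-IR
  effect_type <- rep(NA_character_, n)
  effect_type[1:20] <- "main"
  effect_type[21:36] <- "interaction"
  effect_type[45:73] <- "main"
  effect_type[74:94] <- "interaction"

  # formal power analysis: 0/42 (IR) vs 2/54 (non-IR) among usable rows
  power_analysis_present <- rep(FALSE, n)
  power_analysis_present[c(45L, 46L)] <- TRUE

  r_original <- numeric(n)
  r_original[ir] <- .seq_mean(44L, 0.36, 0.21)
  r_original[!ir] <- .seq_mean(56L, 0.42, 0.22)
  r_replication <- pmax(r_original - 0.20, 0.01)
  r_replication[!usable] <- NA_real_

  n_original <- integer(n)
  n_original[ir] <- as.integer(round(.seq_mean(44L, 71, 45)))
  n_original[!ir] <- as.integer(round(.seq_mean(56L, 90, 60)))
  n_original[98L] <- 230025L  # the unusually large study (not IR)

  st <- study_table(data.frame(
    study_id = sprintf("F%03d", seq_len(n)),
    internal_replication_count = internal_count,
    discipline = discipline,
    effect_type = effect_type,
    p_original = .seq_mean(n, 0.0205, 0.0195),
    r_original = r_original,
    n_original = n_original,
    p_replication = p_replication,
    r_replication = r_replication,
    replication_power = .seq_mean(n, 0.92, 0.05),
    surprisingness = .seq_mean(n, 3.05, 1.5),
    challenge = .seq_mean(n, -0.05, 0.9),
    power_analysis_present = power_analysis_present,
    stringsAsFactors = FALSE),
    provenance = "synthetic fixture reproducing documented marginals")
  st
}
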