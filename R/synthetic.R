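# Synthetic reproducibility-project-style datasets under two competing
# accounts of replication failure. In both worlds the original lab's
# published record (original study + internal conceptual replications) is
# produced by QRP machinery: every candidate study is run with optional
# stopping, only significant results are published, and published effects
# are HARKed. The signal the lab's candidate studies tap is uncorrelated
# with the replication-relevant latent effect, so in the QRP world internal
# replication carries no information about independent replication success
# (the group success proportions are equal in expectation by construction).
# In the moderator world, the replication team's effect is attenuated less
# for internally replicated effects (coupling > 0), which makes internal
# replication genuinely predictive.

#' Convert a correlation to a standardized mean difference
#'
#' Equal-group conversion d = 2r / sqrt(1 - r^2); inverse of [d_to_r()].
#' @param r correlation in (-1, 1).
#' @return Cohen's d.
#' @export
r_to_d <- function(r) 2 * r / sqrt(1 - r^2)

#' Convert a standardized mean difference to a correlation
#'
#' Equal-group conversion r = d / sqrt(d^2 + 4).
#' @param d Cohen's d.
#' @return correlation.
#' @export
d_to_r <- function(d) d / sqrt(d^2 + 4)

#' Configure a synthetic-data world
#'
#' The generator's study conditions. Defaults emulate the reproducibility
#' dataset's documented marginals: 100 effects, 44% with internal
#' replications (with counts distributed 20:10:9:5 over 1, 2, 3, >3),
#' replication power targeted at .92 against the original's claimed effect
#' size, and a 42% cognitive / 58% social discipline mix.
#'
#' @param world `"qrp_world"` (internal replication uninformative) or
#'   `"moderator_world"` (internally replicated effects attenuate less).
#' @param n_studies number of effects (default 100).
#' @param frac_internal fraction of labs that pursue internal replications
#'   until they publish them (default .44).
#' @param null_fraction fraction of effects whose replication-relevant
#'   latent effect is exactly zero (default .5).
#' @param effect_mean,effect_sd mean and sd of the non-null latent effect
#'   on the correlation scale (default .4 and .1).
#' @param power_target nominal power of the replication study against the
#'   original's claimed effect (default .92).
#' @param attenuation fraction by which the replication team's effect is
#'   attenuated relative to the latent effect (default .5): the QRP-world
#'   mechanism by which even clean replications of real effects can fail.
#' @param coupling in `moderator_world`, the fractional reduction in
#'   attenuation enjoyed by internally replicated effects (0 = none, 1 =
#'   internally replicated effects replicate at full strength). Forced to
#'   0 in `qrp_world`; `coupling = 0` makes the two worlds identical.
#' @param prop_cognitive discipline mix (default .42 cognitive).
#' @param missing_rate fraction of studies with a missing replication
#'   outcome (default .04, i.e. 4 of 100).
#' @param internal_count_probs distribution of the targeted number of
#'   internal replications among pursuing labs (counts 1-4; default the
#'   documented 20:10:9:5 marginal).
#' @param n_min,n_max,step,alpha optional-stopping schedule of the original
#'   lab's candidate studies (per group).
#' @param max_attempts cap on candidate studies a lab will run.
#' @param n_rep_max cap on the replication's per-group sample size.
#' @param seed master seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(world = c("qrp_world", "moderator_world"),
                         n_studies = 100, frac_internal = 0.44,
                         null_fraction = 0.5, effect_mean = 0.4,
                         effect_sd = 0.1, power_target = 0.92,
                         attenuation = 0.5,
                         coupling = if (match.arg(world) ==
                                        "moderator_world") 1 else 0,
                         prop_cognitive = 0.42, missing_rate = 0.04,
                         internal_count_probs = c(20, 10, 9, 5) / 44,
                         n_min = 10, n_max = 50, step = 1, alpha = 0.05,
                         max_attempts = 40, n_rep_max = 1000,
                         seed = NULL) {
  world <- match.arg(world)
  probs <- c(frac_internal, null_fraction, power_target, attenuation,
             coupling, prop_cognitive, missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all fractions/probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (world == "qrp_world" && coupling != 0) {
    stop("coupling is a moderator_world parameter; qrp_world has 0",
         call. = FALSE)
  }
  if (power_target >= stats::pnorm(stats::qnorm(0.975) *
                                   (sqrt(2 * n_rep_max) - 1))) {
    stop("power target unreachable at n_rep_max", call. = FALSE)
  }
  stopifnot(n_studies >= 1, effect_sd >= 0,
            abs(sum(internal_count_probs) - 1) < 1e-8)
  structure(list(world = world, n_studies = as.integer(n_studies),
                 frac_internal = frac_internal,
                 null_fraction = null_fraction, effect_mean = effect_mean,
                 effect_sd = effect_sd, power_target = power_target,
                 attenuation = attenuation, coupling = coupling,
                 prop_cognitive = prop_cognitive,
                 missing_rate = missing_rate,
                 internal_count_probs = internal_count_probs,
                 n_min = n_min, n_max = n_max, step = step, alpha = alpha,
                 max_attempts = as.integer(max_attempts),
                 n_rep_max = as.integer(n_rep_max), seed = seed),
            class = "world_config")
}

#' Read a world configuration from YAML
#'
#' @param path YAML file whose keys are [world_config()] arguments.
#' @return A `world_config`.
#' @export
world_config_from_yaml <- function(path) {
  do.call(world_config, yaml::read_yaml(path))
}

# Exact power of a two-sided two-sample t test at per-group size n.
.t_power <- function(d, n, alpha = 0.05) {
  df <- 2 * n - 2
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

# Run one optional-stopping candidate study per active lab, in rounds,
# until each lab has `target` significant studies or its attempt budget is
# exhausted. Returns counts plus the first significant run per lab.
.run_until_significant <- function(m, target, cfg) {
  des <- optional_stopping_design(cfg$n_min, cfg$n_max, cfg$step,
                                  cfg$alpha, "two_sample", 0, m)
  achieved <- integer(m)
  attempts <- integer(m)
  first <- data.frame(n_stop = rep(NA_integer_, m), p = rep(NA_real_, m),
                      d = rep(NA_real_, m))
  active <- achieved < target & attempts < cfg$max_attempts
  while (any(active)) {
    idx <- which(active)
    runs <- .os_run(length(idx), 0, des)
    attempts[idx] <- attempts[idx] + 1L
    hit <- idx[runs$stopped]
    achieved[hit] <- achieved[hit] + 1L
    new_first <- hit[is.na(first$p[hit])]
    if (length(new_first) > 0L) {
      ii <- match(new_first, idx)
      first$n_stop[new_first] <- runs$n_stop[ii]
      first$p[new_first] <- runs$p[ii]
      first$d[new_first] <- runs$d[ii]
    }
    active <- achieved < target & attempts < cfg$max_attempts
  }
  # labs whose budget ran out before any significance: fall back to one
  # final (non-significant) run as their published original
  fail <- which(is.na(first$p))
  if (length(fail) > 0L) {
    runs <- .os_run(length(fail), 0, des)
    first$n_stop[fail] <- runs$n_stop
    first$p[fail] <- runs$p
    first$d[fail] <- runs$d
  }
  list(achieved = achieved, first = first)
}

#' Generate a synthetic study table
#'
#' Simulates `n_studies` effects: the original lab's record is produced by
#' the QRP machinery (optional stopping + publication filter + HARKing;
#' labs pursuing internal replication keep running candidate studies until
#' their targeted number of internal replications is published), and the
#' independent replication is run cleanly as a single two-sample t test at
#' a size powered at `power_target` against the original's claimed effect.
#'
#' @param config a [world_config()].
#' @param seed overrides `config$seed`.
#' @return A validated [study_table()].
#' @export
generate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  n <- cfg$n_studies
  with_seed(seed, {
    # latent replication-relevant effects
    real <- stats::runif(n) < 1 - cfg$null_fraction
    r_true <- ifelse(real,
                     pmin(0.95, pmax(0.02,
                       stats::rnorm(n, cfg$effect_mean, cfg$effect_sd))),
                     0)
    d_true <- r_to_d(r_true)

    # lab record: originals + internal replications, pure QRP machinery
    pursuing <- stats::runif(n) < cfg$frac_internal
    target_extra <- integer(n)
    target_extra[pursuing] <- sample.int(
      length(cfg$internal_count_probs), sum(pursuing), replace = TRUE,
      prob = cfg$internal_count_probs)
    lab <- .run_until_significant(n, 1L + target_extra, cfg)
    internal_count <- pmax(0L, lab$achieved - 1L)

    d_orig_pub <- apply_harking(lab$first$d)      # HARKing
    r_original <- d_to_r(d_orig_pub)
    p_original <- pmin(1, pmax(1e-12, lab$first$p))
    n_original <- 2L * lab$first$n_stop

    # replication: clean single look, powered against the claimed effect
    d_claimed <- pmax(0.05, d_orig_pub)
    z_need <- stats::qnorm(0.975) + stats::qnorm(cfg$power_target)
    n_rep <- pmin(cfg$n_rep_max,
                  pmax(4L, as.integer(ceiling(2 * z_need^2 /
                                              d_claimed^2)) + 1L))
    replication_power <- .t_power(d_claimed, n_rep, 0.05)

    atten <- cfg$attenuation *
      (1 - cfg$coupling * (internal_count > 0L))
    d_rep_true <- d_true * (1 - atten)
    df_rep <- 2 * n_rep - 2
    ncp <- d_rep_true * sqrt(n_rep / 2)
    t_rep <- (stats::rnorm(n) + ncp) /
      sqrt(stats::rchisq(n, df_rep) / df_rep)
    p_replication <- pmax(1e-300, 2 * stats::pt(-abs(t_rep), df_rep))
    r_replication <- d_to_r(t_rep * sqrt(2 / n_rep))

    # covariates not tied to the mechanism
    discipline <- ifelse(stats::runif(n) < cfg$prop_cognitive,
                         "cognitive", "social")
    effect_type <- ifelse(stats::runif(n) < 0.57, "main", "interaction")
    surprisingness <- pmin(6, pmax(1, stats::rnorm(n, 3, 0.9)))
    challenge <- stats::rnorm(n, 0, 0.8)
    power_analysis_present <- stats::runif(n) < 0.02

    # missing replication outcomes
    n_miss <- round(cfg$missing_rate * n)
    if (n_miss > 0L) {
      miss <- sample.int(n, n_miss)
      p_replication[miss] <- NA_real_
      r_replication[miss] <- NA_real_
    }

    study_table(data.frame(
      study_id = sprintf("S%04d", seq_len(n)),
      internal_replication_count = internal_count,
      discipline = discipline, effect_type = effect_type,
      p_original = p_original, r_original = r_original,
      n_original = n_original, p_replication = p_replication,
      r_replication = r_replication,
      replication_power = replication_power,
      surprisingness = surprisingness, challenge = challenge,
      power_analysis_present = power_analysis_present,
      stringsAsFactors = FALSE),
      provenance = sprintf("synthetic %s (seed %s)", cfg$world,
                           format(seed %||% "unset")))
  })
}

#' Check that the pipeline discriminates the two worlds
#'
#' Generates paired datasets from a QRP-world and a moderator-world
#' configuration (sharing all parameters except the coupling), runs the
#' primary success comparison on each, and reports the directional Bayes
#' factors: the QRP world should support the null (BF_0+) and the
#' moderator world the order-restricted alternative (BF_+0).
#'
#' @param config_qrp,config_mod paired [world_config()]s.
#' @param n_runs seeded replicate runs per world (default 20).
#' @param seed master seed from which run seeds are derived.
#' @return data.frame (class `world_discrimination`) with one row per run
#'   and world, containing `bf_0plus`, `bf_plus0` and the success
#'   proportions; fractions of runs past conventional evidence thresholds
#'   are attached as attributes `frac_qrp_bf0plus_gt3` and
#'   `frac_mod_bfplus0_gt10`.
#' @export
world_discrimination_check <- function(config_qrp, config_mod,
                                       n_runs = 20, seed = 1) {
  stopifnot(config_qrp$world == "qrp_world",
            config_mod$world == "moderator_world")
  rows <- list()
  for (i in seq_len(n_runs)) {
    for (cfg in list(config_qrp, config_mod)) {
      tab <- generate_dataset(cfg, seed = child_seed(seed, i))
      rep <- run_primary_comparison(tab, seed = child_seed(seed, 1000 + i),
                                    method = "integration",
                                    include_es_rows = FALSE)
      row <- rep$rows[["replication_success"]]
      rows[[length(rows) + 1L]] <- data.frame(
        world = cfg$world, run = i,
        bf_0plus = row$bf$bf_0plus, bf_plus0 = row$bf$bf_plus0,
        prop_internal = row$groups$proportion[1L],
        prop_not_internal = row$groups$proportion[2L])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "frac_qrp_bf0plus_gt3") <-
    mean(out$bf_0plus[out$world == "qrp_world"] > 3)
  attr(out, "frac_mod_bfplus0_gt10") <-
    mean(out$bf_plus0[out$world == "moderator_world"] > 10)
  class(out) <- c("world_discrimination", "data.frame")
  out
}

#' @export
print.world_discrimination <- function(x, ...) {
  cat("World discrimination check\n")
  cat(sprintf("  qrp_world runs with BF0+ > 3:   %.0f%%\n",
              100 * attr(x, "frac_qrp_bf0plus_gt3")))
  cat(sprintf("  moderator_world runs with BF+0 > 10: %.0f%%\n",
              100 * attr(x, "frac_mod_bfplus0_gt10")))
  print(as.data.frame(x))
  invisible(x)
}
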