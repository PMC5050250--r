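# Generative models of three questionable research practices (QRPs):
# optional stopping ("sampling until significant"), publication bias (the
# file drawer), and HARKing (sign-aligning effects with post hoc
# hypotheses). Observations are unit-normal and tests are standard t tests
# with closed-form p-values, so rates and inflation are measured exactly
# as a sequential analyst would produce them.

#' Configure an optional-stopping design
#'
#' A researcher peeks at the accumulating data at sizes `n_min`,
#' `n_min + step`, ... up to `n_max` (per group for the two-sample test)
#' and stops at the first peek with p < `alpha`.
#'
#' @param n_min,n_max first and last per-group sample size examined.
#' @param step observations added between peeks (default 1: peek after
#'   every added observation).
#' @param alpha significance threshold (default .05, two-sided).
#' @param test `"two_sample"` (default) or `"one_sample"`.
#' @param delta true standardized mean difference (0 for a null effect).
#' @param n_sims number of simulated studies.
#' @param seed RNG seed.
#' @return An object of class `os_design`.
#' @export
optional_stopping_design <- function(n_min = 10, n_max = 50, step = 1,
                                     alpha = 0.05,
                                     test = c("two_sample", "one_sample"),
                                     delta = 0, n_sims = 1000,
                                     seed = NULL) {
  test <- match.arg(test)
  stopifnot(n_min >= 2, n_min <= n_max, step >= 1, alpha > 0, alpha < 1,
            n_sims >= 1)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 step = as.integer(step), alpha = alpha, test = test,
                 delta = delta, n_sims = as.integer(n_sims), seed = seed),
            class = "os_design")
}

# Workhorse: m sequential studies under the current RNG stream. `delta`
# may be a vector (one true effect per study). Returns one row per study
# with the state at the stopping peek (or the final peek if never
# significant). Because all n_max observations are drawn before peeking,
# two designs differing only in their peek schedule share identical data
# under the same seed (common random numbers).
.os_run <- function(m, delta, design) {
  n_max <- design$n_max
  peeks <- seq(design$n_min, n_max, by = design$step)
  two <- design$test == "two_sample"

  y1 <- matrix(stats::rnorm(n_max * m), n_max, m)
  y1 <- y1 + rep(delta, each = n_max)
  s1 <- apply(y1, 2L, cumsum)
  q1 <- apply(y1^2, 2L, cumsum)
  if (two) {
    y2 <- matrix(stats::rnorm(n_max * m), n_max, m)
    s2 <- apply(y2, 2L, cumsum)
    q2 <- apply(y2^2, 2L, cumsum)
  }

  stopped <- rep(FALSE, m)
  n_stop <- rep(n_max, m)
  p_out <- rep(NA_real_, m)
  d_out <- rep(NA_real_, m)

  for (n in peeks) {
    active <- !stopped
    last <- n == peeks[length(peeks)]
    if (!any(active) && !last) next
    idx <- if (last) seq_len(m) else which(active)
    m1 <- s1[n, idx] / n
    v1 <- pmax(0, (q1[n, idx] - n * m1^2) / (n - 1))
    if (two) {
      m2 <- s2[n, idx] / n
      v2 <- pmax(0, (q2[n, idx] - n * m2^2) / (n - 1))
      sp2 <- (v1 + v2) / 2
      tt <- (m1 - m2) / sqrt(sp2 * 2 / n)
      df <- 2 * n - 2
      d <- (m1 - m2) / sqrt(sp2)
    } else {
      tt <- m1 / sqrt(v1 / n)
      df <- n - 1
      d <- m1 / sqrt(v1)
    }
    p <- 2 * stats::pt(-abs(tt), df)
    sig <- is.finite(p) & p < design$alpha
    newly <- idx[active[idx] & sig]
    if (length(newly) > 0L) {
      stopped[newly] <- TRUE
      n_stop[newly] <- n
      ii <- match(newly, idx)
      p_out[newly] <- p[ii]
      d_out[newly] <- d[ii]
    }
    if (last) {
      rest <- idx[is.na(p_out[idx])]
      ii <- match(rest, idx)
      p_out[rest] <- p[ii]
      d_out[rest] <- d[ii]
    }
  }
  data.frame(stopped = stopped, n_stop = n_stop, p = p_out, d = d_out)
}

#' Simulate optional stopping
#'
#' Runs `n_sims` sequential studies under the design and reports the
#' fraction that stopped significant (the false-positive rate when
#' `delta = 0`), the distribution of stopping sample sizes, and the effect
#' estimates at stopping. Designs that share a seed, test type, `delta`
#' and `n_max` see identical observations and differ only in where they
#' peek, which makes schedule comparisons sharp (common random numbers).
#'
#' @param design an [optional_stopping_design()].
#' @return An object of class `qrp_sim` with elements
#'   `false_positive_rate` (rejection rate; a true false-positive rate only
#'   when `delta = 0`), `stop_n`, `p_values`, `estimates` (signed Cohen's
#'   d at stopping), `stopped`, and the design echo.
#' @export
simulate_optional_stopping <- function(design) {
  stopifnot(inherits(design, "os_design"))
  runs <- with_seed(design$seed,
                    .os_run(design$n_sims, design$delta, design))
  structure(list(false_positive_rate = mean(runs$stopped),
                 stop_n = runs$n_stop, p_values = runs$p,
                 estimates = runs$d, stopped = runs$stopped,
                 design = design),
            class = "qrp_sim")
}

#' @export
print.qrp_sim <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Optional stopping: %d sims, peeks %d..%d by %d (%s, delta = %g)\n",
    d$n_sims, d$n_min, d$n_max, d$step, d$test, d$delta))
  cat(sprintf("  significant-stop rate: %.4f\n", x$false_positive_rate))
  cat(sprintf("  mean n at stop: %.1f; mean |d| among significant: %.3f\n",
              mean(x$stop_n),
              mean(abs(x$estimates[x$stopped]))))
  invisible(x)
}

#' Apply a publication filter to study results
#'
#' Significant results are always retained; non-significant results are
#' retained with probability `prob_report_nonsignificant` (0 reproduces a
#' total file drawer, 1 is the identity).
#'
#' @param p_values numeric vector of p-values.
#' @param estimates effect estimates aligned with `p_values`.
#' @param prob_report_nonsignificant probability of publishing a
#'   non-significant result.
#' @param alpha significance threshold (default .05).
#' @param seed RNG seed.
#' @return list with logical `published`, and `p_values`/`estimates`
#'   restricted to the published subset.
#' @export
apply_publication_bias <- function(p_values, estimates,
                                   prob_report_nonsignificant = 0,
                                   alpha = 0.05, seed = NULL) {
  stopifnot(length(p_values) == length(estimates),
            prob_report_nonsignificant >= 0,
            prob_report_nonsignificant <= 1)
  published <- with_seed(seed, {
    sig <- !is.na(p_values) & p_values < alpha
    sig | stats::runif(length(p_values)) < prob_report_nonsignificant
  })
  list(published = published, p_values = p_values[published],
       estimates = estimates[published])
}

#' Apply HARKing to effect estimates
#'
#' Hypothesizing after the results are known: every effect is reported as
#' confirming the (post hoc) prediction, so reported effect sizes are never
#' negative. Order is preserved.
#'
#' @param estimates numeric vector of signed effect estimates.
#' @return `abs(estimates)`.
#' @export
apply_harking <- function(estimates) abs(estimates)

#' Configure a QRP world for a single lab
#'
#' Describes how one original lab produces its published record for one
#' effect: how many candidate internal studies it runs, whether each uses
#' optional stopping (vs a single look at `n_fixed` per group), the
#' publication filter, and whether HARKing is applied.
#'
#' @param n_candidates candidate internal studies per effect (default 4).
#' @param optional_stopping run each candidate sequentially (default TRUE)?
#' @param n_min,n_max,step,alpha optional-stopping schedule (see
#'   [optional_stopping_design()]).
#' @param n_fixed per-group sample size when `optional_stopping = FALSE`.
#' @param prob_report_nonsignificant publication filter (default 0: total
#'   file drawer).
#' @param harking apply HARKing to published effects (default TRUE)?
#' @param delta true standardized effect of the studied phenomenon.
#' @return An object of class `qrp_world_config`.
#' @export
qrp_world_config <- function(n_candidates = 4, optional_stopping = TRUE,
                             n_min = 10, n_max = 50, step = 1,
                             alpha = 0.05, n_fixed = 30,
                             prob_report_nonsignificant = 0,
                             harking = TRUE, delta = 0) {
  stopifnot(n_candidates >= 1)
  structure(list(n_candidates = as.integer(n_candidates),
                 optional_stopping = isTRUE(optional_stopping),
                 n_min = n_min, n_max = n_max, step = step, alpha = alpha,
                 n_fixed = n_fixed,
                 prob_report_nonsignificant = prob_report_nonsignificant,
                 harking = isTRUE(harking), delta = delta),
            class = "qrp_world_config")
}

#' Simulate the published record of many effects under QRPs
#'
#' Each of `n_effects` labs runs `n_candidates` studies on its effect under
#' the enabled QRPs; significant results are always published and
#' non-significant ones pass the publication filter. An effect counts as
#' internally replicated when at least two published significant studies
#' exist (the original plus one internal replication).
#'
#' @param world a [qrp_world_config()].
#' @param n_effects number of effects (labs).
#' @param seed RNG seed.
#' @return data.frame with one row per effect: `n_published`,
#'   `n_significant_published`, `internal_replication_count`
#'   (`max(0, n_significant_published - 1)`), `internally_replicated`,
#'   `mean_published_effect` (NA when nothing is published), `truth`
#'   (TRUE when `delta != 0`).
#' @export
simulate_publication_record <- function(world, n_effects, seed = NULL) {
  stopifnot(inherits(world, "qrp_world_config"), n_effects >= 1)
  with_seed(seed, {
    k <- world$n_candidates
    m <- n_effects * k
    if (world$optional_stopping) {
      des <- optional_stopping_design(world$n_min, world$n_max,
                                      world$step, world$alpha,
                                      "two_sample", world$delta, m)
      runs <- .os_run(m, world$delta, des)
    } else {
      n <- world$n_fixed
      des <- optional_stopping_design(n, n, 1, world$alpha, "two_sample",
                                      world$delta, m)
      runs <- .os_run(m, world$delta, des)
    }
    pub <- apply_publication_bias(runs$p, runs$d,
                                  world$prob_report_nonsignificant,
                                  world$alpha)
    eff <- rep(seq_len(n_effects), each = k)
    published <- pub$published
    sig <- !is.na(runs$p) & runs$p < world$alpha
    d_pub <- runs$d
    if (world$harking) d_pub <- apply_harking(d_pub)

    n_published <- tabulate(eff[published], nbins = n_effects)
    n_sig_pub <- tabulate(eff[published & sig], nbins = n_effects)
    sum_d <- vapply(seq_len(n_effects), function(i) {
      sel <- published & eff == i
      if (!any(sel)) NA_real_ else mean(d_pub[sel])
    }, 0)
    data.frame(effect = seq_len(n_effects),
               n_published = n_published,
               n_significant_published = n_sig_pub,
               internal_replication_count = pmax(0L, n_sig_pub - 1L),
               internally_replicated = n_sig_pub >= 2L,
               mean_published_effect = sum_d,
               truth = rep(world$delta != 0, n_effects))
  })
}
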