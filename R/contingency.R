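# Dirichlet-multinomial (Gunel-Dickey style) Bayes factors for 2x2 tables
# under the independent-multinomial sampling plan (group totals fixed by
# design), with order-restricted one-sided variants computed by posterior
# restriction, and Beta-posterior estimation of the group contrast.

#' Construct a 2x2 success/failure contingency table
#'
#' Successes and failures for two groups whose totals are fixed by design
#' (the independent-multinomial sampling plan: each group's row is a
#' binomial sample).
#'
#' @param successes integer vector of length 2, successes per group.
#' @param totals integer vector of length 2, group sizes.
#' @param labels character vector of length 2 naming the groups.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(successes, totals,
                            labels = c("group1", "group2")) {
  stopifnot(length(successes) == 2L, length(totals) == 2L,
            length(labels) == 2L, !anyNA(successes), !anyNA(totals))
  successes <- as.integer(round(successes))
  totals <- as.integer(round(totals))
  if (any(totals < 1L)) stop("group totals must be positive", call. = FALSE)
  if (any(successes < 0L) || any(successes > totals)) {
    stop("successes must lie in [0, total] for each group", call. = FALSE)
  }
  structure(list(successes = successes, totals = totals,
                 labels = as.character(labels)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat("2x2 contingency table (group totals fixed):\n")
  for (i in 1:2) {
    cat(sprintf("  %-28s %d out of %d\n", x$labels[i], x$successes[i],
                x$totals[i]))
  }
  invisible(x)
}

#' Log marginal likelihood of binomial rows under Dirichlet priors
#'
#' The Dirichlet-multinomial log evidence of one or two success/failure
#' rows, omitting the binomial coefficients (they are identical under the
#' null and alternative models and cancel from every Bayes factor). With
#' `shared = FALSE` each row gets its own Beta(a, a) success probability;
#' with `shared = TRUE` the rows are pooled under a single probability.
#' For a single row (y, n - y) with a = 1 this is log B(y + 1, n - y + 1).
#'
#' @param counts numeric vector `c(successes, failures)` for a single row,
#'   or a 2-column matrix with one row per group.
#' @param a Dirichlet/Beta prior concentration (default 1, uniform).
#' @param shared pool all rows under one success probability?
#' @return log marginal likelihood (a scalar).
#' @export
dm_log_evidence <- function(counts, a = 1, shared = FALSE) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    stop("prior concentration 'a' must be a positive number", call. = FALSE)
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 2L, all(counts >= 0))
  if (shared) counts <- matrix(colSums(counts), nrow = 1L)
  sum(lbeta(a + counts[, 1L], a + counts[, 2L]) - lbeta(a, a))
}

# P(p_1 > p_2) under independent Beta posteriors; sampled ties count half.
.beta_direction_prob <- function(shape1, shape2, method, n_samples, seed) {
  if (method == "integration") {
    f <- function(p) stats::dbeta(p, shape1[1L], shape1[2L]) *
      stats::pbeta(p, shape2[1L], shape2[2L])
    stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
  } else {
    with_seed(seed, {
      p1 <- stats::rbeta(n_samples, shape1[1L], shape1[2L])
      p2 <- stats::rbeta(n_samples, shape2[1L], shape2[2L])
      mean(p1 > p2) + 0.5 * mean(p1 == p2)
    })
  }
}

.match_direction <- function(direction, labels) {
  i <- match(direction, labels)
  if (is.na(i)) {
    stop("'direction' must name one of the groups: ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  i
}

#' Gunel-Dickey style Bayes factor for a 2x2 table
#'
#' Compares the null model of a single shared success probability against
#' the alternative of independent per-group probabilities, each under a
#' Beta(a, a) prior (independent-multinomial sampling plan; the group
#' totals are the fixed margin). The two-sided Bayes factor is the closed
#' form `exp(log_ev_alt - log_ev_null)`. When `direction` names a group,
#' the order-restricted Bayes factor is obtained by posterior restriction:
#' `bf_plus0 = bf10 * P(direction holds | data, alt) / (1/2)`, with the
#' direction probability computed from the independent Beta posteriors by
#' sampling (default, reproducible under `seed`) or by deterministic 1-D
#' integration.
#'
#' @param table a [contingency_2x2()].
#' @param a prior concentration (default 1).
#' @param direction optional: label of the group whose success probability
#'   the alternative asserts to be larger. When omitted only the two-sided
#'   `bf10` is filled in.
#' @param method `"sampling"` or `"integration"` for the direction
#'   probability.
#' @param n_samples posterior sample count for `method = "sampling"`.
#' @param seed RNG seed for sampling (NULL: use current RNG state).
#' @return A `bf_result` with elements `bf10`, `bf_plus0`, `bf_0plus`,
#'   `log_evidence_null`, `log_evidence_alt`, `posterior_prob_direction`
#'   and a `config` echo.
#' @export
contingency_bf <- function(table, a = 1, direction = NULL,
                           method = c("sampling", "integration"),
                           n_samples = 1e5, seed = NULL) {
  stopifnot(inherits(table, "contingency_2x2"))
  method <- match.arg(method)
  rows <- cbind(table$successes, table$totals - table$successes)
  log_ev_alt <- dm_log_evidence(rows, a = a, shared = FALSE)
  log_ev_null <- dm_log_evidence(rows, a = a, shared = TRUE)
  bf10 <- exp(log_ev_alt - log_ev_null)

  p_dir <- NA_real_
  bf_plus0 <- NA_real_
  if (!is.null(direction)) {
    i <- .match_direction(direction, table$labels)
    j <- 3L - i
    p_dir <- .beta_direction_prob(a + rows[i, ], a + rows[j, ],
                                  method, n_samples, seed)
    bf_plus0 <- bf10 * p_dir / 0.5
  }

  structure(list(
    bf10 = bf10,
    bf_plus0 = bf_plus0,
    bf_0plus = if (is.na(bf_plus0)) NA_real_ else 1 / bf_plus0,
    log_evidence_null = log_ev_null,
    log_evidence_alt = log_ev_alt,
    posterior_prob_direction = p_dir,
    config = list(model = "gunel_dickey_indep_multinomial", a = a,
                  direction = direction, method = method,
                  n_samples = if (method == "sampling" &&
                                  !is.null(direction)) n_samples else NULL,
                  seed = seed,
                  table = list(labels = table$labels,
                               successes = table$successes,
                               totals = table$totals))),
    class = "bf_result")
}

#' @export
print.bf_result <- function(x, digits = 3, ...) {
  cat("Bayes factor (", x$config$model, ")\n", sep = "")
  cat(sprintf("  BF10 (two-sided): %.*g\n", digits, x$bf10))
  if (!is.na(x$bf_plus0)) {
    cat(sprintf("  BF+0 = %.*g, BF0+ = %.*g  [alternative: '%s' larger]\n",
                digits, x$bf_plus0, digits, x$bf_0plus,
                x$config$direction))
    cat(sprintf("  posterior P(direction) = %.*g\n", digits,
                x$posterior_prob_direction))
  }
  invisible(x)
}

#' Beta-posterior estimation of the group contrast in a 2x2 table
#'
#' Draws the two success probabilities from their independent
#' Beta(a + y_i, a + n_i - y_i) posteriors and summarizes the log odds
#' ratio or proportion difference by the posterior median and an
#' equal-tailed credible interval. The contrast is signed toward the
#' directional alternative: it is (direction group) minus (other group),
#' so positive values support the order-restricted hypothesis.
#'
#' @param table a [contingency_2x2()].
#' @param estimand `"log_odds_ratio"` or `"proportion_difference"`.
#' @param direction label of the group taken as the first term of the
#'   contrast (default: first group).
#' @param a prior concentration (default 1).
#' @param n_samples number of posterior draws (default 100,000).
#' @param seed RNG seed (NULL: use current RNG state).
#' @param level credible level (default .95).
#' @return A `posterior_summary` with `median`, `ci_low`, `ci_high`, the
#'   config echo, and the interval type (`"percentile"`).
#' @export
posterior_contrast <- function(table,
                               estimand = c("log_odds_ratio",
                                            "proportion_difference"),
                               direction = NULL, a = 1, n_samples = 1e5,
                               seed = NULL, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"), a > 0,
            level > 0, level < 1)
  estimand <- match.arg(estimand)
  i <- if (is.null(direction)) 1L else .match_direction(direction,
                                                        table$labels)
  j <- 3L - i
  y <- table$successes
  nn <- table$totals
  draws <- with_seed(seed, {
    p1 <- stats::rbeta(n_samples, a + y[i], a + nn[i] - y[i])
    p2 <- stats::rbeta(n_samples, a + y[j], a + nn[j] - y[j])
    if (estimand == "log_odds_ratio") {
      stats::qlogis(p1) - stats::qlogis(p2)
    } else {
      p1 - p2
    }
  })
  qs <- stats::quantile(draws, c(0.5, (1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  posterior_summary(estimand = estimand, median = qs[1L], ci_low = qs[2L],
                    ci_high = qs[3L], level = level, n_samples = n_samples,
                    seed = seed, interval = "percentile",
                    config = list(a = a,
                                  direction = table$labels[i],
                                  table = list(labels = table$labels,
                                               successes = y, totals = nn)))
}

#' Build a posterior summary object
#'
#' @param estimand one of `"log_odds_ratio"`, `"proportion_difference"`,
#'   `"mean_difference"`.
#' @param median,ci_low,ci_high posterior median and interval endpoints.
#' @param level credible level.
#' @param n_samples number of posterior draws behind the summary.
#' @param seed seed used to generate the draws.
#' @param interval `"percentile"` or `"hdi"`.
#' @param config list echoing the model configuration.
#' @param diagnostics optional list (e.g. split-chain rhat).
#' @return An object of class `posterior_summary`.
#' @export
posterior_summary <- function(estimand, median, ci_low, ci_high,
                              level = 0.95, n_samples = NA_integer_,
                              seed = NULL, interval = "percentile",
                              config = list(), diagnostics = list()) {
  stopifnot(ci_low <= median, median <= ci_high)
  structure(list(estimand = estimand, median = median, ci_low = ci_low,
                 ci_high = ci_high, level = level, n_samples = n_samples,
                 seed = seed, interval = interval, config = config,
                 diagnostics = diagnostics),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Posterior %s: median %.*g, %g%% CrI [%.*g, %.*g] (%s)\n",
              x$estimand, digits, x$median, 100 * x$level, digits,
              x$ci_low, digits, x$ci_high, x$interval))
  if (length(x$diagnostics) > 0L && !is.null(x$diagnostics$rhat)) {
    cat(sprintf("  split-chain Rhat = %.3f (%s)\n", x$diagnostics$rhat,
                if (isTRUE(x$diagnostics$converged)) "converged"
                else "NOT converged"))
  }
  invisible(x)
}

#' Serialize a result object to JSON
#'
#' Emits the full configuration echo (prior concentration, direction, seed,
#' sample counts) alongside the numbers, for audit.
#'
#' @param x a `bf_result`, `posterior_summary`, or `comparison_report`.
#' @param path optional file to write to.
#' @return JSON string (invisibly, when `path` is given).
#' @export
result_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}
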