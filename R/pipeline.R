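# Orchestration of the study-table analyses: the primary success
# comparison, the reproducibility-predictor comparisons, and the
# field-of-study subgroups. Every row of a report echoes its configuration
# (prior concentration, direction, seed, sample counts) and reports
# exclusion counts; nothing is dropped silently.

.GROUP_LABELS <- c("internally replicated", "internally unreplicated")

# Directional alternatives per predictor. For categorical predictors the
# alternative asserts that `level` is more frequent in `direction`; for
# continuous ones, that the mean is larger in `direction`. The posterior
# contrast is always signed toward the alternative, so positive medians
# support the order-restricted (moderator-account) hypothesis. These
# defaults encode the convention of the emulated analysis and are
# overridable via the `directions` argument of the pipeline functions.
default_predictor_directions <- function() {
  list(
    field_of_study = list(type = "categorical", column = "discipline",
                          level = "social",
                          direction = "internally replicated"),
    effect_type = list(type = "categorical", column = "effect_type",
                       level = "main",
                       direction = "internally unreplicated"),
    p_original = list(type = "continuous", column = "p_original",
                      direction = "internally replicated"),
    r_original = list(type = "continuous", column = "r_original",
                      direction = "internally unreplicated"),
    replication_power = list(type = "continuous",
                             column = "replication_power",
                             direction = "internally unreplicated"),
    surprisingness = list(type = "continuous", column = "surprisingness",
                          direction = "internally replicated"),
    challenge = list(type = "continuous", column = "challenge",
                     direction = "internally replicated"),
    power_analysis = list(type = "categorical",
                          column = "power_analysis_present",
                          level = "TRUE",
                          direction = "internally replicated"),
    n_original = list(type = "continuous", column = "n_original",
                      direction = "internally unreplicated",
                      transform = "log", exclude_outlier = TRUE)
  )
}

.split_groups <- function(table) {
  ir <- table$internal_replication_count > 0
  list(ir = as.data.frame(table)[ir, , drop = FALSE],
       not_ir = as.data.frame(table)[!ir, , drop = FALSE])
}

.success_table <- function(table, alpha = 0.05) {
  g <- .split_groups(table)
  usable <- lapply(g, function(d) d[!is.na(d$p_replication), , drop = FALSE])
  y <- vapply(usable, function(d) sum(d$p_replication < alpha), 0L)
  nn <- vapply(usable, nrow, 0L)
  list(tab = contingency_2x2(y, nn, .GROUP_LABELS),
       n_missing = nrow(table) - sum(nn))
}

.jeffreys_note <- function(bf_plus0) {
  if (is.na(bf_plus0)) return(NA_character_)
  bf <- max(bf_plus0, 1 / bf_plus0)
  side <- if (bf_plus0 >= 1) "alternative" else "null"
  sprintf("%s evidence for the %s", jeffreys_label(bf), side)
}

.contingency_row <- function(variable, tab, n_missing, a, n_samples, seed,
                             method, estimands, notes = character(0)) {
  bf <- contingency_bf(tab, a = a, direction = tab$labels[1L],
                       method = method, n_samples = n_samples, seed = seed)
  posts <- lapply(estimands, function(e) {
    posterior_contrast(tab, estimand = e, direction = tab$labels[1L],
                       a = a, n_samples = n_samples,
                       seed = child_seed(seed, match(e, estimands)))
  })
  names(posts) <- estimands
  if (length(estimands) > 1L) {
    notes <- c(notes, paste(
      "log-odds-ratio and proportion-difference estimands both reported;",
      "the emulated analysis mixes the two scales across rows"))
  }
  list(variable = variable, type = "categorical",
       groups = data.frame(group = tab$labels, successes = tab$successes,
                           totals = tab$totals,
                           proportion = tab$successes / tab$totals),
       n_missing = n_missing, n_excluded = 0L,
       bf = bf, posteriors = posts,
       label = .jeffreys_note(bf$bf_plus0), notes = notes)
}

.insufficient_row <- function(variable, type, groups, note) {
  list(variable = variable, type = type, groups = groups,
       n_missing = NA_integer_, n_excluded = 0L, bf = NULL,
       posteriors = list(), label = "insufficient data", notes = note)
}

#' Primary comparison: independent replication success by internal
#' replication status
#'
#' Builds the 2x2 success table (replication p < `alpha`) by internal
#' replication group, computes the order-restricted Gunel-Dickey style
#' Bayes factor (alternative: internally replicated effects replicate
#' more often) and the Beta-posterior contrast (log odds ratio and
#' proportion difference), and compares the two groups' effect-size
#' reductions (simple and Fisher-z/Cohen's q) with the JZS Bayes factor
#' plus robust estimation.
#'
#' @param table a [study_table()].
#' @param seed master seed; per-row seeds are derived from it, so a fixed
#'   seed makes the whole report reproducible.
#' @param n_samples posterior draws per sampled quantity (default 100,000).
#' @param a Dirichlet prior concentration (default 1).
#' @param alpha replication-success threshold (default .05).
#' @param method direction-probability method, `"sampling"` or
#'   `"integration"`.
#' @param include_es_rows include the effect-size-reduction rows (default
#'   TRUE; they require the robust sampler and are the slow part).
#' @param robust_samples retained draws for the robust sampler.
#' @return A `comparison_report`.
#' @export
run_primary_comparison <- function(table, seed = NULL, n_samples = 1e5,
                                   a = 1, alpha = 0.05,
                                   method = c("sampling", "integration"),
                                   include_es_rows = TRUE,
                                   robust_samples = 2e4) {
  method <- match.arg(method)
  st <- .success_table(table, alpha)
  rows <- list()
  if (any(st$tab$totals < 1L)) {
    rows$replication_success <- .insufficient_row(
      "replication_success", "categorical", NULL,
      "a group has no usable replication outcome")
  } else {
    rows$replication_success <- .contingency_row(
      "replication_success", st$tab, st$n_missing, a, n_samples,
      child_seed(seed, 1L), method,
      c("log_odds_ratio", "proportion_difference"))
  }

  if (include_es_rows) {
    g <- .split_groups(table)
    es <- list(
      es_reduction_simple = lapply(g, function(d) {
        es_reduction_simple(d$r_original, d$r_replication)
      }),
      es_reduction_q = lapply(g, function(d) {
        ok <- !is.na(d$r_replication) & abs(d$r_original) < 1 &
          abs(d$r_replication) < 1
        es_reduction_q(d$r_original[ok], d$r_replication[ok])
      }))
    for (k in names(es)) {
      vals <- lapply(es[[k]], function(v) v[!is.na(v)])
      rows[[k]] <- .continuous_row(
        k, vals$ir, vals$not_ir,
        direction = "internally unreplicated",  # smaller reduction favors
        seed = child_seed(seed, 10L + match(k, names(es))),
        robust_samples = robust_samples,
        notes = "reduction distributions are typically non-normal; favor the robust estimate")
    }
  }
  .comparison_report("primary comparison", rows, table, seed, n_samples,
                     a, alpha, method)
}

# JZS + robust estimation for a continuous variable; contrast signed
# toward the directional alternative.
.continuous_row <- function(variable, v_ir, v_not, direction, seed,
                            robust_samples, notes = character(0),
                            n_excluded = 0L) {
  groups <- data.frame(group = .GROUP_LABELS,
                       n = c(length(v_ir), length(v_not)),
                       mean = c(mean(v_ir), mean(v_not)),
                       sd = c(stats::sd(v_ir), stats::sd(v_not)))
  if (length(v_ir) < 2L || length(v_not) < 2L) {
    return(.insufficient_row(variable, "continuous", groups,
                             "fewer than 2 usable values in a group"))
  }
  first_ir <- direction == .GROUP_LABELS[1L]
  x <- if (first_ir) v_ir else v_not
  y <- if (first_ir) v_not else v_ir
  bf <- tryCatch(jzs_bf(x, y, direction = "x"),
                 error = function(e) NULL)
  post <- robust_difference(x, y, n_samples = robust_samples,
                            seed = child_seed(seed, 1L))
  list(variable = variable, type = "continuous", groups = groups,
       n_missing = NA_integer_, n_excluded = n_excluded,
       bf = bf, posteriors = list(mean_difference = post),
       label = if (is.null(bf)) "degenerate data"
               else .jeffreys_note(bf$bf_plus0),
       notes = c(notes, paste("contrast signed toward the alternative:",
                              direction, "larger")))
}

#' Reproducibility-predictor comparisons
#'
#' Compares the two internal-replication groups on each reproducibility
#' predictor: categorical predictors through the contingency Bayes factor
#' (with the proportion-difference posterior contrast), continuous ones
#' through the JZS Bayes factor and robust estimation. Original sample
#' size is analyzed on the natural-log scale with the unusually large
#' study flagged and excluded (see [log_sample_size()]); exclusion counts
#' are reported in the row.
#'
#' @inheritParams run_primary_comparison
#' @param directions declarative per-predictor directional alternatives;
#'   see [default_predictor_directions()].
#' @param robust_samples retained draws for the robust sampler.
#' @return A `comparison_report`.
#' @export
run_predictor_comparisons <- function(table, seed = NULL, n_samples = 1e5,
                                      a = 1,
                                      method = c("sampling", "integration"),
                                      directions =
                                        default_predictor_directions(),
                                      robust_samples = 2e4) {
  method <- match.arg(method)
  # predictor groups are formed among studies with a usable replication
  # outcome, matching the group sizes of the success analysis
  usable <- as.data.frame(table)[!is.na(table$p_replication), ,
                                 drop = FALSE]
  g <- .split_groups(usable)
  rows <- list()
  for (name in names(directions)) {
    spec <- directions[[name]]
    vals <- lapply(g, function(d) d[[spec$column]])
    if (spec$type == "categorical") {
      keep <- lapply(vals, function(v) v[!is.na(v)])
      y <- vapply(keep, function(v) sum(as.character(v) == spec$level), 0L)
      nn <- vapply(keep, length, 0L)
      if (any(nn < 1L)) {
        rows[[name]] <- .insufficient_row(name, "categorical", NULL,
                                          "empty group")
        next
      }
      first_ir <- spec$direction == .GROUP_LABELS[1L]
      labels <- if (first_ir) .GROUP_LABELS else rev(.GROUP_LABELS)
      tab <- contingency_2x2(if (first_ir) y else rev(y),
                             if (first_ir) nn else rev(nn), labels)
      rows[[name]] <- .contingency_row(
        name, tab, nrow(table) - sum(nn), a, n_samples,
        child_seed(seed, 100L + match(name, names(directions))), method,
        "proportion_difference",
        notes = sprintf("level '%s' of %s; alternative: more frequent in %s",
                        spec$level, spec$column, spec$direction))
    } else {
      n_excluded <- 0L
      if (isTRUE(spec$exclude_outlier)) {
        flags <- lapply(g, function(d) log_sample_size(d)$excluded)
        n_excluded <- sum(unlist(flags))
        vals <- Map(function(v, f) v[!f], vals, flags)
      }
      if (identical(spec$transform, "log")) vals <- lapply(vals, log)
      vals <- lapply(vals, function(v) v[!is.na(v)])
      rows[[name]] <- .continuous_row(
        name, vals$ir, vals$not_ir, spec$direction,
        child_seed(seed, 200L + match(name, names(directions))),
        robust_samples,
        notes = if (identical(spec$transform, "log"))
          "natural-log transformed" else character(0),
        n_excluded = n_excluded)
    }
  }
  .comparison_report("reproducibility predictors", rows, table, seed,
                     n_samples, a, NA_real_, method)
}

#' Field-of-study subgroup comparisons
#'
#' Repeats the primary comparison within the social-psychology and
#' cognitive-psychology subsets. Subgroups in which either
#' internal-replication group has fewer than 2 usable records are flagged
#' insufficient and no Bayes factor is emitted.
#'
#' @inheritParams run_primary_comparison
#' @return A named list of `comparison_report`s (social, cognitive).
#' @export
run_field_subgroups <- function(table, seed = NULL, n_samples = 1e5,
                                a = 1, alpha = 0.05,
                                method = c("sampling", "integration"),
                                include_es_rows = TRUE,
                                robust_samples = 2e4) {
  method <- match.arg(method)
  out <- list()
  for (field in c("social", "cognitive")) {
    sub <- as.data.frame(table)[table$discipline == field, , drop = FALSE]
    usable <- sub[!is.na(sub$p_replication), , drop = FALSE]
    sizes <- table(factor(usable$internal_replication_count > 0,
                          levels = c(TRUE, FALSE)))
    if (any(sizes < 2L)) {
      rows <- list(replication_success = .insufficient_row(
        "replication_success", "categorical", NULL,
        sprintf("subgroup '%s' has a group with fewer than 2 studies",
                field)))
      out[[field]] <- .comparison_report(
        sprintf("subgroup: %s", field), rows, sub, seed, n_samples, a,
        alpha, method)
    } else {
      sub_tab <- study_table(sub, provenance =
                               sprintf("%s subset", field))
      out[[field]] <- run_primary_comparison(
        sub_tab, seed = child_seed(seed, match(field,
                                               c("social", "cognitive"))),
        n_samples = n_samples, a = a, alpha = alpha, method = method,
        include_es_rows = include_es_rows,
        robust_samples = robust_samples)
      out[[field]]$title <- sprintf("subgroup: %s", field)
    }
  }
  out
}

.comparison_report <- function(title, rows, table, seed, n_samples, a,
                               alpha, method) {
  structure(list(title = title, rows = rows,
                 n_studies = nrow(table),
                 config = list(seed = seed, n_samples = n_samples, a = a,
                               alpha = alpha, method = method)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("Comparison report:", x$title, sprintf("(%d studies)\n",
                                             x$n_studies))
  for (row in x$rows) {
    cat(sprintf("\n%s [%s]\n", row$variable, row$type))
    if (!is.null(row$groups)) {
      print(row$groups, row.names = FALSE, digits = digits)
    }
    if (!is.null(row$bf)) {
      cat(sprintf("  BF+0 = %.*g  BF0+ = %.*g  (%s)\n", digits,
                  row$bf$bf_plus0, digits, row$bf$bf_0plus, row$label))
    }
    for (nm in names(row$posteriors)) {
      p <- row$posteriors[[nm]]
      cat(sprintf("  %s: median %.*g [%.*g, %.*g]\n", nm, digits,
                  p$median, digits, p$ci_low, digits, p$ci_high))
    }
    if (!is.na(row$n_missing %||% NA) && isTRUE(row$n_missing > 0)) {
      cat(sprintf("  missing: %d\n", row$n_missing))
    }
    if (isTRUE(row$n_excluded > 0)) {
      cat(sprintf("  excluded: %d\n", row$n_excluded))
    }
    for (note in row$notes) cat("  note:", note, "\n")
  }
  invisible(x)
}

#' Jeffreys evidence label for a Bayes factor
#'
#' Conventional interpretation bands: BF in (1, 3) is anecdotal ("not
#' worth more than a bare mention"), (3, 10) substantial, (10, 30) strong,
#' and above 30 very strong. A BF below 1 is labeled for the complementary
#' hypothesis through 1/BF; BF = 1 exactly is labeled anecdotal.
#'
#' @param bf positive Bayes factor(s).
#' @return character vector of labels.
#' @export
jeffreys_label <- function(bf) {
  stopifnot(all(bf > 0))
  b <- pmax(bf, 1 / bf)
  cut(b, c(1, 3, 10, 30, Inf),
      labels = c("anecdotal", "substantial", "strong", "very strong"),
      include.lowest = TRUE, right = FALSE) |> as.character()
}
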