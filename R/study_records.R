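# Study-level data model: one row per original effect, with its independent
# replication outcome and the reproducibility-predictor covariates.

#' Canonical study-table column names
#'
#' The schema of a study table: one row per original effect. Probabilities
#' must lie in (0, 1], effect sizes (Pearson r) in [-1, 1], and missing
#' values are permitted only for the independent-replication outcome fields
#' (`p_replication`, `r_replication`, `replication_power`), the rating
#' columns (`surprisingness`, `challenge`) and `effect_type`.
#'
#' @return Character vector of canonical column names.
#' @export
study_table_columns <- function() {
  c("study_id", "internal_replication_count", "discipline", "effect_type",
    "p_original", "r_original", "n_original", "p_replication",
    "r_replication", "replication_power", "surprisingness", "challenge",
    "power_analysis_present")
}

.optional_cols <- c("p_replication", "r_replication", "replication_power",
                    "surprisingness", "challenge", "effect_type")

#' Construct a validated study table
#'
#' @param records data.frame with the columns of [study_table_columns()].
#' @param provenance free-text note recording where the table came from.
#'
#' @return A `study_table`: a data.frame with a `provenance` attribute.
#' @export
study_table <- function(records, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(study_table_columns(), names(records))
  if (length(missing_cols) > 0L) {
    stop("study table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, study_table_columns()]
  records$power_analysis_present <- as.logical(records$power_analysis_present)
  problems <- validate_study_table(records)
  if (nrow(problems) > 0L) {
    msg <- paste(utils::head(sprintf("row %d, %s: %s", problems$row,
                                     problems$field, problems$message), 5L),
                 collapse = "; ")
    cond <- simpleError(paste0("invalid study table (", nrow(problems),
                               " problem(s)): ", msg))
    class(cond) <- c("bayesrep_validation_error", class(cond))
    cond$problems <- problems
    stop(cond)
  }
  structure(records, provenance = provenance,
            class = c("study_table", "data.frame"))
}

#' Validate study-table records
#'
#' Checks every record against the schema invariants and returns a report
#' instead of failing, so malformed input can be diagnosed row by row.
#'
#' @param records data.frame with the canonical columns.
#' @return data.frame with columns `row`, `field`, `message`; zero rows when
#'   the table is valid.
#' @export
validate_study_table <- function(records) {
  probs <- list()
  bad <- function(rows, field, message) {
    if (length(rows) > 0L) {
      probs[[length(probs) + 1L]] <<-
        data.frame(row = rows, field = field, message = message)
    }
  }
  n <- nrow(records)
  rown <- seq_len(n)

  id <- as.character(records$study_id)
  bad(rown[is.na(id)], "study_id", "missing identifier")
  dup <- duplicated(id) & !is.na(id)
  bad(rown[dup], "study_id", "duplicated identifier")

  irc <- records$internal_replication_count
  bad(rown[is.na(irc) | irc < 0 | irc != round(irc)],
      "internal_replication_count", "must be a non-negative integer")

  disc <- as.character(records$discipline)
  bad(rown[is.na(disc) | !disc %in% c("cognitive", "social")],
      "discipline", "must be 'cognitive' or 'social'")

  et <- as.character(records$effect_type)
  bad(rown[!is.na(et) & !et %in% c("main", "interaction")],
      "effect_type", "must be 'main', 'interaction', or missing")

  in_prob <- function(x) !is.na(x) & x > 0 & x <= 1
  bad(rown[!in_prob(records$p_original)], "p_original",
      "must be a probability in (0, 1]")
  pr <- records$p_replication
  bad(rown[!is.na(pr) & !(pr > 0 & pr <= 1)], "p_replication",
      "must be a probability in (0, 1] or missing")

  ro <- records$r_original
  bad(rown[is.na(ro) | abs(ro) > 1], "r_original", "must lie in [-1, 1]")
  rr <- records$r_replication
  bad(rown[!is.na(rr) & abs(rr) > 1], "r_replication",
      "must lie in [-1, 1] or missing")

  no <- records$n_original
  bad(rown[is.na(no) | no < 1 | no != round(no)], "n_original",
      "must be a positive integer")

  rp <- records$replication_power
  bad(rown[!is.na(rp) & (rp < 0 | rp > 1)], "replication_power",
      "must lie in [0, 1] or missing")

  sp <- records$surprisingness
  bad(rown[!is.na(sp) & (sp < 1 | sp > 6)], "surprisingness",
      "must lie in [1, 6] or missing")

  pa <- records$power_analysis_present
  bad(rown[is.na(pa)], "power_analysis_present", "must be TRUE or FALSE")

  if (length(probs) == 0L) {
    data.frame(row = integer(0), field = character(0),
               message = character(0))
  } else {
    out <- do.call(rbind, probs)
    out[order(out$row), , drop = FALSE]
  }
}

#' Read a study table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. Missing values are encoded as
#' empty fields. A column mapping allows external exports with different
#' header names to be adapted without editing the file.
#'
#' @param path path to the CSV file.
#' @param columns optional named character vector mapping canonical names
#'   (see [study_table_columns()]) to the column names used in the file,
#'   e.g. `c(p_replication = "T_pval_USE..R.")`.
#' @param provenance provenance note stored on the table; defaults to the
#'   file path.
#'
#' @return A validated [study_table()].
#' @export
read_study_table <- function(path, columns = NULL, provenance = path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columns)) {
    if (is.null(names(columns)) || any(names(columns) == "")) {
      stop("'columns' must be a named vector (canonical = file name)",
           call. = FALSE)
    }
    missing_src <- setdiff(unname(columns), names(raw))
    if (length(missing_src) > 0L) {
      stop("mapped column(s) not present in file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(columns)) names(raw)[names(raw) == columns[[canon]]] <- canon
  }
  missing_cols <- setdiff(study_table_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    cond <- simpleError(paste0("missing mandatory column(s): ",
                               paste(missing_cols, collapse = ", ")))
    class(cond) <- c("bayesrep_schema_error", class(cond))
    stop(cond)
  }
  study_table(raw, provenance = provenance)
}

#' Write a study table to CSV
#'
#' Missing values are written as empty fields (never sentinel numbers), so
#' a write/read round trip is the identity on the table.
#'
#' @param table a [study_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, study_table_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.study_table <- function(x, ...) {
  n_ir <- sum(x$internal_replication_count > 0)
  cat(sprintf("Study table: %d effects (%d internally replicated, %d not)\n",
              nrow(x), n_ir, nrow(x) - n_ir))
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("Provenance:", prov, "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Flag independent replication success
#'
#' An effect counts as independently replicated when the replication team's
#' p-value is strictly below `alpha`. Missingness propagates.
#'
#' @param p_replication numeric vector of replication p-values (or a
#'   `study_table`, whose `p_replication` column is used).
#' @param alpha significance threshold (default .05).
#' @return logical vector (NA where the replication outcome is missing).
#' @export
replication_success_flag <- function(p_replication, alpha = 0.05) {
  if (inherits(p_replication, "study_table")) {
    p_replication <- p_replication$p_replication
  }
  p_replication < alpha
}

#' Effect-size reduction by simple subtraction
#'
#' @param r_original,r_replication correlation-scale effect sizes in [-1, 1].
#' @return `r_original - r_replication`.
#' @export
es_reduction_simple <- function(r_original, r_replication) {
  stopifnot(all(abs(r_original) <= 1, na.rm = TRUE),
            all(abs(r_replication) <= 1, na.rm = TRUE))
  r_original - r_replication
}

#' Effect-size reduction on the Fisher-z scale (Cohen's q)
#'
#' q = z(r_original) - z(r_replication) with z(r) = atanh(r), the difference
#' of Fisher-transformed correlations.
#'
#' @inheritParams es_reduction_simple
#' @return Cohen's q.
#' @export
es_reduction_q <- function(r_original, r_replication) {
  if (any(abs(r_original) >= 1, na.rm = TRUE) ||
      any(abs(r_replication) >= 1, na.rm = TRUE)) {
    stop("Fisher z is undefined at |r| = 1", call. = FALSE)
  }
  atanh(r_original) - atanh(r_replication)
}

#' Natural-log original sample sizes with an outlier exclusion flag
#'
#' Sample sizes are analyzed on the natural-log scale because raw sizes are
#' strongly right-skewed. Records at or above `exclusion_threshold` are
#' flagged as excluded rather than dropped, so the same table serves
#' analyses with and without the exclusion. The default threshold is chosen
#' so that exactly the one unusually large study (N = 230,025) in the
#' emulated dataset is excluded.
#'
#' @param table a [study_table()] (or data.frame with `n_original`).
#' @param exclusion_threshold flag records with `n_original >=` this value.
#' @return data.frame with per-record `log_n` and logical `excluded`.
#' @export
log_sample_size <- function(table, exclusion_threshold = 230025) {
  n <- table$n_original
  stopifnot(all(n >= 1, na.rm = TRUE))
  data.frame(log_n = log(n), excluded = n >= exclusion_threshold)
}
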