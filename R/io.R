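#' Read a cause list from disk
#'
#' Accepts either a plain text file with one cause per line, or a CSV with a
#' `cause` column (detected from the header).
#'
#' @param path File path.
#' @return A [cause_list()].
#' @export
read_cause_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cause-list file not found: %s", path))
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("(^|,)\\s*\"?cause\"?\\s*(,|$)", trimws(first))) {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"cause" %in% names(df)) abort(sprintf("%s: CSV cause list needs a `cause` column.", path))
    cause_list(df$cause)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    cause_list(lines[nzchar(lines)])
  }
}

#' Read labelled deaths from a long-format CSV
#'
#' Expects a UTF-8 CSV with header `death_id,true_cause,predicted_cause`
#' (the `predicted_cause` column may be absent for unlabelled prediction
#' input). Malformed rows are reported with their line numbers; unknown
#' causes name both the label and the offending death.
#'
#' @param path File path.
#' @param causes Optional [cause_list()] to validate labels against.
#' @return A tibble with columns `death_id`, `true_cause`, and (if present)
#'   `predicted_cause`.
#' @export
read_labels <- function(path, causes = NULL) {
  if (!file.exists(path)) abort(sprintf("Labels file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("death_id", "true_cause")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  has_pred <- "predicted_cause" %in% names(df)
  if (nrow(df) == 0) abort(sprintf("%s: no deaths (empty file).", path))
  # +1 for the header: report 1-based file line numbers
  bad <- which(is.na(df$death_id) | !nzchar(trimws(df$death_id)) |
                 is.na(df$true_cause) | !nzchar(trimws(df$true_cause)) |
                 (if (has_pred) is.na(df$predicted_cause) | !nzchar(trimws(df$predicted_cause)) else FALSE))
  if (length(bad)) {
    abort(sprintf("%s: malformed row(s) at line(s) %s (empty or missing fields).",
                  path, paste(utils::head(bad + 1L, 5), collapse = ", ")))
  }
  df$death_id <- trimws(df$death_id)
  df$true_cause <- trimws(df$true_cause)
  if (has_pred) df$predicted_cause <- trimws(df$predicted_cause)
  if (anyDuplicated(df$death_id)) {
    dup <- unique(df$death_id[duplicated(df$death_id)])
    abort(sprintf("%s: duplicate death_id(s): %s", path,
                  paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (!is.null(causes)) {
    causes <- as_cause_list(causes)
    for (col in intersect(c("true_cause", "predicted_cause"), names(df))) {
      bad <- which(!df[[col]] %in% causes)
      if (length(bad)) {
        abort(sprintf("%s: unknown %s \"%s\" at line %d (death_id %s).",
                      path, col, df[[col]][bad[1]], bad[1] + 1L, df$death_id[bad[1]]))
      }
    }
  }
  df[intersect(c("death_id", "true_cause", "predicted_cause"), names(df))]
}

#' Write labelled deaths to CSV
#'
#' @param data Tibble with `death_id`, `true_cause` and optionally
#'   `predicted_cause` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a pre-tabulated confusion matrix from CSV
#'
#' The dialect is: first column `true_cause` holding the cause of each row,
#' remaining columns named by predicted causes, integer cells. The row order
#' fixes the cause-list order; the predicted-cause columns must be a
#' permutation of the rows.
#'
#' @param path File path.
#' @return A `confusion_matrix`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("Matrix file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "true_cause") {
    abort(sprintf("%s: first column must be `true_cause`.", path))
  }
  causes <- trimws(as.character(df$true_cause))
  pred_causes <- trimws(names(df)[-1])
  if (!setequal(causes, pred_causes)) {
    abort(sprintf("%s: predicted-cause columns must match the true-cause rows.", path))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(cells) || anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    abort(sprintf("%s: cells must be non-negative integers.", path))
  }
  # reorder columns to row order so indexing follows the cause list
  cells <- cells[, match(causes, pred_causes), drop = FALSE]
  rownames(cells) <- causes
  colnames(cells) <- causes
  confusion_matrix(cells, causes)
}

#' Write a confusion matrix to CSV
#'
#' @param x A `confusion_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "confusion_matrix"))
  df <- as.data.frame(x$counts)
  out <- tibble::add_column(tibble::as_tibble(df), true_cause = as.character(x$causes), .before = 1)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an evaluation report to disk
#'
#' CSV output is a long table (`metric`, `cause`, `value`) holding the
#' per-cause concordance/CCC/CSMF entries and the overall scalars, rounded at
#' presentation to three decimals in the printed form only — the file keeps
#' full precision. JSON output nests per-cause and overall sections, also at
#' full precision.
#'
#' @param x A `"va_evaluation"` or `"resampling_summary"` object.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  long <- report_long(x)
  if (format == "csv") {
    readr::write_csv(long, path, progress = FALSE)
  } else {
    jsonlite::write_json(report_list(x), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

report_long <- function(x) {
  if (inherits(x, "va_evaluation")) {
    per_cause <- tidy.va_evaluation(x)
    dplyr::bind_rows(
      tidyr::pivot_longer(
        per_cause[c("cause", "concordance", "ccc", "csmf_true", "csmf_pred")],
        -"cause", names_to = "metric", values_to = "value"
      )[c("metric", "cause", "value")],
      tibble(
        metric = c("ccc_overall", "csmf_accuracy", "cccsmf_accuracy", "chance_constant"),
        cause = NA_character_,
        value = c(x$concordance$ccc_overall, x$csmf_accuracy, x$cccsmf_accuracy, x$chance)
      )
    )
  } else if (inherits(x, "resampling_summary")) {
    tidyr::pivot_longer(x$summary, -"metric", names_to = "statistic", values_to = "value")
  } else {
    abort("`write_report()` understands va_evaluation and resampling_summary objects.")
  }
}

report_list <- function(x) {
  if (inherits(x, "va_evaluation")) {
    list(
      per_cause = tidy.va_evaluation(x),
      overall = list(
        ccc = x$concordance$ccc_overall,
        csmf_accuracy = x$csmf_accuracy,
        cccsmf_accuracy = x$cccsmf_accuracy,
        chance_constant = x$chance,
        n = as.integer(x$matrix$n),
        j = x$concordance$j,
        n_defined_causes = x$concordance$n_defined_causes
      )
    )
  } else if (inherits(x, "resampling_summary")) {
    list(summary = x$summary, config = x$config[setdiff(names(x$config), "causes")])
  } else {
    abort("`write_report()` understands va_evaluation and resampling_summary objects.")
  }
}
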