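#' Construct a validated cause list
#'
#' A cause list is the ordered, mutually exclusive, collectively exhaustive
#' set of `J` causes of death that a study assigns deaths to. Its order is
#' fixed and defines the row/column indexing of every confusion matrix and
#' CSMF vector built from it.
#'
#' Identifiers are matched case-sensitively after trimming surrounding
#' whitespace; no fuzzy matching is attempted, since silently merging two
#' causes corrupts every downstream mortality fraction.
#'
#' @param causes Character vector of at least two distinct, non-empty cause
#'   identifiers.
#' @return A character vector of class `"cause_list"`.
#' @examples
#' cause_list(c("Stroke", "Diabetes", "Other"))
#' @export
cause_list <- function(causes) {
  causes <- trimws(as.character(causes))
  if (length(causes) < 2) {
    abort("A cause list needs at least 2 causes: individual-level chance correction is undefined for J < 2.")
  }
  if (anyNA(causes) || any(!nzchar(causes))) {
    abort("Cause identifiers must be non-empty and non-missing.")
  }
  if (anyDuplicated(causes)) {
    dup <- unique(causes[duplicated(causes)])
    abort(sprintf("Duplicate cause identifiers: %s", paste(dup, collapse = ", ")))
  }
  structure(causes, class = c("cause_list", "character"))
}

as_cause_list <- function(x) {
  if (inherits(x, "cause_list")) x else cause_list(x)
}

#' @export
print.cause_list <- function(x, ...) {
  cat(sprintf("<cause_list: J = %d>\n", length(x)))
  print(unclass(x), ...)
  invisible(x)
}

default_causes <- function(j) {
  cause_list(sprintf("cause_%02d", seq_len(j)))
}

#' Build a confusion matrix from labelled deaths
#'
#' Cross-tabulates true against predicted causes for a cohort of deaths given
#' in long format (one row per death). The resulting matrix `M` has entry
#' `M[j, j']` equal to the number of deaths with true cause `j` and predicted
#' cause `j'`; rows are always indexed by the full cause list, so causes never
#' observed in the data keep their all-zero rows and columns.
#'
#' @param data A data frame with one row per death.
#' @param causes A [cause_list()] (or character vector) fixing cause order.
#'   When `NULL`, the sorted union of observed labels is used; pass the list
#'   explicitly whenever the ordering or the presence of unobserved causes
#'   matters.
#' @param true,pred,id Unquoted column names holding the true cause, the
#'   predicted cause, and the death identifier. `id` may be absent from
#'   `data`, in which case row numbers identify deaths in error messages.
#' @return An object of class `"confusion_matrix"`.
#' @examples
#' deaths <- tibble::tibble(
#'   death_id = 1:6,
#'   true_cause = c("a", "a", "b", "b", "b", "a"),
#'   predicted_cause = c("a", "b", "b", "b", "a", "a")
#' )
#' build_confusion_matrix(deaths, causes = c("a", "b"))
#' @export
build_confusion_matrix <- function(data, causes = NULL, true = true_cause,
                                   pred = predicted_cause, id = death_id) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of labelled deaths.")
  if (nrow(data) == 0) abort("`data` has no deaths; a confusion matrix needs n >= 1.")
  true_v <- trimws(as.character(rlang::eval_tidy(rlang::enquo(true), data)))
  pred_v <- trimws(as.character(rlang::eval_tidy(rlang::enquo(pred), data)))
  id_q <- rlang::enquo(id)
  ids <- tryCatch(rlang::eval_tidy(id_q, data), error = function(e) NULL)
  if (is.null(ids)) ids <- paste0("row ", seq_len(nrow(data)))
  if (anyDuplicated(ids)) {
    abort(sprintf(
      "Duplicate death identifiers: %s",
      paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", ")
    ))
  }

  if (is.null(causes)) causes <- sort(unique(c(true_v, pred_v)))
  causes <- as_cause_list(causes)
  check_labels_known(true_v, causes, ids, "true cause")
  check_labels_known(pred_v, causes, ids, "predicted cause")

  counts <- table(
    factor(true_v, levels = causes),
    factor(pred_v, levels = causes)
  )
  new_confusion_matrix(unclass(as.matrix(counts)), causes)
}

check_labels_known <- function(labels, causes, ids, what) {
  bad <- which(!labels %in% causes)
  if (length(bad)) {
    first <- bad[1]
    abort(sprintf(
      "Unknown %s label \"%s\" (death_id %s)%s; not in the cause list.",
      what, labels[first], as.character(ids[first]),
      if (length(bad) > 1) sprintf(" and %d more", length(bad) - 1) else ""
    ))
  }
  invisible(labels)
}

#' Construct a confusion matrix from pre-tabulated counts
#'
#' @param counts Square matrix of non-negative integer counts; rows are true
#'   causes, columns predicted causes. Row/column order follows `causes`.
#' @param causes Cause identifiers; defaults to the matrix row names.
#' @return An object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(counts, causes = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(causes)) abort("`causes` is required when `counts` has no row names.")
  causes <- as_cause_list(causes)
  if (nrow(counts) != ncol(counts) || nrow(counts) != length(causes)) {
    abort("`counts` must be a square J x J matrix matching the cause list.")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion-matrix cells must be non-negative integers.")
  }
  new_confusion_matrix(counts, causes)
}

new_confusion_matrix <- function(counts, causes) {
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(true_cause = causes, predicted_cause = causes)
  n <- sum(counts)
  if (n < 1) abort("Confusion matrix is empty (n = 0).")
  structure(
    list(counts = counts, causes = causes, n = n),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: J = %d causes, n = %d deaths>\n",
              length(x$causes), as.integer(x$n)))
  print(x$counts, ...)
  invisible(x)
}

#' @export
as.matrix.confusion_matrix <- function(x, ...) x$counts

#' @export
dim.confusion_matrix <- function(x) dim(x$counts)

#' Tidy a confusion matrix into long format
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `true_cause`, `predicted_cause`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame.table(x$counts, stringsAsFactors = FALSE))
  names(out) <- c("true_cause", "predicted_cause", "n")
  out$n <- as.integer(out$n)
  out[c("true_cause", "predicted_cause", "n")]
}

#' Expand a confusion matrix back into labelled deaths
#'
#' Inverse of [build_confusion_matrix()] up to the (arbitrary) death
#' identifiers: emits one row per counted death.
#'
#' @param x A `confusion_matrix`.
#' @param id_prefix Prefix for the generated death identifiers.
#' @return A tibble with columns `death_id`, `true_cause`, `predicted_cause`.
#' @export
expand_matrix <- function(x, id_prefix = "d") {
  stopifnot(inherits(x, "confusion_matrix"))
  long <- tidy.confusion_matrix(x)
  long <- long[long$n > 0, , drop = FALSE]
  out <- tibble(
    true_cause = rep(long$true_cause, long$n),
    predicted_cause = rep(long$predicted_cause, long$n)
  )
  tibble(
    death_id = sprintf("%s%d", id_prefix, seq_len(nrow(out))),
    true_cause = out$true_cause,
    predicted_cause = out$predicted_cause
  )
}

#' Cause-specific mortality fractions from a confusion matrix
#'
#' `true_csmf()` returns the normalised row sums (the observed cause
#' composition of the cohort); `pred_csmf()` the normalised column sums (the
#' composition implied by the predictions). Both sum to one.
#'
#' @param x A `confusion_matrix`.
#' @return A tibble with columns `cause` and `fraction`, in cause-list order.
#' @examples
#' m <- va_example_matrix("pcva")
#' true_csmf(m)
#' pred_csmf(m)
#' @export
true_csmf <- function(x) {
  stopifnot(inherits(x, "confusion_matrix"))
  tibble(cause = as.character(x$causes), fraction = unname(rowSums(x$counts)) / x$n)
}

#' @rdname true_csmf
#' @export
pred_csmf <- function(x) {
  stopifnot(inherits(x, "confusion_matrix"))
  tibble(cause = as.character(x$causes), fraction = unname(colSums(x$counts)) / x$n)
}

# Coerce a CSMF given as a csmf tibble, named vector, or bare numeric vector
# into a numeric vector ordered by `causes` (when alignment is possible).
csmf_vector <- function(x, causes = NULL, arg = "csmf") {
  if (is.data.frame(x)) {
    if (!all(c("cause", "fraction") %in% names(x))) {
      abort(sprintf("`%s` data frame needs `cause` and `fraction` columns.", arg))
    }
    v <- stats::setNames(as.numeric(x$fraction), x$cause)
  } else if (is.numeric(x)) {
    v <- x
  } else {
    abort(sprintf("`%s` must be a numeric vector or a cause/fraction data frame.", arg))
  }
  if (!is.null(causes)) {
    causes <- as_cause_list(causes)
    if (!is.null(names(v))) {
      missing <- setdiff(causes, names(v))
      extra <- setdiff(names(v), causes)
      if (length(missing) || length(extra)) {
        abort(sprintf("`%s` causes do not match the cause list (missing: %s; extra: %s).",
                      arg,
                      paste(missing, collapse = ", ") %|empty|% "none",
                      paste(extra, collapse = ", ") %|empty|% "none"))
      }
      v <- v[as.character(causes)]
    } else if (length(v) != length(causes)) {
      abort(sprintf("`%s` has length %d but the cause list has J = %d.",
                    arg, length(v), length(causes)))
    }
  }
  if (anyNA(v) || any(v < 0)) abort(sprintf("`%s` fractions must be non-negative.", arg))
  if (abs(sum(v) - 1) > 1e-9) {
    abort(sprintf("`%s` fractions must sum to 1 (got %.12f).", arg, sum(v)))
  }
  out <- as.numeric(v)
  names(out) <- names(v)
  out
}

`%|empty|%` <- function(x, y) if (nzchar(x)) x else y
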