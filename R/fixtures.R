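#' Worked-example confusion matrices from a published PCVA validation study
#'
#' Three confusion matrices over the three-cause list (Stroke, Diabetes,
#' Other) from the PHMRC adult gold-standard validation exercise, embedded
#' exactly as published so the package's worked examples are reproducible
#' without any external data:
#'
#' * `"pcva"` — physician-certified verbal autopsy against the gold standard
#'   (n = 2,675; the row/column totals of the published table fall slightly
#'   short of the 2,702 interviews the database is described as holding, and
#'   the counts are kept exactly as printed).
#' * `"random_allocation"` — the Random Allocation baseline on the same
#'   deaths (n = 2,702).
#' * `"random_from_train"` — the Random-From-Train baseline on the same
#'   deaths, whose predicted marginals track the truth closely even though
#'   its individual-level assignments are chance-level.
#'
#' @param method Which matrix to return.
#' @return A `confusion_matrix`.
#' @examples
#' evaluate_matrix(va_example_matrix("pcva"))
#' @export
va_example_matrix <- function(method = c("pcva", "random_allocation", "random_from_train")) {
  method <- match.arg(method)
  causes <- c("Stroke", "Diabetes", "Other")
  counts <- switch(method,
    pcva = rbind(
      c(123, 18, 125),
      c(58, 6, 55),
      c(83, 95, 2112)
    ),
    random_allocation = rbind(
      c(87, 84, 95),
      c(32, 61, 53),
      c(746, 780, 764)
    ),
    random_from_train = rbind(
      c(281, 42, 24),
      c(111, 31, 22),
      c(223, 106, 1961)
    )
  )
  rownames(counts) <- causes
  confusion_matrix(counts, causes)
}

#' Write the embedded example matrices to disk
#'
#' Convenience used by the command-line `fixtures` subcommand: writes each
#' matrix of [va_example_matrix()] as a confusion-matrix CSV plus the
#' three-cause list, into `dir`.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_example_files <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in c("pcva", "random_allocation", "random_from_train")) {
    p <- file.path(dir, paste0(m, "_matrix.csv"))
    write_matrix(va_example_matrix(m), p)
    paths <- c(paths, p)
  }
  cl <- file.path(dir, "causes.txt")
  writeLines(c("Stroke", "Diabetes", "Other"), cl)
  invisible(c(paths, cl))
}
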