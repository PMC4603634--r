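#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Run `code` under a fixed RNG state when `seed` is given, untouched otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    if (!rlang::is_scalar_integerish(seed)) {
      abort("`seed` must be a single integer (or NULL).")
    }
    withr::with_seed(as.integer(seed), code)
  }
}

is_count <- function(x, min = 1L) {
  rlang::is_scalar_integerish(x) && !is.na(x) && x >= min
}

stop_not_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
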