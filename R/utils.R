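#' Half-up rounding
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in clinical reporting tables. Base [round()] uses
#' round-half-to-even, which would turn 92.555 into 92.56 or 92.55 depending
#' on binary representation; report percentages must be stable.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(92.555, 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

as_date_scalar <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  assert_that(length(d) == 1L && !is.na(d), paste0("invalid ", what))
  d
}

# Cheap one-row tibble for hot paths: skips tibble()'s quosure machinery.
fast_row <- function(...) tibble::new_tibble(list(...), nrow = 1L)

# Derive a per-patient RNG substream seed from the cohort seed so patient
# streams are reproducible independently of simulation order. Kept < 2^31.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
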