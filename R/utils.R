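#' Integer percentage, rounded half away from zero
#'
#' Display-rounding used throughout screen and conservation summaries:
#' `100 * n / d` rounded to the nearest integer, with ties (x.5) going away
#' from zero rather than to even as [base::round()] would.
#'
#' @param n Numerator (count).
#' @param d Denominator (count, > 0).
#' @return Integer percentage.
#' @examples
#' percent_round(289, 1915) # 15
#' percent_round(701, 890)  # 79
#' @export
percent_round <- function(n, d) {
  stopifnot(all(d > 0))
  x <- 100 * n / d
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# clamp numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# checked tibble column access: abort with a helpful message if columns absent
check_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# deterministic child seed derived from a master seed (kept < 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 1L
}
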