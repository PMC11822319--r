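#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"), which does
#' not reproduce conventionally printed percentages such as 83.125 -> 83.13.
#' Reports in this package therefore round halves up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(83.125, 2) # 83.13
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Format a fraction as a printed percentage
#'
#' @param x Fraction in \[0, 1\].
#' @param digits Decimal digits in the percentage (default 2, as in report
#'   values like 7.44).
#' @return Numeric percentage rounded half-up.
#' @examples
#' percent(5876 / 78980) # 7.44
#' @export
percent <- function(x, digits = 2) {
  round_half_up(100 * x, digits)
}

# Read a one-name-per-line list file; "#" starts a comment, blanks ignored.
read_list_file <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
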