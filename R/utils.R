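#' Decimal half-up rounding
#'
#' Rounds half-way cases away from zero, the convention used when reporting
#' proportions and percentages in validation tables (e.g. 0.955 -> 0.96),
#' unlike [base::round()]'s round-half-even. A small epsilon guards against
#' binary floating-point representations of exact decimal halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @seealso [round_ratio()] for exact rounding of ratios of integer counts.
#' @export
#' @examples
#' round_half_up(0.955, 2)  # 0.96, not 0.95
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Exact half-up rounding of a ratio of counts
#'
#' Computes `num/den` rounded half-up to `digits` decimals using integer
#' arithmetic only, so ratios such as 764/800 round exactly as they would in
#' decimal arithmetic (0.955 -> 0.96) with no floating-point half-way
#' artefacts.
#'
#' @param num,den non-negative integer counts, `den > 0`. Vectorised.
#' @param digits number of decimal places.
#' @return numeric vector of rounded ratios; `NA` where `den` is 0.
#' @export
#' @examples
#' round_ratio(764, 800, 2)  # 0.96
#' round_ratio(115, 395, 2)  # 0.29
round_ratio <- function(num, den, digits = 2) {
  p <- 10^digits
  out <- rep(NA_real_, length(num))
  ok <- !is.na(den) & den > 0 & !is.na(num)
  # floor((2*num*p + den) / (2*den)) is the half-up rounding of num*p/den
  out[ok] <- floor((2 * num[ok] * p + den[ok]) / (2 * den[ok])) / p
  out
}

#' @noRd
as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Far-future sentinel for open-ended registration spells.
#' @noRd
.far_date <- as.Date("9999-12-31")

#' @noRd
stop_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}
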