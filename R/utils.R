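#' Round a percentage to the nearest integer, ties away from zero
#'
#' Integer percentages in screen summaries are rounded to the nearest whole
#' percent, with halves rounded away from zero (so 12.5% prints as 13%).
#'
#' @param count numerator count.
#' @param total denominator count, must be positive.
#' @return integer percentage.
#' @examples
#' percent_round(108, 407) # 27
#' percent_round(256, 407) # 63
#' @export
percent_round <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  x <- 100 * count / total
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Truncate a percentage to one decimal place
#'
#' Cross-species specificity/sensitivity percentages are reported at one
#' decimal with truncation (27/70 = 38.57...% prints as 38.5).
#'
#' @inheritParams percent_round
#' @return percentage truncated to one decimal.
#' @examples
#' percent_trunc1(27, 70) # 38.5
#' @export
percent_trunc1 <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  x <- 100 * count / total
  # small guard so values that are exact in decimal are not truncated down
  # by binary floating point (e.g. 100 * 23 / 201)
  trunc(x * 10 + 1e-9) / 10
}

# internal: stop with a consistent message when a scalar check fails
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
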