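#' Round half away from zero
#'
#' Decimal rounding in which a tie digit of 5 is always carried away from
#' zero, matching how cluster annotation scores are conventionally printed
#' (base [round()] uses round-half-to-even instead).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(2.675, 2)  # 2.68, where round() gives 2.67
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish configuration errors
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("coexnet_config_error", "error")))
}

format_error <- function(msg) {
  stop(errorCondition(msg, class = c("coexnet_format_error", "error")))
}
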