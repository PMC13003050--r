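#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported risk-share percentages use
#' conventional half-away-from-zero rounding (8/11 -> 72.7, 7/9 -> 77.8).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared abort helper: consistent error classes for programmatic handling
abort_domain <- function(msg, class = "no2risk_domain_error") {
  rlang::abort(msg, class = c(class, "no2risk_error"))
}
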