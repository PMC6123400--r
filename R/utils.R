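# Shared helpers: typed error conditions, logging, rounding.

sd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "spermdyn_error")))
}

#' Log a timestamped message to standard error
#'
#' @param msg Message text.
#' @param level One of "info", "warn", "error".
#' @export
sd_log <- function(msg, level = c("info", "warn", "error")) {
  level <- match.arg(level)
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), msg))
  invisible(NULL)
}

#' Round half away from zero
#'
#' Plain half-up rounding (0.05 at one decimal rounds to 0.1), as opposed to
#' base R's round-half-even. This is the rule used for all reported
#' percentages.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # nudge by an epsilon scaled to x so binary representations of exact halves
  # (e.g. 63.765 stored fractionally below) still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

is_wholenumber <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) < tol)
}
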