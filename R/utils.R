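#' Round half away from zero
#'
#' Base `round()` uses banker's rounding (half to even); genotype-class
#' percentages in reports follow the half-up convention instead, so that
#' e.g. 37.5% prints as 38%.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a p-value threshold for display
#'
#' Two significant figures, as significance thresholds are conventionally
#' printed (0.05/28 displays as 0.0018). Comparisons always use the
#' full-precision value; this is display only.
#'
#' @param x numeric scalar.
#' @return character scalar.
#' @export
format_threshold <- function(x) {
  format(signif(x, 2), scientific = FALSE, trim = TRUE)
}

# internal: p-values in scientific notation with 2 significant digits
format_pval <- function(p) {
  ifelse(p == 0, "0", formatC(p, format = "e", digits = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_param <- function(msg) stop(msg, call. = FALSE)
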