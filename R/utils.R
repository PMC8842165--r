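#' Integer percentage with round-half-to-even
#'
#' Screen-level overlap and confirmation figures are reported as integer
#' percentages. Rounding uses round-half-to-even (base R's `round`), so
#' e.g. `report_percent(209, 224)` gives 93.
#'
#' @param numerator,denominator Non-negative counts.
#' @param digits Decimal digits to keep (default 0, integer percent).
#' @return Numeric percentage; 0 (with attribute `undefined = TRUE`) when
#'   the denominator is 0.
#' @examples
#' report_percent(209, 224) # 93
#' report_percent(18, 86)   # 21
#' @export
report_percent <- function(numerator, denominator, digits = 0) {
  stopifnot(length(numerator) == 1, length(denominator) == 1,
            numerator >= 0, denominator >= 0)
  if (denominator == 0) {
    return(structure(0, undefined = TRUE))
  }
  round(100 * numerator / denominator, digits = digits)
}

# geometric mean via logs; x > 0
geo_mean <- function(x) exp(mean(log(x)))

#' @keywords internal
is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

stop_if_not_count <- function(x, name) {
  if (!is_count(x)) stop(sprintf("`%s` must be a single non-negative integer", name),
                         call. = FALSE)
  invisible(x)
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 levels
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
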