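#' Period classes for oscillating genes
#'
#' Rhythmic transcripts are binned by oscillation period into the circadian
#' class and the two ultradian harmonics: `P24` for periods of 24 +/- 4 h,
#' `P12` for 12 +/- 2 h and `P8` for 8 +/- 1 h. Periods outside all three
#' windows are labelled `NONE`. All windows are closed at both ends, so a
#' boundary period such as 9 h is classified (as `P8`) rather than dropped.
#'
#' @param period_hours numeric vector of oscillation periods in hours; all
#'   values must be strictly positive.
#' @return character vector of the same length with values in
#'   `c("P8", "P12", "P24", "NONE")`.
#' @examples
#' classify_period(c(24, 9, 15.5))
#' @export
classify_period <- function(period_hours) {
  if (!is.numeric(period_hours) || anyNA(period_hours)) {
    stop("'period_hours' must be numeric with no missing values")
  }
  if (any(period_hours <= 0)) {
    stop("'period_hours' must be strictly positive")
  }
  out <- rep("NONE", length(period_hours))
  out[period_hours >= 20 & period_hours <= 28] <- "P24"
  out[period_hours >= 10 & period_hours <= 14] <- "P12"
  out[period_hours >= 7 & period_hours <= 9] <- "P8"
  out
}

#' @rdname classify_period
#' @format NULL
#' @export
PERIOD_CLASSES <- c("P8", "P12", "P24", "NONE")
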