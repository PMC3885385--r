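#' Fit the group-specific index-altitude slope on first-survey values
#'
#' Ordinary least-squares regression of first-survey CTI (or CTV) on square
#' altitude. Its slope `b` (index units per metre) is the standardization
#' constant that converts temporal index changes into metres of equivalent
#' altitudinal displacement.
#'
#' @param first_survey_values Per-square index values from survey 1.
#' @param altitudes Square mean altitudes (m), same length.
#' @return A list of class `slope_b`: `b` (slope), `intercept`, `n`.
#' @export
fit_altitude_slope <- function(first_survey_values, altitudes) {
  ok <- stats::complete.cases(first_survey_values, altitudes)
  y <- first_survey_values[ok]
  a <- altitudes[ok]
  if (length(y) < 3L) stop("need >= 3 squares with defined index", call. = FALSE)
  if (stats::sd(a) == 0) stop("altitudes are all equal; slope undefined", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, a), y)
  structure(list(b = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 n = length(y)),
            class = "slope_b")
}

#' Convert a temporal index change into metres of altitudinal displacement
#'
#' Dividing a raw index change by the index-altitude slope `b` gives the
#' displacement `q = raw_delta / b` (m) one would have to move along the
#' gradient to find the survey-2 index value: `q` is negative (downhill)
#' when a community gained warm-dwelling species under a negative `b`. The
#' returned `shift_m = -q` uses the positive-uphill convention, so a
#' community change towards warm-dwelling species is a positive uphill shift
#' (for CTV, positive means increased thermal variability).
#'
#' For example, a CTI change of +0.05 in a group with `b = -0.001` per metre
#' gives `q = -50` m (the same CTI is found 50 m downhill) and
#' `shift_m = +50`, an uphill community shift of 50 m.
#'
#' @param raw_delta Survey-2 minus survey-1 index value (index units).
#' @param b Slope in index units per metre: a number or a `slope_b` fit.
#' @return A list with `quotient` (`raw_delta / b`, negative = downhill) and
#'   `shift_m` (`-raw_delta / b`, positive = uphill).
#' @export
standardize_change <- function(raw_delta, b) {
  if (inherits(b, "slope_b")) b <- b$b
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b)) {
    stop("`b` must be a single finite number", call. = FALSE)
  }
  if (b == 0) stop("slope b is zero; standardized shift undefined", call. = FALSE)
  q <- raw_delta / b
  list(quotient = q, shift_m = -q)
}

#' Per-square standardized community shifts for one index
#'
#' Computes, for each square with the index defined in both surveys, the raw
#' temporal change (survey 2 minus survey 1), fits the first-survey
#' index-altitude slope `b`, and standardizes the change into metres with
#' the positive-uphill convention. Squares lacking the index in either
#' survey are dropped (richness 0 for CTI, richness < 2 for CTV). The
#' variance-model covariate `richness` is the square's mean richness across
#' the two surveys.
#'
#' @param indices A `community_indices` table from [index_table()].
#' @param index `"cti"` or `"ctv"`.
#' @param slope Optional externally supplied `slope_b` (e.g. a sensitivity
#'   analysis); fitted from the data when `NULL`.
#' @return A `data.frame` of class `standardized_changes` with one row per
#'   retained square: `square_id`, `altitude_m`, `altitudinal_range_m`,
#'   `richness`, `index_survey1` (first-survey index value, kept so the
#'   slope can be re-estimated under resampling), `raw_delta`, `quotient_m`,
#'   `shift_m`; the `slope_b` fit is attached as attribute `"slope"`.
#' @export
standardized_changes <- function(indices, index = c("cti", "ctv"),
                                 slope = NULL) {
  index <- match.arg(index)
  stopifnot(inherits(indices, "community_indices"))
  s1 <- indices[indices$survey == 1L, , drop = FALSE]
  s2 <- indices[indices$survey == 2L, , drop = FALSE]
  s2 <- s2[match(s1$square_id, s2$square_id), , drop = FALSE]

  v1 <- s1[[index]]
  v2 <- s2[[index]]
  if (is.null(slope)) slope <- fit_altitude_slope(v1, s1$altitude_m)
  if (slope$b >= 0) {
    stop("fitted index-altitude slope b is ", signif(slope$b, 3),
         " (>= 0); the index does not decline with altitude and ",
         "standardized shifts would be uninterpretable", call. = FALSE)
  }
  keep <- !is.na(v1) & !is.na(v2)
  raw_delta <- v2[keep] - v1[keep]
  std <- standardize_change(raw_delta, slope)
  out <- data.frame(
    square_id = s1$square_id[keep],
    altitude_m = s1$altitude_m[keep],
    altitudinal_range_m = s1$altitudinal_range_m[keep],
    richness = (s1$richness[keep] + s2$richness[keep]) / 2,
    index_survey1 = v1[keep],
    raw_delta = raw_delta,
    quotient_m = std$quotient,
    shift_m = std$shift_m,
    stringsAsFactors = FALSE
  )
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(n_drop, " square(s) dropped: ", index,
            " undefined in at least one survey")
  }
  attr(out, "slope") <- slope
  attr(out, "index") <- index
  class(out) <- c("standardized_changes", "data.frame")
  out
}

#' Ratio of community change rates between two groups
#'
#' Because standardized shifts are metres-denominated for every taxon group,
#' shift rates are directly comparable: the ratio of two groups' predicted
#' shifts at a common altitude says how many times faster one community is
#' changing than the other.
#'
#' @param shift_a,shift_b Predicted shifts (m) of groups a and b at the same
#'   altitude.
#' @return `shift_a / shift_b`.
#' @export
shift_rate_ratio <- function(shift_a, shift_b) {
  if (shift_b == 0) stop("reference shift is zero; ratio undefined", call. = FALSE)
  shift_a / shift_b
}
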