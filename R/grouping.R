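#' Fraction of total interval length beyond a bound
#'
#' Treats a set of intervals as a length measure (overlaps count with
#' multiplicity, as in a stack of horizontal bars) and returns the fraction of
#' the summed length lying below or above `bound`. Degenerate intervals
#' contribute zero length.
#'
#' @param low,high Numeric vectors of interval endpoints, `low <= high`.
#' @param bound The cut point, kcal/g.
#' @param side `"below"` or `"above"`.
#' @return Proportion in \[0, 1\].
#' @examples
#' excluded_fraction(0, 1, bound = 0.25, side = "below")
#' @export
excluded_fraction <- function(low, high, bound, side = c("below", "above")) {
  side <- match.arg(side)
  if (length(low) == 0) stop("no intervals", call. = FALSE)
  if (any(low > high)) stop("intervals must satisfy low <= high", call. = FALSE)
  total <- sum(high - low)
  if (total <= 0) return(0)
  cut <- if (side == "below") {
    sum(pmax(0, pmin(bound, high) - low))
  } else {
    sum(pmax(0, high - pmax(bound, low)))
  }
  cut / total
}

#' Tail quantiles of the interval length measure
#'
#' The cumulative length function \eqn{L(x) = \sum_i \max(0, \min(x, h_i) - l_i)}
#' is piecewise linear and non-decreasing; its inverse at `tail` and
#' `1 - tail` of the total length gives the pair of values that cut off
#' exactly that fraction of summed interval length at each extreme.
#'
#' @inheritParams excluded_fraction
#' @param tail Fraction of total length to exclude per side (default 0.025).
#' @return Named vector `c(q_low, q_high)`.
#' @examples
#' length_measure_quantiles(c(0, 2), c(1, 3))   # two disjoint unit intervals
#' @export
length_measure_quantiles <- function(low, high, tail = 0.025) {
  if (length(low) == 0) stop("no intervals", call. = FALSE)
  if (any(low > high)) stop("intervals must satisfy low <= high", call. = FALSE)
  if (tail <= 0 || tail >= 0.5) stop("`tail` must lie in (0, 0.5)", call. = FALSE)
  total <- sum(high - low)
  if (total <= 0) stop("zero total interval length", call. = FALSE)
  c(q_low = length_measure_inverse(low, high, tail * total),
    q_high = length_measure_inverse(low, high, (1 - tail) * total))
}

# Invert L(x) = target exactly on the piecewise-linear grid of endpoints.
length_measure_inverse <- function(low, high, target) {
  knots <- sort(unique(c(low, high)))
  lvals <- vapply(knots, function(x) sum(pmax(0, pmin(x, high) - low)), numeric(1))
  if (target <= lvals[1]) return(knots[1])
  j <- max(which(lvals <= target))
  if (j == length(knots)) return(knots[j])
  slope <- (lvals[j + 1] - lvals[j]) / (knots[j + 1] - knots[j])
  knots[j] + (target - lvals[j]) / slope
}

#' Generalized heat-of-combustion expression for a food group
#'
#' Summarises a group's global intervals as "center +/- p%": the center is the
#' midpoint of the 2.5%/97.5% quantiles of the interval length measure
#' (rounded to 2 decimals for reporting), and p is the quantile half-width as
#' a percentage of the center, rounded to the nearest integer. The fractions
#' of total interval length excluded below `center (1 - p/100)` and above
#' `center (1 + p/100)` are recorded; integer rounding of p can leave them
#' slightly above the nominal tail.
#'
#' @inheritParams length_measure_quantiles
#' @param group Optional group label carried into the result.
#' @param atwater Benchmark heat of combustion for the overestimation range,
#'   kcal/g (the classical 4.2 for vegetable-source carbohydrate).
#' @return One-row data frame: `group`, `center`, `pct_half_width`,
#'   `pct_half_width_raw`, `q_low`, `q_high`, `tail_low_fraction`,
#'   `tail_high_fraction`, `overestimation_min`, `overestimation_max`,
#'   `n_foods`.
#' @examples
#' generalized_expression(c(3.8, 3.85), c(4.0, 4.1))
#' @export
generalized_expression <- function(low, high, tail = 0.025, group = NA_character_,
                                   atwater = 4.2) {
  q <- length_measure_quantiles(low, high, tail)
  center <- round(unname(q["q_low"] + q["q_high"]) / 2, 2)
  pct_raw <- 100 * unname(q["q_high"] - q["q_low"]) / (2 * center)
  pct <- max(1L, as.integer(round(pct_raw)))
  p <- pct / 100
  tail_lo <- excluded_fraction(low, high, center * (1 - p), "below")
  tail_hi <- excluded_fraction(low, high, center * (1 + p), "above")
  over <- atwater_overestimation(center, pct, atwater)
  data.frame(group = group, center = center,
             pct_half_width = pct, pct_half_width_raw = pct_raw,
             q_low = unname(q["q_low"]), q_high = unname(q["q_high"]),
             tail_low_fraction = tail_lo, tail_high_fraction = tail_hi,
             overestimation_min = over[["min"]], overestimation_max = over[["max"]],
             n_foods = length(low), stringsAsFactors = FALSE)
}

#' Overestimation implied by the classical 4.2 kcal/g benchmark
#'
#' Given a generalized expression `center +/- pct%`, the relative
#' overestimation incurred by using the benchmark value instead of any heat in
#' the expression's interval ranges from
#' \eqn{100 (A - c(1+p))/A} to \eqn{100 (A - c(1-p))/A} percent, rounded to
#' the nearest integer.
#'
#' @param center Group center, kcal/g.
#' @param pct Integer percent half-width.
#' @param atwater Benchmark value, kcal/g.
#' @return Named vector `c(min, max)` in percent.
#' @examples
#' atwater_overestimation(3.88, 4)
#' @export
atwater_overestimation <- function(center, pct, atwater = 4.2) {
  if (center <= 0) stop("`center` must be positive", call. = FALSE)
  p <- pct / 100
  c(min = round(100 * (atwater - center * (1 + p)) / atwater),
    max = round(100 * (atwater - center * (1 - p)) / atwater))
}

#' Foods whose global interval escapes the generic HCcinf band
#'
#' Checks containment of each food's global interval in
#' `[hcc_inf (1 - pct/100), hcc_inf (1 + pct/100)]` (boundary inclusive) and
#' returns the offenders with the distance by which they escape. Containment
#' counts recomputed from tables rounded to 2 decimals are sensitive to
#' boundary cases, so this is a diagnostic, not a reproduction target.
#'
#' @param results Food-level results with columns `hcc_inf`, `low`, `high`.
#' @param pct Band half-width, percent.
#' @return Subset of `results` (non-contained foods) with an `excess` column,
#'   kcal/g.
#' @export
generic_containment <- function(results, pct = 4) {
  stopifnot(is.data.frame(results),
            all(c("hcc_inf", "low", "high") %in% names(results)))
  band_lo <- results$hcc_inf * (1 - pct / 100)
  band_hi <- results$hcc_inf * (1 + pct / 100)
  excess <- pmax(0, band_lo - results$low, results$high - band_hi)
  out <- results[excess > 0, , drop = FALSE]
  out$excess <- excess[excess > 0]
  out
}
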