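#' Two-sided normal tolerance factor
#'
#' Factor \eqn{k} such that \eqn{\bar x \pm k s} covers at least a fraction
#' `coverage` of a normal population with confidence `confidence`. The default
#' method is Howe's approximation
#' \deqn{k = z_{(1+P)/2} \sqrt{\frac{\nu (1 + 1/n)}{\chi^2_{1-\gamma,\,\nu}}}, \quad \nu = n - 1,}
#' accurate to a few parts per thousand for the sample sizes of composition
#' databases. `method = "exact"` computes the factor by numerically inverting
#' the coverage-probability integral (conditioning on the sample mean), and is
#' used in this package as an internal cross-check of the approximation.
#'
#' @param n Number of observations (>= 2). Vectorised for `method = "howe"`.
#' @param coverage Fraction of the population to be covered, in (0, 1).
#' @param confidence Confidence level, in (0, 1).
#' @param method `"howe"` (default) or `"exact"`.
#' @return The tolerance factor k. As n grows it approaches the central
#'   normal quantile, e.g. 1.6449 for 90% coverage.
#' @examples
#' tolerance_factor(10)                  # 90% coverage / 90% confidence
#' tolerance_factor(10, method = "exact")
#' @export
tolerance_factor <- function(n, coverage = 0.90, confidence = 0.90,
                             method = c("howe", "exact")) {
  method <- match.arg(method)
  if (any(n < 2)) stop("tolerance factor requires n >= 2", call. = FALSE)
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1)
    stop("`coverage` and `confidence` must lie in (0, 1)", call. = FALSE)
  if (method == "howe") {
    nu <- n - 1
    z <- stats::qnorm((1 + coverage) / 2)
    z * sqrt(nu * (1 + 1 / n) / stats::qchisq(1 - confidence, nu))
  } else {
    vapply(n, tolerance_factor_exact, numeric(1),
           coverage = coverage, confidence = confidence)
  }
}

# Exact two-sided factor: for a standard normal sample, the content of
# xbar +/- k s exceeds `coverage` iff s >= r(xbar)/k, where r(x) solves
# pnorm(x + r) - pnorm(x - r) = coverage. Confidence is the expectation of
# P(chi2_{n-1} >= (n-1) r(X)^2 / k^2) over X ~ N(0, 1/n); invert in k.
tolerance_factor_exact <- function(n, coverage, confidence) {
  nu <- n - 1
  r_of <- function(x) {
    vapply(x, function(xi) {
      stats::uniroot(function(r) stats::pnorm(xi + r) - stats::pnorm(xi - r) - coverage,
                     lower = 1e-10, upper = 20, tol = 1e-12)$root
    }, numeric(1))
  }
  conf_of <- function(k) {
    integrand <- function(z) {
      r <- r_of(z / sqrt(n))
      stats::pchisq(nu * r^2 / k^2, nu, lower.tail = FALSE) * stats::dnorm(z)
    }
    2 * stats::integrate(integrand, 0, 8, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(k) conf_of(k) - confidence,
                 lower = 0.5, upper = 60, tol = 1e-9)$root
}

#' Tolerance interval for one composition record
#'
#' Builds the per-carbohydrate composition interval
#' \eqn{\bar C_i \mp h\, se_i \sqrt n} (the tolerance factor h applied to the
#' sample standard deviation recovered from the standard error), clamped to
#' the physical range \[0, 100\] percent. When `se` or `n` is missing, or
#' `se = 0`, the interval degenerates to the mean — the rule used for foods
#' whose database entry carries a single composition value.
#'
#' @param mean_pct Mean composition, percent of carbohydrate mass.
#' @param se Standard error of the mean, percent (`NA` when unavailable).
#' @param n Number of observations behind the mean (`NA` when unavailable).
#' @param coverage,confidence Tolerance-interval parameters, see
#'   [tolerance_factor()].
#' @return Named numeric vector `c(low, high)` in percent.
#' @examples
#' composition_interval(50, se = 2, n = 4)
#' composition_interval(12)            # degenerate: no dispersion information
#' @export
composition_interval <- function(mean_pct, se = NA_real_, n = NA_real_,
                                 coverage = 0.90, confidence = 0.90) {
  if (is.na(mean_pct) || mean_pct < 0 || mean_pct > 100)
    stop("`mean_pct` must lie in [0, 100]", call. = FALSE)
  if (!is.na(se) && se < 0) stop("`se` must be non-negative", call. = FALSE)
  if (is.na(se) || is.na(n) || se == 0)
    return(c(low = mean_pct, high = mean_pct))
  if (n < 2) stop("composition interval with se > 0 requires n >= 2", call. = FALSE)
  h <- tolerance_factor(n, coverage, confidence)
  half <- h * se * sqrt(n)
  c(low = max(0, mean_pct - half), high = min(100, mean_pct + half))
}

#' Composition intervals for a table of records
#'
#' Applies [composition_interval()] row-wise to a composition table.
#'
#' @param records Data frame with columns `mean_pct`, `se`, `n` (plus any
#'   identifying columns, which are preserved).
#' @inheritParams composition_interval
#' @return `records` with `low` and `high` columns appended.
#' @export
composition_intervals <- function(records, coverage = 0.90, confidence = 0.90) {
  stopifnot(is.data.frame(records), "mean_pct" %in% names(records))
  se <- if ("se" %in% names(records)) records$se else rep(NA_real_, nrow(records))
  n  <- if ("n"  %in% names(records)) records$n  else rep(NA_real_, nrow(records))
  iv <- t(mapply(composition_interval, records$mean_pct, se, n,
                 MoreArgs = list(coverage = coverage, confidence = confidence)))
  records$low <- iv[, 1]
  records$high <- iv[, 2]
  records
}

#' Rescale a food's composition to the carbohydrate-mass basis
#'
#' Composition databases report carbohydrate contents per 100 g of food; the
#' energy propagation needs them per 100 g of carbohydrate. Means are rescaled
#' by `100 / sum(means)` so they sum to 100, and standard errors are scaled by
#' the same factor.
#'
#' @param records Data frame of one food's composition rows, with columns
#'   `mean_pct` and optionally `se`.
#' @return The rescaled data frame; means sum to 100.
#' @examples
#' normalize_to_carb_basis(data.frame(carb_id = c("glucose", "starch"),
#'                                    mean_pct = c(40, 40)))
#' @export
normalize_to_carb_basis <- function(records) {
  stopifnot(is.data.frame(records), "mean_pct" %in% names(records))
  total <- sum(records$mean_pct, na.rm = TRUE)
  if (total <= 0)
    stop("degenerate food: all carbohydrate compositions are zero", call. = FALSE)
  f <- 100 / total
  records$mean_pct <- records$mean_pct * f
  if ("se" %in% names(records)) records$se <- records$se * f
  records
}

#' Carbohydrate classes recognised in food composition tables
#'
#' The six food-facing classes, plus the mapping from common composition-table
#' component names onto them (free glucose, fructose, sucrose, maltose
#' reported anhydrous, starch, and dietary fiber treated as cellulose).
#'
#' @return `food_carb_ids()`: character vector of the six class ids.
#' @export
food_carb_ids <- function() {
  c("glucose", "fructose", "sucrose", "maltose_anhydrous", "starch", "cellulose")
}

#' @rdname food_carb_ids
#' @return `default_carb_class_map()`: named character vector mapping source
#'   component names to class ids.
#' @export
default_carb_class_map <- function() {
  c(glucose = "glucose", fructose = "fructose", sucrose = "sucrose",
    maltose = "maltose_anhydrous", starch = "starch",
    fiber = "cellulose", cellulose = "cellulose",
    maltose_anhydrous = "maltose_anhydrous")
}
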