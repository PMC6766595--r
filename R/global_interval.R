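#' Enumerate all endpoint combinations of composition and heat intervals
#'
#' For k carbohydrates, each with a composition interval \[Cil, Cih\] (percent
#' of carbohydrate mass) and a heat-of-combustion interval \[HCil, HCih\]
#' (kcal/g), forms every combination of one endpoint per interval — 2^k
#' composition sets times 2^k heat sets — and evaluates the candidate heat
#' \eqn{0.01 \sum_i C_i \, HC_i} for each. With all six classes present this
#' is the full 4,096 = 64 x 64 enumeration; degenerate (zero-width) intervals
#' still contribute both formally distinct choices, so the count is always
#' exactly \eqn{2^{2k}}.
#'
#' @param comp_low,comp_high Numeric vectors of composition endpoints, percent,
#'   named by carbohydrate id.
#' @param heat_low,heat_high Numeric vectors of heat endpoints, kcal/g, named
#'   by the same carbohydrate ids.
#' @return Numeric vector of `2^(2k)` candidate heats, kcal/g.
#' @examples
#' cands <- enumerate_candidates(
#'   comp_low = c(glucose = 40, starch = 40),
#'   comp_high = c(glucose = 60, starch = 60),
#'   heat_low = c(glucose = 3.7, starch = 4.0),
#'   heat_high = c(glucose = 3.8, starch = 4.2))
#' range(cands)
#' @export
enumerate_candidates <- function(comp_low, comp_high, heat_low, heat_high) {
  ids <- names(comp_low)
  if (is.null(ids) || is.null(names(heat_low)))
    stop("interval vectors must be named by carbohydrate id", call. = FALSE)
  if (!setequal(ids, names(heat_low)) || !setequal(ids, names(comp_high)) ||
      !setequal(ids, names(heat_high)))
    stop("composition and heat intervals are keyed by different carbohydrates",
         call. = FALSE)
  comp_high <- comp_high[ids]
  heat_low <- heat_low[ids]
  heat_high <- heat_high[ids]
  if (any(comp_low > comp_high) || any(heat_low > heat_high))
    stop("interval endpoints must satisfy low <= high", call. = FALSE)
  k <- length(ids)
  # rows of `choices`: one endpoint selection per interval (FALSE = low)
  choices <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  comp_sets <- t(ifelse(t(choices), comp_high, comp_low))   # 2^k x k
  heat_sets <- t(ifelse(t(choices), heat_high, heat_low))
  as.vector(0.01 * comp_sets %*% t(heat_sets))
}

#' Global interval, closed form, and mean of the enumerated candidates
#'
#' `global_interval()` is the range (min, max) of the enumerated candidate
#' heats: the food's global interval, expected to contain the true heat of
#' combustion of its carbohydrate mass. `hcc_f()` is their arithmetic mean,
#' the enumeration-based global heat of combustion.
#'
#' @param candidates Numeric vector from [enumerate_candidates()].
#' @return `global_interval()`: named vector `c(low, high)`, kcal/g.
#' @export
global_interval <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate values", call. = FALSE)
  c(low = min(candidates), high = max(candidates))
}

#' @rdname global_interval
#' @return `hcc_f()`: mean candidate heat, kcal/g.
#' @export
hcc_f <- function(candidates) {
  if (length(candidates) == 0) stop("no candidate values", call. = FALSE)
  mean(candidates)
}

#' @rdname global_interval
#' @inheritParams enumerate_candidates
#' @return `global_interval_closed_form()`: the same `c(low, high)` computed
#'   without enumeration as \eqn{(0.01\sum C_{il} HC_{il},\ 0.01\sum C_{ih} HC_{ih})},
#'   valid because every term is non-negative. Kept as an independent
#'   cross-check of the literal enumeration.
#' @export
global_interval_closed_form <- function(comp_low, comp_high, heat_low, heat_high) {
  ids <- names(comp_low)
  c(low = 0.01 * sum(comp_low * heat_low[ids]),
    high = 0.01 * sum(comp_high[ids] * heat_high[ids]))
}

#' Simplified global heat of combustion from mean compositions
#'
#' The composition-weighted mean of the representative heats,
#' \eqn{HC_{c,inf} = 0.01 \sum_i \bar C_i \, HC_i}, using mean compositions on
#' the carbohydrate-mass basis. A cheap stand-in for the enumeration mean
#' [hcc_f()]; across the published food tables the two differ by at most
#' 0.01 kcal/g.
#'
#' @param means Named numeric vector of mean compositions, percent of
#'   carbohydrate mass.
#' @param refs Reference table as from [carb_reference_table()].
#' @return Heat of combustion, kcal/g.
#' @examples
#' hcc_inf(c(starch = 100))
#' @export
hcc_inf <- function(means, refs = carb_reference_table()) {
  if (length(means) == 0) return(0)
  ids <- names(means)
  if (is.null(ids)) stop("`means` must be named by carbohydrate id", call. = FALSE)
  unknown <- setdiff(ids, refs$carb_id)
  if (length(unknown))
    stop("unknown carbohydrate id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  rep_hc <- refs$representative[match(ids, refs$carb_id)]
  0.01 * sum(means * rep_hc)
}

#' Full food-level propagation for one food
#'
#' Normalises the food's composition rows to the carbohydrate-mass basis,
#' builds the per-carbohydrate tolerance intervals, enumerates all endpoint
#' combinations against the reference heat intervals, and summarises the
#' result. Carbohydrate classes absent from `records` contribute degenerate
#' zero-composition intervals and are dropped from the enumeration (the
#' candidate values are identical to padding with zeros).
#'
#' @param records One food's composition rows: columns `carb_id`, `mean_pct`,
#'   optionally `se`, `n`, `food_id`, `group`.
#' @param refs Reference table, see [carb_reference_table()].
#' @param coverage,confidence Tolerance-interval parameters.
#' @param normalize Rescale compositions to sum to 100 first (default TRUE).
#' @return One-row data frame: `food_id`, `group`, `hcc_inf`, `hcc_f`, `low`,
#'   `high`, `length`, `n_enumerated`.
#' @export
food_global <- function(records, refs = carb_reference_table(),
                        coverage = 0.90, confidence = 0.90, normalize = TRUE) {
  stopifnot(is.data.frame(records), all(c("carb_id", "mean_pct") %in% names(records)))
  unknown <- setdiff(records$carb_id, refs$carb_id)
  if (length(unknown))
    stop("unknown carbohydrate id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$carb_id))
    stop("duplicated carbohydrate id within one food", call. = FALSE)
  if (normalize) records <- normalize_to_carb_basis(records)
  iv <- composition_intervals(records, coverage, confidence)
  present <- iv$mean_pct > 0 | iv$high > 0
  iv <- iv[present, , drop = FALSE]
  if (nrow(iv) == 0)
    stop("degenerate food: all carbohydrate compositions are zero", call. = FALSE)
  ids <- iv$carb_id
  ref_rows <- refs[match(ids, refs$carb_id), ]
  comp_low <- stats::setNames(iv$low, ids)
  comp_high <- stats::setNames(iv$high, ids)
  heat_low <- stats::setNames(ref_rows$low, ids)
  heat_high <- stats::setNames(ref_rows$high, ids)
  cands <- enumerate_candidates(comp_low, comp_high, heat_low, heat_high)
  gi <- global_interval(cands)
  data.frame(
    food_id = if ("food_id" %in% names(records)) records$food_id[1] else NA_character_,
    group = if ("group" %in% names(records)) records$group[1] else NA_character_,
    hcc_inf = hcc_inf(stats::setNames(iv$mean_pct, ids), refs),
    hcc_f = hcc_f(cands),
    low = unname(gi["low"]),
    high = unname(gi["high"]),
    length = unname(gi["high"] - gi["low"]),
    n_enumerated = length(cands),
    stringsAsFactors = FALSE
  )
}

#' Filter foods by global-interval length
#'
#' Foods whose global interval is longer than `max_length` carry too much
#' composition uncertainty to be informative and are set aside. The boundary
#' is inclusive: a length exactly equal to `max_length` is kept.
#'
#' @param results Data frame of food-level results with a `length` column.
#' @param max_length Maximum admissible interval length, kcal/g.
#' @param tol Absolute slack when comparing against `max_length`, absorbing
#'   round-off in lengths derived from 2-decimal endpoints.
#' @return List with elements `kept` and `dropped`.
#' @export
length_filter <- function(results, max_length = 0.32, tol = 1e-9) {
  stopifnot(is.data.frame(results), "length" %in% names(results))
  drop <- results$length > max_length + tol
  list(kept = results[!drop, , drop = FALSE],
       dropped = results[drop, , drop = FALSE])
}
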