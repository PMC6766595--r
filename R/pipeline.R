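#' Pipeline configuration
#'
#' Bundles the tunable parameters of the food-level pipeline: the reference
#' table, the coverage/confidence of the composition tolerance intervals, the
#' maximum admissible global-interval length, the per-tail exclusion fraction
#' of the group stage, and the benchmark heat for the overestimation range.
#'
#' @param refs Reference table (defaults to the packaged constants).
#' @param coverage,confidence Tolerance-interval parameters, in (0, 1).
#' @param max_length Global-interval length cut-off, kcal/g.
#' @param tail Per-tail exclusion fraction for the group stage, in (0, 0.5).
#' @param atwater Benchmark heat of combustion, kcal/g.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(refs = carb_reference_table(),
                            coverage = 0.90, confidence = 0.90,
                            max_length = 0.32, tail = 0.025, atwater = 4.2) {
  if (coverage <= 0 || coverage >= 1 || confidence <= 0 || confidence >= 1)
    stop("`coverage` and `confidence` must lie in (0, 1)", call. = FALSE)
  if (max_length <= 0) stop("`max_length` must be positive", call. = FALSE)
  if (tail <= 0 || tail >= 0.5) stop("`tail` must lie in (0, 0.5)", call. = FALSE)
  structure(list(refs = refs, coverage = coverage, confidence = confidence,
                 max_length = max_length, tail = tail, atwater = atwater),
            class = "pipeline_config")
}

#' Run the food-level pipeline end to end
#'
#' composition intervals -> endpoint enumeration -> global intervals ->
#' length filter -> per-group generalized expressions. Foods dropped by the
#' length filter are reported on standard error with their interval lengths;
#' groups left empty after filtering are skipped with a warning.
#'
#' @param composition A composition table (data frame with columns `food_id`,
#'   `group`, `carb_id`, `mean_pct`, `se`, `n`) or the path of a CSV in that
#'   dialect.
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return List with `foods` (all per-food results), `kept`, `dropped`, and
#'   `groups` (one [generalized_expression()] row per group).
#' @examples
#' tab <- simulate_composition_table(synthetic_config(
#'   n_foods = c(fruit = 3), se_scale = 0, missing_se_prob = 0))
#' run_pipeline(tab$records, quiet = TRUE)$foods
#' @export
run_pipeline <- function(composition, config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(composition)) composition <- read_composition_csv(composition)
  validate_composition(composition, config$refs)
  say <- function(...) if (!quiet) message(...)

  foods <- do.call(rbind, lapply(split(composition, composition$food_id), function(d)
    food_global(d, refs = config$refs,
                coverage = config$coverage, confidence = config$confidence)))
  foods <- foods[order(foods$group, foods$food_id), , drop = FALSE]
  rownames(foods) <- NULL

  flt <- length_filter(foods, config$max_length)
  if (nrow(flt$dropped))
    say("dropped ", nrow(flt$dropped), " food(s) with interval length > ",
        config$max_length, " kcal/g: ",
        paste(sprintf("%s (%.3f)", flt$dropped$food_id, flt$dropped$length),
              collapse = ", "))

  groups <- list()
  for (g in unique(foods$group)) {
    kept_g <- flt$kept[flt$kept$group == g, , drop = FALSE]
    if (nrow(kept_g) == 0 || sum(kept_g$high - kept_g$low) == 0) {
      warning("group '", g, "' has no usable intervals after filtering; skipped",
              call. = FALSE)
      next
    }
    groups[[g]] <- generalized_expression(kept_g$low, kept_g$high,
                                          tail = config$tail, group = g,
                                          atwater = config$atwater)
  }
  groups <- if (length(groups)) do.call(rbind, c(groups, make.row.names = FALSE)) else NULL

  list(foods = foods, kept = flt$kept, dropped = flt$dropped, groups = groups)
}

#' Read a food composition table from CSV
#'
#' Expected header: `food_id, group, carb_id, mean_pct, se, n`; empty `se` or
#' `n` cells mean "not available". Rows with unknown carbohydrate ids or
#' unparseable numbers are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param carb_class_map Named vector translating source component names to
#'   the canonical class ids; see [default_carb_class_map()].
#' @return Data frame of composition records.
#' @export
read_composition_csv <- function(path, carb_class_map = default_carb_class_map()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("food_id", "group", "carb_id", "mean_pct")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("composition CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d$se <- if ("se" %in% names(d)) suppressWarnings(as.numeric(d$se)) else NA_real_
  d$n <- if ("n" %in% names(d)) suppressWarnings(as.numeric(d$n)) else NA_real_
  d$mean_pct <- suppressWarnings(as.numeric(d$mean_pct))
  mapped <- unname(carb_class_map[d$carb_id])
  bad <- which(is.na(mapped))
  if (length(bad))
    stop("unknown carbohydrate id(s) at data line(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(d$carb_id[bad]), collapse = ", "), call. = FALSE)
  d$carb_id <- mapped
  bad_mean <- which(is.na(d$mean_pct) | d$mean_pct < 0 | d$mean_pct > 100)
  if (length(bad_mean))
    stop("mean_pct outside [0, 100] at data line(s) ",
         paste(bad_mean, collapse = ", "), call. = FALSE)
  d
}

#' Write a results table to CSV or JSON
#'
#' CSV output rounds kcal/g quantities to 2 decimals, matching tabular report
#' style; JSON keeps full precision and round-trips through
#' [read_report_json()] exactly.
#'
#' @param results Data frame (food-level or group-level results).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param digits Decimal places for CSV output.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json"), digits = 2) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "csv") {
    out <- results
    num <- vapply(out, is.numeric, logical(1)) &
      !names(out) %in% c("n_enumerated", "n_foods", "pct_half_width")
    out[num] <- lapply(out[num], round, digits = digits)
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(schema = "carbheat-report/1", results = results),
                         path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "carbheat-report/1"))
    stop("unrecognised report schema: ", doc$schema, call. = FALSE)
  doc$results
}

#' Published global intervals for 68 vegetal foods
#'
#' The transcribed reference table of published food-level results — 31
#' fruits, 24 vegetables and 13 cereals — giving for each food the simplified
#' heat `hcc_inf`, the enumeration mean `hcc_f`, and the global-interval
#' endpoints (all kcal/g, 2 decimals). The per-food composition means and
#' standard errors behind these intervals are not published, so this table is
#' the input fixture for the group-level stage rather than a recomputation
#' target.
#'
#' @return Data frame with columns `food_id`, `food`, `group`, `hcc_inf`,
#'   `hcc_f`, `low`, `high`.
#' @examples
#' nrow(published_food_intervals())
#' @export
published_food_intervals <- function() {
  path <- system.file("extdata", "published_food_intervals.csv",
                      package = "carbheat", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

validate_composition <- function(d, refs) {
  stopifnot(is.data.frame(d))
  need <- c("food_id", "group", "carb_id", "mean_pct")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("composition table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(d$carb_id), refs$carb_id)
  if (length(unknown))
    stop("unknown carbohydrate id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  invisible(d)
}
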