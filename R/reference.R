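#' Correct a measured heat of combustion for lipid and protein contamination
#'
#' Bomb-calorimetry samples of nominally pure carbohydrates carry small
#' residual lipid and protein masses. The measured heat `hc_exp` (kcal per g
#' of whole sample) is corrected by removing the contaminant heats and
#' re-expressing the remainder per gram of carbohydrate:
#'
#' \deqn{HC = \frac{HC_{exp} M_T - 9.3\, M_l - 5.8\, M_p}{M_T - M_l - M_p}}
#'
#' The default contaminant heats are the classical values for vegetable-source
#' lipids (9.3 kcal/g) and cereal proteins (5.8 kcal/g).
#'
#' @param hc_exp Measured heat of combustion, kcal per g of whole sample.
#' @param m_total Sample mass, g.
#' @param m_lipid Lipid mass in the sample, g.
#' @param m_protein Protein mass in the sample, g.
#' @param lipid_hc Heat of combustion assigned to the lipid fraction, kcal/g.
#' @param protein_hc Heat of combustion assigned to the protein fraction, kcal/g.
#' @return Corrected heat of combustion, kcal per g of carbohydrate. Vectorised
#'   over the measurement arguments.
#' @examples
#' correct_heat(4.0, 1.0, 0.01, 0.02)
#' @export
correct_heat <- function(hc_exp, m_total, m_lipid = 0, m_protein = 0,
                         lipid_hc = 9.3, protein_hc = 5.8) {
  args <- recycle_args(hc_exp = hc_exp, m_total = m_total,
                       m_lipid = m_lipid, m_protein = m_protein)
  with(args, {
    if (any(!is.finite(hc_exp)) || any(hc_exp <= 0))
      stop("`hc_exp` must be positive and finite", call. = FALSE)
    if (any(m_total <= 0))
      stop("`m_total` must be positive", call. = FALSE)
    if (any(m_lipid < 0) || any(m_protein < 0))
      stop("contaminant masses must be non-negative", call. = FALSE)
    carb_mass <- m_total - m_lipid - m_protein
    if (any(carb_mass <= 0))
      stop("degenerate sample: lipid + protein mass >= total mass leaves no carbohydrate",
           call. = FALSE)
    (hc_exp * m_total - lipid_hc * m_lipid - protein_hc * m_protein) / carb_mass
  })
}

#' Convert a hydrated-form heat of combustion to the anhydrous basis
#'
#' A crystal hydrate carries `water_mass` g of bound water per `molar_mass`
#' g of anhydrous substance, so each gram of hydrate contains less combustible
#' mass than a gram of the anhydrous form. The anhydrous heat is
#'
#' \deqn{HC_{anh} = HC_{hyd} \frac{X + m_{H_2O}}{X} + HH}
#'
#' where \eqn{X} is the anhydrous molar mass (g/mol) and \eqn{HH} the hydration
#' heat (kcal per g of anhydrous substance). With the maltose constants
#' (X = 342.3, 18 g water, HH = 0.03) the monohydrate representative value
#' 3.76 kcal/g maps to 3.99 kcal/g anhydrous.
#'
#' @param hc_hyd Heat of combustion of the hydrated form, kcal/g.
#' @param molar_mass Molar mass of the anhydrous substance, g/mol.
#' @param water_mass Bound water per formula unit, g (18 per water of
#'   crystallisation).
#' @param hydration_heat Hydration heat, kcal per g of anhydrous substance.
#' @return Heat of combustion of the anhydrous form, kcal/g.
#' @seealso [anhydrous_to_hydrated()] for the inverse map.
#' @examples
#' hydrated_to_anhydrous(3.76, molar_mass = 342.3, hydration_heat = 0.03)
#' @export
hydrated_to_anhydrous <- function(hc_hyd, molar_mass, water_mass = 18,
                                  hydration_heat = 0) {
  if (any(molar_mass <= 0)) stop("`molar_mass` must be positive", call. = FALSE)
  if (any(water_mass < 0)) stop("`water_mass` must be non-negative", call. = FALSE)
  if (any(hc_hyd <= 0)) stop("`hc_hyd` must be positive", call. = FALSE)
  hc_hyd * (molar_mass + water_mass) / molar_mass + hydration_heat
}

#' @rdname hydrated_to_anhydrous
#' @param hc_anh Heat of combustion of the anhydrous form, kcal/g.
#' @export
anhydrous_to_hydrated <- function(hc_anh, molar_mass, water_mass = 18,
                                  hydration_heat = 0) {
  if (any(molar_mass <= 0)) stop("`molar_mass` must be positive", call. = FALSE)
  (hc_anh - hydration_heat) * molar_mass / (molar_mass + water_mass)
}

#' Two-sided Grubbs test for a single outlier
#'
#' Computes \eqn{G = \max_i |x_i - \bar x| / s} and flags the most extreme
#' observation when G exceeds the two-sided critical value
#' \eqn{\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}} with
#' \eqn{t = t_{\alpha/(2n),\,n-2}}. One outlier per call; constant sequences
#' are never flagged.
#'
#' @param values Numeric vector, at least 3 values.
#' @param alpha Significance level (two-sided).
#' @return Index of the flagged value, or `integer(0)` when nothing is flagged.
#' @examples
#' grubbs_flag(c(3.70, 3.72, 3.74, 3.76, 4.50))
#' @export
grubbs_flag <- function(values, alpha = 0.05) {
  if (length(values) < 3)
    stop("Grubbs test requires at least 3 values", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numerics", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) return(integer(0))
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  if (g > grubbs_critical(length(values), alpha)) which.max(dev) else integer(0)
}

#' @rdname grubbs_flag
#' @param n Number of observations.
#' @return `grubbs_critical()`: the two-sided critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test requires at least 3 values", call. = FALSE)
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Boxplot (IQR fence) outlier screening
#'
#' Flags values outside `[Q1 - whisker * IQR, Q3 + whisker * IQR]`, with
#' quartiles from [stats::quantile()] (type 7).
#'
#' @param values Numeric vector, at least 4 values.
#' @param whisker Fence multiplier; 1.5 is the conventional whisker.
#' @return Integer vector of flagged indices (possibly empty).
#' @export
boxplot_flags <- function(values, whisker = 1.5) {
  if (length(values) < 4)
    stop("boxplot screening requires at least 4 values", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("`values` must be finite numerics", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  which(values < q[1] - whisker * iqr | values > q[2] + whisker * iqr)
}

#' Is a new measurement consistent with a set of bibliographic values?
#'
#' Appends `value` to `biblio_values` and screens the pooled set with the
#' Grubbs test and (when the pooled set has at least 4 points) the boxplot
#' fences; `value` is consistent when neither procedure flags it.
#'
#' @param value Candidate measurement, kcal/g.
#' @param biblio_values Reference measurements, kcal/g (non-empty).
#' @param alpha Significance level for the Grubbs test.
#' @return `TRUE` when `value` is not assigned as an outlier.
#' @export
is_consistent_with_reference <- function(value, biblio_values, alpha = 0.05) {
  if (length(biblio_values) < 1)
    stop("`biblio_values` must be non-empty", call. = FALSE)
  pooled <- c(biblio_values, value)
  idx <- length(pooled)
  flagged <- FALSE
  if (length(pooled) >= 3)
    flagged <- idx %in% grubbs_flag(pooled, alpha)
  if (!flagged && length(pooled) >= 4)
    flagged <- idx %in% boxplot_flags(pooled)
  !flagged
}

# Packaged reference constants: representative values and overall intervals,
# kcal/g, for the seven carbohydrate entries (maltose in both crystal forms).
.carb_reference <- data.frame(
  carb_id = c("glucose", "fructose", "sucrose", "maltose_monohydrate",
              "maltose_anhydrous", "starch", "cellulose"),
  representative = c(3.74, 3.76, 3.95, 3.76, 3.99, 4.16, 4.15),
  low  = c(3.69, 3.70, 3.91, 3.71, 3.93, 4.07, 4.05),
  high = c(3.78, 3.81, 4.00, 3.81, 4.04, 4.25, 4.25),
  stringsAsFactors = FALSE
)

#' Reference heats of combustion for the six food carbohydrates
#'
#' Returns the packaged table of representative heats of combustion and
#' overall intervals (kcal/g) for glucose, fructose, sucrose, maltose
#' (monohydrate and anhydrous), starch and cellulose. These merge critically
#' screened bibliographic determinations with modern isoperibolic
#' bomb-calorimetry measurements; the anhydrous-maltose entry derives from the
#' monohydrate one through [hydrated_to_anhydrous()].
#'
#' @return A data frame with columns `carb_id`, `representative`, `low`,
#'   `high`; every row satisfies `low <= representative <= high`.
#' @examples
#' carb_reference_table()
#' @export
carb_reference_table <- function() {
  .carb_reference
}

#' Read or write the reference table as a versioned JSON document
#'
#' The serialized form carries a schema marker, units, and one record per
#' carbohydrate; `read_reference_json()` validates the schema and interval
#' ordering on the way in.
#'
#' @param refs A reference table as returned by [carb_reference_table()].
#' @param path File path for the JSON document.
#' @return `read_reference_json()` returns the reference table data frame.
#' @export
write_reference_json <- function(refs, path) {
  stopifnot(is.data.frame(refs),
            all(c("carb_id", "representative", "low", "high") %in% names(refs)))
  doc <- list(schema = "carb-reference/1", units = "kcal/g", carbohydrates = refs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "carb-reference/1"))
    stop("unrecognised reference-table schema: ", doc$schema, call. = FALSE)
  refs <- doc$carbohydrates
  if (any(refs$low > refs$representative | refs$representative > refs$high))
    stop("reference table violates low <= representative <= high", call. = FALSE)
  refs
}

#' Read replicate calorimetry measurements from CSV
#'
#' Expects the header `sample_id, hc_exp, m_total, m_lipid, m_protein`;
#' missing contaminant masses are read as 0.
#'
#' @param path CSV file path.
#' @return Data frame of measurement sets.
#' @export
read_measurements_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "hc_exp", "m_total", "m_lipid", "m_protein")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("measurement CSV missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d$m_lipid[is.na(d$m_lipid)] <- 0
  d$m_protein[is.na(d$m_protein)] <- 0
  d
}

# Recycle scalar arguments against the longest one, erroring on ragged lengths.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad))
    stop("arguments must have length 1 or ", n, ": ",
         paste(names(args)[bad], collapse = ", "), call. = FALSE)
  lapply(args, rep_len, n)
}
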