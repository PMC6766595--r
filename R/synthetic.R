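#' Configuration for the synthetic composition-table generator
#'
#' Composition profiles are drawn from per-group Dirichlet distributions over
#' the six carbohydrate classes. The default concentration vectors make fruit
#' profiles fructose/glucose/sucrose-heavy and cereal profiles
#' starch-dominated, with vegetables in between, so group-level heats land
#' near the values typical of each food group.
#'
#' @param n_foods Named integer vector: foods to generate per group.
#' @param concentration Named list of Dirichlet concentration vectors (one per
#'   group, each over the six classes of [food_carb_ids()]); all positive.
#' @param se_scale Relative dispersion of the per-entry replicate noise: the
#'   underlying sample SD for a class is `se_scale * true_mean`. 0 gives a
#'   noiseless table. The default 0.004 makes typical food-level global
#'   interval lengths match the 0.1-0.35 kcal/g magnitude seen in composition
#'   databases of this kind.
#' @param n_obs_range Integer range (inclusive) for the per-entry number of
#'   observations.
#' @param missing_se_prob Probability that an entry's `se` and `n` are
#'   withheld, mimicking database rows that report a single value.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_foods = c(fruit = 31, vegetable = 24, cereal = 13),
                             concentration = default_group_concentrations(),
                             se_scale = 0.004,
                             n_obs_range = c(3, 12),
                             missing_se_prob = 0.1,
                             seed = 1L) {
  stopifnot(all(n_foods >= 1), !is.null(names(n_foods)),
            all(names(n_foods) %in% names(concentration)))
  for (g in names(n_foods)) {
    a <- concentration[[g]]
    if (length(a) != 6 || any(a <= 0) || !setequal(names(a), food_carb_ids()))
      stop("concentration for group '", g,
           "' must be positive and named by the six carbohydrate classes",
           call. = FALSE)
  }
  if (se_scale < 0) stop("`se_scale` must be non-negative", call. = FALSE)
  if (missing_se_prob < 0 || missing_se_prob > 1)
    stop("`missing_se_prob` must lie in [0, 1]", call. = FALSE)
  if (length(n_obs_range) != 2 || n_obs_range[1] < 2 || n_obs_range[2] < n_obs_range[1])
    stop("`n_obs_range` must be an increasing pair with minimum >= 2", call. = FALSE)
  structure(list(n_foods = n_foods, concentration = concentration,
                 se_scale = se_scale, n_obs_range = as.integer(n_obs_range),
                 missing_se_prob = missing_se_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @return `default_group_concentrations()`: the default named list of
#'   concentration vectors.
#' @export
default_group_concentrations <- function() {
  list(
    fruit = c(glucose = 25, fructose = 30, sucrose = 25,
              maltose_anhydrous = 1, starch = 4, cellulose = 15),
    vegetable = c(glucose = 20, fructose = 20, sucrose = 15,
                  maltose_anhydrous = 1, starch = 14, cellulose = 30),
    cereal = c(glucose = 1, fructose = 1, sucrose = 2,
               maltose_anhydrous = 2, starch = 84, cellulose = 10)
  )
}

#' Simulate a composition table with known per-food true heats
#'
#' For each food, a true composition is drawn from the group's Dirichlet
#' distribution and scaled to 100% of carbohydrate mass; its true heat of
#' combustion is \eqn{0.01 \sum_i C_i^{true} HC_i} with the representative
#' reference heats. Observed means perturb the truth by sampling noise
#' consistent with the emitted `se` (the standard error \eqn{s/\sqrt n} of
#' `n` replicates with SD `s = se_scale * true_mean`); with probability
#' `missing_se_prob` an entry's `se`/`n` are withheld. The output CSV dialect
#' matches what [read_composition_csv()] expects.
#'
#' @param cfg A [synthetic_config()].
#' @param refs Reference table used for the true heats.
#' @return List with `records` (composition table: `food_id`, `group`,
#'   `carb_id`, `mean_pct`, `se`, `n`) and `truth` (`food_id`, `true_hc`).
#' @export
simulate_composition_table <- function(cfg, refs = carb_reference_table()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ids <- food_carb_ids()
  with_local_seed(cfg$seed, {
    recs <- list()
    truth <- list()
    for (g in names(cfg$n_foods)) {
      alpha <- cfg$concentration[[g]][ids]
      for (j in seq_len(cfg$n_foods[[g]])) {
        food <- sprintf("%s_%03d", g, j)
        true_c <- 100 * rdirichlet1(alpha)
        n_obs <- sample(seq(cfg$n_obs_range[1], cfg$n_obs_range[2]), 6, replace = TRUE)
        s <- cfg$se_scale * true_c
        se <- s / sqrt(n_obs)
        obs <- pmin(100, pmax(0, true_c + stats::rnorm(6, 0, se)))
        hide <- stats::runif(6) < cfg$missing_se_prob
        se[hide] <- NA_real_
        n_out <- ifelse(hide, NA_integer_, n_obs)
        recs[[food]] <- data.frame(food_id = food, group = g, carb_id = ids,
                                   mean_pct = obs, se = se, n = n_out,
                                   stringsAsFactors = FALSE)
        truth[[food]] <- data.frame(
          food_id = food, group = g,
          true_hc = 0.01 * sum(true_c * refs$representative[match(ids, refs$carb_id)]),
          stringsAsFactors = FALSE)
      }
    }
    list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Simulate replicate calorimetry measurements around a known true heat
#'
#' Draws `n` normal replicates of the raw measured heat `hc_exp` whose
#' expected value, after the lipid/protein correction of [correct_heat()],
#' recovers `true_hc` exactly. With `sd = 0` and no contamination the
#' round-trip is exact.
#'
#' @param true_hc True corrected heat of combustion, kcal/g of carbohydrate.
#' @param n Number of replicates (>= 1).
#' @param sd Replicate standard deviation on the corrected scale, kcal/g.
#' @param contamination Optional named list or vector with `m_lipid`,
#'   `m_protein`, `m_total` (g); default: 1 g pure sample.
#' @param seed Integer seed.
#' @param lipid_hc,protein_hc Contaminant heats passed through to the
#'   correction, kcal/g.
#' @return Data frame of measurement sets: `sample_id`, `hc_exp`, `m_total`,
#'   `m_lipid`, `m_protein`.
#' @export
simulate_measurements <- function(true_hc, n, sd = 0, contamination = NULL,
                                  seed = 1L, lipid_hc = 9.3, protein_hc = 5.8) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  if (true_hc <= 0) stop("`true_hc` must be positive", call. = FALSE)
  if (is.null(contamination))
    contamination <- c(m_lipid = 0, m_protein = 0, m_total = 1)
  contamination <- unlist(contamination)
  m_l <- contamination[["m_lipid"]]
  m_p <- contamination[["m_protein"]]
  m_t <- contamination[["m_total"]]
  if (m_t <= 0 || m_l < 0 || m_p < 0 || m_l + m_p >= m_t)
    stop("invalid contamination masses", call. = FALSE)
  # invert the correction: hc_exp that yields `true` on the corrected scale
  hc_exp_of <- function(true) {
    (true * (m_t - m_l - m_p) + lipid_hc * m_l + protein_hc * m_p) / m_t
  }
  with_local_seed(seed, {
    corrected <- true_hc + stats::rnorm(n, 0, sd)
    data.frame(sample_id = sprintf("rep_%04d", seq_len(n)),
               hc_exp = hc_exp_of(corrected),
               m_total = m_t, m_lipid = m_l, m_protein = m_p,
               stringsAsFactors = FALSE)
  })
}

# One Dirichlet draw via normalised gamma deviates.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha   # pathological underflow guard
  g / sum(g)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# (or clearing) the caller's state afterwards: no hidden global side effects.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
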