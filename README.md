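# carbheat

Interval estimates for the heat of combustion of the carbohydrate mass in
fruits, vegetables and cereals.

Food-energy calculations conventionally assign every vegetable-source
carbohydrate the classical heat of combustion of 4.2 kcal/g. But the six
carbohydrates that dominate vegetal foods burn quite differently —
monosaccharides near 3.74–3.76 kcal/g, starch and cellulose near
4.15–4.16 kcal/g — so the right value for a food depends on *which*
carbohydrates it contains, and its uncertainty on how well the composition
is known. `carbheat` is aimed at nutrition and food-composition researchers
who want defensible per-food and per-group values instead of the single
benchmark.

## Method

Three stages, each exposed as ordinary R functions:

1. **Carbohydrate reference intervals.** Each carbohydrate *i* carries a
   representative heat HC*i* and an overall interval [HC*il*, HC*ih*]
   (packaged: `carb_reference_table()`), supported by a
   lipid/protein-contamination correction
   HC = (HC<sub>exp</sub>·M<sub>T</sub> − 9.3·M<sub>l</sub> − 5.8·M<sub>p</sub>)/(M<sub>T</sub> − M<sub>l</sub> − M<sub>p</sub>),
   a hydrate↔anhydrous conversion HC<sub>anh</sub> = HC<sub>hyd</sub>(X+18)/X + HH,
   and Grubbs/boxplot outlier screening.
2. **Food-level global intervals.** Per-carbohydrate composition intervals
   C̄*i* ∓ h·se*i*·√n (two-sided normal tolerance intervals, 90% coverage /
   90% confidence) are combined with the heat intervals by exhaustively
   enumerating all 2^k × 2^k endpoint combinations (4,096 when all six
   classes are present) of the candidate heats 0.01·Σ C*i*·HC*i*. The
   min–max of the candidates is the food's *global interval*; their mean is
   HC<sub>cf</sub>; foods with interval length > 0.32 kcal/g are set aside.
3. **Group generalization.** A group's intervals are treated as a length
   measure; the 2.5%/97.5% quantiles of cumulative interval length give a
   "center ± p%" expression per group and the overestimation range implied
   by the 4.2 kcal/g benchmark.

A Dirichlet-based synthetic composition generator with known ground truth
(`simulate_composition_table()`) makes every stage testable end to end.

## Worked example

Group-level summaries from the packaged table of 68 published food global
intervals:

```r
library(carbheat)
pub <- published_food_intervals()
s <- pub[pub$group == "fruit", ]
generalized_expression(s$low, s$high, group = "fruit")
#>   group center pct_half_width pct_half_width_raw  q_low   q_high
#> 1 fruit   3.88              4           3.796714 3.7365 4.031125
#>   tail_low_fraction tail_high_fraction overestimation_min overestimation_max
#> 1        0.01498489         0.02253776                  4                 11
#>   n_foods
#> 1      31
```

Reading: the 31 fruit intervals are summarised as **3.88 kcal/g ± 4%** —
the 2.5% and 97.5% length-measure quantiles are 3.7365 and 4.0311 kcal/g,
and 1.5%/2.3% of the summed interval length falls outside the ±4% band.
Using the classical 4.2 kcal/g for fruit carbohydrate overestimates the
heat of combustion by 4–11%. The same call on the vegetable and cereal
subsets gives 3.98 ± 5% (up to 10% overestimation) and 4.13 ± 3% (up to
5%).

A full pipeline run on synthetic data with known truth:

```r
tab <- simulate_composition_table(synthetic_config(seed = 202))
out <- run_pipeline(tab$records, quiet = TRUE)
m <- merge(out$foods, tab$truth, by = "food_id")
mean(m$low <= m$true_hc & m$true_hc <= m$high)
#> [1] 1
```

The numbered scripts under `analysis/` run the stages as a narrative
(reference values → food intervals → group expressions → synthetic
validation) and write their tables under `results/`.

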