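test_that("two-carbohydrate enumeration matches the brute-force oracle", {
  toy <- toy_two_carb()
  cands <- do.call(enumerate_candidates, toy)
  expect_length(cands, 16)
  # independent brute force over the 16 combinations
  brute <- c()
  for (c1 in c(40, 60)) for (c2 in c(40, 60))
    for (h1 in c(3.7, 3.8)) for (h2 in c(4.0, 4.2))
      brute <- c(brute, 0.01 * (c1 * h1 + c2 * h2))
  expect_equal(sort(cands), sort(brute))
  gi <- global_interval(cands)
  expect_equal(unname(gi), c(3.08, 4.80))
  # mean factorises over independent endpoint choices: midpoints
  expect_equal(hcc_f(cands), 0.01 * (50 * 3.75 + 50 * 4.10))
  expect_equal(hcc_f(cands), 3.925)
})

test_that("six carbohydrates give the full 4096-candidate enumeration", {
  set.seed(42)
  case <- random_interval_case(6)
  cands <- do.call(enumerate_candidates, case)
  expect_length(cands, 4096)
  expect_length(do.call(enumerate_candidates, random_interval_case(3)), 64)
})

test_that("degenerate intervals collapse the enumeration to one value", {
  cands <- enumerate_candidates(
    comp_low = c(glucose = 50, starch = 50), comp_high = c(glucose = 50, starch = 50),
    heat_low = c(glucose = 3.74, starch = 4.16), heat_high = c(glucose = 3.74, starch = 4.16))
  expect_length(unique(round(cands, 12)), 1L)
  expect_equal(cands[1], hcc_inf(c(glucose = 50, starch = 50)))
  gi <- global_interval(cands)
  expect_equal(unname(gi["high"] - gi["low"]), 0)
})

test_that("enumeration agrees with closed-form endpoints and midpoint mean", {
  set.seed(99)
  for (k in c(2, 4, 6)) {
    case <- random_interval_case(k)
    cands <- do.call(enumerate_candidates, case)
    expect_length(cands, 2^(2 * k))
    gi <- global_interval(cands)
    cf <- do.call(global_interval_closed_form, case)
    expect_equal(gi, cf, tolerance = 1e-12)
    mid <- 0.01 * sum((case$comp_low + case$comp_high) / 2 *
                        (case$heat_low + case$heat_high) / 2)
    expect_equal(hcc_f(cands), mid, tolerance = 1e-12)
    # permutation invariance in the carbohydrate ordering
    p <- sample(k)
    gi_p <- global_interval(enumerate_candidates(
      case$comp_low[p], case$comp_high[p], case$heat_low[p], case$heat_high[p]))
    expect_equal(gi_p, gi, tolerance = 1e-12)
  }
})

test_that("candidates built from means that sum to 100 stay in the heat hull", {
  set.seed(17)
  refs <- carb_reference_table()
  for (i in 1:10) {
    w <- runif(6); w <- 100 * w / sum(w)
    ids <- food_carb_ids()
    comp <- setNames(w, ids)
    heat_low <- setNames(refs$low[match(ids, refs$carb_id)], ids)
    heat_high <- setNames(refs$high[match(ids, refs$carb_id)], ids)
    cands <- enumerate_candidates(comp, comp, heat_low, heat_high)
    expect_true(all(cands >= 3.69 - 1e-12 & cands <= 4.25 + 1e-12))
  }
})

test_that("enumeration validates its inputs", {
  toy <- toy_two_carb()
  names(toy$heat_low) <- c("glucose", "fructose")
  expect_error(do.call(enumerate_candidates, toy), "keyed by different")
  expect_error(global_interval(numeric(0)), "no candidate")
  expect_error(hcc_f(numeric(0)), "no candidate")
})

test_that("simplified heat reproduces the reference arithmetic", {
  expect_equal(hcc_inf(c(starch = 100)), 4.16)
  expect_equal(hcc_inf(c(glucose = 50, fructose = 50)), 3.75)
  expect_equal(hcc_inf(setNames(numeric(0), character(0))), 0)
  expect_equal(hcc_inf(c(glucose = 0, starch = 0)), 0)
  expect_error(hcc_inf(c(unknown_carb = 100)), "unknown carbohydrate")
})

test_that("food-level propagation assembles a consistent result row", {
  d <- data.frame(food_id = "f1", group = "fruit",
                  carb_id = c("glucose", "fructose", "starch"),
                  mean_pct = c(30, 50, 20), se = c(1, 2, NA), n = c(4, 6, NA))
  out <- food_global(d)
  expect_identical(out$n_enumerated, 64L)
  expect_true(out$low <= out$hcc_f && out$hcc_f <= out$high)
  expect_true(out$low <= out$hcc_inf && out$hcc_inf <= out$high)
  expect_equal(out$length, out$high - out$low)
  # zero-composition classes drop out of the enumeration without changing it
  d0 <- rbind(d, data.frame(food_id = "f1", group = "fruit",
                            carb_id = "sucrose", mean_pct = 0, se = NA, n = NA))
  out0 <- food_global(d0)
  expect_equal(out0[c("hcc_inf", "hcc_f", "low", "high")],
               out[c("hcc_inf", "hcc_f", "low", "high")], tolerance = 1e-12)
  expect_error(food_global(d[0, ]), "degenerate")
})

test_that("length filter keeps the boundary and drops longer intervals", {
  res <- data.frame(food_id = c("a", "b", "c"),
                    length = c(0.33, 0.32, 0))
  flt <- length_filter(res)
  expect_identical(flt$kept$food_id, c("b", "c"))
  expect_identical(flt$dropped$food_id, "a")
})

test_that("published tables pass the length filter with five boundary foods", {
  pub <- published_food_intervals()
  pub$length <- pub$high - pub$low
  flt <- length_filter(pub)
  expect_identical(nrow(flt$dropped), 0L)
  expect_identical(sum(abs(pub$length - 0.32) < 1e-9), 5L)
  # enumeration mean and simplified value agree to 0.01 kcal/g on every food
  expect_lte(max(abs(pub$hcc_f - pub$hcc_inf)), 0.01 + 1e-9)
})
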