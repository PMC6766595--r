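test_that("contamination correction reproduces hand arithmetic and identities", {
  # no contamination: correction is the identity
  expect_identical(correct_heat(4.0, 1, 0, 0), 4.0)
  # hand oracle: (4.0 - 0.01*9.3 - 0.02*5.8)/0.97
  expect_equal(correct_heat(4.0, 1.0, 0.01, 0.02), (4.0 - 0.093 - 0.116) / 0.97)
  expect_equal(round(correct_heat(4.0, 1.0, 0.01, 0.02), 4), 3.9082)
  # identity property over random valid inputs
  set.seed(11)
  hc <- runif(50, 3, 5); m <- runif(50, 0.5, 2)
  expect_equal(correct_heat(hc, m, 0, 0), hc)
})

test_that("contamination correction rejects degenerate and invalid samples", {
  expect_error(correct_heat(4.0, 1.0, 0.6, 0.4), "degenerate")
  expect_error(correct_heat(4.0, 1.0, 0.7, 0.5), "degenerate")
  expect_error(correct_heat(4.0, 1.0, -0.1, 0), "non-negative")
  expect_error(correct_heat(4.0, 0), "positive")
  expect_error(correct_heat(-1, 1), "positive")
})

test_that("correction is increasing in hc_exp and decreasing in lipid mass", {
  grid <- expand.grid(hc = c(3.5, 4, 4.5), ml = c(0, 0.05, 0.1))
  for (i in seq_len(nrow(grid))) {
    hc <- grid$hc[i]; ml <- grid$ml[i]
    up <- correct_heat(hc + 0.01, 1, ml, 0.02) - correct_heat(hc, 1, ml, 0.02)
    expect_gt(up, 0)
    # removing lipid-rich mass raises the carbohydrate-basis heat only while
    # the current estimate stays below the lipid heat; here it always does
    dn <- correct_heat(hc, 1, ml + 0.01, 0.02) - correct_heat(hc, 1, ml, 0.02)
    expect_lt(dn, 0)
  }
})

test_that("hydrate conversion reproduces the published maltose values", {
  # monohydrate representative 3.76 -> anhydrous 3.99
  expect_equal(round(hydrated_to_anhydrous(3.76, 342.3, 18, 0.03), 2), 3.99)
  expect_equal(hydrated_to_anhydrous(3.76, 342.3, 18, 0.03), 3.987723,
               tolerance = 1e-6)
  # interval upper endpoint 3.81 -> 4.04
  expect_equal(round(hydrated_to_anhydrous(3.81, 342.3, 18, 0.03), 2), 4.04)
  # identity when there is no bound water and no hydration heat
  expect_equal(hydrated_to_anhydrous(3.9, 342.3, 0, 0), 3.9)
})

test_that("hydrate conversion is linear and invertible", {
  v <- seq(3.5, 4.2, by = 0.1)
  f <- hydrated_to_anhydrous(v, 342.3, 18, 0.03)
  # linear in hc_hyd: second differences vanish
  expect_equal(diff(diff(f)), rep(0, length(v) - 2), tolerance = 1e-12)
  back <- anhydrous_to_hydrated(f, 342.3, 18, 0.03)
  expect_equal(back, v, tolerance = 1e-12)
  expect_error(hydrated_to_anhydrous(3.8, -1), "positive")
})

test_that("Grubbs test flags a gross outlier and spares tight data", {
  expect_identical(grubbs_flag(c(3.7, 3.7, 3.7, 3.7)), integer(0))
  expect_identical(grubbs_flag(c(3.70, 3.72, 3.74, 3.76, 4.50)), 5L)
  # statistic oracle: G of c(1, 2, 9) is |9 - 4| / sd
  x <- c(1, 2, 9)
  g <- max(abs(x - mean(x))) / sd(x)
  expect_equal(g, 5 / sd(x))
  expect_lt(g, grubbs_critical(3, 0.05))  # n = 3 can barely ever reject
  expect_error(grubbs_flag(c(1, 2)), "at least 3")
})

test_that("Grubbs critical values match the published table", {
  # two-sided, alpha = 0.05: standard critical-value table entries
  expect_equal(grubbs_critical(5, 0.05), 1.715, tolerance = 5e-4)
  expect_equal(grubbs_critical(10, 0.05), 2.290, tolerance = 5e-4)
})

test_that("boxplot fences flag spread-out points and respect permutations", {
  expect_identical(boxplot_flags(c(1, 2, 3, 4)), integer(0))
  x <- c(3.7, 3.71, 3.72, 3.73, 5.0)
  expect_identical(boxplot_flags(x), 5L)
  # permutation invariance of the flagged value
  set.seed(3)
  for (i in 1:5) {
    p <- sample(length(x))
    expect_identical(x[p][boxplot_flags(x[p])], 5.0)
  }
  expect_error(boxplot_flags(c(1, 2, 3)), "at least 4")
})

test_that("outlier screens never flag constants and always catch 100-sigma points", {
  set.seed(7)
  for (n in c(5, 8, 12)) {
    x <- rnorm(n, 4, 0.02)
    spike <- mean(x) + 100 * sd(x)
    y <- c(x, spike)
    expect_identical(grubbs_flag(y), length(y))
    expect_true(length(y) %in% boxplot_flags(y))
    const <- rep(4, n)
    expect_identical(grubbs_flag(const), integer(0))
    expect_identical(boxplot_flags(const), integer(0))
  }
})

test_that("consistency screen accepts central values, rejects gross ones", {
  biblio <- c(3.70, 3.72, 3.74, 3.76)
  expect_true(is_consistent_with_reference(mean(biblio), biblio))
  expect_false(is_consistent_with_reference(10 * mean(biblio), biblio))
  # single reference value: no spread to reject against
  expect_true(is_consistent_with_reference(3.74, 3.74))
  expect_error(is_consistent_with_reference(3.74, numeric(0)), "non-empty")
})

test_that("reference table carries the packaged constants", {
  refs <- carb_reference_table()
  expect_setequal(refs$carb_id,
                  c("glucose", "fructose", "sucrose", "maltose_monohydrate",
                    "maltose_anhydrous", "starch", "cellulose"))
  get <- function(id) refs[refs$carb_id == id, ]
  expect_identical(get("glucose")$representative, 3.74)
  expect_identical(unlist(get("starch")[, c("representative", "low", "high")],
                          use.names = FALSE), c(4.16, 4.07, 4.25))
  expect_identical(unlist(get("maltose_anhydrous")[, c("representative", "low", "high")],
                          use.names = FALSE), c(3.99, 3.93, 4.04))
  expect_identical(get("fructose")$low, 3.70)
  expect_identical(get("cellulose")$high, 4.25)
  expect_true(all(refs$low <= refs$representative & refs$representative <= refs$high))
  expect_true(all(refs$low > 0))
})

test_that("reference JSON round-trips and the packaged document matches", {
  tmp <- tmpfile()
  write_reference_json(carb_reference_table(), tmp)
  back <- read_reference_json(tmp)
  expect_equal(back, carb_reference_table())
  packaged <- read_reference_json(
    system.file("extdata", "carb_reference.json", package = "carbheat"))
  expect_equal(packaged, carb_reference_table())
})

test_that("measurement CSV reader validates headers and fills missing masses", {
  tmp <- tmpfile()
  writeLines(c("sample_id,hc_exp,m_total,m_lipid,m_protein",
               "a,4.0,1.0,0.01,0.02", "b,3.9,1.0,,"), tmp)
  d <- read_measurements_csv(tmp)
  expect_identical(nrow(d), 2L)
  expect_identical(d$m_lipid[2], 0)
  writeLines("sample_id,hc_exp", tmp)
  expect_error(read_measurements_csv(tmp), "missing column")
})
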