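# Toy two-carbohydrate case used across enumeration tests: equal 40-60%
# composition intervals and heats [3.7, 3.8] / [4.0, 4.2] kcal/g.
toy_two_carb <- function() {
  list(comp_low = c(glucose = 40, starch = 40),
       comp_high = c(glucose = 60, starch = 60),
       heat_low = c(glucose = 3.7, starch = 4.0),
       heat_high = c(glucose = 3.8, starch = 4.2))
}

# Random non-negative interval sets for property-style tests.
random_interval_case <- function(k) {
  comp_mid <- runif(k, 0, 100 / k)
  comp_half <- runif(k, 0, 5)
  heat_mid <- runif(k, 3.5, 4.5)
  heat_half <- runif(k, 0, 0.2)
  ids <- paste0("c", seq_len(k))
  list(comp_low = setNames(pmax(0, comp_mid - comp_half), ids),
       comp_high = setNames(comp_mid + comp_half, ids),
       heat_low = setNames(heat_mid - heat_half, ids),
       heat_high = setNames(heat_mid + heat_half, ids))
}

tmpfile <- function(ext = ".csv") tempfile(fileext = ext)

# Reference table with the overall intervals collapsed onto the
# representative values: removes the heat-interval contribution so that
# noiseless compositions yield zero-width global intervals.
degenerate_refs <- function() {
  r <- carb_reference_table()
  r$low <- r$representative
  r$high <- r$representative
  r
}

expected_group_hc <- function(group, refs = carb_reference_table()) {
  a <- default_group_concentrations()[[group]]
  w <- a / sum(a)
  sum(w * refs$representative[match(names(a), refs$carb_id)])
}
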