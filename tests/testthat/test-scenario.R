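# Scenario engine: cumulative averages, percent change, base-case identity,
# and ordering properties of intervention runs.

test_that("cumulative averages are inclusive-window means", {
  o <- data.frame(year = 2010:2014, death_rate = c(9, 9, 1, 2, 3))
  expect_equal(cumulative_average(o, "death_rate", 2012, 2014), 2)
  o2 <- data.frame(year = 2012:2040, death_rate = 7)
  expect_equal(cumulative_average(o2, "death_rate", 2012, 2040), 7)
  expect_error(cumulative_average(o, "death_rate", 2012, 2040), "not covered")
  expect_error(cumulative_average(o, "nope", 2012, 2014), "unknown outcome")
})

test_that("percent change is the signed base-relative difference", {
  expect_equal(percent_change(2.795, 5.74), -51.3, tolerance = 1e-3)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1259, 612), 105.7, tolerance = 1e-3)
  expect_error(percent_change(1, 0), "positive")
})

test_that("base vs base comparison is exactly zero everywhere", {
  b <- test_bundle()
  cmp <- compare_scenarios(scenario(), b, base_run = test_base_run())
  expect_true(all(cmp$pct_change == 0))
  # determinism: re-running the base case reproduces it bit for bit
  r2 <- run_scenario(scenario(), b)
  expect_identical(r2$outcomes, test_base_run()$outcomes)
})

test_that("output before 2012 is identical across scenarios", {
  b <- test_bundle()
  base <- test_base_run()$outcomes
  alls <- run_scenario(scenario("all"), b)$outcomes
  pre <- base$year < 2012
  expect_equal(alls[pre, ], base[pre, ], tolerance = 1e-12)
})

test_that("the all-clusters run never exceeds the base death rate after 2012", {
  b <- test_bundle()
  base <- test_base_run()$outcomes
  alls <- run_scenario(scenario("all"), b)$outcomes
  post <- base$year >= 2013
  expect_true(all(alls$death_rate[post] <= base$death_rate[post] + 1e-12))
})

test_that("adding a cluster never increases the cumulative death rate", {
  b <- test_bundle()
  br <- test_base_run()
  d40 <- function(cl) cumulative_average(run_scenario(scenario(cl), b),
                                         "death_rate", end = 2040)
  care <- d40(c("care_est", "care_emg"))
  care_air <- d40(c("care_est", "care_emg", "air_est", "air_emg"))
  alls <- d40("all")
  expect_lte(care_air, care)
  expect_lte(alls, care_air)
})

test_that("the cluster report covers every domain, variant and window", {
  rep <- report_clusters(test_bundle(), domains = "air", windows = 2020)
  expect_setequal(rep$variant, c("established", "emerging", "combined"))
  expect_equal(nrow(rep), 3 * 6)
  expect_true(all(is.finite(rep$pct_change)))
})
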