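# Population stocks: stratification, initialization, and the quarterly
# birth/death/aging/migration/first-event update.

test_that("strata enumerate 6 contiguous age bands x sex x CVD status", {
  st <- strata_table()
  expect_equal(nrow(st), 24L)
  expect_equal(length(unique(st$age_band)), 6L)
  # contiguous, non-overlapping, ordered; childcare/school/12+/65 splits
  expect_equal(cvdsim:::BAND_LOWER[-1], cvdsim:::BAND_UPPER[-6] + 1)
  expect_true(all(c("2-5", "6-11", "12-17", "65+") %in% st$age_band))
})

test_that("initialization builds a valid state and totals add up", {
  st <- initialize_population(uniform_bundle(10))
  expect_s3_class(st, "cvd_state")
  expect_equal(st$time, 1990)
  expect_equal(sum(st$counts), 240)
  for (P in st$prev) expect_equal(rowSums(P), rep(1, 24), tolerance = 1e-9)
})

test_that("default 2010 adult population is close to the census anchor", {
  o <- test_base_run()$outcomes
  expect_lt(abs(o$adults[o$year == 2010] - 234.9) / 234.9, 0.10)
})

test_that("a missing stratum count fails naming the stratum", {
  b <- test_bundle()
  idx <- cvdsim:::stratum_index(6L, 2L, 2L)  # female, 65+, post-CVD
  b$demography$init_counts[idx] <- NA
  expect_error(initialize_population(b), "65\\+\\|female\\|post_cvd")
})

test_that("zero rates leave the state unchanged except time", {
  st <- initialize_population(uniform_bundle(5))
  demo <- list(birth_rate = 0, male_birth_frac = .5, bg_death = rep(0, 24),
               migration = rep(0, 24), aging_rate = rep(0, 24))
  hz <- list(event_first = rep(0, 24), event_recur = rep(0, 24),
             case_fatality = rep(0, 24), pcvd_death = rep(0, 24),
             attr_death = rep(0, 24))
  res <- advance_quarter(st, demo, hz)
  expect_equal(res$state$time, 1990.25)
  expect_equal(res$state$counts, st$counts)
  expect_equal(res$state$prev, st$prev)
})

test_that("a 0.04/yr death rate removes 1% of the stock in one quarter", {
  st <- initialize_population(uniform_bundle(10))
  demo <- list(birth_rate = 0, male_birth_frac = .5,
               bg_death = c(rep(0, 23), 0.04),  # one stratum only
               migration = rep(0, 24))
  # suppress aging so the single-stratum arithmetic is exact
  hz <- list(event_first = rep(0, 24), event_recur = rep(0, 24),
             case_fatality = rep(0, 24), pcvd_death = rep(0, 24),
             attr_death = rep(0, 24))
  res <- advance_quarter(st, demo, hz)
  expect_equal(sum(res$deaths_bg), 10 * 0.01)
})

test_that("aging alone conserves the closed population to 1e-9 relative", {
  st <- initialize_population(uniform_bundle(10))
  demo <- list(birth_rate = 0, male_birth_frac = .5, bg_death = rep(0, 24),
               migration = rep(0, 24))
  hz <- list(event_first = rep(0, 24), event_recur = rep(0, 24),
             case_fatality = rep(0, 24), pcvd_death = rep(0, 24),
             attr_death = rep(0, 24))
  total0 <- sum(st$counts)
  for (q in 1:40) st <- advance_quarter(st, demo, hz)$state
  expect_equal(sum(st$counts), total0, tolerance = 1e-9)
})

test_that("every quarter conserves people: d(total) = births + migration - deaths", {
  b <- test_bundle()
  st <- initialize_population(b)
  plan <- cvdsim:::plan_effects(b, scenario(), NULL)
  dims <- b$dims
  names(dims) <- vapply(dims, `[[`, "", "name")
  for (q in 1:20) {
    M <- cvdsim:::strata_multipliers(st$prev, dims)
    hz <- cvdsim:::build_hazard_set(b, st, M)
    res <- advance_quarter(st, b$demography, hz)
    delta <- sum(res$state$counts) - sum(st$counts)
    expected <- res$births + res$migration -
      sum(res$deaths_bg) - sum(res$deaths_attr)
    expect_equal(delta, expected, tolerance = 1e-9)
    st <- res$state
  }
})

test_that("a cohort pulse moves through the aging chain as the two-stage recursion predicts", {
  b <- uniform_bundle(0)
  idx <- cvdsim:::stratum_index(2L, 1L, 1L)  # male, 2-5 (width 4 years)
  b$demography$init_counts[idx] <- 1
  st <- initialize_population(b)
  demo <- list(birth_rate = 0, male_birth_frac = .5, bg_death = rep(0, 24),
               migration = rep(0, 24))
  hz <- list(event_first = rep(0, 24), event_recur = rep(0, 24),
             case_fatality = rep(0, 24), pcvd_death = rep(0, 24),
             attr_death = rep(0, 24))
  for (q in 1:16) st <- advance_quarter(st, demo, hz)$state  # 4 years
  # independent oracle: per-quarter recursion of the first two chain stages
  a <- 1; bb <- 0
  for (q in 1:16) {
    flow <- a / 16                  # width 4 years -> 1/16 per quarter
    a <- a - flow
    bb <- bb * (1 - 1 / 24) + flow  # width 6 years -> 1/24 per quarter
  }
  nxt <- cvdsim:::stratum_index(3L, 1L, 1L)
  expect_equal(st$counts[idx], a, tolerance = 1e-12)
  expect_equal(st$counts[nxt], bb, tolerance = 1e-12)
  # after one band width most of the cohort has left the source band
  expect_lt(st$counts[idx], 0.40)
})

test_that("negative stocks are caught with a useful message", {
  st <- initialize_population(uniform_bundle(1))
  demo <- list(birth_rate = 0, male_birth_frac = .5,
               bg_death = rep(5, 24), migration = rep(-2, 24))
  hz <- list(event_first = rep(0, 24), event_recur = rep(0, 24),
             case_fatality = rep(0, 24), pcvd_death = rep(0, 24),
             attr_death = rep(0, 24))
  expect_error(advance_quarter(st, demo, hz), "negative stock")
})
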