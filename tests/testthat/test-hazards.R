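# Hazard construction: multiplicative relative-risk combination, death-rate
# and YPLL definitions.

test_that("reference-category populations have multiplier exactly 1", {
  rr <- list(bp = cbind(event = c(1, 1.4, 2), cvd_death = c(1, 1.4, 2),
                        attr_death = c(1, 1, 1)))
  m <- combined_risk_multiplier(list(bp = c(1, 0, 0)), rr)
  expect_identical(unname(m["event"]), 1)
  expect_identical(unname(m["attr_death"]), 1)
})

test_that("expected relative risks combine as prevalence-weighted products", {
  rr <- list(a = cbind(event = c(1, 2), cvd_death = c(1, 2),
                       attr_death = c(1, 1)),
             b = cbind(event = c(1, 1.4), cvd_death = c(1, 1.4),
                       attr_death = c(1, 1)))
  # one dimension 50/50 between RR 1 and RR 2 -> 1.5
  m1 <- combined_risk_multiplier(list(a = c(.5, .5)), rr["a"])
  expect_equal(unname(m1["event"]), 1.5)
  # two dimensions at expected RR 1.5 and 1.2 -> product 1.8
  m2 <- combined_risk_multiplier(list(a = c(.5, .5), b = c(.5, .5)), rr)
  expect_equal(unname(m2["event"]), 1.5 * (1 + .5 * .4))
})

test_that("missing relative risks raise a configuration error", {
  expect_error(combined_risk_multiplier(list(zz = c(1, 0)), list()),
               "zz")
})

test_that("shifting mass to higher-RR categories never lowers a multiplier", {
  set.seed(7)
  rr <- list(x = cbind(event = c(1, 1.5, 2.5), cvd_death = c(1, 1.4, 2.2),
                       attr_death = c(1, 1.1, 1.6)))
  for (i in 1:25) {
    p <- as.vector(stats::rmultinom(1, 100, c(.5, .3, .2))) / 100
    # move mass from category 1 to category 3
    d <- min(p[1], stats::runif(1, 0, .3))
    p2 <- p + c(-d, 0, d)
    m1 <- combined_risk_multiplier(list(x = p), rr)
    m2 <- combined_risk_multiplier(list(x = p2), rr)
    expect_true(all(m2 >= m1 - 1e-12))
  }
})

test_that("treatment attenuation removes exactly the targeted excess", {
  rr <- list(x = cbind(event = c(1, 2), cvd_death = c(1, 2),
                       attr_death = c(1, 1)))
  att <- list(x = cbind(event = c(1, .25), cvd_death = c(1, 1),
                        attr_death = c(1, 1)))
  m <- combined_risk_multiplier(list(x = c(.5, .5)), rr, att)
  expect_equal(unname(m["event"]), 1 + .5 * 1 * .25)   # excess scaled by 0.25
  expect_equal(unname(m["cvd_death"]), 1.5)            # untouched hazard
})

test_that("death rate and YPLL follow their definitions", {
  le <- test_bundle()$life_expectancy
  deaths <- rep(0, 24)
  idx <- cvdsim:::stratum_index(5L, 1L, 2L)
  deaths[idx] <- 0.001   # 1,000 deaths (millions)
  flows <- replicate(4, list(deaths_attr = deaths / 4,
                             events_first = rep(0, 24),
                             events_recur = rep(0, 24)), simplify = FALSE)
  out <- annual_outcomes(flows, adults = 1, le_table = le)
  expect_equal(out$death_rate, 1)  # 1,000 deaths per 1,000,000 adults
  expect_equal(out$ypll_rate, le[5, 1] * 1)
  expect_error(annual_outcomes(flows[1:3], 1, le), "4 quarters")
})

test_that("per-stratum YPLL/death ratio equals remaining life expectancy", {
  le <- test_bundle()$life_expectancy
  st <- strata_table()
  for (i in which(st$adult)) {
    d <- rep(0, 24); d[i] <- 0.37
    expect_equal(ypll_from_deaths(d, le) / sum(d), le[st$band[i], st$sex[i]])
  }
})
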