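# The lever inventory, cluster partition, ramp rule and recipients.

test_that("the packaged table expands to 50 levers in 6 exact clusters", {
  lv <- load_levers()
  expect_equal(nrow(lv), 50L)
  counts <- table(lv$cluster)
  expect_equal(as.vector(counts[c("care_est", "care_emg", "air_est", "air_emg",
                                  "life_est", "life_emg")]),
               c(22L, 12L, 3L, 2L, 3L, 8L))
  expect_equal(anyDuplicated(lv$id), 0L)
  # care levers price a recipient population; air/lifestyle do not
  expect_true(all(!is.na(lv$unit_cost[lv$domain == "care"])))
  expect_true(all(is.na(lv$unit_cost[lv$domain != "care"])))
})

test_that("paired rows expand into non-CVD and post-CVD levers sharing settings", {
  lv <- load_levers()
  bb <- lv[lv$row_id == "borderline_bp_care", ]
  expect_equal(nrow(bb), 2L)
  expect_setequal(bb$cvd_split, c("non_cvd", "post_cvd"))
  expect_equal(bb$initial, c(0, 0))
  expect_equal(bb$best, c(100, 100))
  expect_equal(unique(bb$unit_cost), 220)
})

test_that("a corrupted lever table is rejected with an integrity error", {
  lv <- utils::read.csv(system.file("extdata", "levers.csv",
                                    package = "cvdsim"))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(lv[-1, ], tmp, row.names = FALSE)
  expect_error(load_levers(tmp), "expected 50 levers")
})

test_that("the ramp rule interpolates 2012-2017 and holds elsewhere", {
  lv <- load_levers()
  bp <- lv[lv$id == "bp_care_non", ]
  scn <- scenario("care_est")
  expect_equal(lever_value(bp, scn, 2012), 60)
  expect_equal(lever_value(bp, scn, 2014.5), 80)   # midpoint of 60 -> 100
  expect_equal(lever_value(bp, scn, 2017), 100)
  expect_equal(lever_value(bp, scn, 2035), 100)
  expect_equal(lever_value(bp, scn, 2005), 60)
  # piecewise-linear and monotone between the endpoints
  tt <- seq(2012, 2017, by = .25)
  vals <- vapply(tt, function(t) lever_value(bp, scn, t), 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals, 60 + (tt - 2012) / 5 * 40)
  # physical lever: sodium reaches its best-plausible level after the ramp
  na <- lv[lv$id == "sodium_hyp", ]
  expect_equal(lever_value(na, scenario("life_emg"), 2030), 1850)
  # inactive levers hold their initial setting
  expect_equal(lever_value(na, scenario("care_est"), 2035), 4000 - 300)
})

test_that("unknown clusters and levers are rejected", {
  expect_error(scenario("bogus_cluster"), "bogus_cluster")
  expect_error(scenario(levers = "not_a_lever"), "not_a_lever")
})

test_that("recipients track the published 2010 pool plus covered increments", {
  lv <- load_levers()
  bp <- as.list(lv[lv$id == "bp_care_non", ])
  # at the 2010 anchor the recipient pool is the printed one (the setting
  # acts as a quality-adjusted coverage scalar, not target x setting)
  expect_equal(recipients(bp, growth = 1, intensity = 0), 39.4 * 0.8)
  # an emerging lever with zero initial recipients covers target x uptake
  pd <- as.list(lv[lv$id == "prediab_care_non", ])
  expect_equal(recipients(pd, growth = 1, intensity = 0), 0)
  expect_equal(recipients(pd, growth = 1, intensity = 1, uptake = 1),
               pd$target_pop_2010)
  expect_error(recipients(as.list(lv[lv$id == "pm25", ])), "care levers only")
})
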