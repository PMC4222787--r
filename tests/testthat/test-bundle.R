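# The parameter bundle: structure, the null bundle, serialization, and the
# command-line wrapper.

test_that("the default bundle carries 89 effect specs over 50 levers", {
  b <- test_bundle()
  expect_equal(nrow(b$effects), 89L)
  expect_equal(nrow(b$levers), 50L)
  expect_true(all(b$effects$min <= b$effects$mean))
  expect_true(all(b$effects$mean <= b$effects$max))
  expect_true(isTRUE(b$meta$synthetic))
  # every effect resolves to a lever and (where set) a dimension
  expect_true(all(b$effects$lever %in% c(b$levers$id, "apnea_cascade")))
  dims <- vapply(b$dims, `[[`, "", "name")
  expect_true(all(stats::na.omit(b$effects$dim) %in% dims))
})

test_that("structural violations are rejected by validation", {
  b <- test_bundle()
  b1 <- b; b1$effects <- b1$effects[-1, ]
  expect_error(validate_bundle(b1), "89")
  b2 <- b; b2$effects$min[5] <- b2$effects$max[5] + 1
  expect_error(validate_bundle(b2), "min <= mean <= max")
  b3 <- b; b3$life_expectancy[3, ] <- 100
  expect_error(validate_bundle(b3), "decreasing")
})

test_that("the null bundle makes every scenario equal the base case", {
  nb <- null_bundle()
  base <- run_scenario(scenario(), nb)
  alls <- run_scenario(scenario("all"), nb)
  cmp <- compare_scenarios(scenario("all"), nb, base_run = base)
  expect_true(all(cmp$pct_change == 0))
  expect_equal(alls$outcomes, base$outcomes, tolerance = 1e-12)
  # PSA summaries collapse to zero as well
  p <- run_psa(scenario("care"), nb, n_draws = 3, seed = 1)
  expect_true(all(p$summary$median == 0 & p$summary$p2.5 == 0 &
                    p$summary$p97.5 == 0))
})

test_that("the null bundle differs only in intervention-effect parameters", {
  b <- test_bundle(); nb <- null_bundle()
  for (nm in c("demography", "dims", "interactions", "hazards",
               "life_expectancy", "levers")) {
    expect_identical(b[[nm]], nb[[nm]])
  }
  diff_cost <- names(b$costs)[!mapply(identical, b$costs, nb$costs)]
  expect_setequal(diff_cost, c("uptake_est", "uptake_emg", "rm_synergy"))
})

test_that("a bundle survives a JSON round trip numerically intact", {
  b <- test_bundle()
  path <- tempfile(fileext = ".json")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  expect_equal(unclass(b), unclass(b2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # and produces bit-comparable simulations
  r1 <- run_scenario(scenario("life_emg"), b)$outcomes
  r2 <- run_scenario(scenario("life_emg"), b2)$outcomes
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the CLI writes trajectory and PSA outputs and flags bad usage", {
  out1 <- tempfile(fileext = ".csv")
  expect_equal(cli(c("simulate", "--scenario", "base", "--out", out1)), 0L)
  expect_true(file.exists(out1))
  traj <- utils::read.csv(out1, comment.char = "#")
  expect_equal(nrow(traj), 51L)
  # identical seeds give byte-identical PSA summaries
  out2 <- tempfile(fileext = ".csv"); out3 <- tempfile(fileext = ".csv")
  expect_equal(cli(c("psa", "--scenario", "air_est", "--draws", "4",
                     "--seed", "7", "--out", out2)), 0L)
  expect_equal(cli(c("psa", "--scenario", "air_est", "--draws", "4",
                     "--seed", "7", "--out", out3)), 0L)
  expect_identical(readLines(out2), readLines(out3))
  # unknown cluster -> exit 2 mentioning the token; bad subcommand -> 2
  expect_equal(suppressMessages(
    cli(c("simulate", "--scenario", "nope", "--out", out1))), 2L)
  expect_equal(suppressMessages(cli("frobnicate")), 2L)
})
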