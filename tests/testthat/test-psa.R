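# Monte Carlo PSA: uniform parameter draws, the percentile convention, and
# paired-comparison summaries.

test_that("percentiles use midpoint interpolation between order statistics", {
  expect_equal(percentile(1:200, .025), 5.5)
  expect_equal(percentile(1:200, .975), 195.5)
  expect_equal(percentile(1:200, .5), 100.5)
})

test_that("the percentile operator matches a sort-based oracle", {
  # independent oracle: h = n p + 1/2, linear interpolation on sorted values
  oracle <- function(x, p) {
    s <- sort(x); n <- length(s)
    h <- pmin(pmax(n * p + 0.5, 1), n)
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  set.seed(99)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:500, 1))
    p <- stats::runif(3)
    expect_equal(percentile(x, p), oracle(x, p), tolerance = 1e-12)
  }
})

test_that("draws are uniform within bounds and reproducible", {
  b <- test_bundle()
  set.seed(11); d1 <- sample_draw(b$effects)
  set.seed(11); d2 <- sample_draw(b$effects)
  expect_identical(d1, d2)
  expect_length(d1, 89L)
  expect_true(all(d1 >= b$effects$min & d1 <= b$effects$max))
  # degenerate spec min = max = m always returns m
  degen <- data.frame(id = "d", min = .3, max = .3)
  expect_equal(unname(sample_draw(degen)), .3)
  expect_error(sample_draw(data.frame(id = "x", min = 1, max = 0)), "min > max")
  # law of large numbers on the uniform sampler
  flat <- data.frame(id = paste0("u", 1:10000), min = 0, max = 1)
  set.seed(5)
  expect_lt(abs(mean(sample_draw(flat)) - 0.5), 0.02)
})

test_that("scenario = base case gives exactly zero percent change", {
  p <- run_psa(scenario(), test_bundle(), n_draws = 3, seed = 2)
  expect_true(all(p$summary$median == 0))
  expect_true(all(p$summary$p2.5 == 0))
  expect_true(all(p$summary$p97.5 == 0))
})

test_that("degenerate effect specs collapse the uncertainty range", {
  b <- test_bundle()
  b$effects$min <- b$effects$mean
  b$effects$max <- b$effects$mean
  p <- run_psa(scenario("air_est"), b, n_draws = 4, seed = 3)
  expect_equal(p$summary$p2.5, p$summary$median)
  expect_equal(p$summary$p97.5, p$summary$median)
})

test_that("summaries are ordered and reproducible from the seed", {
  b <- test_bundle()
  p1 <- run_psa(scenario("air_est"), b, n_draws = 6, seed = 17)
  p2 <- run_psa(scenario("air_est"), b, n_draws = 6, seed = 17)
  expect_identical(p1$summary, p2$summary)
  expect_identical(p1$draws, p2$draws)
  expect_true(all(p1$summary$p2.5 <= p1$summary$median))
  expect_true(all(p1$summary$median <= p1$summary$p97.5))
  # a different seed gives different draws
  p3 <- run_psa(scenario("air_est"), b, n_draws = 6, seed = 18)
  expect_false(identical(p1$draws, p3$draws))
})
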