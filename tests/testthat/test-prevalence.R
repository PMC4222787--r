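# Risk-factor prevalence dynamics: category flows, interactions, stationary
# vectors, and probability conservation.

mini_state <- function(b = test_bundle()) initialize_population(b)

test_that("zero transition rates leave prevalences unchanged", {
  b <- test_bundle()
  dims <- lapply(b$dims, function(d) {
    if (!is.null(d$transitions)) d$transitions$rate <- 0
    d
  })
  st <- mini_state(b)
  st2 <- advance_prevalence(st, dims, b$interactions)
  expect_equal(st2$prev, st$prev)
})

test_that("a 0.1/yr onset moves 0.025 x source prevalence in one quarter", {
  b <- test_bundle()
  d <- b$dims[[which(vapply(b$dims, `[[`, "", "name") == "obesity")]]
  d$transitions <- data.frame(from = 1, to = 2, rate = 0.1, bands = "")
  st <- mini_state(b)
  p1 <- st$prev$obesity[, 1]
  st2 <- advance_prevalence(st, list(d), interactions = NULL)
  adult <- strata_table()$band %in% 2:6
  expect_equal(st2$prev$obesity[adult, 2],
               (st$prev$obesity[, 2] + 0.025 * p1)[adult], tolerance = 1e-12)
})

test_that("an obesity->glucose multiplier of 2 doubles the onset flow", {
  b <- test_bundle()
  gi <- which(vapply(b$dims, `[[`, "", "name") == "glucose")
  st <- mini_state(b)
  # force everyone obese so the prevalence-weighted multiplier is exactly 2
  st$prev$obesity[, 1] <- 0; st$prev$obesity[, 2] <- 1
  ia2 <- data.frame(source_dim = "obesity", source_cat = 2,
                    target_dim = "glucose", from = 1, to = 2, mult = 2)
  ia1 <- ia2; ia1$mult <- 1
  d <- b$dims[gi]
  d[[1]]$transitions <- d[[1]]$transitions[1, ]  # onset normal->prediabetic
  flow <- function(ia) {
    s2 <- advance_prevalence(st, d, ia)
    s2$prev$glucose[, 2] - st$prev$glucose[, 2]
  }
  adult <- strata_table()$band %in% 5:6
  expect_equal(flow(ia2)[adult], 2 * flow(ia1)[adult], tolerance = 1e-12)
})

test_that("stationary vectors match hand-solved balance equations", {
  # symmetric two-state chain
  expect_equal(
    equilibrium_prevalence(data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = c(.1, .1)), 2),
    c(.5, .5))
  # onset 0.3 vs regression 0.1: 0.3 p1 = 0.1 p2 with p1 + p2 = 1
  expect_equal(
    equilibrium_prevalence(data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = c(.3, .1)), 2),
    c(.25, .75))
  expect_error(
    equilibrium_prevalence(data.frame(from = c(1, 2), to = c(2, 1),
                                      rate = c(0, 0)), 2),
    "reducible|degenerate")
})

test_that("advancing from the stationary vector is a fixed point", {
  tr <- data.frame(from = c(1, 2, 2, 3), to = c(2, 1, 3, 2),
                   rate = c(.2, .1, .15, .05), bands = "")
  pi <- equilibrium_prevalence(tr, 3)
  d <- list(name = "x", kind = "chain", categories = c("a", "b", "c"),
            applies_bands = 5:6, transitions = tr,
            rr = matrix(1, 3, 3))
  st <- mini_state()
  st$prev$x <- matrix(rep(pi, each = 24), 24, 3)
  for (q in 1:8) st <- advance_prevalence(st, list(d), NULL)
  expect_equal(st$prev$x[1, ], pi, tolerance = 1e-6)
})

test_that("prevalence vectors stay probability vectors under random rates", {
  set.seed(42)
  b <- test_bundle()
  for (rep in 1:5) {
    dims <- lapply(b$dims, function(d) {
      if (!is.null(d$transitions)) {
        d$transitions$rate <- stats::runif(nrow(d$transitions), 0, 1.5)
      }
      d
    })
    st <- mini_state(b)
    for (q in 1:12) st <- advance_prevalence(st, dims, b$interactions)
    for (P in st$prev) {
      expect_equal(rowSums(P), rep(1, 24), tolerance = 1e-9)
      expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
    }
  }
})

test_that("smoking chain has no inflow to never and relapse only from recent quitters", {
  b <- test_bundle()
  sm <- b$dims[[which(vapply(b$dims, `[[`, "", "name") == "smoking")]]
  tr <- sm$transitions
  expect_false(any(tr$to == 1))                       # never has no inflow
  relapse <- tr[tr$to == 2 & tr$from != 1, ]
  expect_true(all(relapse$from == 3))                 # only recent_ex -> current
  expect_false(any(tr$from == 4 & tr$to != 4))        # long-term ex is absorbing
})

test_that("a cessation lever weakly lowers smoking prevalence at all times", {
  b <- test_bundle()
  base <- run_scenario(scenario(), b)
  quit <- run_scenario(scenario(levers = "quit_services"), b)
  adult <- strata_table()$band %in% 5:6
  expect_true(all(quit$final_state$prev$smoking[adult, 2] <=
                    base$final_state$prev$smoking[adult, 2] + 1e-12))
})
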