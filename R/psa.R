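# Probabilistic sensitivity analysis: repeated paired simulation under
# uniform draws of the 89 intervention effect-size parameters, summarized by
# the median and the 2.5/97.5 percentiles of the percent-change comparisons.

#' Percentile with the Hazen (midpoint) interpolation convention
#'
#' Linear interpolation between order statistics at plotting position
#' `h = n p + 1/2` (R's `quantile` type 5). With this convention the 2.5th
#' and 97.5th percentiles of the integers 1..200 are 5.5 and 195.5.
#'
#' @param x Numeric vector.
#' @param probs Probabilities.
#' @return Percentiles of `x`.
#' @examples
#' percentile(1:200, c(.025, .5, .975))
#' @export
percentile <- function(x, probs) {
  unname(stats::quantile(x, probs, type = 5, names = FALSE))
}

#' Sample one draw of the uncertain effect-size parameters
#'
#' Each of the 89 effect sizes is drawn independently from its uniform
#' (min, max) distribution, using the current RNG state.
#'
#' @param specs The bundle's `effects` data frame (columns `id`, `min`,
#'   `max`).
#' @return Named numeric vector of sampled effect sizes (a parameter draw).
#' @examples
#' b <- default_bundle()
#' set.seed(1)
#' d <- sample_draw(b$effects)
#' all(d >= b$effects$min & d <= b$effects$max)
#' @export
sample_draw <- function(specs) {
  if (any(specs$min > specs$max)) {
    stop("effect spec with min > max: ",
         paste(specs$id[specs$min > specs$max], collapse = ", "))
  }
  v <- stats::runif(nrow(specs), specs$min, specs$max)
  names(v) <- specs$id
  v
}

#' Paired Monte Carlo probabilistic sensitivity analysis
#'
#' For each of `n_draws` draws of the 89 effect-size parameters, runs BOTH
#' the base case and the scenario under that draw's parameters, computes the
#' cumulative-average percent changes for every outcome and window, and
#' summarizes the draws by the median and the 2.5/97.5 percentiles. The
#' paired design matches each scenario run with a base-case run from the
#' same model calibration, and the whole analysis is reproducible from the
#' seed.
#'
#' @param scn A `cvd_scenario`.
#' @param bundle A `cvd_bundle`.
#' @param n_draws Number of Monte Carlo draws (>= 2; default 200).
#' @param seed Integer RNG seed (required).
#' @param windows End years of the reporting windows.
#' @return Object of class `cvd_psa`: list with `summary` (data frame:
#'   `outcome`, `window`, `median`, `p2.5`, `p97.5`, `n_draws`, `seed`),
#'   `draws` (per-draw percent-change array), and metadata.
#' @examples
#' \donttest{
#' p <- run_psa(scenario("all"), default_bundle(), n_draws = 20, seed = 1)
#' p$summary
#' }
#' @export
run_psa <- function(scn, bundle = default_bundle(), n_draws = 200, seed,
                    windows = c(2020, 2040)) {
  if (missing(seed)) stop("a seed is required for PSA runs")
  if (n_draws < 2) stop("n_draws must be at least 2")
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(i) sample_draw(bundle$effects))
  grid <- expand.grid(outcome = OUTCOME_VARS, window = windows,
                      stringsAsFactors = FALSE)
  pct <- matrix(NA_real_, n_draws, nrow(grid))
  # The base case activates no levers, so effect draws never enter it and
  # the paired base run is identical under every draw; compute it once.
  base_invariant <- length(active_lever_ids(scenario(), bundle$levers)) == 0
  base_run <- if (base_invariant) run_scenario(scenario(), bundle) else NULL
  for (i in seq_len(n_draws)) {
    cmp <- tryCatch(
      compare_scenarios(scn, bundle, windows, draw = draws[[i]],
                        base_run = if (base_invariant) base_run
                                   else run_scenario(scenario(), bundle,
                                                     draws[[i]])),
      error = function(e) stop("PSA draw ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    pct[i, ] <- cmp$pct_change
  }
  s <- grid
  s$median <- apply(pct, 2, percentile, probs = .5)
  s$p2.5 <- apply(pct, 2, percentile, probs = .025)
  s$p97.5 <- apply(pct, 2, percentile, probs = .975)
  s$n_draws <- n_draws
  s$seed <- seed
  structure(list(summary = s, draws = pct, grid = grid, scenario = scn,
                 seed = seed, n_draws = n_draws,
                 bundle_version = bundle$meta$version,
                 percentile_convention = "Hazen (type 5)"),
            class = "cvd_psa")
}

#' @export
print.cvd_psa <- function(x, ...) {
  cat("<cvd_psa> ", x$n_draws, " paired draws, seed ", x$seed, "\n", sep = "")
  s <- x$summary
  for (w in unique(s$window)) {
    cat("\n% change vs base case, 2012-", w,
        " (median [95% uncertainty range])\n", sep = "")
    sub <- s[s$window == w, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-42s %6.1f [%6.1f, %6.1f]\n",
                  OUTCOME_LABELS[sub$outcome[i]], sub$median[i],
                  sub$p2.5[i], sub$p97.5[i]))
    }
  }
  invisible(x)
}

#' @export
plot.cvd_psa <- function(x, window = max(x$summary$window), ...) {
  s <- x$summary[x$summary$window == window, ]
  n <- nrow(s)
  graphics::plot(NA, xlim = range(c(s$p2.5, s$p97.5, 0)),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = paste0("% change vs base case, 2012-", window),
                 ylab = "", ...)
  graphics::axis(2, at = n:1, labels = OUTCOME_LABELS[s$outcome], las = 1,
                 cex.axis = .7)
  graphics::segments(s$p2.5, n:1, s$p97.5, n:1)
  graphics::points(s$median, n:1, pch = 16)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
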