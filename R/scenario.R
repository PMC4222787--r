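# Scenario comparison: cumulative averages over the 2012-2020 and 2012-2040
# reporting windows and signed percent changes against the status-quo base
# case, mirroring the published outcome-by-cluster table layout.

OUTCOME_VARS <- c("death_rate", "ypll_rate", "cost_mgmt", "cost_acute",
                  "cost_prod", "cost_combined")
OUTCOME_LABELS <- c(death_rate = "Death rate (per 1,000 adults)",
                    ypll_rate = "YPLL rate (per 1,000 adults)",
                    cost_mgmt = "Risk management costs ($/adult)",
                    cost_acute = "Acute and extended care costs ($/adult)",
                    cost_prod = "Productivity costs ($/adult)",
                    cost_combined = "Combined costs ($/adult)")

#' Cumulative average of an annual outcome over a reporting window
#'
#' "Cumulative" results are arithmetic means of the annual values over the
#' inclusive window (2012 through the end year). Rates are undiscounted;
#' cost series are already discounted annually.
#'
#' @param run A `cvd_run` (or its annual outcomes data frame).
#' @param outcome Outcome column name, one of
#'   `death_rate, ypll_rate, cost_mgmt, cost_acute, cost_prod, cost_combined`.
#' @param start,end First and last calendar year of the window (inclusive).
#' @return The window mean of the annual outcome.
#' @export
cumulative_average <- function(run, outcome, start = 2012, end = 2040) {
  o <- if (inherits(run, "cvd_run")) run$outcomes else run
  if (!outcome %in% names(o)) stop("unknown outcome: ", outcome)
  if (start < min(o$year) || end > max(o$year)) {
    stop("window ", start, "-", end, " not covered by the series (",
         min(o$year), "-", max(o$year), ")")
  }
  mean(o[[outcome]][o$year >= start & o$year <= end])
}

#' Signed percent change of a scenario value against the base case
#'
#' @param scenario_value,base_value Outcome values (base must be positive).
#' @return `100 * (scenario_value - base_value) / base_value`.
#' @examples
#' percent_change(2.795, 5.74)  # -51.3
#' @export
percent_change <- function(scenario_value, base_value) {
  if (any(base_value <= 0)) stop("base value must be positive")
  100 * (scenario_value - base_value) / base_value
}

#' Compare a scenario against the base case
#'
#' Runs the scenario and the base case under the same parameter values and
#' tabulates cumulative-average outcomes and percent changes for the
#' 2012-2020 and 2012-2040 windows.
#'
#' @param scn A `cvd_scenario`.
#' @param bundle A `cvd_bundle`.
#' @param windows End years of the reporting windows.
#' @param draw Optional effect-size draw applied to both runs.
#' @param base_run Optional precomputed base-case `cvd_run` under the same
#'   bundle and draw (saves one simulation).
#' @return A data frame of class `cvd_comparison` with columns `outcome`,
#'   `window`, `base`, `scenario`, `pct_change`.
#' @export
compare_scenarios <- function(scn, bundle = default_bundle(),
                              windows = c(2020, 2040), draw = NULL,
                              base_run = NULL) {
  if (is.null(base_run)) base_run <- run_scenario(scenario(), bundle, draw)
  srun <- run_scenario(scn, bundle, draw)
  rows <- expand.grid(outcome = OUTCOME_VARS, window = windows,
                      stringsAsFactors = FALSE)
  rows$base <- mapply(function(v, w) cumulative_average(base_run, v, end = w),
                      rows$outcome, rows$window)
  rows$scenario <- mapply(function(v, w) cumulative_average(srun, v, end = w),
                          rows$outcome, rows$window)
  rows$pct_change <- percent_change(rows$scenario, rows$base)
  class(rows) <- c("cvd_comparison", "data.frame")
  attr(rows, "scenario") <- scn
  rows
}

#' @export
print.cvd_comparison <- function(x, digits = 1, ...) {
  scn <- attr(x, "scenario")
  cat("Scenario vs base case",
      if (length(scn$clusters)) paste0("(", paste(scn$clusters, collapse = " + "), ")"),
      "\n")
  for (w in unique(x$window)) {
    cat("\nWindow 2012-", w, " (cumulative averages)\n", sep = "")
    sub <- x[x$window == w, ]
    tab <- data.frame(Outcome = OUTCOME_LABELS[sub$outcome],
                      Base = round(sub$base, 1),
                      Scenario = round(sub$scenario, 1),
                      `Change %` = round(sub$pct_change, digits),
                      check.names = FALSE)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Cluster-by-outcome report table
#'
#' Runs the established, emerging and combined variants of each policy
#' domain (or any list of scenarios) and assembles one table per reporting
#' window with the base-case column and percent changes, mirroring the
#' standard grouped layout.
#'
#' @param bundle A `cvd_bundle`.
#' @param domains Character vector among `care`, `air`, `lifestyle`, `all`.
#' @param windows End years of the reporting windows.
#' @return Data frame with columns `domain`, `variant`, `outcome`, `window`,
#'   `base`, `scenario`, `pct_change`.
#' @export
report_clusters <- function(bundle = default_bundle(),
                            domains = c("care", "air", "lifestyle", "all"),
                            windows = c(2020, 2040)) {
  base_run <- run_scenario(scenario(), bundle)
  variants <- list(established = "_est", emerging = "_emg",
                   combined = c("_est", "_emg"))
  pieces <- list()
  for (d in domains) {
    pref <- switch(d, care = "care", air = "air", lifestyle = "life",
                   all = c("care", "air", "life"))
    for (v in names(variants)) {
      cl <- as.vector(outer(pref, variants[[v]], paste0))
      cmp <- compare_scenarios(scenario(cl), bundle, windows,
                               base_run = base_run)
      cmp$domain <- d
      cmp$variant <- v
      pieces[[paste(d, v)]] <- as.data.frame(cmp)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("domain", "variant", "outcome", "window", "base", "scenario",
          "pct_change")]
}
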