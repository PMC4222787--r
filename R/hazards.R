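# Hazard construction: categorical prevalences and relative risks combine
# multiplicatively into per-stratum hazard multipliers for CVD events, CVD
# deaths, and non-CVD deaths attributable to cardiovascular risk factors
# (COPD, renal disease, smoking/diet-related cancers, aggregated).

HAZARD_NAMES <- c("event", "cvd_death", "attr_death")

#' Combined relative-risk multiplier for one stratum
#'
#' The expected relative risk within each risk dimension is the
#' prevalence-weighted mean of the category relative risks; dimensions
#' combine multiplicatively (standard comparative-risk form). A stratum with
#' all mass in reference categories has multiplier exactly 1.
#'
#' @param prev Named list of prevalence vectors, one per risk dimension.
#' @param rr Named list of k x 3 relative-risk matrices with columns
#'   `event`, `cvd_death`, `attr_death` (reference category row = 1).
#' @param attenuation Optional named list of k x 3 excess-retention matrices
#'   in `[0, 1]`; entry (c, h) scales the excess `RR - 1` of category c for
#'   hazard h (1 = untreated, 0 = excess fully removed by treatment).
#' @return Named numeric vector of multipliers for the three hazards.
#' @examples
#' rr <- list(bp = cbind(event = c(1, 1.4, 2), cvd_death = c(1, 1.4, 2),
#'                       attr_death = c(1, 1, 1)))
#' combined_risk_multiplier(list(bp = c(0.5, 0, 0.5)), rr)
#' @export
combined_risk_multiplier <- function(prev, rr, attenuation = NULL) {
  if (!all(names(prev) %in% names(rr))) {
    stop("missing relative-risk entries for dimension(s): ",
         paste(setdiff(names(prev), names(rr)), collapse = ", "))
  }
  out <- c(event = 1, cvd_death = 1, attr_death = 1)
  for (d in names(prev)) {
    R <- rr[[d]]
    A <- if (!is.null(attenuation[[d]])) attenuation[[d]] else 1
    Reff <- 1 + (R - 1) * A
    for (h in HAZARD_NAMES) out[h] <- out[h] * sum(prev[[d]] * Reff[, h])
  }
  out
}

# Vectorized over the 24 strata: returns a 24 x 3 matrix of multipliers.
# atten: named list (by dim) of lists (by hazard) of 24 x k retention
# matrices; absent entries mean no attenuation.
strata_multipliers <- function(prev, dims, atten = NULL) {
  M <- matrix(1, 24, 3, dimnames = list(NULL, HAZARD_NAMES))
  for (d in dims) {
    P <- prev[[d$name]]
    R <- d$rr
    ad <- atten[[d$name]]
    for (h in seq_along(HAZARD_NAMES)) {
      rcol <- R[, h]
      if (all(rcol == 1)) next
      if (is.null(ad) || is.null(ad[[h]])) {
        M[, h] <- M[, h] * as.numeric(P %*% rcol)
      } else {
        Reff <- 1 + outer(rep(1, 24), rcol - 1) * ad[[h]]
        M[, h] <- M[, h] * rowSums(P * Reff)
      }
    }
  }
  M
}

# Assemble the per-stratum per-year hazard set for one quarter.
# direct: 24 x 3 matrix of direct lever multipliers (1 = none);
# cf_factor: scalar/24-vector multiplier on acute case fatality.
build_hazard_set <- function(bundle, state, M, direct = NULL, cf_factor = 1) {
  hz <- bundle$hazards
  old <- as.numeric(strata_table()$band == 6L)
  t_old <- if (is.null(hz$trend_old)) 0 else hz$trend_old
  trend <- exp((hz$trend + t_old * old) * (state$time - 2012))
  if (is.null(direct)) direct <- matrix(1, 24, 3)
  list(
    event_first = hz$base_event * hz$scale_event * trend * M[, 1] * direct[, 1],
    event_recur = hz$base_recur * hz$scale_event * trend * M[, 1] * direct[, 1],
    case_fatality = pmin(hz$case_fatality * M[, 2] * direct[, 2] * cf_factor, 1),
    pcvd_death = hz$base_pcvd_death * hz$scale_death * trend * M[, 2] * direct[, 2],
    attr_death = hz$base_attr_death * hz$scale_attr * trend * M[, 3] * direct[, 3]
  )
}

#' Years of potential life lost for a vector of deaths
#'
#' Weights deaths in each (age band, sex) cell by the remaining life
#' expectancy at death recorded in the bundle's life-expectancy table, so the
#' YPLL/death ratio within a stratum equals the remaining life expectancy
#' exactly.
#'
#' @param deaths Numeric vector of 24 per-stratum death counts.
#' @param le_table 6 x 2 matrix of remaining life expectancy (years) by age
#'   band (rows) and sex (columns).
#' @return Total years of potential life lost.
#' @export
ypll_from_deaths <- function(deaths, le_table) {
  st <- strata_table()
  sum(deaths * le_table[cbind(st$band, st$sex)])
}

#' Aggregate one calendar year of quarterly flows into outcome rates
#'
#' @param flows List of four quarterly flow records (as returned by
#'   [advance_quarter()]) covering the calendar year.
#' @param adults Mid-year adult population (millions).
#' @param le_table Life-expectancy table (see [ypll_from_deaths()]).
#' @return List with `deaths`, `death_rate` (per 1,000 adults), `ypll_rate`
#'   (per 1,000 adults), `events` (millions).
#' @export
annual_outcomes <- function(flows, adults, le_table) {
  if (length(flows) != 4L) stop("a calendar year requires exactly 4 quarters of flows")
  deaths <- Reduce(`+`, lapply(flows, `[[`, "deaths_attr"))
  events <- sum(vapply(flows, function(f) sum(f$events_first + f$events_recur), 0))
  list(deaths = sum(deaths),
       death_rate = sum(deaths) / adults * 1000,
       ypll_rate = ypll_from_deaths(deaths, le_table) / adults * 1000,
       events = events)
}
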