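# The scenario engine: advances population, prevalences and hazards by
# quarter-year from 1990.00 through 2040.75 and assembles annual outcome
# series. Lever effects phase in along the 2012-2017 ramp, smoothed by a
# first-order uptake/response delay per pathway.

effect_mask <- function(row) {
  bands <- if (nzchar(row$bands)) as.integer(strsplit(row$bands, ";")[[1]]) else 1:6
  strata_mask(cvd = row$cvd, sex = row$sex, bands = bands)
}

# Resolve which levers (and the CPAP cascade) a scenario activates.
plan_effects <- function(bundle, scn, draw = NULL) {
  eff <- bundle$effects
  active_ids <- active_lever_ids(scn, bundle$levers)
  cascade_on <- any(c("apnea_diag", "apnea_cpap_own", "apnea_cpap_use",
                      "apnea_cpap_eff") %in% active_ids)
  eff$value <- if (is.null(draw)) eff$mean else unname(draw[eff$id])
  if (anyNA(eff$value)) stop("draw is missing values for some effect ids")
  eff$active <- eff$lever %in% active_ids |
    (eff$lever == "apnea_cascade" & cascade_on)
  masks <- lapply(seq_len(nrow(eff)), function(i) effect_mask(eff[i, ]))
  list(eff = eff, masks = masks, active_ids = active_ids)
}

# CPAP cascade: effective treatment requires diagnosis, device ownership,
# use, and effective use; the four settings compose multiplicatively.
apnea_plan <- function(levers, active_ids) {
  ids <- c("apnea_diag", "apnea_cpap_own", "apnea_cpap_use", "apnea_cpap_eff")
  j <- match(ids, levers$id)
  list(init = levers$initial[j], best = levers$best[j],
       on = ids %in% active_ids)
}

apnea_settings <- function(ap, r) {
  s <- ifelse(ap$on, ap$init + r * (ap$best - ap$init), ap$init)
  list(cov4 = prod(s / 100), cov4_0 = prod(ap$init / 100),
       cov3 = prod(s[1:3] / 100), cov3_0 = prod(ap$init[1:3] / 100))
}

#' Run one scenario of the simulator
#'
#' Simulates 1990-2040 by quarter-year under a scenario's lever settings and
#' returns annual outcomes: the risk-attributable death rate and YPLL rate
#' per 1,000 adults and the three per-adult cost accounts (risk management,
#' acute/extended care, productivity) in discounted 2008 dollars, plus their
#' sum. Deterministic given (scenario, bundle, draw); output before 2012 is
#' identical across scenarios because levers only move from 2012.
#'
#' @param scn A `cvd_scenario` (default: base case).
#' @param bundle A `cvd_bundle`.
#' @param draw Optional named vector of sampled effect sizes
#'   (see [sample_draw()]); defaults to the effect means.
#' @return An object of class `cvd_run`: list with `outcomes` (annual data
#'   frame), `scenario`, and metadata.
#' @examples
#' \donttest{
#' base <- run_scenario(scenario(), default_bundle())
#' head(summary(base))
#' }
#' @export
run_scenario <- function(scn = scenario(), bundle = default_bundle(),
                         draw = NULL) {
  plan <- plan_effects(bundle, scn, draw)
  eff <- plan$eff
  masks <- plan$masks
  dims <- bundle$dims
  dim_names <- vapply(dims, `[[`, "", "name")
  names(dims) <- dim_names
  demo <- bundle$demography
  dt <- 0.25
  nq <- 204L
  st <- strata_table()
  adult_rows <- which(st$adult)
  n5_rows <- which(st$band == 5)
  n6_rows <- which(st$band == 6)
  post_rows <- which(st$cvd == 2)

  att_rows <- which(eff$pathway == "att" & eff$active)
  haz_rows <- which(eff$pathway == "haz" & eff$active)
  cf_rows <- which(eff$pathway == "cf" & eff$active)
  rate_rows <- which(eff$pathway == "rate" & eff$active)
  prev_rows <- which(eff$pathway == "prev" & eff$active)
  any_active <- any(eff$active)
  ncat <- vapply(dims, function(d) length(d$categories), 0L)
  # hoist effect columns out of the data frame for the quarterly loop
  e_active <- eff$active; e_value <- eff$value; e_dim <- eff$dim
  e_cat <- eff$cat; e_from <- eff$from; e_to <- eff$to
  e_hazard <- eff$hazard; e_dir <- eff$dir
  e_bands <- lapply(eff$bands, function(b)
    if (nzchar(b)) as.integer(strsplit(b, ";")[[1]]) else NULL)
  e_hs <- lapply(seq_len(nrow(eff)), function(i)
    if (is.na(e_hazard[i])) integer(0)
    else if (e_hazard[i] == "all") 1:3 else match(e_hazard[i], HAZARD_NAMES))
  casc <- eff$lever == "apnea_cascade" & e_active
  ap <- apnea_plan(bundle$levers, plan$active_ids)

  state <- initialize_population(bundle)
  u <- numeric(nrow(eff))
  tau <- pmax(eff$tau, dt)

  rec <- list(time = numeric(nq), adults = numeric(nq), n5 = numeric(nq),
              n6 = numeric(nq), post = numeric(nq), events = numeric(nq),
              deaths = matrix(0, nq, 24), ramp = numeric(nq),
              cov3 = numeric(nq), mi = numeric(nq))

  for (q in seq_len(nq)) {
    t <- state$time
    r <- ramp_intensity(t, scn$ramp_start, scn$ramp_end)
    rho <- e_active * r
    aps <- apnea_settings(ap, r)
    rho[casc] <- (aps$cov4 - aps$cov4_0) / (1 - aps$cov4_0)
    u <- u + dt * (rho - u) / tau
    fac_dn <- 1 - e_value * u          # "reduce" pathways
    fac_up <- 1 + e_value * u          # rate increases (dir = +1)

    rate_mult <- NULL
    prev_shift <- NULL
    atten <- NULL
    direct <- NULL
    cf_factor <- 1
    if (any_active) {
      # effects with a neutral factor are skipped entirely so that a
      # zero-effect run follows the base case's floating-point path exactly
      if (length(rate_rows)) {
        for (i in rate_rows) {
          m <- if (e_dir[i] > 0) fac_up[i] else fac_dn[i]
          if (m == 1) next
          d <- e_dim[i]
          if (is.null(rate_mult)) rate_mult <- list()
          rate_mult[[d]] <- c(rate_mult[[d]],
                              list(list(from = e_from[i], to = e_to[i],
                                        bands = e_bands[[i]], mult = m)))
        }
      }
      if (length(prev_rows)) {
        for (i in prev_rows) {
          if (fac_dn[i] == 1) next
          d <- e_dim[i]
          if (is.null(prev_shift)) prev_shift <- list()
          v <- prev_shift[[d]]
          if (is.null(v)) v <- rep(1, 24)
          v[masks[[i]]] <- v[masks[[i]]] * fac_dn[i]
          prev_shift[[d]] <- v
        }
      }
      if (length(att_rows)) {
        for (i in att_rows) {
          if (fac_dn[i] == 1) next
          d <- e_dim[i]
          if (is.null(atten)) atten <- list()
          if (is.null(atten[[d]])) atten[[d]] <- list(NULL, NULL, NULL)
          for (h in e_hs[[i]]) {
            A <- atten[[d]][[h]]
            if (is.null(A)) A <- matrix(1, 24, ncat[[d]])
            A[masks[[i]], e_cat[i]] <- A[masks[[i]], e_cat[i]] * fac_dn[i]
            atten[[d]][[h]] <- A
          }
        }
      }
      if (length(haz_rows)) {
        for (i in haz_rows) {
          if (fac_dn[i] == 1) next
          if (is.null(direct)) direct <- matrix(1, 24, 3)
          for (h in e_hs[[i]])
            direct[masks[[i]], h] <- direct[masks[[i]], h] * fac_dn[i]
        }
      }
      for (i in cf_rows) cf_factor <- cf_factor * fac_dn[i]
    }

    state <- advance_prevalence(state, dims, bundle$interactions,
                                rate_mult, prev_shift, dt)
    M <- strata_multipliers(state$prev, dims, atten)
    hz <- build_hazard_set(bundle, state, M, direct, cf_factor)
    res <- advance_quarter(state, demo, hz, dt)

    rec$time[q] <- t
    rec$adults[q] <- sum(state$counts[adult_rows])
    rec$n5[q] <- sum(state$counts[n5_rows])
    rec$n6[q] <- sum(state$counts[n6_rows])
    rec$post[q] <- sum(state$counts[post_rows])
    rec$events[q] <- sum(res$events_first + res$events_recur)
    rec$deaths[q, ] <- res$deaths_attr
    rec$ramp[q] <- r
    rec$cov3[q] <- aps$cov3
    # managed-prevalence index: adults in categories that require clinical
    # management (non-normal BP / cholesterol / glucose; current smokers at
    # half weight), per adult -- drives the background management cost
    Na <- state$counts[adult_rows]
    pv <- state$prev
    rec$mi[q] <- sum(Na * (
      rowSums(pv$bp[adult_rows, 2:3]) + rowSums(pv$chol[adult_rows, 2:3]) +
        rowSums(pv$glucose[adult_rows, 2:3]) +
        0.5 * pv$smoking[adult_rows, 2] +
        0.5 * pv$obesity[adult_rows, 2])) / sum(Na)
    state <- res$state
  }

  out <- assemble_outcomes(rec, bundle, plan)
  structure(list(outcomes = out, scenario = scn,
                 bundle_version = bundle$meta$version,
                 draw = draw, final_state = state),
            class = "cvd_run")
}

# Aggregate the quarterly record into annual outcomes and cost accounts.
assemble_outcomes <- function(rec, bundle, plan) {
  years <- 1990:2040
  yr_of <- floor(rec$time + 1e-9)
  le <- bundle$life_expectancy
  cc <- bundle$costs
  levers <- bundle$levers
  active_ids <- plan$active_ids
  st <- strata_table()

  ref5 <- mean(rec$n5[yr_of == 2010])
  ref6 <- mean(rec$n6[yr_of == 2010])
  if (is.finite(suppressWarnings(as.numeric(cc$ref_n5)))) ref5 <- as.numeric(cc$ref_n5)
  if (is.finite(suppressWarnings(as.numeric(cc$ref_n6)))) ref6 <- as.numeric(cc$ref_n6)
  g_q <- (rec$n5 + cc$growth_w * rec$n6) / (ref5 + cc$growth_w * ref6)

  # care lever costs, computed per quarter then summed by year ($ millions)
  care <- levers[levers$domain == "care", ]
  cascade_aux <- c("apnea_cpap_own", "apnea_cpap_use", "apnea_cpap_eff")
  rm_q <- numeric(length(rec$time))
  acute_cov_q <- rep(NA_real_, length(rec$time))
  # established preventive care screens and refers patients into the
  # emerging services, raising their uptake when both clusters run together
  est_on <- any(levers$id[levers$cluster == "care_est"] %in% active_ids)
  syn <- if (is.null(cc$rm_synergy)) 0 else cc$rm_synergy
  # the background management cost tracks the prevalence of managed
  # conditions with elasticity rm_mi_k (> 1: the marginally managed cases
  # enter and leave the system first); mi is scenario-dependent but its
  # 2010 reference is not (levers only move from 2012)
  kmi <- if (is.null(cc$rm_mi_k)) 0 else cc$rm_mi_k
  mi_ref <- mean(rec$mi[yr_of == 2010])
  mi_fac <- (rec$mi / mi_ref)^kmi
  for (j in seq_len(nrow(care))) {
    lv <- care[j, ]
    if (lv$id %in% cascade_aux) next  # CPAP pool billed once, on diagnosis row
    upt <- if (identical(lv$status, "established")) cc$uptake_est
           else cc$uptake_emg * (1 + syn * est_on)
    rho <- if (lv$id %in% active_ids) rec$ramp else 0
    if (identical(lv$id, "apnea_diag")) {
      dcov <- rec$cov3 - rec$cov3[1]
      incr <- lv$target_pop_2010 * g_q * upt * dcov * lv$unit_cost
    } else {
      incr <- lv$target_pop_2010 * g_q * upt * rho *
        abs(lv$best - lv$initial) / 100 * lv$unit_cost
    }
    base <- lv$recipient_pop_2010 * g_q * lv$unit_cost
    if (identical(lv$account, "acute_extended")) {
      acute_cov_q <- (lv$initial + rho * (lv$best - lv$initial) * upt) / 100
    } else {
      rm_q <- rm_q + cc$rm_base_scale * base + incr
    }
  }
  # the whole risk-management account (background and lever increments)
  # scales with the managed-prevalence factor: prevention shrinks the pool
  # of patients needing management
  rm_q <- rm_q * mi_fac
  # events and deaths are per-quarter flows (summed over the year); the
  # post-CVD stock and lever spending are per-year rates (x dt when summed)
  acute_lv <- care[care$account == "acute_extended", ]
  ae_lever_q <- acute_lv$unit_cost * rec$events * acute_cov_q
  ae_flow_q <- ae_lever_q + cc$acute_cost_per_event * rec$events
  ae_stock_q <- cc$extended_cost_per_py * rec$post
  deaths_q <- rowSums(rec$deaths)
  prod_flow_q <- cc$prod_cost_per_death * deaths_q +
    cc$prod_cost_per_event * rec$events
  prod_stock_q <- cc$prod_cost_per_py * rec$post

  agg <- function(x, rate = FALSE) {
    v <- vapply(years, function(y) {
      i <- yr_of == y
      if (rate) sum(x[i] * 0.25) else sum(x[i])
    }, 0)
    v
  }
  adults_y <- vapply(years, function(y) mean(rec$adults[yr_of == y]), 0)
  deaths_y <- t(vapply(years, function(y) colSums(rec$deaths[yr_of == y, , drop = FALSE]),
                       numeric(24)))
  ypll_y <- apply(deaths_y, 1, ypll_from_deaths, le_table = le)
  disc <- discount_to_base(1, years, rate = cc$discount_rate,
                           base_year = cc$base_year)
  # real per-adult cost-intensity growth (constant 2008 $; technology and
  # severity drift), applied account-wide before discounting
  itrend <- function(g) exp(g * (years - cc$base_year))
  out <- data.frame(
    year = years,
    adults = adults_y,
    deaths = rowSums(deaths_y),
    events = agg(rec$events),
    post_stock = vapply(years, function(y) mean(rec$post[yr_of == y]), 0),
    n5 = vapply(years, function(y) mean(rec$n5[yr_of == y]), 0),
    n6 = vapply(years, function(y) mean(rec$n6[yr_of == y]), 0),
    death_rate = rowSums(deaths_y) / adults_y * 1000,
    ypll_rate = ypll_y / adults_y * 1000,
    cost_mgmt = agg(rm_q, rate = TRUE) / adults_y * disc * itrend(cc$trend_rm),
    cost_acute = (agg(ae_flow_q) + agg(ae_stock_q, rate = TRUE)) /
      adults_y * disc * itrend(cc$trend_ae),
    cost_prod = (agg(prod_flow_q) + agg(prod_stock_q, rate = TRUE)) /
      adults_y * disc * itrend(cc$trend_prod)
  )
  out$cost_combined <- out$cost_mgmt + out$cost_acute + out$cost_prod
  out
}

#' @export
print.cvd_run <- function(x, ...) {
  o <- x$outcomes
  act <- x$scenario$clusters
  cat("<cvd_run> ",
      if (!length(act) && !length(x$scenario$levers)) "base case"
      else paste("clusters:", paste(act, collapse = ", ")), "\n", sep = "")
  w <- o$year >= 2012
  cat(sprintf("  death rate 2012-2040 mean: %.2f per 1,000 adults\n",
              mean(o$death_rate[w])))
  cat(sprintf("  combined cost 2012-2040 mean: %.0f $ per adult (discounted)\n",
              mean(o$cost_combined[w])))
  invisible(x)
}

#' @export
summary.cvd_run <- function(object, ...) {
  object$outcomes[, c("year", "adults", "death_rate", "ypll_rate",
                      "cost_mgmt", "cost_acute", "cost_prod",
                      "cost_combined")]
}

#' @export
plot.cvd_run <- function(x, which = c("death_rate", "cost_combined"), ...) {
  o <- x$outcomes
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  labs <- c(death_rate = "Deaths per 1,000 adults",
            ypll_rate = "YPLL per 1,000 adults",
            cost_mgmt = "Risk-management $/adult",
            cost_acute = "Acute/extended $/adult",
            cost_prod = "Productivity $/adult",
            cost_combined = "Combined $/adult")
  for (v in which) {
    graphics::plot(o$year, o[[v]], type = "l", xlab = "Year",
                   ylab = labs[[v]], ...)
    graphics::abline(v = 2012, lty = 3)
  }
  invisible(x)
}
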