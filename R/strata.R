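#' @keywords internal
"_PACKAGE"

# Age-band layout: six contiguous bands distinguishing childcare ages (2-5),
# school ages (6-11), adolescents (12-17), and adults split at 65.
BAND_LABELS <- c("0-1", "2-5", "6-11", "12-17", "18-64", "65+")
BAND_LOWER  <- c(0, 2, 6, 12, 18, 65)
BAND_UPPER  <- c(1, 5, 11, 17, 64, Inf)
BAND_WIDTH  <- c(2, 4, 6, 6, 47, Inf)
SEX_LABELS  <- c("male", "female")
CVD_LABELS  <- c("non_cvd", "post_cvd")
ADULT_BANDS <- 5:6

#' Enumerate the population strata
#'
#' The model population is segmented into 24 strata: 6 age bands x 2 sexes x
#' 2 cardiovascular-disease states (not-yet-diagnosed `non_cvd` versus
#' already-diagnosed `post_cvd`). Children are always `non_cvd`; their
#' `post_cvd` strata exist structurally but carry zero counts.
#'
#' @return A data frame with one row per stratum and columns `band`, `sex`,
#'   `cvd` (integer codes), `age_band`, `sex_label`, `cvd_label`, `adult`
#'   (logical) and `label`.
#' @examples
#' strata_table()
#' @export
strata_table <- function() {
  tab <- .cvdsim_cache$strata
  if (is.null(tab)) {
    g <- expand.grid(band = 1:6, sex = 1:2, cvd = 1:2)
    g$age_band <- BAND_LABELS[g$band]
    g$sex_label <- SEX_LABELS[g$sex]
    g$cvd_label <- CVD_LABELS[g$cvd]
    g$adult <- g$band %in% ADULT_BANDS
    g$label <- paste(g$age_band, g$sex_label, g$cvd_label, sep = "|")
    tab <- g
    .cvdsim_cache$strata <- tab
  }
  tab
}

.cvdsim_cache <- new.env(parent = emptyenv())

# Static flow indices for the quarterly update, computed once.
flow_indices <- function() {
  fi <- .cvdsim_cache$flow
  if (is.null(fi)) {
    st <- strata_table()
    idx_from <- which(st$band < 6L)
    idx_non <- which(st$cvd == 1L)
    fi <- list(
      idx_from = idx_from,
      tgt_age = stratum_index(st$band[idx_from] + 1L, st$sex[idx_from],
                              st$cvd[idx_from]),
      idx_non = idx_non,
      tgt_post = stratum_index(st$band[idx_non], st$sex[idx_non], 2L),
      non_mask = as.numeric(st$cvd == 1L),
      post_mask = as.numeric(st$cvd == 2L),
      aging_rate = ifelse(is.finite(BAND_WIDTH[st$band]),
                          1 / BAND_WIDTH[st$band], 0),
      birth_idx = stratum_index(1L, 1:2, 1L)
    )
    .cvdsim_cache$flow <- fi
  }
  fi
}

# Memoized band-restriction masks over the 24 strata.
band_mask <- function(bands) {
  key <- paste(bands, collapse = ";")
  m <- .cvdsim_cache$bmask[[key]]
  if (is.null(m)) {
    m <- strata_table()$band %in% bands
    if (is.null(.cvdsim_cache$bmask)) .cvdsim_cache$bmask <- list()
    .cvdsim_cache$bmask[[key]] <- m
  }
  m
}

# Index of a stratum in the canonical ordering (band fastest, then sex, cvd).
stratum_index <- function(band, sex, cvd) {
  (cvd - 1L) * 12L + (sex - 1L) * 6L + band
}

# Logical mask over the 24 strata. cvd: "all", "non_cvd", "post_cvd";
# sex: 0 both, 1 male, 2 female; bands: integer vector.
strata_mask <- function(cvd = "all", sex = 0L, bands = 1:6) {
  st <- strata_table()
  m <- st$band %in% bands
  if (sex > 0L) m <- m & st$sex == sex
  if (cvd != "all") m <- m & st$cvd_label == cvd
  m
}

#' Initialize the population state
#'
#' Builds the simulation state at the start of the horizon (1990.00) from the
#' stratum counts and initial risk-factor prevalence vectors recorded in a
#' parameter bundle.
#'
#' @param bundle A parameter bundle, see [default_bundle()].
#' @return An object of class `cvd_state`: a list with elements `time`,
#'   `counts` (numeric vector of 24 stratum counts, millions of persons) and
#'   `prev` (named list of 24 x k prevalence matrices, one per risk
#'   dimension).
#' @examples
#' st <- initialize_population(default_bundle())
#' sum(st$counts)  # total population, millions
#' @export
initialize_population <- function(bundle) {
  st <- strata_table()
  counts <- bundle$demography$init_counts
  if (is.null(counts) || length(counts) != 24L || anyNA(counts)) {
    missing <- if (is.null(counts)) st$label else st$label[is.na(counts)]
    stop("bundle demography is missing initial counts for stratum: ",
         paste(missing, collapse = ", "))
  }
  if (any(counts < 0)) stop("initial stratum counts must be nonnegative")
  prev <- lapply(bundle$dims, function(d) {
    p <- d$init_prev
    stopifnot(nrow(p) == 24L)
    bad <- abs(rowSums(p) - 1) > 1e-9
    if (any(bad)) {
      stop("initial prevalence rows for dimension '", d$name,
           "' do not sum to 1: stratum ", paste(st$label[bad], collapse = ", "))
    }
    p
  })
  names(prev) <- vapply(bundle$dims, `[[`, "", "name")
  structure(list(time = 1990.00, counts = as.numeric(counts), prev = prev),
            class = "cvd_state")
}

#' @export
print.cvd_state <- function(x, ...) {
  st <- strata_table()
  cat("<cvd_state> t =", format(x$time, nsmall = 2),
      "| total population:", format(round(sum(x$counts), 1), nsmall = 1), "M\n")
  adults <- sum(x$counts[st$adult])
  cat("  adults (18+):", round(adults, 1), "M;",
      "post-CVD:", round(sum(x$counts[st$cvd == 2]), 1), "M\n")
  cat("  risk dimensions:", paste(names(x$prev), collapse = ", "), "\n")
  invisible(x)
}

# Convert a per-year rate into a per-quarter fraction, clipped to [0, 1].
quarter_fraction <- function(rate, dt = 0.25) {
  pmin(pmax(rate * dt, 0), 1)
}

#' Advance the population stocks by one quarter
#'
#' Applies birth, background death, attributable death, first-event
#' (non-CVD to post-CVD) transition, aging and net migration flows to the
#' stratum counts, using simple per-quarter fractional flows. Risk-factor
#' prevalence vectors are mixed across strata wherever people move, so a
#' cohort carries its risk profile into the next age band and into the
#' post-CVD state.
#'
#' @param state A `cvd_state`.
#' @param demography The bundle's demography parameter list.
#' @param hazards A list of per-stratum per-year rates for this quarter with
#'   elements `event_first`, `event_recur`, `case_fatality`, `pcvd_death`,
#'   `attr_death` (each length 24; `case_fatality` is a fraction of events).
#' @param dt Time step in years (0.25).
#' @return A list with the advanced `state` plus per-quarter flow totals
#'   (`births`, `migration`, `deaths_bg`, `deaths_attr` by stratum,
#'   `events_first`, `events_recur`).
#' @export
advance_quarter <- function(state, demography, hazards, dt = 0.25) {
  N <- state$counts
  st <- strata_table()
  fi <- flow_indices()

  # --- outcome flows (computed from state at start of quarter) -------------
  f_ev1 <- quarter_fraction(hazards$event_first, dt)
  f_ev2 <- quarter_fraction(hazards$event_recur, dt)
  events_first <- N * f_ev1 * fi$non_mask
  events_recur <- N * f_ev2 * fi$post_mask
  cf <- pmin(pmax(hazards$case_fatality, 0), 1)
  fatal_first <- cf * events_first
  fatal_recur <- cf * events_recur
  pcvd_deaths <- N * quarter_fraction(hazards$pcvd_death, dt) * fi$post_mask
  attr_other <- N * quarter_fraction(hazards$attr_death, dt)
  deaths_attr <- fatal_first + fatal_recur + pcvd_deaths + attr_other
  deaths_bg <- N * quarter_fraction(demography$bg_death, dt)
  to_post <- events_first - fatal_first  # survivors of a first event

  # --- demographic flows ---------------------------------------------------
  births_total <- sum(N) * demography$birth_rate * dt
  births <- numeric(24)
  births[fi$birth_idx] <- births_total *
    c(demography$male_birth_frac, 1 - demography$male_birth_frac)
  migration <- demography$migration * dt
  aging_rate <- if (!is.null(demography$aging_rate)) demography$aging_rate
                else fi$aging_rate
  aging_out <- N * quarter_fraction(aging_rate, dt)

  # --- apply flows simultaneously -----------------------------------------
  N2 <- N - deaths_attr - deaths_bg - aging_out + births + migration
  # aging inflow: band i -> i+1, same sex and cvd status
  idx_from <- fi$idx_from
  inflow_age <- numeric(24)
  inflow_age[fi$tgt_age] <- aging_out[idx_from]
  N2 <- N2 + inflow_age
  # first-event survivors: non_cvd -> post_cvd, same band and sex
  idx_non <- fi$idx_non
  move <- to_post[idx_non]
  N2[idx_non] <- N2[idx_non] - move
  N2[fi$tgt_post] <- N2[fi$tgt_post] + move

  if (any(N2 < -1e-12)) {
    bad <- which(N2 < -1e-12)
    stop("negative stock after quarter at t=", state$time, " in stratum ",
         paste(st$label[bad], collapse = ", "),
         " (outflows exceed stock; check rate magnitudes)")
  }
  N2 <- pmax(N2, 0)

  # --- mix prevalence vectors along the people flows -----------------------
  # Deaths/births are category-neutral for prevalence except that new
  # entrants to a dimension's first applicable band arrive in the reference
  # category (handled by the band-1..k inflow carrying the source band's
  # vector, which for pre-applicability bands is the reference vector).
  prev2 <- state$prev
  for (dn in names(prev2)) {
    P <- prev2[[dn]]
    C <- P * N                             # category counts at start
    stay <- N - deaths_attr - deaths_bg - aging_out
    stay[idx_non] <- stay[idx_non] - move  # careful: movers leave non stratum
    stayC <- P * pmax(stay, 0)
    newC <- stayC
    newC[fi$birth_idx, 1] <- newC[fi$birth_idx, 1] + births[fi$birth_idx]
    newC <- newC + P * migration  # migrants carry the local profile
    # aging inflow carries the source stratum's vector
    newC[fi$tgt_age, ] <- newC[fi$tgt_age, ] + P[idx_from, ] * aging_out[idx_from]
    # first-event survivors carry the non-CVD vector into post-CVD
    newC[fi$tgt_post, ] <- newC[fi$tgt_post, ] + P[idx_non, ] * move
    tot <- rowSums(newC)
    ok <- tot > 1e-12
    P2 <- P
    P2[ok, ] <- newC[ok, ] / tot[ok]
    prev2[[dn]] <- P2
  }

  state$time <- state$time + dt
  state$counts <- N2
  state$prev <- prev2
  list(state = state,
       births = births_total,
       migration = sum(migration),
       deaths_bg = deaths_bg,
       deaths_attr = deaths_attr,
       events_first = events_first,
       events_recur = events_recur)
}
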