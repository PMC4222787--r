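# Risk-factor prevalence dynamics: categorical state chains (blood pressure,
# cholesterol, glucose, smoking, obesity) advanced by per-quarter fractional
# flows, binary exposures moved directly by their levers, and algebraic
# cross-factor interactions that scale transition rates.

# Parse a transition's band restriction ("" = all applicable bands).
transition_bands <- function(bands_str, applies_bands) {
  if (is.na(bands_str) || !nzchar(bands_str)) return(applies_bands)
  v <- .cvdsim_cache$tbands[[bands_str]]
  if (is.null(v)) {
    v <- as.integer(strsplit(bands_str, ";")[[1]])
    if (is.null(.cvdsim_cache$tbands)) .cvdsim_cache$tbands <- list()
    .cvdsim_cache$tbands[[bands_str]] <- v
  }
  v
}

# Per-stratum multiplier on a transition rate from the interaction table.
# An interaction (source dim/category -> target transition) scales the rate
# by 1 + (mult - 1) * prevalence(source category); mult = 1 means no
# interaction and zero source prevalence leaves the rate unchanged.
interaction_multiplier <- function(interactions, prev, dim_name, from, to) {
  m <- rep(1, 24)
  if (is.null(interactions) || nrow(interactions) == 0) return(m)
  rows <- interactions$target_dim == dim_name &
    interactions$from == from & interactions$to == to
  for (i in which(rows)) {
    ps <- prev[[interactions$source_dim[i]]][, interactions$source_cat[i]]
    m <- m * (1 + (interactions$mult[i] - 1) * ps)
  }
  m
}

#' Advance risk-factor prevalence vectors by one quarter
#'
#' For each categorical chain dimension, moves probability mass between
#' adjacent categories using per-quarter fractional flows
#' (`rate * dt`, clipped to `[0, 1]`). Transition rates are first scaled by
#' any algebraic interaction effects (e.g. obesity raising diabetes onset)
#' and by lever-driven rate multipliers. Binary exposure dimensions are set
#' directly from their baseline prevalence times a lever shift factor.
#'
#' @param state A `cvd_state`.
#' @param dims The bundle's list of risk-dimension definitions.
#' @param interactions Interaction-effect data frame
#'   (`source_dim`, `source_cat`, `target_dim`, `from`, `to`, `mult`).
#' @param rate_mult Named list: for dimension `d`, a list of lever-effect
#'   entries `list(from, to, bands, mult)`; the multiplier applies to every
#'   transition row with matching `from`/`to` whose band restriction lies
#'   within `bands` (`NULL` bands = all bands). NULL for no lever effects.
#' @param prev_shift Named list: for binary dimension `d`, a scalar or
#'   24-vector multiplier on the exposed prevalence, or NULL.
#' @param dt Time step in years (0.25).
#' @return The state with advanced prevalence matrices.
#' @export
advance_prevalence <- function(state, dims, interactions = NULL,
                               rate_mult = NULL, prev_shift = NULL,
                               dt = 0.25) {
  st <- strata_table()
  for (d in dims) {
    P <- state$prev[[d$name]]
    if (d$kind == "binary") {
      shift <- if (!is.null(prev_shift[[d$name]])) prev_shift[[d$name]] else 1
      mask <- band_mask(d$applies_bands)
      p2 <- d$base_exposed * shift
      P[mask, 2] <- p2[mask]
      P[mask, 1] <- 1 - p2[mask]
    } else {
      tr <- d$transitions
      flows_out <- matrix(0, 24, ncol(P))
      flows_in <- matrix(0, 24, ncol(P))
      for (i in seq_len(nrow(tr))) {
        from <- tr$from[i]; to <- tr$to[i]
        bands <- transition_bands(tr$bands[i], d$applies_bands)
        mult <- interaction_multiplier(interactions, state$prev, d$name, from, to)
        for (rm in rate_mult[[d$name]]) {
          if (rm$from == from && rm$to == to &&
              (is.null(rm$bands) || all(bands %in% rm$bands))) {
            mult <- mult * rm$mult
          }
        }
        rate <- tr$rate[i] * mult
        f <- quarter_fraction(rate, dt)
        fl <- P[, from] * f * band_mask(bands)
        flows_out[, from] <- flows_out[, from] + fl
        flows_in[, to] <- flows_in[, to] + fl
      }
      P <- P - flows_out + flows_in
      if (any(P < -1e-9) || any(P > 1 + 1e-9)) {
        bad <- which(rowSums(P < -1e-9 | P > 1 + 1e-9) > 0)[1]
        stop("prevalence entry outside [0,1] for dimension '", d$name,
             "', stratum ", st$label[bad],
             " (transition rates too large for the quarter step)")
      }
      P <- pmin(pmax(P, 0), 1)
      P <- P / rowSums(P)
    }
    state$prev[[d$name]] <- P
  }
  state
}

#' Stationary prevalence of a categorical chain
#'
#' Solves for the stationary probability vector of the continuous-time chain
#' implied by a dimension's transition rates. Used to initialize prevalence
#' vectors consistently and as a test oracle: advancing from the stationary
#' vector leaves it fixed.
#'
#' @param transitions Data frame with columns `from`, `to`, `rate`.
#' @param k Number of categories.
#' @return Stationary probability vector of length `k`.
#' @examples
#' # onset 0.3, regression 0.1 on two categories -> (0.25, 0.75)
#' equilibrium_prevalence(data.frame(from = c(1, 2), to = c(2, 1),
#'                                   rate = c(0.3, 0.1)), k = 2)
#' @export
equilibrium_prevalence <- function(transitions, k) {
  Q <- matrix(0, k, k)
  for (i in seq_len(nrow(transitions))) {
    Q[transitions$from[i], transitions$to[i]] <-
      Q[transitions$from[i], transitions$to[i]] + transitions$rate[i]
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  A <- rbind(t(Q), rep(1, k))
  if (qr(A)$rank < k) {
    stop("transition rates define a reducible or degenerate chain; ",
         "no unique stationary prevalence vector exists")
  }
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  if (any(pi < -1e-9)) stop("stationary vector has negative entries")
  pi <- pmax(pi, 0)
  pi / sum(pi)
}
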