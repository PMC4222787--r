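# The 50 intervention levers and their six clusters. The packaged CSV holds
# one row per published lever row; rows flagged cvd_split == "both" expand
# into separate non-CVD and post-CVD levers sharing settings and costs.

CLUSTER_IDS <- c("care_est", "care_emg", "air_est", "air_emg",
                 "life_est", "life_emg")
CLUSTER_SIZES <- c(care_est = 22L, care_emg = 12L, air_est = 3L,
                   air_emg = 2L, life_est = 3L, life_emg = 8L)

#' Load the intervention lever table
#'
#' Reads the packaged lever inventory (or a user-supplied file in the same
#' layout), expands rows that apply separately to the non-CVD and post-CVD
#' populations, and checks the cluster partition: the six clusters must
#' contain exactly 22, 12, 3, 2, 3 and 8 levers (50 in total, pairwise
#' disjoint).
#'
#' @param path Path to a lever CSV; defaults to the packaged table.
#' @return A data frame of 50 lever specifications with columns `id`,
#'   `row_id`, `label`, `cluster`, `domain`, `status`, `target_pop_2010`,
#'   `recipient_pop_2010`, `unit_cost`, `initial`, `best`, `units`,
#'   `cvd_split`, `account`.
#' @examples
#' levers <- load_levers()
#' table(levers$cluster)
#' @export
load_levers <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "levers.csv", package = "cvdsim")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "label", "cluster", "domain", "status", "target_pop_2010",
              "recipient_pop_2010", "unit_cost", "initial", "best", "units",
              "cvd_split", "account")
  if (!all(needed %in% names(raw))) {
    stop("lever table is missing column(s): ",
         paste(setdiff(needed, names(raw)), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    r$row_id <- r$id
    if (identical(r$cvd_split, "both")) {
      a <- r; a$id <- paste0(r$id, "_non");  a$cvd_split <- "non_cvd"
      b <- r; b$id <- paste0(r$id, "_post"); b$cvd_split <- "post_cvd"
      # shared settings and costs; the 2010 recipient pool is split in
      # proportion to the non/post share of the target population (4:1 by
      # default, recorded once here rather than guessed downstream)
      a$target_pop_2010 <- r$target_pop_2010 * 0.8
      b$target_pop_2010 <- r$target_pop_2010 * 0.2
      a$recipient_pop_2010 <- r$recipient_pop_2010 * 0.8
      b$recipient_pop_2010 <- r$recipient_pop_2010 * 0.2
      rbind(a, b)
    } else r
  })
  levers <- do.call(rbind, rows)
  rownames(levers) <- NULL
  if (nrow(levers) != 50L) {
    stop("lever table integrity: expected 50 levers after expansion, got ",
         nrow(levers))
  }
  counts <- table(factor(levers$cluster, levels = CLUSTER_IDS))
  bad <- counts != CLUSTER_SIZES[names(counts)]
  if (any(bad)) {
    stop("cluster partition violated: ",
         paste(names(counts)[bad], "=", counts[bad],
               "(expected", CLUSTER_SIZES[names(counts)[bad]], ")",
               collapse = "; "))
  }
  if (any(levers$initial == levers$best)) {
    stop("every lever must have best-plausible different from initial: ",
         paste(levers$id[levers$initial == levers$best], collapse = ", "))
  }
  levers
}

#' Define an intervention scenario
#'
#' A scenario names the clusters (and/or individual levers) whose levers are
#' ramped linearly from their initial to their best-plausible settings over
#' 2012-2017, remaining at full effect thereafter. The base case is the
#' empty active set: no lever changes after 2012.
#'
#' @param clusters Character vector of cluster ids among
#'   `care_est, care_emg, air_est, air_emg, life_est, life_emg`, or the
#'   shorthands `"care"`, `"air"`, `"lifestyle"` (both statuses), or
#'   `"all"`. `character(0)` (default) is the base case.
#' @param levers Optional character vector of individual lever ids to
#'   activate in addition to the clusters.
#' @param ramp_start,ramp_end,horizon_end Calendar years of the linear
#'   ramp-up and the simulation horizon.
#' @return An object of class `cvd_scenario`.
#' @examples
#' scenario()                  # base case
#' scenario("all")             # all six clusters
#' scenario(c("care_est", "care_emg"))
#' @export
scenario <- function(clusters = character(0), levers = character(0),
                     ramp_start = 2012, ramp_end = 2017, horizon_end = 2040) {
  expand <- c(care = "care_est|care_emg", air = "air_est|air_emg",
              lifestyle = "life_est|life_emg",
              all = paste(CLUSTER_IDS, collapse = "|"))
  cl <- unique(unlist(lapply(clusters, function(x) {
    if (x %in% names(expand)) strsplit(expand[[x]], "|", fixed = TRUE)[[1]] else x
  })))
  unknown <- setdiff(cl, CLUSTER_IDS)
  if (length(unknown)) {
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
  }
  tab <- load_levers()
  unknown_l <- setdiff(levers, tab$id)
  if (length(unknown_l)) {
    stop("unknown lever id(s): ", paste(unknown_l, collapse = ", "))
  }
  structure(list(clusters = cl, levers = levers, ramp_start = ramp_start,
                 ramp_end = ramp_end, horizon_end = horizon_end),
            class = "cvd_scenario")
}

#' @export
print.cvd_scenario <- function(x, ...) {
  act <- active_lever_ids(x, load_levers())
  cat("<cvd_scenario> ",
      if (!length(act)) "base case (no lever changes after 2012)"
      else paste0(length(act), " active levers; clusters: ",
                  paste(x$clusters, collapse = ", ")),
      "\n  ramp ", x$ramp_start, "-", x$ramp_end,
      ", horizon ", x$horizon_end, "\n", sep = "")
  invisible(x)
}

active_lever_ids <- function(scenario, levers) {
  unique(c(levers$id[levers$cluster %in% scenario$clusters], scenario$levers))
}

#' Lever setting at a calendar time under the ramp rule
#'
#' Inactive levers hold their initial setting throughout. Active levers
#' interpolate linearly from the initial setting at the ramp start (2012) to
#' the best-plausible setting at the ramp end (2017) and stay there.
#'
#' @param lever One row of the lever table (list or single-row data frame).
#' @param scn A `cvd_scenario`.
#' @param t Calendar time in years.
#' @return The lever setting (percent, index, or physical units as given).
#' @examples
#' lv <- load_levers()
#' bp <- lv[lv$id == "bp_care_non", ]
#' lever_value(bp, scenario("care_est"), 2014.5)  # midpoint: 80
#' @export
lever_value <- function(lever, scn, t) {
  active <- lever$id %in% active_lever_ids(scn, load_levers()) ||
    lever$cluster %in% scn$clusters
  if (!active || t <= scn$ramp_start) return(lever$initial)
  if (t >= scn$ramp_end) return(lever$best)
  frac <- (t - scn$ramp_start) / (scn$ramp_end - scn$ramp_start)
  lever$initial + frac * (lever$best - lever$initial)
}

# Normalized ramp intensity in [0,1]: |setting - initial| / |best - initial|.
ramp_intensity <- function(t, ramp_start = 2012, ramp_end = 2017) {
  pmin(pmax((t - ramp_start) / (ramp_end - ramp_start), 0), 1)
}

#' Recipient population of a care lever
#'
#' Care levers deliver services to a recipient population that scales with
#' the simulated population (anchored to the published 2010 recipient pool)
#' plus the newly covered fraction of the target population as the lever
#' ramps up. The published tables treat the lever setting as a
#' quality-adjusted coverage scalar, so the 2010 recipients are taken as
#' given rather than recomputed as target x setting.
#'
#' @param lever One row of the lever table (a care lever).
#' @param growth Population growth index relative to 2010 (1 at 2010).
#' @param intensity Smoothed ramp intensity in `[0, 1]` (0 before 2012).
#' @param uptake Fraction of the incremental target population that actually
#'   receives services at full implementation.
#' @return Recipients in millions of persons.
#' @export
recipients <- function(lever, growth = 1, intensity = 0, uptake = 1) {
  if (!identical(lever$domain, "care")) {
    stop("recipients() applies to care levers only; '", lever$id,
         "' is in domain '", lever$domain, "'")
  }
  base <- lever$recipient_pop_2010 * growth
  incr <- lever$target_pop_2010 * growth * uptake * intensity *
    (abs(lever$best - lever$initial) / 100)
  base + incr
}
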