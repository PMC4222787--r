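# The three per-adult cost accounts, in constant 2008 dollars, discounted
# annually at 3% back to the 2012 base year. Risk management covers
# individual-level clinical/behavioral management of risk factors (care
# lever recipients x unit costs); acute/extended covers acute, rehabilitation
# and disability care driven by events and the post-CVD stock; productivity
# covers lost paid and household work from deaths, disability and
# hospitalization.

#' Discount an amount back to the base year
#'
#' @param amount Dollar amount (vectorized).
#' @param year Calendar year of the amount (vectorized).
#' @param rate Annual discount rate (default 0.03).
#' @param base_year Discounting base year (default 2012). Amounts dated
#'   before the base year are historical and reported undiscounted.
#' @return Discounted amount: `amount / (1 + rate)^(year - base_year)`.
#' @examples
#' discount_to_base(100, 2022)  # 100 / 1.03^10 = 74.41
#' @export
discount_to_base <- function(amount, year, rate = 0.03, base_year = 2012) {
  amount / (1 + rate)^pmax(year - base_year, 0)
}

#' Risk-factor management cost per adult
#'
#' @param levers Lever table rows (care levers contribute; others are
#'   ignored with a warning-free skip).
#' @param recipients Named vector of recipient populations (millions),
#'   aligned with `levers$id`.
#' @param adults Adult population (millions).
#' @return Undiscounted cost per adult ($).
#' @examples
#' lv <- load_levers()
#' bp <- lv[startsWith(lv$id, "bp_care"), ]
#' risk_management_cost(bp, c(bp_care_non = 31.52, bp_care_post = 7.88), 234.9)
#' @export
risk_management_cost <- function(levers, recipients, adults) {
  care <- levers[levers$domain == "care", , drop = FALSE]
  total <- sum(care$unit_cost * recipients[care$id], na.rm = TRUE)
  total / adults
}

#' Acute and extended care cost per adult
#'
#' Linear in its drivers: cardiovascular events (acute episodes) and the
#' post-CVD population (rehabilitation and disability care).
#'
#' @param events Events in the year (millions).
#' @param post_stock Post-CVD population (millions of person-years).
#' @param params The bundle's cost parameter list.
#' @param adults Adult population (millions).
#' @return Undiscounted cost per adult ($).
#' @export
acute_extended_cost <- function(events, post_stock, params, adults) {
  if (any(c(events, post_stock, adults) < 0)) {
    stop("cost drivers must be nonnegative")
  }
  (params$acute_cost_per_event * events +
     params$extended_cost_per_py * post_stock) / adults
}

#' Productivity cost per adult
#'
#' Lost paid or household work from risk-attributable deaths, disability
#' among the post-CVD population, and hospitalization episodes.
#'
#' @param deaths Attributable deaths in the year (millions).
#' @param events Events in the year (millions).
#' @param post_stock Post-CVD population (millions of person-years).
#' @param params The bundle's cost parameter list.
#' @param adults Adult population (millions).
#' @return Undiscounted cost per adult ($).
#' @export
productivity_cost <- function(deaths, events, post_stock, params, adults) {
  if (any(c(deaths, events, post_stock, adults) < 0)) {
    stop("cost drivers must be nonnegative")
  }
  (params$prod_cost_per_death * deaths +
     params$prod_cost_per_event * events +
     params$prod_cost_per_py * post_stock) / adults
}
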