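---
title: "Model structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdsim)
```

`cvdsim` is a desk-scale compartmental system-dynamics model of
cardiovascular risk in the US population. This vignette documents the
model's structure and assumptions, the synthetic parameter bundle and its
calibration, the numerical conventions, and the known limitations — the
things a reader needs to judge what results from this package do and do
not show.

## Population structure and dynamics

The population is a set of 24 stocks: six age bands (0–1, 2–5, 6–11,
12–17, 18–64, 65+) crossed with sex and CVD status (`non_cvd` /
`post_cvd`). The band boundaries are chosen so that every lever's target
population is expressible (childcare ages 2–5, school ages 6–11,
adolescents 12+, and the under/over-65 split used by the aspirin levers);
children are structurally `non_cvd`.

Time advances in quarter-year steps from 1990.00 to 2040.75. All flows are
simple per-quarter fractions of the source stock (`rate × 0.25`, clipped
to [0, 1]) — explicit Euler stock/flow updating, standard in system
dynamics. There is no sub-quarter integration; rates in this model are
small enough that the discretization error is far below the uncertainty
carried by the parameters. Aging moves `stock/width` per year between
adjacent bands (an exponential-residence approximation; a cohort pulse
reaches the next band after about one band width). Births enter the 0–1
band at a fixed per-capita rate; net migration is a constant per-year
age/sex profile. The 1990 initial stocks and the demographic rates were
set so the simulated 2010 population matches census-scale anchors
(≈ 234.9 M adults 18+, ≈ 295 M aged 2+).

Deaths are split into *background* deaths (not attributable to
cardiovascular risk, removed from stocks but not reported) and
*attributable* deaths — fatal first/recurrent CVD events, chronic
post-CVD deaths, and non-CVD deaths attributable to cardiovascular risk
factors (COPD, renal disease, smoking/diet-related cancers, aggregated
into a single hazard). Only attributable deaths enter the reported death
rate and YPLL.

## Risk factors

Each adult stratum carries *marginal* prevalence vectors per risk
dimension; co-occurrence is deliberately not modeled (this is a
compartmental model of subpopulations, not a microsimulation), and
interactions act on rates instead: a transition's rate is scaled by
`1 + (m − 1)·p_source`, e.g. obesity prevalence raising diabetes onset
(m = 1.8), obesity → hypertension (1.5), smoking → diabetes (1.3),
inactivity → obesity (1.4).

Chain dimensions (blood pressure, cholesterol, glucose: 3 ordered
categories; smoking: never/current/recent-ex/long-term-ex; obesity:
2 categories, also for children 2+) evolve by onset/regression flows.
Smoking recency is resolved as: recent ex-smoker = quit within ~2 years
(recent → long-term at 0.5/yr), relapse only from the recent-ex state, and
no inflow into `never`. Periodontal disease and sleep apnea are listed
risk factors without published transition structures; they are reduced to
*binary exposures* — fixed baseline prevalences moved directly by their
levers — as are distress, inactivity, secondhand smoke, aspirin non-use
and the two diet flags. Sodium, trans fat and PM2.5 are population-level
exposures set directly by their levers.

## Hazards

Hazards combine expected relative risks multiplicatively across
dimensions (the standard comparative-risk form; the within-dimension
expectation is prevalence-weighted):

$$\lambda_h(s,t) = \lambda^0_h(s)\, e^{(\theta + \theta_{65+}\mathbf 1[s \in 65+])(t-2012)} \prod_d \sum_c p_{d,c}(s,t)\, \mathrm{RR}^{\mathrm{eff}}_{d,c,h}(t)$$

A treatment lever attenuates the *excess* relative risk of the categories
it treats: $\mathrm{RR}^{\mathrm{eff}} = 1 + (\mathrm{RR} - 1)(1 - e\,u(t))$, which is exactly 1
for reference categories, keeps multipliers positive, and makes
"all mass in reference categories" give a multiplier of exactly 1.
Exposure and direct-pathway levers multiply hazards by $(1 - e\,u(t))$.
Acute case fatality is a bundle fraction of events, scaled by the CVD
death multiplier; event survivors flow to `post_cvd`, which carries
elevated baseline hazards. The secular trend $\theta$ (plus an extra 65+
term $\theta_{65+}$) stands in for the base-case drift of unmodeled risk
composition; both are calibration targets, not empirical estimates.

The CPAP cascade composes multiplicatively: effective treatment =
diagnosed × owns CPAP × uses it × uses it effectively, so the four levers
share one effect pathway and their recipient pool is billed once.

## Levers, clusters and the ramp

The 50 levers ship as a CSV (one row per published table row; rows marked
non-CVD/post-CVD expand into two levers sharing settings and costs, with
the 2010 recipient pool split 4:1 non/post). Clusters partition the levers
22/12/3/2/3/8. An active lever moves linearly from its initial to its
best-plausible setting over 2012–2017 and holds thereafter; inactive
levers hold their initial setting, which defines the base case. Index
levers are normalized to intensity `u ∈ [0,1]` =
(setting − initial)/(best − initial); decreasing-is-better levers
(workplace smoking, PM2.5, sodium, trans fat) use the magnitude of the
move toward best-plausible. Health responses lag implementation through a
first-order delay per pathway (`du/dt = (ramp − u)/τ`); the per-domain τ
scales are calibrated (care responds within a few years; tobacco-stock
benefits accrue over a decade or more).

The published recipient populations are not always `target ×
setting/100`; the bundle therefore records both and treats the setting as
a quality-adjusted coverage scalar anchored at the printed 2010 recipient
pool, with lever increments proportional to `target × Δsetting/100 ×
uptake`. Consistency is deliberately not forced.

## Costs

Three accounts per adult, constant 2008 dollars, each discounted by
`1.03^-(year − 2012)` from 2012 on (historical years undiscounted):

* **Risk management** — care-lever recipients × unit costs plus a
  calibrated background scale (ancillary visits/labs not itemized as
  levers). The whole account scales with a *managed-prevalence factor*
  `(mi(t)/mi(2010))^k`: `mi` counts adults in non-normal BP/cholesterol/
  glucose categories (plus half-weighted current smokers and obese
  adults), so prevention shrinks the pool needing management. The
  elasticity `k` and an uptake-synergy term (established-care screening
  boosts emerging-service uptake when both care clusters run) are
  calibrated against the published care cost changes.
* **Acute/extended** — the acute/rehabilitation lever's per-event costs
  (billed to this account, not to risk management) plus calibrated
  per-event and per-post-CVD-person-year coefficients.
* **Productivity** — calibrated per-death and per-person-year
  coefficients plus a fixed per-event (hospitalization) term.

Each account also carries a small real intensity trend (technology/
severity drift in constant dollars; the productivity trend is slightly
negative because deaths shift toward post-working ages). "Cumulative"
results over a window are the *means* of annual values, 2012 through the
end year inclusive — this is what makes 2012–2040 base-case costs lower
than 2012–2020 despite growth, via discounting. YPLL is not discounted.

## The synthetic bundle and calibration

The source model's parameter values (demography, transition rates,
relative risks, cost coefficients, and the 89 effect-size distributions)
are not published. The packaged bundle is therefore **synthetic**: every
value is either a field-plausible choice (relative risks at
epidemiological orders of magnitude, NHANES-flavored prevalences) or the
output of the package's own staged calibration, and the bundle metadata
says so. `calibrate()` proceeds in stages, each a deterministic 1-D
monotone bisection or an exact linear solve against run drivers:

1. **Rates** — hazard level and secular trends to the base-case death-rate
   anchors (5.17 and 5.74 per 1,000 adults for the 2020/2040 windows); the
   65+ trend plus a joint adult life-expectancy scale to the YPLL anchors
   (66.7 / 72.1).
2. **Effects** — per-cluster effect-size scales to the published
   established/emerging 2040 medians (loose tolerance: they pin the
   within-domain split), then a per-domain scale to the combined-domain
   2040 medians (within care, only the established side is scaled, because
   the emerging median's printed range is narrow), then per-domain response
   delays to the combined 2020 medians.
3. **Uptake** — recipient-uptake scalars, the uptake synergy, and the
   managed-prevalence elasticity to the published care and lifestyle
   risk-management cost changes.
4. **Costs** — analytic solves for the cost coefficients and intensity
   trends against both base-window levels and the all-clusters 2040
   percent changes, with nonnegativity constraints.

The calibrated constants are frozen into `default_bundle()`, so
calibrating the packaged bundle is approximately a no-op, and a run of the
package never depends on network access or hidden state. Effect-size
uncertainty half-widths are set per cluster (8–40% relative) at the order
of magnitude suggested by the corresponding intervention literatures; the
min/max bounds are `mean × (1 ∓ hw)`.

Window sizes used throughout — 204 quarters, 24 strata, 13 risk
dimensions, 200 PSA draws — keep a single 50-year run well under a second
and a full paired PSA of all scenarios in minutes on one CPU.

## PSA conventions

Each PSA draw samples the 89 effect sizes independently from their
uniform distributions. The paired design evaluates base case and scenario
under the same draw; because the base case activates no levers, its run
is draw-invariant and is computed once. Percentiles use the Hazen
(midpoint) convention — linear interpolation at `h = np + 1/2`
(`quantile` type 5), recorded in the PSA object; with 200 draws the
2.5/97.5 percentiles interpolate between the 5th/6th and 195th/196th
order statistics. Identical seeds give bit-identical summaries.

## What the synthetic-data tests do and do not show

The generator-plus-calibration design means the packaged bundle
*reproduces* published aggregate anchors; passing tests demonstrate that
the simulator's mechanics (conservation, probability bookkeeping, ramp
and discount arithmetic, percentile conventions, monotone lever
responses) are correct and that the calibrated system lands the published
medians within their uncertainty ranges. They do **not** validate the
synthetic parameter values against real surveillance data: relative
risks, transition rates and cost coefficients are stand-ins, the marginal
(non-joint) risk representation cannot capture comorbidity targeting, and
the single aggregate non-CVD death hazard hides disease-specific
dynamics. Race/ethnicity, income and geography are absent by design.
Conclusions about *relative* cluster impacts are the intended use;
absolute projections inherit every calibration assumption. The
uncertainty ranges produced by the packaged half-widths are narrower than
the published ones for some outcomes; only medians are calibrated.

## Numerical choices and degenerate inputs

Per-quarter fractions are clipped to [0, 1]; negative stocks abort with
the offending stratum named. Prevalence vectors are renormalized after
each update and violations beyond 1e-9 abort. `equilibrium_prevalence`
refuses reducible chains (rank test) rather than returning an arbitrary
stationary vector. Calibration bisections are seeded with fixed brackets
and a fixed iteration budget, so calibration is deterministic; where a
target is outside the feasible bracket the nearer endpoint is used and
reported in the residual table. Ties in percentile interpolation cannot
occur (strict linear interpolation); percent change requires a positive
base.
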