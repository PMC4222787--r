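# cvdsim

A compartmental system-dynamics model of cardiovascular-disease (CVD) risk
in the United States population, 1990–2040, built to compare policy
intervention portfolios — clinical and behavioral **care**, tobacco and
air-quality (**air**), and nutrition and physical-activity (**lifestyle**)
levers, each split into *established* and *emerging* interventions — in
terms of deaths, years of potential life lost (YPLL), and per-adult costs.

## The model

The population is segmented into 24 strata: six age bands
(0–1, 2–5, 6–11, 12–17, 18–64, 65+) × sex × CVD status (not-yet vs
already-diagnosed). Stocks advance in quarter-year steps through birth,
background death, net migration, aging, and first-event transitions into
the post-CVD state, with per-quarter fractional flows (rate · Δt, clipped
to [0, 1]).

Each stratum carries marginal prevalence vectors for categorical risk
factors — blood pressure, cholesterol and glucose (normal / borderline /
high), smoking (never / current / recent ex / long-term ex), obesity — plus
binary exposures (distress, periodontal disease, untreated sleep apnea,
inactivity, secondhand smoke, aspirin non-use, poor diet flags) and
population exposures (sodium, trans fat, PM2.5). Cross-factor interactions
act algebraically on transition rates (e.g. obesity raises diabetes onset).

Hazards combine multiplicatively across risk dimensions. For stratum *s*
and hazard *h* (first/recurrent CVD events, CVD death, attributable
non-CVD death):

    lambda_h(s,t) = lambda0_h(s) · e^{theta (t - 2012)} · prod_d ( sum_c p_{d,c}(s,t) · RR_eff_{d,c,h}(t) )

where treatment levers attenuate the excess relative risk of treated
categories, `RR_eff = 1 + (RR - 1)(1 - e·u(t))`, with `e` the lever's
effect size and `u(t)` its 2012–2017 implementation ramp smoothed by a
first-order uptake delay. Death rates and YPLL are reported per 1,000
adults; three cost accounts (risk-factor management, acute/extended care,
productivity) are reported per adult in 2008 dollars discounted 3%/yr to
2012.

The 50 intervention levers (22 + 12 care, 3 + 2 air, 3 + 8 lifestyle) ramp
linearly from their initial to best-plausible settings over 2012–2017 when
their cluster is active. Uncertainty comes from a paired Monte Carlo
probabilistic sensitivity analysis (PSA): 89 effect-size parameters drawn
from uniform (min, max) distributions, 200 draws, with median and
2.5/97.5-percentile summaries of percent changes against the base case.

All parameter values in the packaged bundle are **synthetic**: structured
like the source model's inputs and calibrated so base-case outcomes and
cluster intervention medians match published anchor values, but not a
transcription of any proprietary dataset (see `?default_bundle` and the
methods vignette).

## Worked example

```r
library(cvdsim)

bundle <- default_bundle()
base   <- run_scenario(scenario(), bundle)          # status-quo base case
cmp    <- compare_scenarios(scenario("all"), bundle, base_run = base)
print(cmp)
```

```
Scenario vs base case (care_est + care_emg + air_est + air_emg + life_est + life_emg)

Window 2012-2020 (cumulative averages)
                                 Outcome   Base Scenario Change %
           Death rate (per 1,000 adults)    5.2      3.4    -34.4
            YPLL rate (per 1,000 adults)   66.7     43.9    -34.2
         Risk management costs ($/adult)  612.0   1230.3    101.0
 Acute and extended care costs ($/adult)  636.0    508.4    -20.1
            Productivity costs ($/adult) 2217.0   1593.5    -28.1
                Combined costs ($/adult) 3465.0   3332.2     -3.8

Window 2012-2040 (cumulative averages)
                                 Outcome   Base Scenario Change %
           Death rate (per 1,000 adults)    5.6      2.6    -53.7
            YPLL rate (per 1,000 adults)   71.8     32.9    -54.1
         Risk management costs ($/adult)  490.0   1027.8    109.7
 Acute and extended care costs ($/adult)  539.0    346.4    -35.7
            Productivity costs ($/adult) 1769.0    995.4    -43.7
                Combined costs ($/adult) 2798.0   2369.5    -15.3
```

Activating all six clusters cuts the cumulative 2012–2040 risk-attributable
death rate by about half relative to the base case, while combined
per-adult costs fall by roughly 15%: the large increase in risk-factor
management spending is more than offset by avoided acute care and
productivity losses. With uncertainty:

```r
psa <- run_psa(scenario("all"), bundle, n_draws = 200, seed = 1)
print(psa)   # medians with 95% uncertainty ranges per outcome and window
plot(psa)
```

A thin command-line wrapper is included (`inst/scripts/cvdsim`), e.g.
`cvdsim psa --scenario care_est,care_emg --draws 200 --seed 7 --out psa.csv`.

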