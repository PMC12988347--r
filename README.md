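# dielflux

Day–night (diel) analysis of continuous soil-respiration time series.

Soil respiration (Rs, µmol CO2 m⁻² s⁻¹) — the sum of root and microbial
CO2 efflux — is usually modelled as an exponential function of soil
temperature Ts,

    Rs = Rs0 · exp(β · Ts),      Q10 = exp(10 β),

and nighttime fluxes are often extrapolated from relationships fitted to
daytime measurements. Continuous chamber records show that nighttime Rs is
frequently *higher* than daytime Rs despite cooler nights, most plausibly
because recently fixed photosynthate takes hours to reach roots and
rhizosphere microbes as respiratory substrate, arriving after dark. Under
that mechanism, daytime-fitted temperature relationships systematically
underestimate nighttime fluxes,

    Bias% = 100 · (Rs_pred − Rs_obs) / Rs_obs  < 0.

`dielflux` is for ecosystem ecologists and carbon-cycle modellers working
with hourly chamber flux tables (COSORE-style CSVs). It provides:

* **Solar partitioning** — NOAA-equation sunrise/sunset, midpoint-rule
  day/night labels, sunset-anchored nights, hemisphere-aware seasons.
* **Quality control** — the standard exclusion cascade for chamber data:
  treatments, non-positive fluxes, Tukey-fence outliers, ≥3 h per period
  per day, ≥10 days per month, with a per-rule removal report.
* **Diel analysis** — paired daily day/night means, Student's t-tests,
  period-specific exponential fits (log-scale OLS, optional NLS), Q10,
  and temperature adjustment to the site mean Ts.
* **Extrapolation bias** — nighttime predictions from daytime parameters,
  bias percentages and significance, root vs heterotrophic attribution
  (Rroot = Rs − Rh), and forest-type Pg C extrapolation.
* **Association** — standardized major axis (model-II) regression with
  confidence intervals, cross-site night-vs-day SMA, and 0–45-day
  Rs–GPP lag correlation profiles.
* **Model evaluation** — diel summaries of hourly land-model output
  (GPP = 0 day/night rule, percent nighttime suppression, SMA).
* **A mechanistic synthetic generator** — diurnal temperature harmonics,
  light-driven GPP, a gamma substrate-supply kernel (the photosynthate
  lag), two respiration components with separate temperature
  sensitivities, and multiplicative chamber noise — with recorded ground
  truth, so the whole pipeline is testable against known answers.

## Worked example

Simulate one forest site-summer with an 8-hour photosynthate lag and run
the per-site analysis:

```r
library(dielflux)

cfg  <- generator_config(site_id = "demo", seed = 11)  # lag_mean = 8 h
site <- generate_site(cfg)
res  <- analyze_site(site$series, site$meta)
```

This prints (via the summaries in `res`):

```
night - day Rs: +0.060 umol m-2 s-1 (2.2%), p = 0.0011 [pos]
night - day Ts: -1.79 C
Q10 day = 5.25, night = 9.63 (true component Q10 = 2.0)
night bias from day fit: -29.3% (p = 5.9e-247)
```

Read: nights are 1.8 °C cooler yet respire significantly *more* than days
(+2.2 %), so the excess cannot be a temperature effect. The apparent
fitted Q10s (5.3 day, 9.6 night) sit far above the true component value
of 2.0 because substrate supply co-varies with temperature — Rs0 and Q10
absorb every co-varying driver. Predicting night fluxes from the daytime
fit underestimates them by 29 %.

Batch-level synthesis across sites (`run_pipeline()`) adds the cross-site
SMA of night on day means (slope > 1 when the night excess grows with
flux magnitude), significance-class counts, forest-type summaries ordered
by site temperature, and the Pg C consequence of the nighttime gap.

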