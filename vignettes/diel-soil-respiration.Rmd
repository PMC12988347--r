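---
title: "Diel partitioning of soil respiration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diel partitioning of soil respiration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielflux)
```

## The problem

Soil respiration (Rs, the CO2 efflux from the soil surface, in
µmol CO2 m⁻² s⁻¹) is widely modelled as an exponential function of soil
temperature,

$$R_s = R_{s0}\, e^{\beta T_s}, \qquad Q_{10} = e^{10\beta},$$

and nighttime fluxes are routinely *predicted* from relationships fitted to
daytime data, because chambers, gap-filling schemes and upscaling products
are all biased toward daylight hours. That practice is only safe if the
day and night flux regimes differ by temperature alone. Continuous chamber
records suggest they do not: nighttime Rs is frequently *higher* than
daytime Rs even though nights are cooler, plausibly because recent
photosynthate takes several hours to travel from the canopy to roots and
rhizosphere microbes, arriving as respiratory substrate after dark.

`dielflux` implements the full analysis chain for interrogating this
question on hourly chamber series — solar day/night partitioning, a
quality-control cascade, period-specific temperature-response fits,
temperature adjustment, nighttime-extrapolation bias, component
attribution, model-II regression and GPP lag profiles — together with a
mechanistic synthetic-data generator so that every stage can be validated
against a known ground truth.

## The synthetic generator

`generate_site()` builds an hourly site-summer from, per hour $t$ (solar
time internally, site standard time in the output):

* soil temperature: $T_s(t) = \bar T + A \sin\!\big(2\pi (t - 6 - \phi)/24\big)$,
  with half-amplitude $A$ (`ts_amplitude`, default 2 °C — typical damping
  at 5 cm under a forest canopy) and phase $\phi$ (`ts_phase_lag`, default
  3 h: the 5-cm peak trails solar noon);
* canopy uptake: $\mathrm{GPP}(t) = G_{max}\, m_d \max(0, \sin e(t))$ with
  solar elevation $e(t)$ and a lognormal AR(1) day-to-day multiplier $m_d$
  (mean 1, CV `gpp_day_cv` = 0.25, autocorrelation `gpp_day_ar1` = 0.6 —
  synoptic weather memory);
* substrate supply: $S(t) = \sum_\tau k(\tau)\,\mathrm{GPP}(t-\tau)$, a
  discretised gamma kernel with mean `lag_mean` (default 8 h, the
  mixed-forest transport-lag scale reported in field studies) and shape
  `lag_shape` (default 12), unit mass over 0–48 h;
* respiration: $R_{root} = b_r S e^{\beta_r T_s}$,
  $R_h = b_h (1 + p S) e^{\beta_h T_s}$, both at $Q_{10} = 2$ by default;
* observation: $R_s = (R_{root} + R_h)\,\varepsilon$, with multiplicative
  lognormal noise of mean 1 and CV `noise_cv` (default 0.10, the
  heteroscedastic, strictly positive error structure of chamber data).

The gamma kernel is a design choice: field estimates give a lag scale but
no functional form, and a gamma is the simplest positive unimodal kernel
whose centre and width are independently controllable. `night_base_factor`
multiplies the basal flux while the sun is below the horizon; it exists to
create *known* diel asymmetries with a closed-form expected extrapolation
bias of $100(1/f - 1)$ %, used in validation.

With the defaults, the generated summers show a night-minus-day flux
excess of roughly +3–5 %, apparent (fitted) day/night Q10 of ~5/~10 —
inflated above the true component value of 2 because substrate co-varies
with temperature, which is precisely the confounding the analysis is
designed to expose — and a nighttime extrapolation bias around −30 %.
These sit in or near the ranges continuous chamber databases produce.

### What the generator does not emulate

Instrument drift and step changes, rain-pulse (Birch) effects, soil
moisture limitation of the temperature response, snow, phenology drift
across the season, chamber-to-chamber spatial variance, and xylem
transport of dissolved CO2 (a second proposed mechanism for elevated
nighttime flux that has no agreed equations and is deliberately not
simulated). Passing tests therefore demonstrate that the *pipeline*
recovers known truths under realistic noise — not that any particular
field site obeys this model.

### The null configuration

`null_config()` defines the no-mechanism reference used for false-positive
control. Two details matter. First, with the generator's equations a
"lag of zero" is *not* a diel null: $S(t)$ collapses onto GPP itself,
which is strictly a daytime quantity, so the substrate pathway must be
switched off entirely (`gpp_max = 0`, `base_root = 0`). Second, the
temperature harmonic is given a phase of 6 h (peak at 18:00 solar) at an
equatorial site: the day window then sweeps exactly the same distribution
of temperatures as the night window, so *any* function of temperature —
including the exponential — has equal day and night means, and the
expected diel difference is exactly zero. Under this configuration the
paired day-night test rejects at close to its nominal 5 % level.

## Analysis conventions and numerical choices

* **Day/night**: an hour belongs to the day when its midpoint falls in
  [sunrise, sunset), computed from the NOAA solar-position equations at
  zenith 90.833° (refraction plus solar radius). The midpoint rule is
  unambiguous for bins straddling the terminators. Nights are
  sunset-anchored: the "night of date d" runs sunset(d) → sunrise(d+1),
  which defines the pairing unit for the paired t-tests. Polar dates
  raise an error naming the date rather than guessing.
* **Season**: summer is June–August in the Northern Hemisphere,
  December–February in the Southern, selected on the night-anchored date.
* **QC cascade**, in order: treatment exclusion; non-positive Rs; Tukey
  fences [Q1 − 1.5 IQR, Q3 + 1.5 IQR] with type-7 (linear-interpolation)
  quantiles computed on the analysed subset; ≥3 valid day **and** ≥3 valid
  night hours per diel date; ≥10 surviving days per calendar month.
  Fences are applied once, as in standard practice; recomputing them on
  the filtered output can remove a handful of further rows, so the
  cascade is idempotent for the coverage rules and idempotent to within
  ~0.1 % of rows for the outlier rule.
* **Temperature fits**: ordinary least squares on
  $\ln R_s = \ln R_{s0} + \beta T_s$ is the default estimator — closed
  form, and exactly matched to multiplicative lognormal noise. A
  nonlinear least-squares refit on the natural scale (initialised from
  the log fit) is available; the two agree within 5 % in Q10 at chamber
  noise levels. Fits require ≥30 hours and non-degenerate temperature
  (zero variance errors out). $Q_{10} = e^{10\beta}$ is exact by
  construction.
* **Temperature adjustment**:
  $R_s^{adj} = R_s \times Q_{10}^{(\bar T_s - T_s)/10}$ with the
  period-matched Q10 and the site mean summer soil temperature as
  reference. One caveat is worth knowing: the fitted Q10s carry
  estimation error, which propagates into the adjusted day and night
  means as a per-site random offset comparable to the paired-test
  standard error. Within a single site the "adjusted difference" test is
  therefore anti-conservative; across sites these offsets are independent
  and mean-zero, so cross-site comparisons of adjusted fluxes — which is
  how the adjustment is used here — are well calibrated.
* **Extrapolation bias**: daytime parameters applied to nighttime
  temperatures, $\mathrm{Bias}\% = 100(\bar R_{pre} - \bar R_{obs})/\bar R_{obs}$
  on the *means* of hourly values (the aggregate form, not a mean of
  ratios); negative = underestimation. Component attribution derives
  root respiration as $R_{root} = R_s - R_h$ (trenching convention),
  drops negative-root hours (rejecting sites where they exceed 20 %),
  and fits each component separately. Because a sum of exponentials is
  not the exponential of the sum, component bias fluxes add to the total
  only approximately (≈2 % relative on noiseless data); the observed
  parts add exactly.
* **Global scaling**: flux gap × forest-class area × seasonal night
  seconds × 12 g mol⁻¹ × 10⁻⁶ × 10⁻¹⁵ Pg g⁻¹. Areas are configuration
  constants of the magnitude given by coarse land-cover products; night
  duration defaults to 92 × 12 h and should be replaced by the solar
  module's class mean when site locations are known.
* **SMA regression**: slope $= \mathrm{sign}(r)\, s_y/s_x$, the model-II
  estimator appropriate when both axes carry error; 95 % CI via
  $b(\sqrt{B+1} \pm \sqrt B)$, $B = F_{0.95;1,n-2}(1-r^2)/(n-2)$.
  Identities tested: $b_{y\sim x} b_{x\sim y} = 1$ and
  $b = b_{OLS}/|r|$.
* **Lag profiles**: Pearson $r$ between daily Rs and GPP shifted 0–45
  days; ties at the peak go to the smallest lag (parsimony); lags with
  <10 pairs are NA. The 0.2 "no stable peak" screening level is scale
  dependent — it is comfortably above the null maximum for year-length
  series but approaches it near ~200 days, where the maximum of 46 null
  correlations has standard scale $\approx 1/\sqrt{n}$ each.
* **Model evaluation**: day/night in model output follows the GPP = 0
  rule, with a 10⁻⁶ µmol m⁻² s⁻¹ epsilon absorbing floating-point zeros;
  the split agrees with the astronomical one on ≥95 % of hours for the
  synthetic driver.

## Problem sizes used in the tests

Validation runs use single site-summers of 92 days × 24 h (≈2,200 hours),
30 replicate summers for Q10 recovery, 200 null seeds for false-positive
control, 100 seeds for the mechanism-sign and lag-null checks, and
15-site batches for the cross-site regressions — sizes at which the
relevant sampling distributions are well resolved while a full validation
sweep completes in well under a minute each.

## Known limitations

The pipeline assumes hourly (or finer) chamber data with concurrent soil
temperature; it performs no gap-filling, no turbulence screening, and no
partitioning of eddy-covariance fluxes (daily GPP is consumed as given).
The equal-weight port averaging is a declared convention, not an inferred
one. The apparent Q10 is an integrated diagnostic, not an intrinsic
kinetic parameter — in both the generator and the field it absorbs every
driver that co-varies with temperature, which is exactly why day- and
night-specific fits differ and why daytime extrapolation goes wrong.
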