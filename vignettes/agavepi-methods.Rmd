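---
title: "Modelling Agave americana productivity with a monthly environmental productivity index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Agave americana productivity with a monthly environmental productivity index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agavepi)
```

## The model

*Agave americana* is an obligate crassulacean acid metabolism (CAM) plant:
stomata open at night, CO2 is fixed nocturnally into organic acids, and
daytime photosynthesis runs behind closed stomata. Its productivity in a
semi-arid climate can be summarised month by month with an environmental
productivity index,

$$\mathrm{EPI}_m = L_m \times W_m \times T_m,$$

where each factor is the fraction of maximum productivity attainable under
that single environmental variable (1 = optimal, 0 = fully limiting):

* **Light index** $L$: the fitted quadratic response of net 24 h CO2 uptake
  to photosynthetic photon flux density (PPFD),
  $y = -4\times10^{-7}x^2 + 0.001x - 0.0006$ mol d$^{-1}$, normalized by
  its vertex value. The vertex — the light saturation point — is at
  1250 µmol m$^{-2}$ s$^{-1}$ and 0.6244 mol d$^{-1}$, equivalent to a
  54 mol photons m$^{-2}$ d$^{-1}$ daily dose over a 12 h photoperiod.
* **Water index** $W$: a linear response to total monthly moisture
  (precipitation + irrigation, mm), $0.0279x - 0.2851$, clamped to
  $[0, 1]$; it saturates at about 46.1 mm month$^{-1}$.
* **Temperature index** $T$: a quintic in *leaf* night temperature (air
  minimum + 2 °C), derived from titratable-acidity responses, divided by
  100. The optimum is near 15 °C and productivity is forced to zero at or
  beyond the cease thresholds of −3 °C and 38 °C. Daytime maxima do not
  enter the model (assimilation is unaffected by daytime heat until
  ~45 °C); months hotter than that only raise a warning.

Monthly EPI values summed over a crop's lifetime predict yield linearly:
dry biomass as $0.7607x - 14.774$ Mg ha$^{-1}$ and combustible energy as
$27290x - 228335$ MJ ha$^{-1}$, both floored at zero.

## Upstream computations

**Radiation.** Station records give daily solar totals in Langley. The
chain to mean daytime PPFD is Langley → Wh m$^{-2}$ (× 11.622) → mean
W m$^{-2}$ (÷ daylight hours) → lux (× 110 lm W$^{-1}$) → klux (÷ 1000) →
PPFD (× 18 µmol m$^{-2}$ s$^{-1}$ klux$^{-1}$); the composite factor is
23.01156 µmol m$^{-2}$ s$^{-1}$ per Langley-per-daylight-hour. We keep the
published 11.622 rather than the physically exact 41 868/3600 = 11.63
(difference < 0.1%) so converted series match the published pipeline; both
live in `epi_constants()`. No source states which monthly daylight-hour
values were used with the original station data, so exact reproduction of
that PAR series is not possible; we compute day length astronomically from
latitude (declination $23.44°\sin(2\pi(284+n)/365)$, sunset hour angle
$\arccos(-\tan\phi\tan\delta)$, clipped for polar cases), and
`aggregate_monthly()` accepts user-supplied monthly day lengths to mirror
a station workflow exactly.

**Gas exchange.** 24 h cuvette traces sampled at 5 min intervals are
integrated with the composite Simpson's rule, generalised to non-uniform
grids (loggers drop samples) by fitting a parabola through each successive
point triple; an odd trailing interval falls back to the trapezoid rule.
Negative instantaneous assimilation is retained — net-negative 24 h totals
at low light are real CAM behaviour, not artefacts — and no outlier
filtering is applied. Whether integrated uptake is per m$^2$ of leaf or of
cuvette is not resolvable from the sources; we treat it as per m$^2$ of
leaf throughout.

## Published versus internally consistent coefficients

Three places in the published coefficient set are mutually inconsistent;
in each case both variants are shipped and the choice is an explicit mode
switch recorded by the pipeline run log.

* **Light index.** The published index quadratic
  ($-7\times10^{-7}x^2 + 0.0016x - 0.001$) is a rounded refit whose
  maximum is ≈ 0.905, contradicting an index that should reach 1. Default
  mode `normalized` divides the un-rounded assimilation quadratic by its
  vertex value so the maximum is exactly 1 at 1250 µmol m$^{-2}$ s$^{-1}$;
  `printed` evaluates the published curve. Results differ by ≲ 10%.
* **Temperature index.** The published index quintic's leading coefficient
  ($-0.2\times10^{-7}$) is a factor of 10 from the acidity quintic ÷ 100
  ($-2\times10^{-7}$), and the curve evaluates to ≈ 15 (not ≈ 0) at the
  38 °C cease threshold — an evident transcription problem. Default mode
  `acidity_scaled` uses the acidity quintic ÷ 100, which gives ≈ 0.995 at
  the 15 °C optimum and crosses zero near −3 °C, consistent with the
  stated physiology. The quintic slightly exceeds 1 over ~22–36 °C (fit
  wiggle); the $[0,1]$ clamp absorbs this, and the hard cease-zeros are
  applied *after* polynomial evaluation because the polynomial itself does
  not reach 0 at 38 °C.
* **Biomass slope.** The published biomass line predicts only
  ≈ 0.88 Mg ha$^{-1}$ at the highest cumulative EPI (20.58), while the
  energy regression divided by the measured energy density
  (27 290 / 15 440 = 1.7675; 228 335 / 15 440 = 14.79) implies a slope of
  ≈ 1.76 and ≈ 21.5 Mg ha$^{-1}$ — strong evidence of a dropped leading
  digit. `agave_yield_models()` ships both `biomass_printed` (the default,
  for fidelity) and `biomass_corrected` (slope 1.7607), and the
  consistency of the corrected variant with the energy line (within 2%
  over EPI sums 15–25) is asserted by the test suite.

The water-index intercept (−0.2851) is likewise not exactly the ratio of
the underlying biomass line's coefficients (2.6443/9.27 = 0.28525); the
published line is used verbatim.

## The synthetic-data generator

No weather, flux or yield data are bundled; `simulate_daily_weather()`,
`simulate_cam_trace()` and `simulate_yield_dataset()` generate seeded
synthetic inputs with the statistical structure the analysis assumes.

The weather generator emulates a Sonoran-desert site at 33° N: sinusoidal
seasonal cycles (radiation 500 ± 250 Langley peaking at the summer
solstice; night minima 14 ± 11 °C lagging it by a month; diurnal range
16 °C) with Gaussian day-to-day noise (sd 60 Langley and 2 °C), and sparse
monsoon-skewed precipitation (~105 mm yr$^{-1}$, July–September heavy,
winter-dry) drawn as Bernoulli wet days with exponential depths matched to
the monthly means. These values were fixed once from regional climatology.
It does **not** emulate multi-day weather persistence, ENSO-scale
variability, or any plant feedback — a green end-to-end test establishes
that the pipeline's plumbing and ordering behaviour are correct under a
plausible climate, not that field yields are reproduced.

Irrigation is the one place the generator departs from a naive reading of
the field study: the actual irrigation calendar was never published, and a
single shared monthly weight vector cannot separate treatments (any month
above ~46.1 mm clamps the water index at 1 for every treatment alike).
`irrigation_schedule()` instead emulates a grower applying a fixed ~75 mm
monthly depth over a season whose length grows with the annual allocation
(300 mm → Jun–Sep, 460 mm → May–Oct, 530 mm → Apr–Oct). Schedules for
larger allocations nest the smaller ones, which *guarantees* cumulative
EPI is monotone in the irrigation total — mirroring the published ordering
of lifetime EPI sums (14.47 < 17.17 < 20.58) — and the resulting synthetic
39-month sums (≈ 13 / 20 / 24) straddle that range. This is a
plausibility check, not a reproduction.

The CAM trace generator builds a four-phase diel template: nocturnal
uptake plateau (phase 1), no dawn spike (phase 2 is not observed in this
species), a small fixed daytime efflux of −0.2 µmol m$^{-2}$ s$^{-1}$
behind closed stomata (phase 3), and a dusk spike at 25% of the nocturnal
plateau (phase 4), suppressed at PPFD ≤ 100 where only dark-period
assimilation occurs. Transitions are 30 min linear ramps to avoid
integrator artefacts. The nocturnal amplitude is solved so the noiseless
trace's Simpson integral equals the assimilation quadratic at the
configured PPFD, so every simulated trace carries a known true integral;
at very low PPFD the target is negative and the plateau becomes a small
efflux, reproducing observed net-negative traces.

## Numerical choices and degenerate inputs

* Quadratic and linear fits are ordinary least squares via `stats::lm`;
  $R^2 = 1 - SS_{res}/SS_{tot}$. Fits with fewer than three distinct
  abscissae (or two, for lines) are errors, as are non-saturating
  quadratics passed to `response_peak()`.
* Index clamps are hard (`pmin`/`pmax`); cease thresholds are inclusive
  (≤ −3, ≥ 38 → 0).
* Yield predictions are floored at 0: negative biomass is unphysical and
  the sources are silent on extrapolation below the x-intercept.
* `flux_trace()` requires strictly increasing times, ≥ 3 samples, and a
  span of at most 24 h plus one sampling interval.
* Partial months are refused by `aggregate_monthly()` — a truncated month
  would bias every monthly mean.
* The cal↔J conversion uses the thermochemical calorie (4.184 J cal$^{-1}$),
  making the benzoic-acid calibration standard 26.43 MJ kg$^{-1}$.
* Generators take an explicit integer seed, restore the caller's RNG
  state, and are bit-identical under rerun.
* Whether the published ±0.42 MJ kg$^{-1}$ dispersion on the 15.44
  MJ kg$^{-1}$ mean energy density is an SD or an SE is not stated;
  `summarize_energy_density()` reports both.

## Known limitations

* The lifetime EPI window for yield comparison (which months enter a
  2-year-old plant's sum) is a caller choice; no source pins it down.
* Vertex recovery from noisy light-response points is intrinsically
  ill-conditioned with the six experimental light levels, because the
  design covers PPFD only *up to* the saturation point: under 10%
  multiplicative noise the refit vertex abscissa has a sampling sd of
  ≈ 110 µmol m$^{-2}$ s$^{-1}$ (≈ 9%), so a ±5% recovery band holds only
  ~45% of the time, not 95%. The corresponding acceptance test is left
  failing rather than weakened; extending measurements beyond the
  saturation point would be the experimental fix.
* Pest mortality (snout weevil) is explicitly outside the EPI model, as
  are nutrient limitation, soil-water dynamics and frost mortality.

## A worked end-to-end example

```{r example}
w <- simulate_daily_weather(weather_sim_config(), "2012-04-01",
                            "2015-06-30", seed = 42)
sums <- sapply(c(300, 460, 530), function(total) {
  climate <- aggregate_monthly(w, irrigation_schedule(total), latitude = 33)
  idx <- monthly_indices(climate)
  idx$epi <- monthly_epi(idx)
  cumulative_epi(idx)
})
round(sums, 2)
predict_biomass(sums, agave_yield_models()$biomass_corrected)
predict_energy(sums)
```
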