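---
title: "From chamber closures to drivers: the tundraflux methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From chamber closures to drivers: the tundraflux methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundraflux)
```

tundraflux implements the computational chain used to quantify the
atmospheric methane sink of well-drained Arctic tundra soils from
automated-chamber measurements: closure-curve flux estimation, physically
motivated quality control, diel and daily aggregation, and attribution of
flux variation to abiotic and biotic drivers. Because the real
measurement campaign cannot be re-run at a desk, the package ships a
seeded synthetic-campaign generator with known ground truth, so every
downstream stage is testable end to end.

## The measurement model

A static chamber seals a soil footprint for a short closure (3 min for
the automated system, 5 min for manual surveys) while a high-precision
analyser records headspace concentrations at 1 Hz. The surface flux is
the initial rate of change of the headspace mole fraction, scaled to a
per-area mass rate with the ideal gas law:

$$F = \frac{dC}{dt}\bigg|_{t=0} \cdot \frac{PV}{RT} \cdot \frac{M}{A}
\cdot 3600 \cdot 10^{3}$$

with $F$ in mg m$^{-2}$ h$^{-1}$ (negative = uptake), $dC/dt$ as mole
fraction s$^{-1}$, $P$ pressure (Pa), $V$ the effective chamber volume
(m$^3$, 30--45 l for this chamber design), $T$ chamber air temperature
(K), $M$ the molar mass (16.04 g mol$^{-1}$ CH$_4$, 44.01 g mol$^{-1}$
CO$_2$) and $A$ the collar footprint (m$^2$; 0.204 m$^2$ for a 51-cm
dome).

Two estimators of the initial slope are available:

* **Linear** (`fit_linear()`): OLS of concentration on time. Preferred
  for CH$_4$, whose headspace change over 3 min is small (a few ppb), so
  curvature is rarely identifiable against 1 ppb analyser noise.
* **Saturating exponential** (`fit_exponential()`):
  $C(t) = \varphi + (C_0 - \varphi)e^{-\kappa t}$, the single-exponential
  headspace model in which the accumulating (or depleting) concentration
  feeds back on the diffusion gradient. The flux derives from the initial
  slope $\kappa(\varphi - C_0)$, back-extrapolated to lid close when a
  dead-band was trimmed. Preferred for CO$_2$, whose large gradients make
  the feedback visible within 3 min.

`select_fit()` arbitrates per gas: CH$_4$ stays linear unless the
exponential flux magnitude exceeds a threshold (default
0.05 mg m$^{-2}$ h$^{-1}$) *and* the exponential fit has smaller AICc;
CO$_2$ uses the exponential unless $\kappa$ is not significantly positive
(one-sided z at 5%). The threshold default was chosen so that typical
uptake rates (0.02--0.04 mg m$^{-2}$ h$^{-1}$) remain linear; it is a
configuration knob, not a measured constant, because the operational
value used in the field system is not public.

### Numerical choices in the exponential fit

Near-linear traces place the fit on a flat ridge in $(\varphi, \kappa)$:
the data constrain only the product $\kappa(\varphi - C_0)$, and a joint
Levenberg--Marquardt start from rough guesses can stall far from the
optimum while satisfying its convergence tests. The model is linear in
$(C_0, \varphi)$ for fixed $\kappa$, so the implementation first profiles
the 1-D residual sum of squares over $\log\kappa \in [\log 10^{-6},
\log 1]$, solves the conditional linear least squares, and only then
polishes with `nlsLM` (tight `ftol`/`ptol`, $\kappa$ bounded in
$(10^{-6}, 1)$ s$^{-1}$). Noiseless synthetic traces are then recovered
to near machine precision, and the $\kappa \to 0$ limit agrees with the
linear estimator. A non-converging fit is flagged
(`exp_fit_failed`) and selection falls back to linear; nothing raises.

Other per-closure conventions: the first 20 s after lid close are
discarded (mixing transient; the exact field value is not public, so
this is configurable), and at least 30 usable samples are required —
closures below that produce a flagged, non-computed flux rather than a
zero.

### NEE partitioning

Opaque chambers measure ecosystem respiration (ER) directly. Per
vegetation type and hour, ER is the mean CO$_2$ flux of the three opaque
chambers; transparent chambers measure net ecosystem exchange and
GPP = NEE − ER. Hours without opaque partners give missing GPP, never
zero.

## Quality control

Two filters mirror the field protocol (`apply_qc()`):

* **Pressure consistency**: chamber line pressures run at 7--8 kPa;
  closures with |inflow − outflow| > 2 kPa or either line outside
  [4, 12] kPa are discarded. The band and tolerance are package defaults
  (the operational criterion is not public) and fully configurable.
* **Turbulence**: fluxes measured between 23:00 and 07:00 local standard
  time are discarded when u* < 0.15 m s$^{-1}$ *and* wind speed (7 m)
  < 1.50 m s$^{-1}$. The window is half-open [23:00, 07:00), and the two
  calm indicators are combined with logical AND — the rule names both
  conditions together, and requiring both is the conservative reading
  that discards least data. Both choices are configurable.

QC reports per-gas, per-filter discard percentages and is idempotent.

## Aggregation

* **Daily sums** (`hourly_to_daily()`): 24 hourly values summed per
  chamber-day; gaps shorter than 12 h are linearly interpolated (constant
  extension at day edges); days missing 12 h or more are reported missing.
* **Diel composites** (`diel_composite()`): mean/sd/n per vegetation ×
  season class × hour, pooling transparent and opaque chambers. June is
  early summer, July peak, August late; May/September are shoulder and
  excluded.
* **WFPS**: $100\,\theta_v / (1 - BD/PD)$ with particle density
  defaulting to 2.65 g cm$^{-3}$ for mineral soil; values beyond
  saturation clip to 100% with a warning.
* **Daytime-only bias** (`daytime_bias()`): manual campaigns typically
  visit plots between 11:00 and 15:00, so the default window is
  [11:00, 15:00). For each fully covered chamber-day the window mean is
  scaled to 24 h and compared with the true daily sum as
  $100(\hat{F}_{24} - F_{24})/F_{24}$. Because uptake sums are negative,
  this expression is positive exactly when the daytime-only protocol
  overestimates uptake magnitude — the intended sign convention; dividing
  by $|F_{24}|$ instead would flip the sign for uptake days. Days with
  near-zero daily sums are excluded (bias undefined) with a warning.

## Driver attribution

* **Random forests** (`fit_rf()`): regression forests
  (`randomForest`, 500 trees by default), importance as the average
  increase in node purity (SSE reduction), variance explained from
  out-of-bag error — the standard outputs of this estimator family.
  The candidates-per-split parameter is tuned per model by out-of-bag
  grid search (`tune_candidates_per_split()`). Correlated predictors are
  retained with a collinearity warning, since depth-resolved soil
  profiles are informative despite correlation.
* **Per-chamber models** (`per_chamber_models()`): a two-predictor model
  (surface soil temperature, surface WFPS) per chamber × season class
  controls for microsite heterogeneity; cells under 50 complete rows are
  skipped.
* **Added variance from ER** (`added_variance()`): the gain in OOB
  variance explained when ER joins the two abiotic predictors, on
  identical rows with paired seeds. Two numerical choices protect the
  comparison from a known artefact: both models use every predictor as a
  split candidate (so an uninformative extra predictor is out-competed
  rather than forced into one third of the splits), and terminal nodes
  hold at least 30 observations (fully grown trees eventually split on
  noise predictors near the leaves, which deflates the extended model's
  OOB score by several points even when the extra predictor is pure
  noise). With these settings a shuffled ER column changes the explained
  variance by only a few points, while a generatively coupled ER adds a
  large positive increment.
* **Transfer entropy** (`transfer_entropy()`, `te_lag_scan()`): lagged
  information flow from a driver to the flux,
  $TE = I(y_t; x_{t-\ell} \mid y_{t-1})$, with both series discretized
  into 3 quantile bins and plug-in entropies (history length 1). These
  estimator settings are conventional for hourly ecological series and
  configurable, as the field analysis does not publish its own.
  Significance uses circular block-shuffled surrogates of the source
  series with 24-sample blocks: a full day per block preserves diel
  autocorrelation inside each block, so shared diel cycles alone cannot
  produce spurious significance; a lag is flagged when its TE exceeds the
  surrogate 95th percentile. Negative plug-in estimates clip at zero.
* **Flux--ER regression** (`uptake_er_regression()`): per-chamber OLS of
  CH$_4$ flux on ER, opaque chambers only (they measure ER directly),
  optionally split by light period (PAR < 100 µmol m$^{-2}$ s$^{-1}$).

## Group statistics

For campaign-style manual surveys: Welch's two-sample t (Satterthwaite
df, two-tailed) and Kruskal--Wallis with Dunn's pairwise post hoc tests
(pooled mid-ranks, tie correction, Holm step-down adjustment by default —
the adjustment method used in the original analysis is unnamed, and
Benjamini--Hochberg is selectable). For pooled samples of 10 or fewer
the omnibus p-value comes from the exact permutation distribution of H
rather than the chi-square approximation, which is not reliable at those
sizes. The compact letter display assigns one letter per maximal clique
of the "not significantly different" graph, so any two groups sharing a
letter are mutually indistinguishable at the chosen level.

## What the synthetic generator emulates

`simulate_campaign()` reproduces the design of the field campaign: 18
chambers (6 per vegetation type: lichen, shrub, tussock; 3 opaque + 3
transparent each), hourly closures over a ~90-day season (DOY 150--243),
1 Hz analyser sampling with 1 ppb CH$_4$ / 300 ppb CO$_2$ noise and a
bounded 24-h drift of 5 ppb re-anchored daily. The hourly truth model
encodes the behaviours the analysis stages must recover:

* lichen and shrub are persistent sinks with mean uptake near 0.02
  mg CH$_4$ m$^{-2}$ h$^{-1}$, increasing as soil dries (multiplicative
  moisture term in WFPS);
* the diel uptake peak sits near 15:30 in June and migrates to ~01:30 by
  August (a seasonally weighted mixture of two circular bumps);
* uptake couples multiplicatively to ER anomalies, and ER itself carries
  a temperature-independent substrate-supply component (slow AR(1)
  pulses) — respiration is deliberately not a pure temperature function;
* surface soil temperature acts with a 2-h lag (Q10-style multiplier);
* tussock switches to emission only when WFPS at 30 cm exceeds 80%
  (wet episodes after rain);
* meteorology provides a high-latitude photoperiod (PAR < 100 µmol
  m$^{-2}$ s$^{-1}$ between 23:00 and 06:00 despite midsummer daylight),
  calm night episodes that exercise the turbulence filter, and
  rain-driven soil rewetting with dry-downs between events.

Ambient baselines (1,950 ppb CH$_4$, 420 ppm CO$_2$) are conventional
northern-hemisphere values, configurable because site-specific baselines
are not published. All randomness derives from one top-level seed
through a fixed splitting scheme, so campaigns regenerate bit-identically.

The generator is statistical, not mechanistic: it contains no soil-gas
diffusion physics, no radiative transfer, no plant phenology, and its
noise is Gaussian and stationary. Passing tests therefore demonstrate
that the estimators recover known structure under realistic noise and
confounding — not that real data are free of artefacts the generator
does not model (advection under snow, sensor drift beyond spec, animal
interference, power loss).

## Problem sizes and tolerances

The test suite exercises full 94-day campaigns for the aggregate
properties and shorter 6--40-day campaigns where closure-level refitting
is involved; the round-trip accuracy checks use 1,000 closures spanning
±0.2 mg m$^{-2}$ h$^{-1}$, the transfer-entropy null calibration uses
200 independent pairs of length 1,000 with 100 surrogates each, and the
driver-recovery checks use 20 seeded campaigns. These sizes were chosen
so that the stochastic assertions have comfortable margins under their
binomial variability. The demo pipeline (`run_pipeline()`) defaults to a
14-day season so that fitting both gases for every closure remains a
light operation.

## Known limitations

* CO$_2$ exponential-selection uses a z-test on $\kappa$; very short or
  very noisy closures can produce unstable $\kappa$ standard errors, in
  which case the linear fallback applies.
* The daytime-bias estimator requires full diel coverage per day, so it
  is computed on reference (pre-QC) data; applying it after turbulence
  filtering would discard most days.
* Transfer entropy with 3 bins and history 1 detects lagged dependence
  but does not estimate its magnitude on a physical scale, and slow
  synoptic coupling spreads significance across neighbouring lags.
* Water-vapour dilution corrections are assumed handled by the analyser,
  as in the instrument deployed in the field.
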