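---
title: "Methods: the TOPMODEL wetland-extent diagnostic, its calibration and projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the TOPMODEL wetland-extent diagnostic, its calibration and projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topwet)
```

## The model

topwet diagnoses the wetland (saturated) area of a drainage basin from its
basin-mean column soil moisture and the empirical distribution of the
compound topographic index (CTI) over its pixels. The chain has four steps,
applied per aggregation window:

1. **Water-table depth.** The basin-mean depth to the water table is taken
   as the saturation deficit of the soil column,
   $\mathrm{WTD} = D\,(1 - \mathrm{SM}/\mathrm{SM}_{sat})$, clipped to
   $[0, D]$. $D$ is the column depth (default 2 m, a 0–200 cm column) and
   $\mathrm{SM}_{sat}$ the column's saturation value in kg/m² (default
   900 kg/m² = porosity 0.45 × 1000 kg/m³ × 2 m). A saturated column puts
   the water table at the surface; an empty one at the column bottom. Both
   $D$ and $\mathrm{SM}_{sat}$ are configuration, not constants: if a
   different pedotransfer choice is preferred, only these two numbers
   change.

2. **CTI threshold.** Under the exponential-transmissivity TOPMODEL
   relation, a pixel is saturated when its CTI deviates above the basin
   mean by at least $M \cdot \mathrm{WTD}$:
   $\mathrm{CTI}^\* = \overline{\mathrm{CTI}} + M\,\mathrm{WTD}$.
   $M$ (here integer 1–15) is the transmissivity-decay parameter: larger
   $M$ makes saturation probability fall off faster with depth, shrinking
   the wetland for a given WTD.

3. **Saturated fraction.** $f = \Pr(\mathrm{CTI} \ge \mathrm{CTI}^\*)$,
   evaluated on the basin's empirical pixel distribution. The comparison is
   inclusive — a pixel exactly at the threshold is saturated. An optional
   per-basin cap `f_max` supports the capped variants of this diagnostic;
   by default no cap is applied. Note the plateau behaviour: at
   $\mathrm{WTD} = 0$ the threshold equals the mean CTI, so the maximum
   diagnosed wetland is the pixel fraction at or above the basin-mean CTI,
   not the whole basin — full saturation of the *mean* column does not
   flood every pixel.

4. **Area.** Wetland area $= f \times$ basin land area (km²).

Aggregation order matters: soil moisture is averaged over the window
(a mapping period, or a calendar year in projections) *first*, then pushed
through the nonlinear chain — one area per window, because calibration
compares against one observed map per period.

The chain is monotone by construction — wetter columns give shallower water
tables, lower thresholds and larger wetlands — and the test suite asserts
this, together with the bounds $f \in [0,1]$,
$\mathrm{WTD} \in [0, D]$, area $\in [0, \text{basin area}]$, on randomized
inputs.

## Calibration

`calibrate_wetlands()` fits one $M$ per basin by exhaustive grid search:
for each $M \in \{1, \dots, 15\}$ the forward chain is run over the
historical periods with the calibration soil moisture, and the $M$
minimising the RMSE (in km², on areas rather than fractions) against the
observed per-period areas is returned, ties broken toward the smallest $M$
(deterministic, and parsimonious in the sense of the weakest topographic
control). No continuous refinement is attempted — the parameter is defined
on this 15-point grid. Periods with missing observations are dropped and
`n_periods_used` is recorded; basins with no observations at all land in an
exceptions table rather than aborting the fit. Basins are processed
independently, so the result is order-independent and trivially resumable.

The returned `wetland_calibration` object behaves like other R model fits:
`coef()` gives the named integer vector of $M$, `fitted()`/`residuals()`
the per-period areas and misfits, `plot()` an observed-vs-fitted
diagnostic, `simulate()` new observation tables under the fitted forward
model, and `project_wetlands()` (also reachable through the fit) drives the
projection stage.

## Projection and agreement maps

`project_wetlands()` applies the calibrated $M$ to a soil-moisture cube
(model × scenario × month × basin), averaging monthly values to annual
means first (the same window-first convention as calibration). Continental
series are basin sums; `ensemble_mean()` is the unweighted arithmetic mean
across members — no member weighting is attempted. Net change between two
years is reported in percent of the base year.

`agreement_map()` rasterises basins to an equal-angle grid (0.2°
by default, anchored at integer degrees, basin assigned by centroid) and
classifies each member's net cell change as loss, gain or unchanged. The
"unchanged" band needs a width $\varepsilon$; the default is 1% of that
member's initial wetland area in the cell, since an absolute band would
mean different things in cells of very different wetland extent. Counts
always satisfy $n_{loss} + n_{gain} + n_{unchanged} = n_{models}$, and the
sum of cell net changes reproduces the continental net change exactly.

## The synthetic-data generator

The generator exists so every stage is testable without any download; its
defaults are the package's standing study conditions and are not tuned per
experiment:

* **Basins** — 200 basins of 4000 CTI pixels each, drawn from a gamma law
  (shape 4, scale 2; mean 8). The gamma choice gives the heavy right tail
  real CTI histograms show; 4000 pixels is far below a real 30–90 m basin
  raster but enough that adjacent-M thresholds almost surely separate at
  least one pixel, which is what identifiability rests on. Areas are
  uniform on 100–5000 km², centroids uniform over a continental-Africa
  box, and each basin hides a true $M$ uniform on 1–15.
* **Soil moisture** — monthly, per (model, scenario, basin):
  $\mathrm{SM}_{sat}\,(b_m + \gamma_m \tau_s (t-t_0)/10 + a\sin 2\pi t +
  \epsilon)$, clipped to $[0, \mathrm{SM}_{sat}]$. Baseline 0.6, seasonal
  amplitude 0.05, monthly noise s.d. 0.02 (all fractions of
  $\mathrm{SM}_{sat}$); scenario trends $\tau_s$ = 0.005, 0.010, 0.015,
  0.020 per decade, ordered mild → severe, chosen so the severest scenario
  wets the column by roughly 0.16 of saturation over the 117-year span — a
  perceptible but not degenerate forcing. Ensemble member 1 is the
  designated *truth* model and keeps the nominal parameters; the other 13
  members perturb the baseline (s.d. 0.02) and scale the trend (s.d. 0.15)
  to exercise ensemble spread. Trends act from the series start rather
  than diverging at a scenario branch point — simpler, and the historical
  scenarios differ only marginally over the calibration window.
* **Observations** — per basin and period, the forward model under the
  hidden true $M$, driven by the truth member's period-mean soil moisture,
  times lognormal noise with CV 0.05 (multiplicative and mean-one:
  classification error scales with extent, and areas stay positive).
  With CV = 0 the loop closes exactly and calibration must recover every
  hidden $M$; the acceptance suite checks exactly that, and ≥90% recovery
  within ±1 at CV = 0.05.
* **Sample points** — drawn over a categorical truth map with a Bernoulli
  label-flip of configurable rate and a seeded 70/30 train/validation
  split; only the validation split enters `accuracy_assessment()`.

What the generator does **not** emulate: spatial autocorrelation within
and between basins, climate teleconnections between members, observation
errors correlated across periods, or anything about the imagery that real
wetland maps are classified from. Passing tests therefore demonstrate the
*machinery* — identifiability of $M$ under the stated noise, conservation
and monotonicity of the accounting — not the accuracy of any real-world
wetland product.

## Statistics

* **Change ledger** — per-unit differences split into gross loss (negative
  diffs) and gross gain (positive diffs); net = gain − loss; percent
  against the base-date total. Gross and net are exposed separately
  because "change" in wetland reporting is used in both senses.
  Percentages print to 2 decimals.
* **Mann–Kendall** — $S = \sum_{i<j}\mathrm{sign}(x_j - x_i)$,
  tie-corrected variance, ±1 continuity correction, two-sided normal
  p-value; an all-tied series returns $S = 0, Z = 0, p = 1$. The
  size check in the acceptance suite uses white-noise series of length 30
  with 10,000 replicates: length 30 is where the normal approximation is
  conventionally considered reliable (the test is visibly conservative at
  single-digit lengths because of the discreteness of $S$).
* **Linear trend** — OLS on the time index with $R^2$ as squared Pearson
  correlation; a zero-variance time index is a hard error.
* **Grid-cell areas** — spherical band formula with $R = 6371$ km; a 0.2°
  cell at the equator is ≈ 494.57 km², and cells telescope exactly to band
  areas.
* **Accuracy** — confusion matrix with rows = reference and columns =
  mapped (stated here because conventions differ), producer's accuracy =
  reference-conditioned recall, user's accuracy = map-conditioned
  precision, overall = trace/total. No area-adjusted (error-adjusted)
  estimators are attempted.

## Numerical and design notes

* The saturated fraction is computed from the sorted pixel vector via
  `findInterval(..., left.open = TRUE)`, which counts pixels strictly
  below the threshold and is exact under ties — it agrees bit-for-bit with
  a naive loop, which the tests assert on randomized cases.
* All generator stages derive their RNG streams from the run seed with
  fixed per-stage offsets, so supplying a pre-built input for one stage
  does not shift the draws of later stages; the pipeline writes no
  timestamps, making whole-run outputs checksum-reproducible.
* CSV is the interchange format throughout, with `#key: value` header
  lines for units and provenance; soil-moisture cubes are written at full
  double precision (`%.17g`) and round-trip bit-identically.
* Problem sizes in the tests and the acceptance script (200 basins, 4000
  pixels, 9 periods, 14 × 4 ensemble, 10,000 trend-test replicates) are
  the package's chosen experiment scale: large enough that the recovery
  and size statistics are stable, small enough to run interactively.

## Known limitations

* One WTD per basin from basin-mean soil moisture (not per pixel); basins
  are treated independently with no lateral transfer.
* $M$ is a 15-point integer grid by construction; no uncertainty interval
  on $M$ is produced, and no regularisation across neighbouring basins.
* The projection inherits whatever biases the driving soil-moisture cube
  has; no bias correction or downscaling beyond the CTI mechanism.
* Coastal wetlands are outside the model: the diagnostic is built for
  inland, soil-moisture-controlled wetlands.
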