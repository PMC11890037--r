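---
title: "Modelling elephant trunkload mass: methods and design notes"
author: "trunkload package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling elephant trunkload mass: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trunkload)
```

## The problem

Elephants harvest food with the trunk, one grasping action at a time. The
dry mass gathered per trunkload is a hard constraint on intake rate, and
because it differs sharply between forage types and seasons it is a
candidate currency for diet choice: an elephant maximising intake should
graze while green grass offers heavy trunkloads and switch to browse, and
eventually bark, as the herbaceous layer declines. This package implements
mechanistic, landscape-resolved estimates of trunkload mass for the five
main forage types, separately for adult bulls and members of breeding
herds, at a daily time step over an annual cycle.

## Models and assumptions

**Green and mixed grass.** A tuft is assumed to be uprooted (or its upper
portion stripped, for robust perennials) in one trunkload, so trunkload
mass equals plant mass, modelled as proportional to the product of leaf
height and basal area: `mass = a · H · B` with no intercept (a vanishing
tuft has vanishing mass). `a` is fitted per vegetation type by ordinary
least squares through the origin, which coincides with the closed form
`sum(m·x)/sum(x²)`, `x = H·B`; this identity is used as a test oracle.
Basal area is derived from the measured basal circumference assuming a
circular base, `B = C²/(4π)` — the field protocol measures circumference,
the model needs area, and no other conversion is defensible without extra
shape data. The mixed-grass variant substitutes `H_mixed`, the mean of the
green and dry leaf heights, averaged per survey point *before*
interpolation (averaging two interpolated series instead would differ only
at second order, but per-point averaging matches how the survey data are
recorded).

**Tuft-selection ceilings.** Elephants do not uproot arbitrarily large
tufts. The mean circumference of tufts each group actually selects (35.5 cm
for bulls, 22.3 cm for breeding herds under the calibrated defaults) is
used as a ceiling when averaging basal area: tufts above the ceiling are
*excluded*, not capped, because the ceiling is interpreted as a limit on
which tufts are selected at all. Exclusion can only decrease the mean
basal area, which the tests assert as an invariant. Whether over-ceiling
robust-perennial tufts should instead contribute a partial upper-portion
mass is an open question; exclusion is the conservative
reading, and the "mass" field of a tuft sample is defined as the harvested
portion so no separate correction factor exists.

**Green leaves.** Trunkload mass scales with the mass of a leaf unit (the
smallest unit the trunk holds, usually a leaflet): small leaves handle
poorly and fall from the grasp. The per-group regression is fitted *with*
an intercept. The harvest relation is sometimes written intercept-free,
but the reported fitted lines the defaults are calibrated to
(Y = 72.902X + 14.196 for bulls; Y = 67.669X + 9.001 for herds) carry
intercepts; the fitted lines are authoritative here, and the package
follows them. A positive intercept is also mechanically
sensible: even for vanishingly small leaf units a trunkload contains a
nonzero bundle of material.

**Leaf aggregation weights.** Species weights for the landscape aggregation
are *relative* accessible densities (canopy below 6 m for bulls, 4 m for
herds), renormalised daily over the species whose canopy is more than 25 %
green. Taking absolute densities (individuals per hectare) at face value
would destroy the grams scale of the output; relative densities keep the
result a per-trunkload mass, consistent with the bark equation, which is
explicitly stated in relative-density form. Availability is binary at the
25 % threshold — no partial weighting by green fraction — and removing the
filter can only add species, which is asserted as a property.

**Canopy bark.** Bark is chewed off a broken branch, so harvested mass is
modelled per species as `W = a·LD + b·(LD)²` with no intercept, where
`L·D` multiplies centimetres by millimetres without unit conversion,
exactly as the fitted coefficients assume. Forked branches contribute the
sum of fork-wise predictions. Group × species mean bark masses feed a
relative-density-weighted mean per unit that is constant over the annual
cycle; woody species never recorded as bark sources contribute zero mass
at their recorded density.

**Phenology.** Quarterly quadrat surveys (five points × twenty-five 1-m²
quadrats per unit and date) are averaged per date — quadrats with no plant
of a category count as 0 cm, since omitting them would bias heights upward
in sparse swards — and interpolated to daily resolution with smoothing
splines. Negative spline excursions are clamped to 0. Forb trunkloads are
scaled by the forb height relative to the unit's observed maximum, so the
relative series peaks at exactly 1.

**Comparisons.** Daily differences between surfaces are tested with
Wilcoxon signed-rank tests paired over *landscape units* (n = 65), not
raster cells: cells within a unit are copies of the same value, and pairing
over cells would pseudo-replicate. Zero differences are excluded by the
usual signed-rank convention, a day of all-zero differences reports p = 1,
and the exact null distribution is used below 26 nonzero pairs (untied);
no multiple-testing correction is applied across days: each day's contrast
is reported on its own at P < 0.01. Significance
masks are invariant under any common positive rescaling of both surfaces,
which is asserted as a property. Tuft-selection contrasts use
Kruskal–Wallis plus Dunn's post hoc z contrasts, and bark group × species
contrasts use an aligned-rank-transform two-way ANOVA; both rank
procedures are implemented in the package (`.dunnTest`, `.artAnova`)
following the standard constructions, as the field data they serve are
non-normal and heteroscedastic.

## The synthetic study generator

The original field measurements are not public, so `simulateStudy()`
generates a complete surrogate study with known ground truth
(`trunkloadParams()`), and every downstream stage is tested by parameter
recovery. Defaults are the study conditions wherever these are stated:

* grass coefficients 0.050541, 0.050016, 0.072608, 0.050897 g·cm⁻³ for
  four vegetation types; leaf regressions Y = 72.902X + 14.196 (bull) and
  Y = 67.669X + 9.001 (herd); bark coefficients for *Colophospermum
  mopane* and two *Grewia* species; ceilings 35.5/22.3 cm against a
  52.7 cm community mean; forb plant masses spanning 2–418 g; 65 landscape
  units; a 364-day window starting 12 March; 25 tufts per grass species,
  100-tuft selection samples, 17/18 leaf observations, 10–13 calibration
  branches and 100 debarked branches per group and species.
* Tuft circumference follows a lognormal law (right-skewed, strictly
  positive); only the means are reported, so the coefficients of
  variation are free parameters. The ceiling target species gets CV 0.6: a
  narrower law would leave almost no community tuft below the herd ceiling,
  degenerating the herd's selectable fraction, whereas the reported
  selection densities span small to very large tufts.
* The seasonal height curve is piecewise: a late-wet-season peak followed
  by exponential dry-season decline to a trough of 25–40 % of peak, then a
  linear rise when the next rains start. Only curve *shapes* are reported;
  this parameterisation reproduces them qualitatively.
* Canopy greenness per woody species is a ramp from fully green to bare
  that crosses the 25 % availability threshold exactly on the species'
  senescence day, with a flush ramp back up in November. Senescence days
  are staggered; three drought-tolerant, smaller-leaved species keep >25 %
  green canopy throughout the window, so green leaf is available (at
  declining mass) on every day, as in the study landscape.
* Noise is multiplicative lognormal on masses (keeping them positive) and
  additive Gaussian truncated at zero on survey heights. Residual
  variances are unpublished; the defaults (tuft mass CV 0.15, leaf
  observation CV 0.10, bark mass CV 0.08, survey height SD 6 cm) give
  fitted adjusted R² in the broad range of the printed fits. The default
  bark calibration branches span lengths of 2–60 cm and diameters of
  1–6 mm, i.e. `LD` from ~2 to ~360 cm·mm, the region where the linear and
  quadratic terms are comparable — a narrower, thicker-branch design
  leaves the linear coefficient unidentified at a dozen branches, which
  is inconsistent with the well-identified positive fits the calibrated
  coefficients come from. Setting all
  noise scales to zero makes every sampled mass an exact model value, and
  the full fitting pipeline then recovers every coefficient to 1e-8
  relative tolerance (a tested invariant).
* Within a unit, the canopy height-class profile is drawn once and shared
  across woody species, so the two groups' relative accessible densities
  coincide and group differences in leaf and bark surfaces stem from the
  harvest models and ceilings alone — the mechanism of interest. Species-
  specific height structure is a straightforward extension the generator
  does not attempt.
* One master seed drives a deterministic per-table seed sequence, so any
  table can be regenerated independently and a fixed seed yields identical
  studies.

What the generator does **not** emulate: elephant movement and bite
sequencing, consumption feedback on forage state, spatial autocorrelation
between units, burn/early-flush dynamics beyond the unit attributes, and
species-level grass fits beyond the pooled vegetation-type fit. Passing
recovery tests therefore demonstrate that the estimation machinery is
correct and unbiased under the stated sampling designs — not that the
models describe any particular real landscape.

## Numerical choices

* Smoothing parameter: generalised cross-validation by default
  (`smooth.spline`), stable at the handful of survey dates a quarterly
  design yields; an explicit `spar` can override it, and
  `smoothing = "off"` switches to an exact natural interpolating spline
  (used by the equivalence tests, which require the daily series to pass
  through the survey means exactly). Fewer than four dates always use the
  exact spline.
* The model window must lie inside the survey window; extrapolation
  beyond the first or last survey is refused rather than clamped.
* Cover and relative-density vectors must arrive normalised to 1 ± 1e-9;
  they are never silently renormalised, and violations are rejected naming
  the offending table.
* Degenerate cases: an all-zero forb series yields relative height 0 with
  a warning; a ceiling below every tuft yields mean basal area 0 with a
  warning; a day with no available woody species yields leaf trunkload 0.
* CSVs are written with `%.17g` precision so a disk round trip is
  lossless; the unit raster uses the ESRI ASCII grid format (unit ids
  ≥ 1, 0 = nodata), read and written by a small built-in parser since no
  raster package is required for a pure reclassification engine.

## Problem sizes used by the test suite

The parameter-recovery suite runs 200 seeded replicates at moderate
observation noise (5 % CV on tuft masses, matching the worked recovery
example of the design; 2 % CV on leaf and bark masses) and requires every
fitted coefficient within 5 % of truth in at least 95 % of replicates.
Sample sizes were chosen by a-priori power analysis so that each
coefficient's sampling error is a comfortable multiple below the 5 % band:
150 tufts per species (the origin-regression slope has a much smaller
effective sample size than nominal because `H·B` is heavy-tailed under
lognormal circumferences), 150 leaf observations per group (the herd
intercept, 9.001 g, is the tightest 5 % band in absolute terms), and 500
calibration branches per species spanning `LD` from ~5 to ~500 cm·mm (the
linear bark term is weakly identified where the quadratic dominates, so
the design needs many thin short branches). The oracle-equivalence check
recomputes a 5-unit, 30-day run cell by cell from the raw tables; the
structural-property checks (bark constancy, bull ≥ herd ordering, forb
equality, min ≤ mean ≤ max, rescaling invariance of significance masks)
use a 20-unit, 60-day study. The acceptance script runs the full 65-unit,
364-day configuration.

## Known limitations

* The leaf and bark aggregation assumes the published relative-density
  reading; if absolute densities were intended, outputs would scale by
  stand density and lose their grams interpretation.
* Landscape min/max are computed over raster cells, which coincides with
  min/max over units under the reclassification engine; with per-cell
  covariates the two would diverge.
* The ceilings are applied as hard exclusions; a soft (probabilistic)
  selection curve would smooth the basal-area means but has no published
  parameterisation.
* No uncertainty propagation: fitted-coefficient sampling error is not
  carried into the daily surfaces; the recovery suite quantifies it
  instead.
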