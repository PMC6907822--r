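---
title: "Phenology-curve crop mapping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenology-curve crop mapping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doublecrop)
```

## The problem

A winter wheat–summer maize rotation produces a distinctive bimodal annual
NDVI trajectory: a first green-up peak during the wheat cycle (day-of-year
60–170) and a second during the maize cycle (DOY 180–270). Single-season
crops, forest/grassland, water and built-up land each trace different
curves. `doublecrop` exploits these temporal signatures to map the
rotation from coarse-resolution (250 m) vegetation-index composites, where
per-pixel spectral information alone is too ambiguous.

The chain is: assemble a dense time series from two sensors, repair
contaminated observations, smooth each annual curve into a stable
phenology signature, classify the signatures, and derive accuracy reports
and multi-year area/change/frequency products.

## Time-series assembly

Each sensor delivers 23 16-day composites per year; their start days are
offset by eight days ("half-period dislocation"), so merging them by
(year, DOY) yields 46 nodes per year — 598 nodes for a 13-year record.
Node timestamps are composite *start* DOYs. The product metadata does not
fix whether start, centre or acquisition day is the right abscissa; start
DOY is used because it matches the product naming convention, and all
operations are consistent under a constant shift. Leap years keep the same
nominal grid, giving a fixed 368-day base period.

Values are integers on the scaled-NDVI convention (true NDVI × 10,000).
Reliability is a parallel cube of summary codes (0 good, 1 marginal,
2 snow/ice, 3 cloud, 255 fill) rather than bit-packed QA, because only the
summary drives any decision here. Cubes are stored as multi-band 16-bit
TIFF with a JSON sidecar for calendar, geotransform and pixel size; the
16-bit offset encoding round-trips every integer value exactly.

## Gap-filling

Cloud- and snow-flagged nodes are replaced by linear interpolation, in
node-index time, between the nearest neighbours flagged good *or* marginal
(marginal values are retained as usable anchors, not replaced). Design
points that were genuinely open:

* **Abscissa** — node index. Within a year the merged nodes are equally
  spaced (8 days) so index- and calendar-time interpolation coincide; the
  equality is asserted in tests on the calendar itself.
* **Edges** — leading/trailing flagged runs take the nearest good value
  (constant extension). Extrapolating a line into an unobserved winter tail
  can overshoot badly at the DOY-1 boundary; constant extension cannot.
* **Year boundary** — the multi-year series is treated as one continuous
  record, so a December gap may interpolate into January of the next year.
  The alternative (clamping per year) only differs for gaps spanning New
  Year, where dormant-season NDVI is flat anyway.
* **Hopeless pixels** — a pixel flagged at every node is masked to `NA`
  and counted, never fabricated.

## HANTS smoothing

The smoother fits `y(t) = a0 + Σ_{i=1..nf} [a_i cos(2πit/T) + b_i
sin(2πit/T)]` by least squares over the currently accepted points and
iterates outlier rejection. Parameters (defaults in parentheses):

| parameter | default | meaning |
|---|---|---|
| valid range | −2000 … 9000 | scaled-NDVI values outside are pre-rejected |
| nf | 3 | annual harmonics above the mean term (frequencies 1, 2, 3) |
| FET | 1000 | max tolerated residual on the suppression side (scaled NDVI) |
| DoD | 8 | overdeterminedness: ≥ 2·nf + 1 + DoD = 15 points kept |
| suppression | low | side on which outliers are rejected |
| base period | 46 nodes = 368 d | one nominal year |

Choices made where the method leaves room:

* **Suppression side = low.** Residual cloud and snow only depress NDVI —
  the synthetic generator enforces the same sign — so points far *below*
  the fitted curve are the suspect ones. On convergence every accepted
  node satisfies `fit ≥ y − FET`.
* **Rejection granularity.** One point per iteration (the worst violating
  residual), the gentle classic behaviour; the accepted set shrinks
  monotonically and the loop provably terminates.
* **Per-year windows by default.** Phenology is annual; each year's 46
  nodes comfortably exceed the 15-point floor. A whole-series mode (one
  harmonic model with an annual base period through all years) is kept
  behind `per_year = FALSE` since either reading of "smoothing the
  13-year series" is defensible.
* **DoD interpretation.** The minimum usable points per fit is read as
  `2·nf + 1 + DoD`; other HANTS lineages exist, but this is the common
  one and is what the 15-point floor above encodes.
* **Non-convergence fallback.** Pixels whose fit fails or never satisfies
  the tolerance keep their gap-filled values: the output never introduces
  new missing data.

**A known, deliberate limitation.** Three harmonics cannot represent a
sharply bimodal curve exactly. For the synthetic wheat–maize class the
harmonic truncation floor is several hundred scaled-NDVI units, and the
one-sided rejection loop then treats genuine senescence troughs as
outliers, inflating the fit between the two peaks. The test suite therefore
asserts exact recovery only for band-limited signals (where it holds to
1e−6), asserts the noise-level RMSE bound for the four classes within
harmonic reach, and for the bimodal class asserts what actually matters
downstream: the wheat peak node survives smoothing to within one node
(8 days), and class separability — hence classification accuracy — is
unimpaired. This mirrors real usage, where FET is calibrated to the
smoothness of real composited imagery.

## Classification

Features are the raw 46 smoothed nodes of one year — no derived phenology
metrics — so the classifier sees exactly the curve the interpretation key
shows. Training points are allocated per class within cells of a coarse
(default 50 km) grid to spread samples across regional growing-condition
gradients; per-tile counts are configurable (default 5/class) since real
allocation "by complexity" has no published numbers. Samples from several
years are pooled by relative node position, mirroring a single
interpretation key applied to every year.

The forest uses 100 trees and `floor(sqrt(46)) = 6` candidate features per
split. Determinism is taken seriously: training sorts samples into a
canonical order first (so assembling the same set in a different order
gives the identical forest), and prediction uses vote matrices with ties
broken towards the lowest class code instead of the library's random
tie-break. Mean and SD signature curves (`class_signatures()`) provide the
interpretation key; the sample (n−1) SD convention is used.

## Accuracy assessment

Confusion matrices are oriented rows = mapped, columns = reference, making
user's accuracy a row quantity. Overall accuracy, kappa, and per-class
user's/producer's accuracies follow the standard closed forms; classes
with an empty row or column get `NA` rather than a fabricated rate.

The area consistency index is implemented as `c = (1 − |x−y|/y)·100`
(x extracted, y statistical area): 100 at exact agreement, 0 when the
error equals the reference, negative (unclamped) when x > 2y. Binning
uses lower-closed bins {>80, 60–80, 40–60, 20–40, <20}, with negatives
falling in "<20". The area regression is ordinary least squares with a
free intercept — reported slopes and determination coefficients elsewhere
do not state a forced zero intercept, and a free intercept is the more
informative diagnostic.

## Multi-year products

* **Growth rates** are year-on-year percentage changes; a span's "average
  growth rate" is the arithmetic mean of its annual rates (not CAGR, which
  would compound).
* **Change maps** split pixels into stable/gain/loss/absent with exact
  area conservation against the two input maps.
* **Planting frequency** is the per-pixel share of years mapped as the
  rotation, on the lattice {100·k/n_years}; its histogram keeps 0% and
  100% as standalone bands because "never" and "always planted" are the
  scientifically distinct categories.
* **Peak metrics** report the windowed maximum at node (8-day)
  resolution; sub-node interpolation would claim precision the data do
  not have.

## The synthetic generator

`generate_scene()` emulates what the downstream stages need to be tested
against: five classes on a patchy landscape, class-specific annual curves
(Gaussian bumps over a baseline — peak timing and height directly
controllable, unlike a double-logistic), per-pixel peak-DOY draws (wheat
from DOY 108–123, maize from 221–228), additive Gaussian observation
noise, and cloud/snow contamination that *only lowers* NDVI by a draw
from U(0.2, 0.6)×10,000 while setting the matching reliability code
(snow only at winter nodes, DOY < 60 or > 330). One RNG stream seeded
once makes every product bit-reproducible.

Default nuisance levels — noise SD 0.02 NDVI, cloud probability 0.10
(0.20 in the end-to-end fixture), winter snow probability 0.15, 10 %
marginal flags — are fixed choices representative of mid-latitude
cloudiness; no published noise model exists for the source imagery, so
they are exposed in `scene_spec()` rather than hidden.

What the generator does **not** emulate: mixed pixels at field boundaries,
inter-annual phenology shifts from weather, sensor drift or BRDF effects,
or spatially correlated cloud fields. Passing tests therefore demonstrate
the correctness of the algorithms and the internal consistency of the
chain — not that real-landscape accuracy will reach the synthetic
figures, which are optimistic precisely because the class curves are
cleanly separated.

## Problem sizes and runtime

The test suite and the acceptance script run the full chain on a 64 × 64,
13-year dual-sensor scene (598 nodes, ~53,000 pixel-year HANTS fits) —
small enough to iterate on quickly, large enough to exercise every stage
including multi-year products; module tests use 8–32-pixel-wide scenes.
`hants_stack()` takes a batch least-squares fast path for pixels whose
first fit already satisfies the tolerance, and iterates only the rest.

## Known limitations

* Harmonic truncation of sharply bimodal curves (discussed above).
* Gap-filling is purely temporal; no spatial-neighbour filling.
* Geo-referencing is carried as an affine sidecar; no projection
  handling or resampling is provided.
* The classifier is as good as its training allocation: with very small
  per-tile counts, rare classes in fragmented landscapes can be
  under-sampled.
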