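---
title: "Methods: multi-metric tidal marsh resilience scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-metric tidal marsh resilience scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshres)
```

## The model and its assumptions

`marshres` scores the resilience of tidal marsh units to relative sea level
rise (RSLR) from thirteen landscape metrics in three categories: *current
condition* (marsh configuration and surrounding land use), *vulnerability*
(erodibility and elevation relative to the tidal frame), and *adaptive
capacity* (shoreline character and room to migrate).  The framework is
deliberately relative: every score is a decile rank **within the analysis
cohort**, so scores answer "which of my marshes are better or worse off",
never "is this marsh above an absolute threshold".  Adding or removing
units from a cohort can change every score; this is a feature of the
design, not an artifact.

Geometric assumptions: all coordinates are planar meters in a projected
CRS that is recorded but never transformed; areas are cell counts ×
cell-size²; rasters share one geometry (row 1 = north edge, cell centers at
half-cell offsets).  No geodesic computation is performed, which is
appropriate at sub-estuary extents.  Elevation and tidal datums must share
one vertical datum; no datum transformation is attempted, and no lidar
elevation bias correction is applied.

## Metric definitions and numerical conventions

* **Core/edge**: a marsh cell is *edge* iff at least one neighbour
  (4-connected by default; the rook convention matches per-cell-side edge
  logic on square grids and is configurable to 8) is non-nodata and not
  marsh; the exposure is *unvegetated* if any such neighbour is also not
  vegetated.  The core-to-edge ratio uses cell counts; with a uniform cell
  size this is proportional to an area/length ratio and decile ranking — the
  only consumer — is invariant to the constant.  A marsh patch with no edge
  cells takes denominator 1; a unit with no marsh gets a missing value and
  is excluded from scoring.
* **Buffered land cover**: membership by cell-center test against the unit
  polygon dilated 150 m (Euclidean distance to the boundary), deterministic
  and resolution-consistent; partial-cell weighting is deliberately not
  attempted.  Percent impervious is intensity-weighted by per-class
  impervious fractions (0.25/0.60/0.90 for the three developed classes by
  default); setting the fractions to 1 recovers a binary developed metric.
  nodata cells are excluded from every denominator.
* **Elevation vs datums**: "below" is strict (`elevation < datum`); ties
  count as not-below.  MHHW (not MHW) is used to capture the full
  transitional extent; datums may be constants per unit or grids evaluated
  per cell, and `pct_below_mtl <= pct_below_mhhw` always holds because the
  datum surfaces are validated as ordered.
* **Sinuosity**: per open polyline, path length / endpoint chord; closed
  rings are split at their two most distant vertices into two open
  segments (deterministic, length-preserving).  The unit value is the
  length-weighted mean; degenerate open segments (coincident endpoints) are
  skipped with a warning.
* **Migration ratio**: six inundation scenarios at 1–6 ft (0.3048–1.8288 m)
  above MHHW.  Potential future marsh per depth *d*: migratable cells
  (natural upland or agriculture; developed/impervious excluded) that are
  not currently marsh, lie in `[MHHW, MHHW + d)`, and are hydrologically
  connected to current marsh or water through cells below `MHHW + d`.  The
  connectivity requirement mirrors connected-inundation mapping practice;
  `migration_connected = FALSE` gives the unconnected "bathtub" variant.
  The restriction to migratable land-cover classes is a documented package
  choice; intensity of the source analysis on this point is unknown.
* **Connectedness**: marsh footprints grouped into connected complexes
  across unit boundaries, now and under a 1.2 m scenario (surviving marsh —
  approximated as marsh staying at or above MTL + SLR — plus reachable
  migration space).  The raw group score `(n_current − n_future) /
  n_current` grows when units *drop out*, i.e. when the future is worse,
  yet the framework lists connectedness as a positive influence.  We
  therefore store the **negated** value as the metric (larger = better) and
  return the raw value alongside (`connectedness_raw`); results using the
  literal orientation can be produced by flipping the metric's sign in
  `metric_directions()`.

## The scoring calculus

Decile breaks are the 10th–90th percentiles under the linear-interpolation
("type 7") quantile convention; the convention is stated once and used for
metrics, category sums and total sums alike.  Rank = 1 + number of breaks
strictly below the value, so a value tying a break falls in the **lower**
bin; with heavily tied data duplicated breaks legitimately leave bins
empty.  Weights (1.5 × hardened shoreline, 2 × migration ratio) are applied
to the signed metric scores at summation, not to raw values.  Vulnerability
category sums are negated before ranking and the rank negated again, so
−10 marks the most vulnerable unit and −1 the least.  The total score ranks
the sum of the three *category scores* (not the thirteen metric scores —
the alternative reading of "summed across the categories" is available via
`category_sum()` for sensitivity work but not used).

One consequence of the lower-bin tie rule is worth stating: if two or more
units tie at a cohort's most extreme category sum, the 90th-percentile
break equals the tied value and the tied units rank below bin 10.  The
"uniquely worst unit scores −10, uniquely best −1" guarantee therefore
holds only for untied extremes; tied extremes still share the cohort's most
extreme score.  This is inherent to the stated convention, not a bug.

Missing data never default to a middle rank: a unit missing a metric is
excluded from that metric's break computation and carries the gap forward
through category and total scores to a missing management key.  Scoring
refuses single-unit cohorts (relative ranks are meaningless); for cohorts
with fewer than ten units the quantile rule still applies, but bins are
necessarily unequally populated — interpret small-cohort scores as
orderings, not calibrated deciles.

Ordinal management categories use the inclusive thresholds: condition and
adaptive capacity are High iff ≥ 6, vulnerability High iff ≤ −6; the key
concatenates Condition-Vulnerability-Adaptive.  Recommendation text is
data, not code: two keys ship with substantive defaults (High-Low-High →
conservation priority; Low-High-Low → major restoration / barrier removal)
and the other six are explicit placeholders for user-supplied tables.

## The synthetic world

`generate_landscape()` states a fixed synthetic world used by every test:
30 m cells; an elevation gradient within each rectangular unit tile running
open water → unvegetated flat → marsh → upland; tidal datums anchored to
elevation-field quantiles so the realized marsh fraction equals the request
by construction (water fraction 0.2, MLLW/MHHW anchors −1.0/+0.5 m, i.e. a
1.5 m range, with a ±0.25 m west–east datum trend keeping the ordering
MLLW ≤ MTL ≤ MHHW everywhere); Gaussian elevation jitter (sd 0.15 m,
a lidar-like scatter) applied after classification so the %-below-datum
metrics vary across units instead of saturating; 3 % of marsh cells
converted to interior ponds; upland split 15 % agriculture and 10 %
developed; three wiggly shoreline polylines per unit, hardened with
probability 0.3.  These defaults were chosen once as plausible for a
mesotidal estuarine landscape and are not tuned to test outcomes.

What the generator does **not** emulate: channel networks and realistic
hydrologic topology, spatially autocorrelated class noise at C-CAP scales,
datum error fields, multi-polygon units, or shorelines derived from the
marsh boundary itself (shorelines are independent synthetic polylines).  A
green test on synthetic data therefore establishes that the *computations*
are correct under the stated conventions — not that the metrics are
accurate on any real estuary, which depends on input data quality the
package does not model.

`generate_metric_table()` draws the thirteen metrics directly on their own
scales (moment-matched beta for percents, gamma for ratios, 1 + gamma for
sinuosity, negated beta for connectedness), enforcing
`pct_below_mtl ≤ pct_below_mhhw` and `pct_natural + pct_agricultural ≤ 100`
by drawing the dependent column as a fraction of the headroom — the
marginal mean is preserved exactly, the sd approximately.

## Interchange formats and the CLI

Rasters are read and written as ESRI ASCII grids (plain text), vectors as
GeoJSON, tables as CSV (`unit_id` key, UTF-8, `.` decimal), configuration
as JSON; a directory of these files round-trips a full landscape with codes
bit-identical and coordinates within 1e−6 m.  These plain-text formats
replace binary geospatial containers so the package runs with no
compiled geospatial stack; the layout is documented in `write_landscape()`.
All randomness flows from the single seed in the configuration; scoring is
seed-free by construction and the end-to-end pipeline is byte-reproducible.

## Known limitations

* No sediment-supply or accretion metric; the metric table accepts
  user-added columns, but the scoring engine ranks only the thirteen
  canonical ones.
* Unit polygons are single rings without holes.
* Tidal-datum gap interpolation is out of scope; datum grids must be
  complete where units need them (a missing datum yields missing metrics).
* The connectedness orientation is a documented package decision (see
  above); national-scale results from the source analysis are not claimed
  to be reproducible here, since they require the national land-cover,
  datum, elevation, shoreline and soils datasets.
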