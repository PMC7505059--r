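---
title: "Methods: catalogue tabulation, voucher cleaning and richness mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: catalogue tabulation, voucher cleaning and richness mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treecensus)
```

## The problem

National tree inventories combine two very different data objects. The
first is a *species catalogue*: one row per accepted species carrying
taxonomy (family, genus, binomial) and categorical attributes —
endemism, IUCN Red List category, national protection category
(NOM-059: P, A, Pr), CITES annex, whether seeds are banked in-country
and/or duplicated abroad, and whether any human use is documented. The
second is a set of *georeferenced voucher records*: herbarium specimens
with decimal coordinates, of very uneven quality. The analyses this
package implements — summary tables, cleaned occurrence sets, gridded
richness maps, richness/effort regression, richness peaks, and
protected-area gap cells — all derive from those two inputs.

## Catalogue model and tabulation

A `catalogue` validates its entries on construction: binomials are
unique (species level only, no infraspecific taxa), the genus equals
the binomial's first epithet, and every status code belongs to a
closed vocabulary. Legacy IUCN v2.3 codes (`LR/cd`, `LR/nt`, `LR/lc`)
are retained as distinct values and never remapped onto v3.1
categories, because published tables keep them separate. Absent status
fields parse as `NE`/`none` rather than erroring: unassessed species
simply omit them in catalogue appendices.

Two definitions are fixed by convention and used everywhere:
*threatened* ⇔ IUCN ∈ {CR, EN, VU}; *banked* ⇔ in-country collection ∪
duplicated collection (the two collections are distinct, so the union
is computed by inclusion–exclusion, never by addition).

`tabulate_catalogue()` produces the ranked family/genus tables (overall
and endemic-only), conservation tables and the banked table. Percentage
policy: `percent(count, total, dp)` is `100·count/total` rounded **half
away from zero** — banker's rounding (R's default `round()`) was
rejected because printed tables round 43.81% to 44% and 6.25 to 6.3.
Family/genus tables use 1 decimal against the total (or endemic total);
conservation tables use 2 decimals; banked rows use 1 decimal against
each row's own category total. Rank ties share a rank (`ties.method =
"min"`) and are listed alphabetically within the tie — printed tables
show ties sharing a rank but an output must be deterministic, so
alphabetical order within equal counts is the package's tie-break.

`catalogue_from_counts()` inverts the tabulation: given marginal counts
(named families with endemic counts, named genera, listing totals,
collection sizes and overlap) it realizes a concrete catalogue with
exactly those margins, filling the remainder with evenly sized filler
families kept strictly smaller than the smallest named family so
printed rankings are preserved. This turns a published summary table
into an executable input: tabulating the realized catalogue must
reproduce the printed percentages, which is what `scripts/acceptance.R`
checks.

## Geometry without a GIS stack

All spatial operations run on plain polygon feature sets (`poly_set`)
in geographic coordinates, with a local equirectangular projection
(`local_crs`) onto a km-scaled plane for anything metric. At country
scale (~1,000 km) centred on the territory this preserves distances to
well under the 1-km and 25-km tolerances that matter here. Point
membership uses even-odd ray casting (holes are just extra rings);
boundary distance is the minimum over point-segment distances in the
projected plane. Polygon I/O is GeoJSON. The package deliberately
carries this small geometry kernel itself and states its convention
(even-odd, first-containing-feature for ties) explicitly.

Per-cell protected fraction is evaluated on a deterministic midpoint
subgrid (default 24 × 24 points per cell): union-of-reserves semantics
is exact under point membership — overlapping or subdivided reserve
polygons can never double-count — and the geometric tolerance,
roughly `cell_km/24` ≈ 1 km at the default resolution, is an order of
magnitude below the 0.05 protected-fraction threshold that defines a
gap cell. Exact polygon clipping would buy nothing at that threshold.

## The cleaning pipeline

Rule order is fixed: **centroid sentinel → out-of-boundary (with
repairs) → coastal snap → low precision → normalise/deduplicate**. The
sentinel rule must run first because the sentinel coordinate lies
*inside* the country and would otherwise survive every later rule. The
order between the precision rule and the boundary rules is a package
choice (flagged in the report); the classes are disjoint in practice.

Numerical choices, with defaults and rationale:

* **Centroid tolerance 0.005°** — matches the sentinel as printed at
  one decimal or fewer (23.0, −102.0) but not nearby genuine
  localities (23.006, −102.0 survives).
* **Repairs** are limited to the two transcription errors that have a
  mechanical explanation — inverted lat/lon and a longitude missing its
  negative sign — plus their composition, tried in that order; the
  first candidate falling on land is accepted and the original
  coordinates retained. No gazetteer re-georeferencing is attempted.
* **Snap distance 1 km, nudge ε = 0.01 km** — offshore points within
  1 km move to the nearest boundary point nudged inside; displacement
  is bounded by 1 km + ε. Points exactly on the boundary (distance 0)
  probe eight compass directions for land.
* **Low precision ≤ 1 stated decimal** (~10 km or coarser). Stated
  precision is read from the coordinate *text* at parse time — trailing
  zeros count only if printed. The historical workflow here is a manual
  review; that is not reproducible, so the package replaces it with a
  policy switch (`flag` default, `delete`, `keep`) and keeps the audit
  trail in the report.
* **Duplicate key**: species + coordinates rounded to 4 decimals
  (~11 m) + canonical state, first occurrence kept in input order. The
  literature rarely defines "duplicate"; exact-tuple equality after
  rounding is conservative and deterministic.

Statuses are recomputed from scratch on every run, which makes the
pipeline idempotent: cleaning its own kept output changes nothing. The
report partitions the input exactly (`n_input = n_kept + deletions +
duplicates`), and with repairs disabled the kept set is a subset of the
kept set with repairs enabled.

## Grid, richness and regression

The grid anchors at the lower-left corner of the boundary envelope in
the projected plane and expands to whole cells (`ceiling`). Cell
membership is half-open, `[x, x+s) × [y, y+s)`, with points exactly on
the envelope's upper/right edge closed into the last cell; coordinates
within 10⁻⁹ km of a grid line are snapped to it first so the convention
is stable under floating-point round-trips. Richness is the number of
*distinct* taxa among records passing an attribute slice; genus and
family come from the catalogue join, never from splitting the record's
name string, and records whose species is absent from the catalogue are
excluded and counted in a join-miss report (real inventories map fewer
species than they list). Cells with no records hold 0, not NA.

Consequences asserted as properties: any attribute slice is cell-wise
≤ the unfiltered layer; family ≤ genus ≤ species richness cell-wise
(each species maps to one genus and family); the global distinct-species
count is invariant to cell size.

The density–richness regression is OLS of richness on density.
Zero-record cells are excluded by default — with them included the
zero-inflated empty cells dominate the fit — but both modes are
exposed. Peaks are cells whose value is *strictly* greater than the
threshold, annotated with intersecting states (4 × 4 probe points per
cell) and sorted by value then cell index. A gap cell exceeds the
richness threshold while its protected fraction is at most 0.05 — the
package's quantification of "few or no protected areas", which is
inherently a judgement call; the threshold is configurable and all four
reserve tiers are pooled by default with a tier filter exposed.

## The synthetic study system

The generator emulates the *structure* of a national voucher dataset,
not any real geography: a ~1,100 × 800 km country with a concave
coastal bay, a south-east and a west peninsula, an interior sentinel
coordinate (20° N, 101° W printed at 1 dp), six rectangular states and
four reserves (one per tier). Species ranges are discs (centre sampled
on land, radius uniform in 30–150 km) — enough to produce spatial
richness gradients and engineered hotspots without modelling climate.
Each species contributes `1 + Poisson(mean_records − 1)` records
(default mean 25), uniform in its disc and rejected back onto land; the
first record sits at the range centre the way a type locality anchors a
collection, which also guarantees an engineered hotspot cell contains
every hotspot species. Stated coordinates are 4 dp, and a candidate
point is only accepted if its *rounded* coordinates are also on land,
so a clean scenario is clean as stated.

Default scenario sizes — 120 species, 40 genera, 15 families, a
30-species hotspot — are desk-scale choices that keep a full pipeline
run around three thousand records; the hotspot acceptance scenario uses
450 species (430 in the hotspot, radius 8 km, 4 records each) so the
published ">400 species per 625 km² cell" peak threshold is exercisable.
Error-injection defaults (0.5% each for sentinel, inverted, sign-loss
and the two offshore classes; 2% each for low precision, duplicates and
state-name corruption) represent a plausibly messy voucher table;
classes draw from disjoint record pools and are kept separable by
construction (low-precision injection is restricted to records > 12 km
inland with unique 1-dp keys, so rounding can neither strand a record
offshore nor create an accidental duplicate). Every injection is
recorded in ground-truth bookkeeping, as is per-cell species richness
on the reference grid.

What passing these tests shows — and what it does not: the pipeline
recovers exactly what the generator injected under separable error
classes, and its layers equal brute-force recomputations. Real voucher
data contain error classes the generator does not emulate (gazetteer
mismatches, truncated rather than rounded coordinates, composite
collections under one number), spatially biased collection effort, and
taxonomies that drift between catalogue and specimens; results on real
data inherit none of the generator's guarantees.

## Known limitations

* The geometry kernel is planar and approximate at continental scale;
  the projection is configurable but not a full CRS machinery, and no
  GeoTIFF export is provided (layers export as gridded CSV).
* Protected fractions carry the midpoint-subgrid tolerance
  (~`cell_km/n_sub`); raise `n_sub` where finer resolution matters.
* No sampling-bias correction, rarefaction or distribution modelling:
  richness layers are raw distinct-taxon counts, which is what printed
  inventory maps show, and the density regression exists precisely to
  expose collection-effort structure.
* Name reconciliation is out of scope; species names are treated as
  already reconciled between catalogue and records, and join misses are
  reported rather than fuzzily matched.
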