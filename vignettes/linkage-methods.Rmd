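---
title: "Temporo-spatial linkage through a typed triple graph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporo-spatial linkage through a typed triple graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(triplelink)
```

## Why a triple graph

Environmental-epidemiology studies of rare diseases routinely need to
combine a small clinical table with external datasets that differ in
both temporal granularity (daily station observations, weekly
surveillance counts) and spatial encoding (point coordinates,
administrative polygons, regular grids). Flattening these into one wide
table up front forces early, irreversible decisions about how to "fill
in the gaps". `triplelink` instead keeps every source in its native
granularity inside one typed triple graph, materializes the links
between them as explicit, provenance-carrying triples, and only at the
end projects a per-patient analytic table.

The graph model is deliberately minimal: IRIs for all resources (no
blank nodes — every entity is minted a stable IRI from its source key),
typed literals, set semantics. Two representational choices matter
downstream:

* **Literal equality is lexical.** Two literals are the same triple only
  if lexical form and datatype IRI both match; `"1.0"` and `"1.00"` are
  distinct. This makes serialization round trips exact and keeps
  source values bit-reproducible through uplift → downlift, at the cost
  of not deduplicating value-equal variants — acceptable because every
  literal in this pipeline has a single producing rule.
* **Deterministic order everywhere.** Pattern matches, query results and
  N-Triples output are sorted, so equal inputs give byte-equal outputs
  and artifacts diff cleanly under version control.

N-Triples was chosen as the persistence format: it is the simplest
line-oriented W3C standard, trivially diffable, and needs no prefix
state. Datatype IRIs are always written explicitly so that parsing is
lossless.

## Uplift

The mapping language is a small declarative subset of R2RML, expressed
in YAML (see `inst/extdata/mapping.yaml`): subject IRI templates with
`{column}` placeholders, constant predicates, column-valued objects with
datatypes, and two named transforms — date normalization
(`dd-MM-yyyy` and similar conventions to `xsd:date`'s `yyyy-MM-dd`) and
codebook decoding (`0` → `Female`). Full R2RML (SQL sources, join
conditions, blank-node maps) is out of scope: the supported subset is
exactly what flat CSV inputs need.

Three contracts are worth stating because they shape the counting
identities the tests rely on:

* A **missing cell** (empty string) suppresses that one triple, never
  the whole row, so the triple count of an uplift run is
  `sum over rows (type assertions + non-missing object maps)`.
* IRI template values are **percent-encoded per RFC 3986** (space →
  `%20`; parentheses, being sub-delims, are kept). A printed station
  label like `Mullingar Automatic Weather Station (AWS)` therefore
  yields `...Mullingar%20Automatic%20Weather%20Station%20(AWS)`; a
  rendering of that IRI elsewhere that drops the `20` after the `%` is a
  typesetting artifact, and the canonical encoding is used here.
* Uplift into an existing graph is **idempotent** (set semantics), so
  re-running a mapping cannot inflate the store.

Gridded inputs (climate reanalysis, pollution transport models) enter
through `gridded_field`, an in-memory (time × lat × lon) array on
strictly monotone axes, with a long-format CSV reader/writer as the
plain-text file form. `subset_grid` keeps the cells whose centre falls
in a closed bounding box and closed date range and returns one table row
per kept cell — the "only the coordinates you need" step that turns a
multi-gigabyte array into an upliftable table. Closed intervals and
cell-centre membership are the simplest contracts to state and test;
both are asserted by an analytic row-count formula
(`n_dates × n_lats × n_lons`).

## Spatial enrichment

Geometries follow GeoSPARQL conventions: entities are `geo:Feature`s
carrying `geo:hasGeometry` to a geometry node with a `geo:asWKT`
literal, WGS84, longitude first. Any explicit CRS other than CRS84 is
rejected rather than silently reprojected.

*Distance* is the haversine great-circle distance on a sphere of radius
6371.0088 km (the IUGG mean radius). The nearest station is the
exhaustive argmin over stations — at national-network scale (tens to
hundreds of stations) a linear scan is faster than building an index —
with ties broken by lexicographically smallest station IRI, a rule
chosen because it is deterministic and auditable from the graph alone.
Whether an operational study should prefer great-circle over planar
distance is underdetermined at this scale; great-circle was chosen as
the physically meaningful default and is asserted against an independent
implementation in the tests.

*Containment* uses even-odd (ray-casting) point-in-polygon in plain
lon/lat coordinates, with boundary points counting as inside. Planar
treatment of county-scale polygons introduces curvature error far below
the positional uncertainty of a townland-centroid address; this is a
documented limitation, not an approximation the code hides.
Multi-polygon islands and holes are out of scope. Region assignment
demands a *unique* containing region and raises an ambiguity error
listing the candidates otherwise — overlapping boundary sets are a data
problem that should stop a pipeline, not be resolved arbitrarily.

*Weekly alignment* maps a diagnosis date to an ISO-8601 week
(weeks start Monday; week 1 contains the first Thursday), the
convention used for `2016-01-04 → 2016-W01` and `2016-01-03 →
2015-W53`. Surveillance systems differ in week conventions
(CDC/MMWR epidemiological weeks start Sunday); ISO is the default here
and the week key is a plain literal (`"2016-W01"`), so a bundle built
under another convention only needs its own key strings.

## Exposure windows and downlift

The exposure window is the closed interval
`[diagnosis − n_days, diagnosis − 1]`: strictly prior to diagnosis,
because the scientific question is what preceded onset; the diagnosis
day itself is excluded by default (it is partly post-hoc) but can be
included by configuration, shifting the window to end on the diagnosis
day while keeping its length exactly `n_days`.

Downlift produces one row per patient (case-level), not per
patient-day: exposure summaries are the analysis unit for a
case-series design. Copied attributes preserve source lexical forms
bit-exactly; computed aggregates are formatted with the shortest decimal
string that round-trips the double, so written tables re-read to
identical values. Aggregates expose an explicit missing-value policy:
`skip` (aggregate over non-missing; the default, matching how
meteorological series with instrument gaps are normally summarized) or
`strict` (any gap poisons the aggregate). An empty window yields `NA`
(`count` yields 0).

## Provenance

Every enrichment, linkage and downlift batch is recorded as a
`prov:Activity` with start/end `xsd:dateTime`, an associated agent, one
`prov:used` per input dataset entity and one `prov:wasGeneratedBy` per
generated entity — four core triples plus one per used/generated entity.
Generated entities are reified at *batch* granularity (one entity per
enrichment predicate batch, e.g.
`.../entity/enrichment/nearestStation`), not one per triple: per-triple
reification would multiply graph size several-fold for no additional
audit power at this pipeline's granularity, where a batch is exactly one
deterministic function of its inputs. `validate_provenance` inverts the
convention: any triple under an enrichment predicate whose batch entity
lacks a generating activity is reported as a violation.

Provenance timestamps would ordinarily defeat reproducibility, so the
pipeline defaults to a *logical clock* — a fixed epoch advancing one
second per event — making reruns of the same configuration byte-identical
while keeping timestamps strictly monotone with stage order. A wall
clock can be injected (`deterministic = FALSE`, or `--wall-clock` in the
CLI) when real audit times matter more than byte reproducibility.

## Queries

`evaluate_query` implements conjunctive triple patterns with a natural
join on shared variables (per-pattern index lookup, then merge), then
filters — closed date ranges, ISO-week equality, point-in-region,
great-circle radius (closed inequality), and exclusion by triple
existence (e.g. "excluding patients with a given comorbidity") — then
projection, with results sorted. Filters are pure row predicates, so
they commute; the tests assert this. SPARQL text parsing, `OPTIONAL`,
`UNION` and aggregation are non-goals: the three query shapes the
package targets (geographical, temporo-spatial, federated-with-
exclusion) all reduce to conjunctive patterns plus filters.

## The synthetic study bundle

`generate_fixtures` emulates the *shapes* of the real inputs, not their
statistics:

* Geometry lives in a lon/lat rectangle near Ireland's bounds
  (−11..−5°E, 51..55.5°N) so distances and polygons have realistic
  magnitudes without shipping real boundaries. Regions tile the
  rectangle exactly (no gaps/overlaps); patients are placed strictly
  inside a region with a 5% interior margin so the true region is
  unambiguous by construction.
* Defaults — 20 patients, 12 stations, 6 regions, a 90-day span, 10 × 10
  grid, 5% missingness, 7-day window — reflect a rare-disease cohort
  linked to a national observation network at a scale where every
  quantity remains hand-checkable.
* Daily temperature follows a seasonal sinusoid (9 °C ± 6 °C annual
  swing, peak near midsummer) with Gaussian noise (σ = 1.5 °C);
  rainfall is truncated-Gaussian. Missingness blanks observation
  *values* only, never keys — gaps in real station archives lose
  measurements, not station-days.
* Weekly counts are derived by summing a hidden Poisson(3) daily
  incidence series per region, so the week-sum identity is checkable;
  dates are emitted `dd-MM-yyyy` and gender/comorbidity as 0/1 codes so
  uplift must exercise its transforms.
* Ground truth (true nearest station with distance, true region, true
  window mean) is computed by brute force from the tables at generation
  time and stored under `answers/`.

What passing on this bundle does **not** show: robustness to
boundary-shaped real polygons (concavities, islands, shared borders),
non-tiling or overlapping administrative units, week conventions other
than ISO, clustered (non-uniform) patient locations, or station series
with structured (non-random) missingness. Those are properties of real
deployments that the generator deliberately does not model.

## Numerical and testing choices

Problem sizes in the test-suite were chosen so each property is exercised
well past its edge cases while the whole suite stays interactive:
500-trial counting identities, 200-graph round trips, 200 random
query/oracle pairs, 1000 point-in-polygon pairs against an independent
winding-number oracle (points within 10⁻⁹ degrees of an edge are judged
by the stated boundary convention instead, since the two algorithms may
legitimately differ exactly on the boundary), and 20 seeds × 50 patients
× 200 stations for the nearest-station brute force. The haversine is
additionally cross-checked against an independently maintained
implementation; triangle-inequality checks allow a 10⁻⁹ km slack for
floating-point rounding. Self-intersection of polygons is checked
pairwise at construction (O(n²), fine at administrative-ring sizes), and
degeneracy is a zero shoelace area below 10⁻¹².

`run_pipeline` wires the stages together and fails — rather than writes
partial output — if any enrichment triple would end up without
provenance. The acceptance script (`scripts/acceptance.R`) recomputes
the same quantities from a fresh installation and seed, writing bare
numbers to JSON; it is the package's reproducibility contract.
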