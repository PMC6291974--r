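---
title: "The two-stage siting model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-stage siting model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehfsiter)
```

`ehfsiter` sites community elderly healthcare clinics in a single planar
community. This vignette is the package's account of the model itself: what
it assumes, which knobs matter, what the synthetic generator does and does
not emulate, and where the design was genuinely open.

## The model

### Demand

The community is described by three numbers — households `P`, persons per
household `N`, elderly ratio `R` — and a set of buildings with floor areas
`a_i`. Every building is assumed fully occupied, so the elderly headcount at
its centroid is its floor-area share of the community total:

$$EP_i = \frac{a_i}{A}\,P\,N\,R,\qquad A=\sum_i a_i .$$

The allocation conserves the community total exactly
(`sum(EP_i) = P·N·R`), which is the invariant the tests assert. The same
share times `P·N` gives a per-building *resident* count, carried separately
because facility sizing standards are written per resident while coverage
demand is elderly.

Accepted walk times from a questionnaire convert to service radii through
the elderly walking speed of 50–60 m/min: 5 minutes means 250–300 m. The
pipeline works with the interval's upper end, giving the clinic radius
`m = 300` and (for the 10-minute center analogue) `M = 600`, which coincide
with the municipal planning standard. Survey percentages are rounded
half-up to two decimals; the response rate is `100·n_valid/n_distributed`
on the same rounding. The survey's own adequacy check is Cochran's
maximum-variance sample size with a finite-population correction,
`n = n_0/(1+(n_0-1)/pop)`, `n_0 = z^2/(4\,\text{margin}^2)`, rounded up
(383 respondents for a 100,000-person community at 95%/5%).

### Stage 1: candidate screening

Four raster layers share one grid (origin lower-left, cell centers, 10 m
cells by default — fine enough to resolve 300 m buffers and the 25 m
candidate lattice):

1. **Developable land** — 1 unless the cell center lies inside a parcel
   flagged used. Ground outside every parcel counts as unused by default
   (`outside_is_used` flips this for partially parceled inputs).
2. **Center catchment mask** — 1 iff the cell center is strictly farther
   than `M` from every existing healthcare center.
3. **Clinic catchment mask** — the same with `m` and the existing clinics.
4. **Elderly density** — a weighted bivariate Gaussian kernel density of
   the building centroids,
   $$\hat f(x)=\sum_i EP_i\,\frac{1}{2\pi h^2}
     \exp\!\Big(-\frac{\lVert x-x_i\rVert^2}{2h^2}\Big),$$
   binned into ten equal-interval classes (1 = sparsest). Quantile binning
   is available via config for heavily skewed surfaces.

The kernel is normalised so the surface integrates to the total elderly
population; the unit is persons/m². A one-dimensional form of this
estimator is sometimes printed with the kernel constant $1/\sqrt2$, which
does not normalise a Gaussian; the application is planar, so the package
uses the correctly normalised bivariate constant $1/(2\pi h^2)$ —
population conservation is part of the test suite.

Suitability is the cellwise **product** of the four layers. The product
form reproduces the screening table exactly: any failed binary zeroes the
cell, and with ten classes and the candidate threshold of 4 (strict), a
cell qualifies iff all screens pass *and* its density class is at least 5.
Candidates are the points of a 25 m lattice anchored at the raster origin
whose containing cell (half-open membership, top/right community edge
assigned to the last cell) exceeds the threshold, enumerated row-major so
the candidate order — the final tie-break downstream — is deterministic.

### Bandwidth

The classical bandwidth target is the minimiser of the mean integrated
squared error, which depends on the unknown density; the package
operationalises it as least-squares cross-validation (LSCV) minimised over
a configurable grid (default: 10 log-spaced values from the cell size to a
quarter of the extent), with weights treated as multiplicities and the
closed-form Gaussian expression for the score. A fixed numeric bandwidth
can always be supplied instead; the fixture uses 100 m, the scale of a
walkable catchment, so the class-5 contour hugs each residential compound
rather than individual towers. LSCV tracks the analytic AMISE optimum
$h^* = \sigma n^{-1/6}$ within a factor of two on Gaussian test data, which
is the property the suite checks.

### Stage 2: greedy bi-objective selection

Per round, over the *remaining* candidates and demand:

1. coverage of candidate `i` = `sum(Popu_k)` over demand with
   `Dist_ik <= m` (boundary inclusive);
2. `Q` = the set of candidates attaining the maximum (the
   maximal-coverage objective);
3. the committed site is the member of `Q` minimising
   `sum(Popu_k · Dist_ik)` over the demand it covers (the p-median
   objective); residual ties go to the earliest candidate in lattice
   order;
4. the site and the demand it covers leave the pool, enforcing single
   assignment and making per-round coverage non-increasing.

The loop stops when demand is exhausted, no candidate reaches any residual
demand, the best coverage drops below `min_covered_population`, or
`max_sites` is reached. Distances are straight-line throughout: the
catchments the model reasons about are circular buffers, and road-network
distances are out of scope. On instances small enough to enumerate
(≤ 8 candidates, ≤ 30 demand points) the greedy trace is checked
round-for-round against exhaustive enumeration.

Facility floor area is `ceil(covered · index/1000)` m², `index` between 15
and 30 m² per 1000 covered persons (default 30, the generous end of the
standard). Sizing uses the resident weight when present, since the
10,000-person allocation floor and the per-1000 index are resident-based;
coverage and the tie-break always use elderly weights. The pipeline
converts the resident-based floor to elderly units by multiplying by `R`
before passing it to the greedy loop.

## The synthetic generator

`generate_community()` draws building centroids from a mixture of isotropic
Gaussian compounds, floor areas log-normal (median 2000 m², log-sd 0.5 — a
mid-rise apartment block), a regular square parcel partition with a
Bernoulli `used` flag, existing facilities pinned at compound centers, and
a multinomial questionnaire. Sampling order is fixed, and the GeoJSON/CSV
writers serialise at full double precision, so a spec plus seed reproduces
every artifact byte-for-byte.

It emulates the statistical structure the model needs — clustered demand,
partial existing coverage, interspersed developable parcels — and nothing
else: no road network, no parcel ownership, no correlation between
building size and location, and `used` parcels are independent of where
buildings stand. Passing tests on generated data therefore demonstrate the
*mechanics* (conservation, screening semantics, greedy optimality per
round, full residual coverage), not calibration to any real community.

`daishan_like_fixture()` is the fixed scenario used in examples and
end-to-end checks: 2.4 km square, 142 buildings in six compounds of
27/19/12/22/17/45 buildings at fixed centers at least 900 m apart, 100,000
residents (`P = 40,000`, `N = 2.5`) with `R = 0.30`, one existing 600 m
center at the 45-building compound and four 300 m clinics at four others,
leaving the 27-building compound unserved; survey probabilities equal the
observed shares 206/122/76/18/0 of 422. Two scenario choices deserve
justification:

* **Compound spread 60 m.** Dense multi-tower compounds of 12–45 buildings
  occupy a footprint of roughly 350 m; a 60 m isotropic spread reproduces
  that and puts essentially every building of a served compound inside its
  facility's catchment — the regime in which the remaining demand is
  concentrated in the unserved compound and complete residual coverage is
  the expected outcome.
* **`min_covered_population = 0` in the fixture config.** The unserved
  compound holds roughly a fifth of the community (≈ 20,000 residents
  spread over 27 buildings, of which one clinic catchment captures most),
  but residual demand after the first selection can fall below the
  10,000-resident floor; the fixture waives the floor so the run
  demonstrates the complete-coverage property. Real planning runs should
  keep the default 10,000.

## Numerical choices and degenerate inputs

* Percent rounding is half-up (not banker's), matching how planning tables
  are printed.
* Coverage at exactly the service radius counts as covered; cell-boundary
  points belong to the cell above/right (half-open), and polygon-boundary
  points count as inside. All three are deterministic tie rules.
* A constant density raster maps to class 1 everywhere (there is no
  "denser" ground to prefer).
* Zero total floor area, zero total KDE weight, an empty candidate set
  passed to the greedy loop, and an empty survey all raise typed errors;
  an empty *extracted* candidate set is a legitimate pipeline outcome
  reported as `no_feasible_sites` (CLI exit code 2).
* Equality in the greedy argmax is exact floating-point equality; both the
  implementation and the enumeration oracle sum demand in input order, so
  the comparison is well defined. Ties beyond the two objectives resolve
  by candidate order for reproducibility.

## Problem sizes

The default checks run the fixture at a 10 m resolution (240×240 cells,
142 buildings, ≈ 30–70 candidates), KDE oracle comparisons at ≤ 50 points
on ≤ 20×20 grids, and greedy-versus-enumeration at ≤ 8 candidates × ≤ 30
demand points over 100 seeds — sizes chosen so the whole suite exercises
every property in well under a minute per module while the enumeration
oracle stays exact.

## Known limitations

* Straight-line distance only; no travel-time or network modelling.
* Single community, single period, no capacity constraints; the greedy
  heuristic is locally optimal per round, not a global MILP optimum.
* Equal-interval density classes depend on the global min/max, so one very
  dense compound can push sparser compounds below the candidate threshold;
  quantile binning mitigates this.
* The package never reprojects: inputs must already be planar metric, and
  lon/lat-looking layers are rejected outright.
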