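# ehfsiter

Two-stage spatial siting of elderly healthcare facilities (EHFs) in large
residential communities.

Planners of large affordable-housing communities face a recurring question:
where should new community healthcare clinics go so that the elderly — often
30% of such a community's residents — can reach one on foot, and how large
should each clinic be? `ehfsiter` implements a complete, reproducible
answer for a single community on a planar metric map:

* **Stage 0 — demand.** The community's elderly population is spread over
  building centroids in proportion to floor area,
  `EP_i = (a_i / A) · P · N · R`, where `a_i` is the floor area of building
  *i*, `A` the total floor area, `P` the number of households, `N` persons
  per household and `R` the elderly ratio. Accepted walk times from a
  resident survey convert to service radii (walking speed 50–60 m/min, so a
  5-minute walk means a 250–300 m clinic radius; the working radii are
  *m* = 300 m for clinics and *M* = 600 m for healthcare centers).
* **Stage 1 — candidate screening.** Four raster layers on a shared metric
  grid: a binary developable-land screen (used parcels → 0), binary
  outside-catchment masks for existing centers (distance > *M*) and clinics
  (distance > *m*), and a population-weighted bivariate Gaussian kernel
  density surface of the elderly, binned into ten equal-interval classes.
  Their cellwise product is the suitability score; a 25 m lattice point is a
  candidate site iff its cell's suitability is strictly greater than 4 —
  equivalently, all screens pass and the density class is ≥ 5.
* **Stage 2 — greedy bi-objective selection.** Each round scores every
  remaining candidate *i* by the remaining demand it covers,
  `max Σ_k Popu_k` over demand points with `Dist_ik ≤ m` (maximal covering
  location problem), keeps the argmax set, and commits the member minimising
  the demand-weighted distance `Σ_k Popu_k · Dist_ik` (p-median tie-break).
  Covered demand is removed (each demand point is assigned once) and the
  loop repeats until demand is exhausted, no candidate reaches any residual
  demand, coverage falls below the allocation floor, or a site cap is hit.
  Each facility is then sized at `ceil(covered · index / 1000)` m² with
  `index` = 15–30 m² per 1000 covered persons.

A seeded synthetic-community generator (clustered buildings, parcel grid,
existing facilities, multinomial survey) makes every stage testable without
any external data.

## Worked example

The built-in fixture is a structural analogue of a real 2.4 km² community:
142 buildings in six residential compounds (27/19/12/22/17/45 buildings),
100,000 residents at a 30% elderly ratio, one existing healthcare center
and four clinics leaving the 27-building compound unserved.

```r
library(ehfsiter)
run <- run_pipeline(daishan_config())
print(run)
#> ehf_run [ok]: 142 buildings, 44 candidates, 1 planned site(s)
#>   demand covered (existing + planned): 100.0% overall, 100.0% of residual
#>  round    x    y covered_population sizing_population weighted_distance q_set_size floor_area
#>      1 1200 1175           5994.111          19980.37          455693.4         44        600
```

One new clinic at (1200, 1175) — 25 m off the unserved compound's center —
covers all 5,994 residual elderly (19,980 residents), bringing the whole
community within a service radius of some facility; at 30 m² per 1000
residents it needs a 600 m² floor. The sizing rule on its own:

```r
size_facility(12430, 30)   # 373  m² for a clinic covering 12,430 persons
size_facility(14390, 30)   # 432  m² for one covering 14,390 persons
derive_service_radius(walk_model(5))   # lower 250, upper 300 (meters)
```

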