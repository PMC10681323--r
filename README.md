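# reeftrace

Residency, site-fidelity and movement-network analysis of passive acoustic
telemetry detections, built for island-shelf receiver arrays monitoring
reef-associated sharks.

## What it does, and for whom

Passive acoustic telemetry yields an event log — one row per reception of a
tagged animal's coded transmission by a moored receiver. Turning that log
into ecology requires a chain of conventions and indices that are easy to
get subtly wrong: receiver-to-station calendar resolution, false-detection
filtering, day-resolution presence metrics, and a family of bespoke
descriptive indices. `reeftrace` packages that chain for movement
ecologists as tested, composable functions with tibbles in and out:

* **Pre-processing** — deployment-calendar resolution of receiver serials to
  stations, fixed-offset local time, duplicate removal, array-wide
  single-detection filtering, exclusion of stations with under six months of
  receiver coverage.
* **Residency** — per-shark detection metrics; the Residency Index
  `RI = detection days / monitoring period` (tag battery life, truncated at
  study end); a rule-based Classification of Residency into Passer-by /
  Transient / Pseudo-resident / Resident; cohort summaries with
  zero-imputation for never-detected animals.
* **Site-fidelity & space use** — per-station Detection Index (product of
  detection and detection-day proportions), Site-Fidelity Index
  (`SFI = DI / ΣDI × 100`, primary site = rank 1), minimum linear
  displacement (greatest great-circle distance between detecting stations,
  plus detection-radius corrections), station Utilization Index and monthly
  Activity Index.
* **Movement networks** — directed station-transition matrices for any data
  subset (sex, maturity, season, diel), node degrees, Mantel permutation
  tests of network overlap, Mann-Whitney comparison of node-degree
  ("mobility") vectors, edge-list/GraphML export.
* **Nonparametric statistics** — chi-squared goodness of fit, tie-corrected
  Spearman, Mann-Whitney, Kruskal-Wallis, Dunn post-hoc, Fisher exact, each
  returning a uniform one-row tibble.
* **Synthetic telemetry** — an agent-based simulator of detection logs with
  known ground truth (behavioural archetypes, ~90 s randomised transmission
  delay, 300 m detection radius, receiver outages, summer-biased
  inter-island excursions), so every pipeline stage is testable without
  field data.

## A worked example

```r
library(reeftrace)

cfg <- sim_scenario("minimal", seed = 7)   # 1 island, 8 stations, 5 sharks
sim <- simulate_sharks(cfg)
res <- run_pipeline(sim$detections, sim$stations, sim$deployments,
                    sim$sharks, sim$config)
res
#> <reef_analysis>
#>   5 tagged sharks, 5 detected; 902 analysed detections
#>   mean RI 0.112 | mean primary SFI 95.7% | mean MLD 6.4 km
#>
#> Pass.-by   Trans. Ps.-res. Resident
#>        3        0        1        1

dplyr::select(tidy(res), tag_id, n_detections, n_detection_days,
              ri, cr, mld_km, sfi_primary)
#> # A tibble: 5 × 7
#>   tag_id n_detections n_detection_days     ri cr       mld_km sfi_primary
#> 1 60001            20                4 0.0110 Pass.-by   4.42        92.3
#> 2 60002           511               65 0.348  Resident   7.66        94.6
#> 3 60003           121               17 0.0726 Pass.-by   7.66        97.1
#> 4 60004           110               14 0.0526 Ps.-res.   7.66        94.6
#> 5 60005           140               18 0.0779 Pass.-by   4.42        99.7
```

Each row is one tagged shark: its detection tallies, Residency Index (share
of the monitoring period with ≥ 2 detections/day), residency class, linear
home-range proxy in km, and the Site-Fidelity Index of its primary
receiver. Shark 60002 was simulated as a resident (daily presence
probability 0.47) and is recovered as one; the three passer-bys left within
a month of tagging.

The package ships the published per-shark summary of the Cayman Islands
Caribbean reef shark cohort as a plain-text fixture, so index arithmetic
can be checked against printed values:

```r
t2 <- cayman_table2()
mean(residency_index(t2$n_detection_days, t2$tag_life_days))
#> [1] 0.0607355   # printed as 0.06 for the 39 detected sharks
```

## Design notes

The methods vignette (`vignettes/reef-shark-telemetry.Rmd`) documents the
model conventions and the reasoning behind the open design choices: the
array-wide reading of the single-detection filter, totality of the
residency classifier, threshold-equality assignment, the dimensional
idiosyncrasies of the Utilization and Activity indices, subset-first
network pairing, and what the simulator does and does not emulate.
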