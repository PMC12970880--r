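# grazemark

Spatial analysis of endozoochorous seed dispersal by ungulates in
grasslands.

Wild and domestic ungulates (deer, cattle, horses, wild boar) disperse
herbaceous seeds in their dung. At the scale of a single grassland plot, the
community of dispersers leaves a spatial fingerprint: species with heavy,
spatially clumped deposits and high seed loads (cattle) can concentrate seed
arrival in patches, while solitary light-dung dispersers (deer) spread seeds
without structure. `grazemark` detects that fingerprint from georeferenced
fecal-deposit and seed-count tables.

## What it computes

Deposits with coordinates `x_i` and per-unit seed content `m_i` (seeds per
gram dry weight x the species' mean dung weight per defecation) form a
quantitatively marked point pattern. Three ring-based statistics, estimated
with a box kernel of half-width `h` over ordered point pairs at distance
`r ± h`, probe different aspects of mark structure:

* `k_m(r)` — **r-mark correlation**: mean mark of deposits having a
  neighbor at distance `r`, relative to the overall mean mark `μ`.
  `k_m(r) > 1`: aggregated feces carry above-average seed loads.
* `I_mm(r)` — **Schlather's mark correlation**: Moran-like correlation of
  the marks of pairs separated by `r` (ring-centered, normalized by the mark
  variance `σ²`). Positive: nearby deposits have similar loads.
* `C_m,K(r)` — **density correlation**: Pearson correlation between a
  deposit's mark and its neighbor count `K_i(r)` within distance `r`.

Inference is by **random labelling**: point locations stay fixed, marks are
permuted (199 simulations by default). Pointwise envelopes take the 5th
lowest/highest simulated values (two-sided pointwise level
`2k/(n_sim+1) = 0.05`), and a rank-based goodness-of-fit test sums squared
deviations from the leave-one-out null mean over 0–50 m:
`p = (1 + #{u_sim ≥ u_obs}) / (1 + n_sim)`, so the smallest attainable p
with 199 simulations is 0.005.

Supporting machinery: CSV readers/writers for the two-table data layout,
seed-content standardization, a two-sided single-outlier Grubbs screen for
extreme samples, per-species and per-family summaries, a synthetic-site
generator (Poisson and Thomas cluster point processes, negative-binomial
seed loads, cluster-shared mark factors) and a configuration-driven
end-to-end pipeline.

## Worked example

Simulate a mixed four-ungulate community on 10 ha (cattle deposits
Thomas-clustered with cluster-shared seed loads) and test for spatial
covariance in seed content:

```r
library(grazemark)

d <- sim_site("martinazo_like", rng_seed = 42)
d
#> fecal_deposits: 118 deposits, 600 seed records, 1747 seeds total
#>   species: cow=24, deer=66, horse=14, wild_boar=14

pat <- to_marked_pattern(d)          # marks = seeds per fecal unit
run_mark_analysis(pat, "schlather", n_sim = 199, rng_seed = 43)
#> mark analysis [schlather]: n_sim = 199, k = 5, GoF p = 0.005
#>   outside envelope at r = 0.5, 1.5, 2.5, 3.5, 4.5, 24.5, 25.5, 26.5, 29.5, 30.5, 31.5 m
```

The observed Schlather curve exceeds its null envelope at short distances
(r ≤ 4.5 m — nearby deposits share similar seed loads, the clustered-cattle
signature) and the goodness-of-fit p-value is at its 0.005 floor: the
random-labelling null is rejected. The descriptive side:

```r
species_totals(seed_content_records(d))
#>     species cumulated_seeds pct_of_site_total
#> 1       cow       129024.00              73.1
#> 2     horse        29520.00              16.7
#> 3      deer        17479.04               9.9
#> 4 wild_boar          557.28               0.3
```

Cattle leave under a quarter of the deposits but nearly three quarters of
the dispersed seeds — their dung is 630 g per defecation against 49.6 g for
deer. The full pipeline (`run_full(run_config(...))`) adds the Grubbs
screen, family summaries, microsite physiognomy, and per-family spatial
analyses for the most frequent plant families, writing tidy CSV/JSON
outputs and a reproducibility manifest. A command-line wrapper lives at
`inst/cli/grazemark.R`:

```sh
Rscript inst/cli/grazemark.R simulate --template martinazo_like --seed 42 --out scratch/site
Rscript inst/cli/grazemark.R run --config config.json
```

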