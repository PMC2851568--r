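# nextinline

Tools for testing the **next-in-line model of S-phase progression**: the
hypothesis that genomic regions replicate in sequence because the replicon
clusters packaged as DNA foci (~0.5–1 Mbp chromatin units, 3–5 replicons
each) are activated in the order of their genetic continuity along the
chromosome — the cluster finishing synthesis hands off to its neighbour on
the DNA fibre, not to its neighbour in nuclear space, and not at random.

The package provides, as a single tested pipeline:

* **Monte-Carlo nuclear simulation** — labeled replication foci (default:
  350 spheres of 500 nm per 1 h time zone × 10 zones, 3500 foci filling
  44% of a 10 µm spherical nucleus) under three activation models
  (*genetic*, *spatial*, *random*), with mitotic segregation down to ~3
  labeled chromosome territories and territory plasticity.
* **3D spatial statistics** — nearest-neighbour separations within and
  between pulse channels, co-association fractions at a 500 nm threshold,
  Welch *t* contrasts, naive volume occupancy, and voxel co-localization.
* **Replicon-cluster content simulation** — cluster DNA content as a
  compound sum: cluster size *k* from a replicons-per-cluster pmf, replicon
  lengths from a positive-truncated normal
  *L* ~ N(μ = 140.6238, σ = 58.8192) kbp, content = Σᵢ Lᵢ; binned
  distribution profiles compared by Pearson correlation.
* **Timing-domain segmentation** — prominence-filtered peak calling on
  binned replication-timing profiles, with valley boundaries refined to
  sub-bin precision; domains tile the profile exactly.
* **DNA fiber analysis** — classification of pulse–chase–pulse labeled
  fiber tracks (30 min / 1 h / 20 min, 2.59 kbp/µm) into *extending*,
  *secondary activation* and *uncoupled* (>250 kbp from any first-pulse
  track) classes, inter-origin distances and fork-rate estimates.

Every simulator attaches ground truth, so each analysis step is validated
end to end; all randomness is seed-scoped and bit-for-bit reproducible.

## Worked example

Simulate a genetic-model nucleus, segregate to 3 territories, deform the
territories, and measure the co-association of consecutively labeled foci:

```r
library(nextinline)

fs <- gen_nuclear_foci(nucleus_config(), model = "genetic", seed = 42) |>
  apply_segregation(3, seed = 43) |>
  apply_plasticity(400, seed = 44)
nrow(fs)
#> [1] 220

d <- nn_cross_channel(zone_subset(fs, 1), zone_subset(fs, 2))
summarize_distances(d)
#> # A tibble: 1 × 3
#>   mean_nm sd_nm     n
#>     <dbl> <dbl> <int>
#> 1    478.  58.5    22

coassociation_fraction(zone_subset(fs, 1), zone_subset(fs, 2), 500)
#> [1] 1
```

Every zone-1 focus keeps a zone-2 focus within 500 nm (mean separation
~478 nm — about one focus diameter, the side-by-side signature). The same
pipeline under the random activation model gives a co-association fraction
of 0.25 at the same seed: random activation does not survive segregation
and plasticity, which is the discrimination at the heart of the package.

Fiber classification with ground truth:

```r
fb <- gen_fibers(fiber_config(), n_fibers = 500, seed = 1)
cohort_report(fb)
#> # fiber_report: 500 fibers (0 excluded)
#> # A tibble: 3 × 3
#>   class                    n proportion
#>   <chr>                <int>      <dbl>
#> 1 extending              290       0.58
#> 2 secondary_activation   185       0.37
#> 3 uncoupled               25       0.05
#> uncoupled fraction: 0.050 per fiber, 0.048 per track group
```

Five percent of fibers carry initiation events uncoupled from first-pulse
synthesis, and extending clusters show wider inter-origin spacing (~180 kbp)
than clusters that trigger secondary activation (~154 kbp) — the spacing
difference that links cluster structure to activation of the adjacent
cluster. Cluster DNA content:

```r
cs <- sample_clusters(10000, seed = 2)
glance(build_profile(cs$dna_content_kbp))
#> # A tibble: 1 × 5
#>   mean_kbp sd_kbp p05_kbp p95_kbp     n
#>      <dbl>  <dbl>   <dbl>   <dbl> <int>
#> 1     567.   162.    316.    849. 10000
```

The mean content equals E[*k*]·E[*L*] (4 × 141.98 kbp) — cluster DNA
contents of a few hundred kbp, on the scale of replication timing domains.

A shell entry point over the same functions is installed at
`system.file("scripts", "nextinline-cli.R", package = "nextinline")`
(subcommands `simulate-foci`, `nn`, `simulate-clusters`,
`simulate-profile`, `segment-domains`, `simulate-fibers`,
`classify-fibers`).

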