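---
title: "Models and methods: simulating and testing next-in-line S-phase progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and testing next-in-line S-phase progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nextinline)
```

## The scientific question

During S phase, mammalian genomes replicate as a sequence of ~1 Mbp chromatin
units — DNA foci, each holding a cluster of 3–5 replicons that fire together
in one replication factory. Different foci replicate in different hours of S
phase, and the question this package addresses is *what orders them*: does a
focus activate because it is the **genetic** neighbour of a focus finishing
synthesis (the next-in-line model, propagating in cis along the chromosome),
because it is the **spatial** neighbour of a decaying factory (propagation
through the nucleoplasm), or at **random** within its chromatin compartment?

The three hypotheses are indistinguishable at labeling time — in early S
phase every pulse-labeled focus has neighbours of the other label within a
few hundred nanometres regardless of mechanism. They separate after two
experimental manipulations that the package simulates explicitly:

1. **Mitotic segregation.** Cells grown for days after labeling dilute the
   labeled chromosomes until ~3 labeled territories remain per nucleus,
   isolating individual chromosomes for analysis.
2. **Territory plasticity.** Chromosome territories deform continuously
   (shifts of 0.2–0.6 µm over 30 min). Spatial relationships that are not
   anchored in the chromosome's own connectivity decay; genetic neighbours
   stay adjacent because the fibre itself links them.

After both, a near-1:1 co-association of consecutively labeled foci at
~500 nm survives only under the genetic model. That is the discrimination
statistic the package computes.

## The nuclear foci simulator

`gen_nuclear_foci()` places `foci_per_zone × n_zones` spheres (default
350 × 10 = 3500, 500 nm diameter) fully inside a 10 µm spherical nucleus.
Centres are sampled uniformly in the ball of radius $R - r$ by rejection from
the bounding cube. Overlap between foci is permitted: the reference
occupancy figure for this configuration is the naive volume-sum ratio
$3500 \, (r/R)^3 = 3500 \times (250/5000)^3 = 0.4375$, which only holds if
overlap is ignored, so the generator matches that convention.

All three activation models share one chromosome representation — 46 chains
by default (a diploid-like territory count; the underlying studies give no
chain geometry, so this is a biologically motivated choice, not a measured
value). Sharing the chains across models matters: mitotic segregation acts
on chromosomes whatever the activation mechanism, so `apply_segregation()`
must behave identically under every model and only the *zone labeling*
may differ:

* **random** — uniform positions; zone labels are a random permutation.
* **spatial** — uniform positions; one seed point per zone, each focus takes
  its nearest seed's zone, and counts are rebalanced to exactly
  `foci_per_zone` by moving the farthest excess foci to the nearest
  under-quota zone. Same-zone foci therefore cluster in space.
* **genetic** — each chain is a random walk with step length equal to the
  focus diameter (touching spheres — the chromatin fibre drawn at focus
  resolution), reflected radially at the nuclear boundary. Zone labels run
  `1..n_zones` repeatedly along the chain.

The cyclic zone assignment deserves a note. A chromosome does not replicate
from one end to the other over 10 hours; labeled foci in metaphase spreads
are distributed along the whole chromosome, which implies many concurrent
activation streams per chromosome, each progressing focus-by-focus. Cyclic
runs of `1..n_zones` are the minimal structure with that property, and they
make the defining invariant of the genetic model exact: *every* focus of
zone $z < n_\mathrm{zones}$ is chain-adjacent (one step, i.e. one focus
diameter) to a focus of zone $z+1$. A block assignment (all zone-1 foci,
then all zone-2 foci, …) would leave only block-boundary foci with that
guarantee and could not reproduce the observed per-focus 1:1 co-association.
Chain lengths are multiples of `n_zones` (3500 foci over 46 chains gives 28
chains of 80 and 18 of 70), so zone runs tile chains exactly and per-zone
counts are exact by construction.

`apply_plasticity()` emulates territory deformation. For the genetic model
each chain moves rigidly — a Gaussian translation (sd `step_sd_nm` per axis)
plus a small rotation about the chain centroid — and is then projected back
into the nucleus by radial clamping. Rigid motion preserves chain-adjacent
separations exactly, and the radial clamp is the Euclidean projection onto a
ball, which is 1-Lipschitz and therefore never increases pairwise distances;
the connectivity contract (adjacent separations within 1.5× their original
value) holds with margin. For the random and spatial models each focus is
displaced independently (isotropic Gaussian), which is the point: nothing
ties a focus to its labeled-time neighbour, so co-association decays.

## Nearest-neighbour and co-association statistics

Distances are centre-to-centre in 3D, matching the mass-centre measurements
of the imaging pipeline the data would come from. `nn_cross_channel()`
computes, for each focus of channel *a*, the distance to its nearest
channel-*b* focus (ties broken toward the lowest focus id);
`nn_within_channel()` excludes self-pairs. Both are checked exactly against
an O(n²) brute-force oracle in the test suite. `coassociation_fraction()`
is the fraction of *a* foci with a *b* neighbour within a threshold
(500 nm by default — the co-association scale of consecutively labeled
foci). The comparison is inclusive with a 1e-6 nm guard because in the
genetic model chain-adjacent foci sit at *exactly* one focus diameter;
without the guard, floating-point round-off in rigid-motion arithmetic would
arbitrarily flip distances at the threshold.

Summary statistics use the sample standard deviation (n−1); the sd of a
singleton is 0 by convention with a warning. Condition contrasts use the
Welch (unequal-variance) two-sided t test: the compared samples throughout
this design have unequal sizes and spreads, so the pooled-variance test
would be the wrong default. Two zero-variance samples with equal means
return p = 1 by convention.

`volume_occupancy()` is the naive volume-sum ratio described above (additive
over disjoint subsets, may exceed 1). `colocalization_fraction()` rasterizes
foci into voxels (centre-in-sphere membership, default 50 nm — the imaging
voxel size is not known, and 50 nm is comfortably below the 500 nm focus
scale) and reports $|V_a \cap V_b| / |V_a|$, the per-voxel co-localization
used for nascent-DNA maturation chases.

## The replicon-cluster content model

Replicon lengths follow a normal distribution with the published fit
μ = 140.6238 kbp, σ = 58.8192 kbp, truncated to positive values. The default
truncation rule resamples non-positive draws, i.e. the model is the normal
*conditioned* on positivity. That conditioning is not free: with these
parameters Φ(−μ/σ) ≈ 0.0084 of the mass is cut, and the closed-form
truncated moments (`truncated_normal_moments()`) are a mean of 141.98 kbp
(+0.97% of μ) and an sd of 57.16 kbp (−2.83% of σ) — removing a far tail
affects the second moment much more than the first. The tests therefore
assert convergence of sample moments to the *truncated* moments; the shift
from the nominal parameters is a property of the model, not an estimation
error. A `"clamp"` truncation rule is available for users who prefer to
keep the nominal moments nearly intact.

Cluster DNA content is a compound sum: draw the cluster size $k$ from a
probability mass function over replicons-per-cluster, then sum $k$
independent replicon lengths, with no inter-replicon gaps. The default pmf
is uniform over {3, 4, 5} (mean 4), motivated by the observation that
clusters typically contain 3–5 replicons within ~1 Mbp; the exact frequency
table used in the original Matlab simulation comes from a separate
publication and is not reproduced here, so the pmf is fully
user-configurable and the simulated means are conditional on it. The test
suite asserts the distribution-free identity
$E[\mathrm{content}] = E[k] \cdot E[L]$ (Wald) against an enumeration
oracle rather than any particular reported mean.

`build_profile()` histograms values from 0 with a fixed bin width (default
50 kbp), normalizes to frequencies, and records mean, sample sd and the
central 90% interval as empirical 5th/95th percentiles with linear
interpolation between order statistics (`stats::quantile` type 7; on the
grid 1..1000 this gives 50.95 and 950.05). `profile_correlation()` is the
Pearson correlation of per-bin frequencies on a shared grid, padding the
shorter profile with empty trailing bins (to which frequencies are
invariant); zero-variance profiles are an error rather than an `NA`.

## Timing-domain segmentation

A replication-timing profile is a binned signal in which higher values
replicate earlier, peaks are timing domains, and valleys separate them.
`call_domains()` operationalizes the by-eye inflection-point reading of
such profiles:

1. optional centred moving-average smoothing (default window 3 bins, edge
   truncated; window 1 is the identity);
2. local maxima (plateau-aware) filtered by **topographic prominence** —
   peak height above the higher of its two key saddles — with the default
   threshold 0.1 × the interquartile range of the smoothed signal, a scale
   that adapts to the profile without tuning;
3. a boundary at the valley between each pair of surviving apexes: the
   argmin bin (ties broken toward the midpoint between the apexes), refined
   to sub-bin precision by intersecting the descending and ascending flank
   lines fitted to the bins around the argmin. The refinement is exact for
   noise-free piecewise-linear valleys and falls back to the argmin bin
   midpoint (error below one bin) when no clean V validates. Profile ends
   count as boundaries, so domains tile the profile with shared boundaries
   and no gaps;
4. domains shorter than `min_domain_length_kbp` (default 0) merge into the
   neighbour with the higher apex, repeating until stable.

Raising the prominence threshold can only remove peaks, so the number of
called domains is monotone non-increasing in it — a property the tests
exercise directly.

The synthetic generator `gen_timing_profile()` plants triangular peaks with
specified lengths and apex heights over 10 kb bins (valleys at zero, apex at
the domain midpoint) plus optional Gaussian noise, and records the planted
boundaries as ground truth. On noise-free profiles segmented without
smoothing, boundaries and domain lengths are recovered exactly; with the
default 3-bin smoothing, recovery is within one bin. Domain lengths in the
275–935 kbp range used throughout the tests correspond to the central 90%
interval of the reference domain-length distribution.

## The DNA fiber simulator and classifier

`gen_fibers()` simulates pulse–chase–pulse labeling on spread fibers: a
30 min first pulse (channel 1), a 60 min chase, a 20 min second pulse
(channel 2), fork rates drawn uniformly from 1–2 kbp/min per fiber, and
lengths converted at 2.59 kbp/µm. Each fiber carries one primary cluster of
3–5 replicons whose origins fire at time zero with inter-origin spacings
drawn from class-specific truncated normal models — 181.2 ± 87.5 kbp for
extending clusters, 119.6 ± 47.0 kbp for clusters that trigger secondary
activation (the measured spacing difference between the two classes, used
here as generator settings), both truncated to 50–250 kbp, the range that
holds 90% of adjacent origins. Forks elongate bidirectionally and fuse where
converging forks meet (the fusion point and time account for unequal firing
times); DNA replicated during each pulse window becomes that channel's
tracks, and abutting coverage merges into single tracks, so closely spaced
origins can legitimately produce one merged channel-1 track.

The ground-truth class mix defaults to 55% extending / 40% secondary
activation / 5% uncoupled — the reported 5% uncoupled rate, with the
remainder split to reflect that both double-labeled classes are common;
the mix is fully configurable. Class construction:

* **extending** — no new origins; the only flank labeling is the single
  channel-2 track of each outgoing fork, separated from the cluster edge by
  the chase distance (rate × 60 min).
* **secondary_activation** — 2–3 new origins fire at the start of the
  second pulse in one or both flanks, placed beyond the point where the
  outgoing fork's track could merge with theirs before the pulse ends, and
  within the 250 kbp coupling distance.
* **uncoupled** — an otherwise-extending fiber plus a remote de-novo
  cluster firing during the second pulse, placed so that its channel-2
  track group is more than 250 kbp from every other track.

Every generated fiber records a total DNA extent of at least 0.8 Mbp
(unlabeled margins included), mirroring the imaging-field selection of the
source protocol; `cohort_report()` excludes fibers below that extent by
default.

`classify_fiber()` applies the scoring rules. The primary cluster is the
largest-span run of channel-1 tracks chained at gaps ≤ 250 kbp. Channel-2
tracks in a flank (near edge within the 250 kbp exclusion distance of the
cluster) are counted: two or more distinct tracks mean secondary
activation; a single track is the extending fork only if its gap from the
cluster edge is compatible with the chase distance (default cap 130 kbp,
just above 2 kbp/min × 60 min), otherwise it too indicates a secondary
origin. **Uncoupled detection is group-level**: channel-2 tracks are
chained at the same 250 kbp gap, and a group with no channel-1 track within
the exclusion distance is an uncoupled initiation. A per-track rule would
misread the outer tracks of a legitimately coupled secondary cluster —
whose first track couples to channel 1 but whose second may sit beyond
250 kbp — as uncoupled; the group rule matches how uniquely-second-label
regions are scored on real spreads. A fiber containing an uncoupled group
(including a channel-2-only fiber) is classified uncoupled.

Origins are proxied by channel-1 track midpoints (exact for symmetric
bidirectional forks), giving inter-origin distances per cluster; fork rates
are estimated as track length over pulse duration, halved for bidirectional
tracks, and flagged when outside 0.5–3 kbp/min. The cohort report gives the
uncoupled fraction both per fiber and per labeled track group, since the
original per-track phrasing is ambiguous between the two.

## Reproducibility and numerical conventions

Every stochastic function takes an explicit integer seed and scopes it with
`withr::local_seed()`, so results are bit-for-bit reproducible and the
global RNG state is never disturbed. Interval formats follow UCSC
conventions (0-based half-open bedGraph and BED6, via rtracklayer); tabular
formats are TSV with a `#key=value` metadata line. `run_pipeline()` writes a
JSON run log with the configuration echo, seed, package version and record
counts for every stage.

Problem sizes in the shipped tests were chosen to make the checked
properties statistically decisive while keeping the suite quick: 3500-focus
nuclei over 20 seeds for the model discrimination, 10⁶ draws for the length
model moments, 1000 fibers for the classification and uncoupled-rate
checks, 112 planted domains for length-distribution recovery.

## What the synthetic data does and does not establish

The generators emulate the *structure* of the real inputs — labeled 3D
centroids, binned timing signal, labeled track intervals — under the
stated study conditions, with known ground truth. Passing tests therefore
establish that the analysis operations are correct and that the genetic
model's signature survives segregation and plasticity *in the simulation*.
They do not validate the measurements themselves: real in-cell separations
(e.g. ~390 nm after a 1 h chase) are measurement results that depend on
microscopy and labeling chemistry the package does not model (no point
spread function, no chromatic shift beyond an optional jitter, no
segmentation errors, spherical nuclei only). Likewise the reference
domain-length statistics (529.5 ± 208.0 kbp) and the cross-profile
correlations above 0.9 were computed on an external ES-cell timing dataset
that ships with neither an accession nor this package, and the original
cluster-simulation means depend on an unpublished replicons-per-cluster
table; these are documented as external validation. What the package
asserts instead are the corresponding internal properties: exact recovery
of planted domains, the compound-sum identity for cluster content, and
high correlation between independent samples of the same cluster model.

## Known limitations

* Chains are equal-step random walks; real chromatin shows scale-dependent
  compaction and confinement to territories beyond a shared nucleus.
* The spatial model's seed-point construction is one of many ways to make
  zones spatially coherent; its discrimination behaviour is intermediate
  between genetic and random by design, not calibrated to data.
* The fiber simulator fires all primary origins synchronously at time zero;
  real clusters show firing-time dispersion within the activation window.
* No fork stalling, asymmetry, or replication-stress responses.
* The domain caller assumes one apex per domain; shoulder peaks below the
  prominence threshold merge silently into their parent domain.
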