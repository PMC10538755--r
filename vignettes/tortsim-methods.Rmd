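---
title: "Simulating tortoise gene flow across barriers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tortoise gene flow across barriers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tortsim)
```

`tortsim` is an agent-based, spatially explicit, forward-in-time simulator of
gene flow for a low-vagility desert reptile on gridded resistance landscapes,
together with the population-genetic toolkit needed to analyse its output.
This vignette is the package's own account of the models it implements, the
parameters that matter, the design choices that were genuinely open, and the
limits of what the synthetic experiments can show.

## The landscape model

Landscapes are rectangular grids of 1 km² cells (25 × 25 by default, roughly
the size of a single desert valley). Each cell carries

* a **resistance** in [0, 1]: 0 is freely traversable, 1 is an absolute
  barrier; and
* a **carrying capacity** `K`: the number of adult tortoises the cell can
  support.

Resistance is the complement of habitat suitability (`resistance = 1 −
habitat`), and capacity follows a stepped habitat-to-density scale
(`carrying_capacity()`): 0 tortoises for no habitat, 1 for marginal habitat
up to 0.20, then 3, 6, …, 24 in 0.1-wide bins. Anthropogenic disturbance
degrades habitat multiplicatively through conversion factors
(`apply_conversion()`): 1.00 for urban/solar development (habitat removed
entirely), 0.75 for a railway or interstate, 0.25 for minor roads and utility
rights-of-way. Minor-road penalties scale with per-cell road length relative
to the grid maximum, so only the densest cells receive the full 0.25.
Overlapping layers compose sequentially, i.e. multiplicatively on the
retained habitat fraction; the composition is order-independent and stays in
[0, 1], which is why we chose it over a "maximum factor wins" rule.

Three hypothetical scenario surfaces (`build_scenario_surface()`) isolate the
barrier question from landscape heterogeneity:

* `no_barrier` — uniform open habitat;
* `barrier` — a one-cell-wide impassable column bisecting the grid (an
  unfenced interstate/railway corridor, placed at the central column);
* `culverts` — the barrier plus three culvert cells (resistance 0.7,
  `K = 3`), evenly spaced along it. The culvert's capacity doubles as a
  per-generation transit quota: at most three distinct individuals may
  occupy or pass through each culvert per generation. Culvert positions are
  evenly spaced because the source material gives no coordinates.

Heterogeneous surfaces (`build_heterogeneous_surface()`) are built from any
habitat raster plus disturbance layers; rasters read and write as Esri ASCII
grids (plain text, bit-exact round trip). The real valley's habitat model and
GIS disturbance layers are not redistributable, so heterogeneous surfaces in
this package are always synthetic.

## The founder generator

The original 170-individual, 20-locus microsatellite dataset is not
released, so `generate_frequencies()` builds synthetic allele-frequency
tables statistically matched to its published summary: mean expected
heterozygosity He ≈ 0.81 and mean allelic richness Ar ≈ 13. Per-locus allele
counts are drawn around the Ar target (truncated normal, sd = Ar/3 — chosen
to echo the published spread of 7 among loci — minimum 2); frequencies come
from a symmetric Dirichlet whose concentration is set from the closed-form
expectation of He, then tempered (`p^t`, renormalised, `t` found by
bisection) so the realised locus-mean He matches the target to 1e-4. Only He
and Ar are calibrated because only they are reported; no attempt is made to
reproduce the empirical allele-size spectrum, and allele states are abstract
integers. `sample_founders()` draws diploid genotypes under Hardy–Weinberg
proportions with no spatial structure, emulating an empirical panel
randomised to erase isolation by distance.

## The simulation engine

Generations are discrete and non-overlapping (one generation ≈ 17 years).
Each generation applies, in order:

1. **Dispersal.** Every adult disperses with probability 0.5. The default
   kernel (`dispersal_kernel = "random_walk"`) moves a disperser through 10
   successive Queen's-case steps, each to a uniformly chosen traversable
   neighbour — the stepwise reading of "move to one of eight neighbouring
   cells, then up to 10 cells". The alternative `"max_ring"` kernel jumps
   straight to a uniformly chosen habitable cell at the largest reachable
   geodesic Chebyshev distance ≤ 10. Both respect barrier impermeability and
   culvert quotas. We made the walk the default after comparing both against
   the published census trajectories: at moderate density the walk's
   equilibrium census (≈ 8 100 of 8 750 seeded) tracks the published value
   (8 394) closely, while the ring kernel's larger redistribution variance
   depresses it by a further ~8%. The ring kernel remains available and
   tested.
2. **Reproduction.** Within each cell holding at least one male and one
   female, expected recruits follow the discrete logistic map
   `E = N + rN(1 − N/K)` with `r = 0.48` per generation (an annual 1% over
   48 breeding years); the realised count is `floor(E)` plus a Bernoulli
   draw on the remainder — deterministic in expectation with minimal added
   variance, which is why we use it instead of a Poisson draw. Each recruit
   draws its mother and father uniformly with replacement from the cell's
   females and males, inherits one uniformly chosen allele per parent per
   locus, and is male or female with probability 1/2. Cells without a mating
   pair produce nothing.
3. **Mutation.** Each allele copy mutates with probability 5 × 10⁻⁴ per
   locus per generation under a k-allele model over the locus's founder
   state space (a single-step model is available as
   `mutation_model = "smm"`). Loci with one state are skipped.
4. **Mortality.** All adults die; the mutated recruit cohort is the next
   generation. A generation with no recruits ends the replicate with an
   extinction flag.

All stochasticity flows through one R generator per replicate; replicate
seeds derive from the master seed by a single `sample.int()` draw, so every
run is bit-reproducible.

### Initial densities

Populations seed every habitable cell at 3 (low), 14 (moderate) or 20
(high) individuals — 1 875 / 8 750 / 12 500 on the open 625-cell landscape —
or at the cell's own `K` (`"variable"`). High density seeds 20 per cell
rather than `K = 24` because the published initial size is 12 500; the
seeding rule behind that figure is not stated, and we chose the value that
reproduces it exactly.

### A known divergence: low-density persistence

Under the rules above, low density (`K = 3`) is demographically subcritical:
with binomially assigned litter sexes, the expected production of a cell of
size `N` is `E(N) · P(both sexes present) < N` for every `N`, so the census
is a supermartingale and the population collapses within about ten
generations. The study this package emulates reports low-density populations
declining ~75% but persisting at N ≈ 460 through generation 200. We explored
a wide family of rule variants (density-dependent emigration, balanced litter
sex ratios, Poisson recruit noise, occupancy-capped arrivals, survival of
unmated adults, both dispersal kernels) and none reproduces persistence
together with the published genetic signature; the original platform
evidently implements a mechanism its description does not pin down. We kept
the documented rules. Consequences: simulated low-density declines reach
100% rather than ~75% (the direction, an extreme low-density collapse, is
reproduced; the level is overshot), and low-density differentiation at
generation 200 cannot be observed because no population survives that long.
Moderate- and high-density results are unaffected.

## Analysis methods

* **Diversity** (`diversity()`): per-locus observed heterozygosity, Nei's
  unbiased expected heterozygosity (`2n/(2n−1)` correction — the unbiased
  form was chosen because samples of 750 from small drifted populations are
  exactly the case the correction exists for), and raw allelic richness
  (no rarefaction, matching a published richness that grows with sample
  size).
* **Differentiation** (`pairwise_fst()`): multilocus Weir–Cockerham (1984)
  θ between the two barrier sides, summing variance components over alleles
  and loci. Groups are assigned by side of the (real or virtual) central
  column; the handful of culvert occupants sitting exactly on the column are
  assigned a side at random.
* **Effective size** (`ld_ne()`): the linkage-disequilibrium method under
  random mating — Burrows' composite disequilibrium over all cross-locus
  allele pairs after screening alleles below `pcrit = 0.05`, bias-corrected
  by `E[r²|S] = 1/S + 3.19/S²` (S ≥ 30), mapped to Ne through
  `(1/3 + sqrt(1/9 − 2.76 r²')) / (2 r²')`, with `r²' ≤ 0` reported as
  infinite. Parametric 95% confidence limits use a chi-square on the number
  of allele-pair comparisons; the jackknife alternative is not implemented.
  Estimates pool both sides before screening (the per-group alternative is
  a one-line change; pooling matches how the landscape-level figures are
  described).
* **Hardy–Weinberg** (`hwe_test()`): Monte-Carlo exact test by re-pairing
  alleles within a locus (≥ 10⁴ shuffles), probability-ordering statistic,
  Bonferroni threshold 0.05/20 = 0.0025 attached.
* **Spatial structure** (`spca()`, `global_local_test()`, `mantel()`):
  spatial PCA as the eigen-decomposition of `(1/n) Xᵀ L X` with `X` the
  centred individual allele-frequency matrix and `L` the symmetrised,
  row-standardised weights of a k = 8 symmetric nearest-neighbour network
  on jittered cell-centre coordinates (k = 8 mirrors the Queen's-case
  neighbourhood; the source material does not name its network). Every axis
  satisfies `λ = var(scores) × I(scores)` exactly, which the tests verify.
  Global/local permutation tests shuffle individual locations 999 times;
  Mantel tests correlate Euclidean genetic distance on allele-frequency
  vectors with geographic distance, permuting one matrix's row/column order.

## Numerical choices and degenerate inputs

Frequency tempering bisects to 1e-4 on He and fails loudly on infeasible
targets (He above `1 − 1/k`). FST returns 0 (not NaN) for fully monomorphic
data. The convergence scan flags stability when successive FST estimates
change by under 10% relative *or* 1e-3 absolute — the absolute guard stops
near-zero estimates from failing a purely relative criterion. The
representative-snapshot rule rounds distances to the replicate-mean FST at
1e-12 before tie-breaking by replicate index, so float noise cannot flip a
tie. Monomorphic loci: skipped by mutation, p = 1 in HWE tests, dropped by
sPCA with a log. Samples smaller than requested are taken whole with a
warning.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the paper-scale 200
generations but scaled-down replicate counts — 5 replicates for the fast
low-density runs, 3 for the moderate/high ones (cross-replicate SDs of the
final census are ~15–50 individuals, far tighter than the acceptance
tolerances, so extra replicates buy nothing) — and the Wright–Fisher
coverage check uses 50 trials at N = S = 100 with 20 loci. Permutation
counts in tests are reduced (99–999) where only calibration, not fine
p-value resolution, is at stake.

## What the synthetic experiments do and do not show

The synthetic founder panel reproduces the published He/Ar summary, not the
empirical allele-frequency spectrum; absolute allelic-richness trajectories
therefore start near 13 rather than the richer empirical panel's effective
pool, and richness comparisons should be read within simulations, never
against field data. The engine omits overlapping generations, age structure,
survival heterogeneity, habitat-weighted movement and social behaviour —
deliberate simplifications inherited from the study design. Passing tests
demonstrate internal consistency of the engine and estimators and agreement
with published moderate/high-density outcomes; they do not validate the
model against real tortoise demography.
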