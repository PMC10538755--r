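# tortsim

Agent-based, spatially explicit, forward-in-time simulation of gene flow for
the Mojave desert tortoise (*Gopherus agassizii*) — and, more generally, for
any low-vagility species on a gridded resistance landscape — together with
the population-genetic analysis stack needed to ask: **do culverts under
roads and railways preserve connectivity, and how does population density
change the answer?**

Linear infrastructure fragments tortoise habitat, but the genetic signal of
fragmentation lags behind the disturbance by decades to centuries in a
long-lived, slow-dispersing species. Forward simulation lets managers see
the predicted genetic and demographic consequences of barriers, crossing
structures and declining densities long before they are measurable in the
field.

## What it implements

**Landscapes.** 25 × 25 grids of 1 km² cells with movement resistance in
[0, 1] (1 = impassable) and carrying capacity binned from habitat
suitability (0–24 tortoises/km²). Disturbance degrades habitat
multiplicatively via conversion factors (urban/solar 1.00,
railway/interstate 0.75, minor roads and rights-of-way 0.25), and
`resistance = 1 − habitat`. Three scenario surfaces — open habitat, a
one-cell-wide absolute barrier, and the barrier pierced by three culvert
cells (resistance 0.7, capacity 3, at most 3 transits per generation) —
plus heterogeneous surfaces built from any habitat raster (Esri ASCII) and
disturbance layers.

**Engine.** Non-overlapping generations (≈ 17 years each): dispersal
(probability 0.5, up to 10 Queen's-case cells), within-cell mating with
logistic recruitment `E = N + rN(1 − N/K)` at `r = 0.48` per generation,
Mendelian inheritance at 20 unlinked microsatellite-like loci with mutation
rate 5 × 10⁻⁴, then complete adult mortality. Initial densities of 3, 14 or
20 individuals per cell give the canonical 1 875 / 8 750 / 12 500 starting
populations.

**Founders.** A synthetic panel generator calibrated to the published
summary of the (unreleased) empirical genotypes: 20 loci, mean expected
heterozygosity 0.81, mean allelic richness 13, Hardy–Weinberg proportions,
no spatial structure.

**Statistics.** Observed/expected heterozygosity and allelic richness;
multilocus Weir–Cockerham θ (pairwise FST between barrier sides);
linkage-disequilibrium effective population size (Burrows' composite
disequilibrium, lowest allele frequency 0.05, random-mating bias correction,
parametric chi-square confidence intervals); Monte-Carlo exact
Hardy–Weinberg tests with Bonferroni correction; spatial PCA (axes maximise
score variance × Moran's *I*) with 999-permutation global/local tests;
Mantel tests for isolation by distance; GENEPOP/Structure/CSV export.

## Worked example

Fifty generations on the culvert landscape at moderate density, three
replicates:

```r
library(tortsim)

freqs    <- generate_frequencies(20, target_he = 0.81, target_ar = 13, seed = 1)
glance(freqs)
#> # A tibble: 1 × 3
#>   n_loci mean_he mean_ar
#>    <int>   <dbl>   <dbl>
#> 1     20    0.81    12.8

founders <- sample_founders(freqs, 12500, seed = 2)
spec <- experiment_spec("culverts", "moderate", n_replicates = 3,
                        n_generations = 50, sample_interval = 10,
                        seed = 42, founders = founders)
exp <- run_experiment(spec)
glance(exp)
#> # A tibble: 1 × 10
#>   scenario density  generation     n  n_sd    ne    ar    ho    he     fst
#>   <chr>    <chr>         <int> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>
#> 1 culverts moderate         50 7714.  23.1 1635.  12.6 0.791 0.812 0.00614
```

The census settles just below the 8 750 seeded (the barrier column costs
4% of the habitat plus edge effects), heterozygosity is essentially intact
after 50 generations, and differentiation across the road is small but
non-zero — the culverts pass enough migrants (at most 9 per generation) to
slow, not stop, divergence. Zooming into one replicate's final snapshot:

```r
smp <- subsample(exp$runs$snapshots[[1]][["50"]], 750, seed = 7)
pairwise_fst(smp)
#> [1] 0.006909178
ld_ne(smp)
#> <tort_ne> Ne = 1796.4 (95% CI 609.4-∞), S = 750, 7393 allele-pair comparisons
```

`autoplot(exp)` draws the Ho and FST time series; `autoplot(surface)` maps a
resistance surface. `tidy()`/`glance()` methods return tibbles throughout,
so results pipe straight into dplyr/ggplot2. A thin command-line wrapper
lives at `inst/cli/tortsim.R`.

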