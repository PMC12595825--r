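# ystrpop

Population-genetic analysis of Y-chromosome STR haplotypes: the complete
desk-side toolchain for studies of paternal population structure, written
for the kind of question asked about regionally stratified cohorts such as
the Iberian Roma — how diverse are the paternal lineages, how strongly are
they structured across regions, how much gene flow connects groups, and how
old are the founder clusters.

A Y-STR haplotype is a vector of repeat counts over a marker panel (the
17-locus AmpFlSTR Yfiler set and the 27-locus Yfiler Plus superset are
built in), haploid and paternally inherited. On top of that data model the
package provides:

* **IO and marker conventions** — delimited-table reading with the `99`
  missing code, intermediate-allele rounding (halves away from zero),
  analysis views handling the duplicated DYS385a/b marker and the
  composite DYS389I/II pair, Arlequin `.arp` export, dataset merging
  across kit versions.
* **Haplogroup prediction** — Bayesian allele-frequency classification
  with trainable per-haplogroup frequency tables, posterior threshold
  (default 0.85) and fitness floor, NO_CALL handling.
* **Diversity** — Nei haplotype diversity
  `HD = n/(n-1) (1 - Σ p_i²)` with a seeded percentile bootstrap, and a
  rarefaction-style permutation test for the number of distinct
  haplogroups.
* **Differentiation** — Slatkin R_ST under the stepwise mutation model
  (squared-step distances), computed as the two-population Φ_ST of an
  exact AMOVA variance decomposition; one- and two-level AMOVA with
  permutation p-values; island-model migration rates
  `M = (1 - R_ST)/(2 R_ST)`; nonmetric MDS embedding (via vegan).
* **Median-joining networks** — weighted median-joining with
  inverse-variance locus weights on a 1–10 scale, ε-relaxed minimum
  spanning networks, Steiner-median insertion, exact maximum-parsimony
  pruning, GraphML/DOT export.
* **Lineage dating** — rho statistic `ρ = mean Σ_l |a_il − root_l|` and
  weighted rho with per-locus pedigree rates, star-genealogy standard
  errors, TMRCA in generations and years.
* **Simulation** — a forward-time Wright–Fisher simulator of haploid STR
  haplotypes under strict single-step mutation, with divergence,
  chain migration, admixture pulses from a diverged host deme, and full
  truth labelling; preset scenarios for five regional demographic
  topologies and a continental east→west chain.

## Worked example

Simulate two regional demes that split 20 generations ago (deme size 250,
μ = 2.5 × 10⁻³ per locus per generation), then run the core analyses:

```r
library(ystrpop)

sim <- simulate_scenario(scenario_config("DIVERGENCE",
  pop_labels = c("East", "West"), pop_sizes = 250, split_time = 20,
  burn_in = 50, sample_sizes = 40, seed = 2024))
ds <- round_intermediate_alleles(sim$dataset)

v <- make_view(ds, "DISTANCE")
pairwise_rst(v, permutations = 999, seed = 1)
#> pairwise RST (2 populations)
#>       East  West
#> East 0.000 0.048
#> West 0.048 0.000

amova(v, permutations = 999, seed = 1)
#> AMOVA (POPS), 999 permutations, seed 1
#>              source df       SS sigma2 percent
#>   Among populations  1   7.3375 0.1226     4.8
#>  Within populations 78 189.6750 2.4317    95.2
#>               Total 79 197.0125 2.5544   100.0
#> Phi:  phi_st = 0.0480 (p = 0.007)

tmrca(make_view(ds, "RHO"), subset = "East")
#> rho = 1.7500 (SE 0.2092), TMRCA = 46.7 generations (SE 5.6)
#>   = 1400 years (SE 167), n = 40, MEDIAN_RATE
```

Reading: about 4.8% of the molecular variance lies between the two demes
(R_ST = 0.048, significant at p = 0.007 over 999 permutations), which the
island model converts to roughly 10 effective migrants per generation
(`migration_rate()`). The East cluster's mean mutational distance to its
modal haplotype is 1.75 repeat steps over the 15 network loci, dating its
common ancestor to ~47 generations (~1,400 years at 30 years/generation) —
deeper than the 20-generation split because lineages keep coalescing in
the ancestral deme.

The same objects feed the network and diversity stages:

```r
vn <- make_view(ds, "NETWORK")
mp_prune(median_joining(vn, compute_weights(vn)))
#> median-joining network: 42 observed + 3 median nodes, 49 links,
#>   spanning cost 250

bootstrap_hd_ci(v, "East", replicates = 1000, seed = 1)
#> n = 40, k = 24, HD = 0.9667, 95% CI [0.9064, 0.9616] (1000 reps)
```

`run_pipeline(ds, "out/")` executes the whole chain and writes per-stage
tables plus a JSON manifest of seeds and settings.

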