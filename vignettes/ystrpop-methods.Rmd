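---
title: "Methods: Y-STR haplotype population genetics with ystrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Y-STR haplotype population genetics with ystrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpop)
```

## Scope and data model

`ystrpop` analyses haploid multilocus haplotypes of Y-chromosome short
tandem repeats (Y-STRs): each individual is a vector of repeat counts over
a marker panel, paternally inherited without recombination. The package
covers the analysis chain used in microgeographic studies of paternal
population structure — for example, comparing regionally stratified Roma
and non-Roma cohorts across Iberia — from raw genotype tables to
differentiation statistics, haplotype networks and lineage dating, plus a
forward-time simulator that generates truth-labelled data under the same
mutational assumptions.

The built-in panels are the 17-locus AmpFlSTR Yfiler set and its 27-locus
Yfiler Plus superset. Two marker idiosyncrasies drive most of the
preprocessing logic:

* **DYS385a/b** is a constitutively duplicated marker: two alleles per
  individual with arbitrary a/b labelling.
* **DYS389I/II** is a composite pair: the DYS389II amplicon contains
  DYS389I, so the reported DYS389II count is the sum of two stretches.

Analyses therefore run on *views* of a dataset rather than on the raw
table. `make_view()` produces:

* `PREDICTION` — loci exactly as reported (haplogroup predictors expect
  DYS389II as the sum);
* `DISTANCE` — all loci, with DYS385a/b sorted ascending within each
  individual so the arbitrary labelling cannot create spurious squared
  differences (the reporting convention is not standardised across
  datasets, so sorting is the only order-free choice);
* `NETWORK` / `RHO` — DYS385a/b dropped and DYS389II replaced by
  DYS389II − DYS389I, so each retained locus is an independently evolving
  stepwise unit. With the 17-locus panel this leaves 15 loci.

Intermediate alleles (e.g. 13.2) are rounded to the nearest integer before
any arithmetic; exact halves round away from zero, a deterministic rule
that does not depend on floating-point parity conventions. Missing alleles
(coded `99` or empty in input files) become `NA` and propagate through all
derived values; downstream statistics use pairwise deletion (a locus is
skipped only for comparisons that involve a missing value), which
preserves sample size and matches common Arlequin-style practice.

## Differentiation: squared-step distances, R~ST~ and AMOVA

Under the stepwise mutation model (SMM) a mutation changes the repeat
count by ±1, so the natural molecular distance between haplotypes *i* and
*j* is the squared-step distance

$$d_{ij} = \sum_l (a_{il} - a_{jl})^2 .$$

The analysis of molecular variance uses the distance formulation: the sum
of squared deviations of any set of individuals equals the sum of its
pairwise distances divided by the set size. Variance components come from
the standard moment equations with unequal-size coefficients; for the
one-level design

$$\sigma^2_w = SS_{WP}/(N-P), \qquad
  \sigma^2_a = \left(SS_{AP}/(P-1) - \sigma^2_w\right)/n_0,$$

with \(n_0 = (N - \sum_p n_p^2/N)/(P-1)\), and
\(\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)\). Slatkin's R~ST~ for
a population pair is exactly this two-population \(\Phi_{ST}\);
`pairwise_rst()` and `amova()` share the component code path, and the test
suite checks both against an independent brute-force oracle that
enumerates pair sums and solves the moment equations with a linear solver.
The two-level design adds among-group and among-population-within-group
components with the usual unbalanced-design coefficients and reports
\(\Phi_{CT}\), \(\Phi_{SC}\) and \(\Phi_{ST}\).

Numerical conventions worth knowing:

* Negative variance components (sampling noise around zero
  differentiation) are **reported as computed**; they are floored at zero
  only when percentages are formed, which keeps printed tables in the
  familiar Arlequin style while preserving the diagnostic sign.
* Permutation p-values use the add-one correction \((b+1)/(B+1)\).
  Individuals are permuted among populations for \(\Phi_{ST}\), whole
  populations among groups for \(\Phi_{CT}\), and individuals within
  their group for \(\Phi_{SC}\). The default is 1,000 permutations in the
  pipeline (10,000 is the field convention for final runs; tests use
  999 or fewer).
* The migration-rate conversion is the haploid equilibrium island-model
  estimator \(M = (1-R_{ST})/(2R_{ST})\) (haploid data halve the usual
  diploid constant). Non-positive R~ST~ maps to `Inf` rather than being
  clamped so that "no detectable structure" regimes (very large M)
  remain visible; R~ST~ values are clamped to zero only where a
  dissimilarity is required, i.e. before MDS.

Nonmetric MDS is delegated to `vegan::metaMDS()` (Kruskal stress-1,
monotone regression, 20 random starts by default) since only ranks of the
distance matrix carry information at these scales.

## Diversity and the distinct-haplogroup test

Haplotype frequencies are obtained by direct counting of full allele
vectors; a haplotype containing a missing allele matches nothing and forms
its own singleton class (the conservative choice — it can only inflate
diversity slightly, and it avoids imputation). Nei's haplotype diversity
is

$$HD = \frac{n}{n-1}\Bigl(1 - \sum_i p_i^2\Bigr),$$

with a percentile bootstrap interval over individuals (default 10,000
replicates, seeded). A simulation study in the test suite checks that the
percentile interval covers the true diversity of a known haplotype
distribution at close to the nominal 95%.

The distinct-haplogroup comparison is a rarefaction-style permutation
test: the observed statistic is the number of distinct haplogroup labels
in the focal cohort, and the null draws samples of the focal size without
replacement from the pooled label multiset. The published description of
this test does not fix the permutation scheme or sidedness; drawing at the
focal sample size respects the strong dependence of distinct counts on
sample size, and the test is reported two-sided
(\(p = 2\min(P_{\ge}, P_{\le})\), capped at 1) so that both unusually low
and unusually high haplogroup richness register. NO_CALL predictions are
excluded before counting.

## Haplogroup prediction

`predict_haplogroup()` implements Bayesian allele-frequency
classification: with per-haplogroup allele frequency tables
\(f(a \mid g, l)\),

$$P(g \mid h) \propto \pi(g) \prod_{l\ \mathrm{non\text{-}missing}}
  f(a_{hl} \mid g, l).$$

Missing loci are skipped; loci without reference observations for some
haplogroup are dropped for that prediction so likelihoods stay
comparable. The *fitness* score of a haplogroup is its mean log10
per-locus likelihood — a measure of absolute (not relative) fit. A call is
made only when the posterior reaches the threshold (default 0.85, the
conventional setting) and fitness reaches the floor; since per-locus
likelihoods never exceed 1, fitness is always ≤ 0 and the conventional
floor of 0 disables the filter. Exact posterior ties give NO_CALL.

Frequency tables are trained from labelled references with
`build_frequency_table()` rather than bundled: published predictor tools
ship proprietary tables that are not printed anywhere reproducible.
Additive smoothing (default 5 × 10⁻⁴ per allele over the observed range
± 2 repeats) prevents a single unobserved allele from zeroing out a
haplogroup. The exact closed form of the published tools' fitness score is
likewise not public; the mean-log10 definition used here is monotone in
the joint likelihood and reduces to it for equal locus counts, and the
conventional threshold of 0 makes the choice inert in practice.

## Median-joining networks

`median_joining()` reimplements the weighted median-joining construction
for multistate STR data. Locus weights are integers on a 1–10 scale,
inversely proportional to repeat-count variance (linear interpolation on
the inverse-variance scale; zero-variance loci get 10, equal variances
give the midpoint 5). Edge length is \(\sum_l w_l\,|\Delta_l|\).

The algorithm alternates: (1) build the ε-relaxed minimum spanning
network — an edge is kept when its length is within ε of the *bottleneck
distance* between its endpoints (the maximal edge on their minimum
spanning tree path), which at ε = 0 yields exactly the union of all
minimum spanning trees; (2) propose component-wise medians of connected
triplets (the median of three integers is the middle value, so no rounding
is involved); (3) add the median that most reduces the minimum spanning
cost, breaking ties toward the lexicographically smallest vector so that
results are independent of input row order. ε defaults to 0 and is
exposed as a parameter, since published network runs rarely state it.

Maximum-parsimony pruning removes median nodes not needed by any
minimum-cost spanning subgraph over the observed haplotypes: exact by
enumeration over median subsets up to 12 medians, greedy single-removal
elimination above that. The exact branch is validated against an
independent Steiner-enumeration oracle in the tests; pruning is idempotent
and never increases the spanning cost. Samples with missing alleles at a
network locus are excluded with a warning rather than imputed. A seeded
per-population subsampling option (20 per reference population) mirrors
the common practice of capping reference sample sizes in large networks.

## Rho and TMRCA

For a haplotype cluster with root \(r\) (by default the modal haplotype,
per-locus majority allele with ties broken toward the smaller allele —
published analyses rarely state their ancestral-node rule, and the modal
haplotype is the standard operational choice; an explicit root can be
supplied), the rho statistic is the mean total absolute repeat difference
to the root:

$$\rho = \frac{1}{N} \sum_i \sum_l |a_{il} - r_l|.$$

Conversion to time uses either a single median pedigree rate
(\(T = \rho/(L\mu)\), default \(\mu = 2.5\times10^{-3}\) per locus per
generation, the median of pedigree-based Y-STR rates) or per-locus rates
(weighted rho: each locus' steps are divided by its own rate before
averaging, giving generations directly). DYS385 is excluded by the RHO
view. The standard error is the star-genealogy approximation
\(\sigma(\rho) = \sqrt{\rho/N}\); a genealogy-aware variance would need a
tree the pipeline does not infer, and the star approximation is the
appropriate match for founder-expansion clusters. Generation time defaults
to 30 years and is configurable. Two estimates are compared by their
difference in units of \(\sqrt{SE_a^2 + SE_b^2}\) and by ±1 SD interval
overlap.

**Known limitation — back mutation.** Because \(\rho\) measures *net*
repeat displacement while mutations accumulate as ±1 steps, back
mutations hide events: with per-locus expected mutation count
\(\lambda = \mathrm{depth}\times\mu\), the expected per-locus contribution
is \(E|S_K|\) for \(K \sim \mathrm{Binomial}(\mathrm{depth}, \mu)\) with
symmetric steps, which is strictly below \(\lambda\). At
\(\lambda = 0.5\) (200 generations at \(\mu = 2.5\times10^{-3}\)) the
shortfall is about 20%, so rho-based dates at that depth are biased
downward by far more than the star-genealogy SE; at \(\lambda \lesssim
0.1\) (up to ~40 generations, the depth range of recent founder events)
the bias is under ~2% and immaterial. The star-simulation tests quantify
exactly this: they check \(\rho\) against the exact binomial-enumeration
expectation rather than against the naive \(\mathrm{depth}\cdot L\cdot\mu\),
and the acceptance suite's depth-200 recovery check documents the biased
regime. Users dating deep clades should treat rho dates as lower bounds
or use squared-distance (ASD) methods, which are unbiased under the SMM.

## The simulator: what it emulates and what it does not

`simulate_scenario()` is a forward-time Wright–Fisher engine for haploid
STR haplotypes: per generation each offspring picks a uniform parent from
its deme (or, with the configured probability, from a source deme;
admixture pulses substitute HOST-deme parents for a binomial fraction at
one generation), then every locus mutates with probability μ by ±1 repeat,
optionally reflecting at allele bounds. Founder-lineage labels are
inherited alongside alleles, so every sampled individual carries a truth
label, and realised migrant counts are recorded. A forward-time engine was
chosen over a coalescent one because pulses, bounds and per-individual
truth labels are then direct bookkeeping rather than post-hoc annotation.

The five preset topologies (panmixia; east→west chain gene flow;
divergence; divergence with unidirectional migration; divergence with
bidirectional migration) mirror the demographic models commonly compared
for Roma regional structure, plus a continental chain spanning Greece →
Romania → Slovakia → Spain. Regional preset defaults are the package's
single fixed choice of realistic study conditions: haploid deme size 250
(small endogamous male effective sizes), a split ~20 generations ago
(six centuries at ~30 years/generation), μ = 2.5 × 10⁻³, and a deep HOST
divergence of 2,000 generations so introgressed lineages are
unambiguous. Mutation is strictly single-step — the same assumption R~ST~
and rho make — with no multi-step tail, no locus-specific rate
heterogeneity, no population growth, and no overlapping generations; real
Y-STR data violate all four to some degree, so passing recovery tests on
simulated data demonstrates internal consistency of the estimators with
their own model, not robustness to model misspecification.

`founder_star()` generates the star-genealogy fixture for TMRCA recovery:
every lineage descends independently from one founder exactly `depth`
generations back.

## Problem sizes and orchestration

The test suite and acceptance script run everything at desk scale by
design: permutation tests at 999 permutations, bootstrap checks at a few
hundred replicates, null calibration over 200 seeded panmixia replicates
of two 50-individual samples, divergence grids over 20 seeds, and star
simulations of 200 lineages over 50 seeds. Defaults in the user-facing
functions stay at the field's conventional 10,000 iterations.

`run_pipeline()` executes the whole chain (round → views → predict →
diversity → R~ST~/M → AMOVA → MDS → network → TMRCA) with one seed,
writing each stage's table plus a JSON manifest of inputs, versions,
seeds and outputs; it and the per-stage exported functions are the
package's scripting surface.
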