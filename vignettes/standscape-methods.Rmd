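---
title: "Methods: local-scale population genetics of selfing stands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-scale population genetics of selfing stands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standscape)
```

# The setting

`standscape` analyses dense biallelic SNP panels sampled from *stands* —
contiguous clusters of a predominantly self-fertilising annual plant,
separated from other clusters by tens of meters — across a local landscape
of tens of kilometers. In this regime almost all individuals are highly
homozygous, stands are strongly differentiated from one another, and the
interesting biology lives in the exceptions: residually heterozygous
plants, recombinant mosaics of a few ancestral genotypes, and occasional
genotypes shared between stands. The package provides the estimators for
this regime together with a forward-in-time simulator that generates
datasets with full pedigree truth, so every estimator is validated against
a known answer rather than against another implementation.

Dosages code the number of copies of `allele_b` at each marker (0/1/2,
`NA` missing); a *multilocus genotype* (MLG) is the full call vector of a
plant.

# Diversity and inbreeding estimators

**Expected heterozygosity.** Per marker and stand, with `n` called
individuals and allele frequency `p`, we use Nei's unbiased gene
diversity `He = (2n/(2n-1)) (1 - p^2 - q^2)`. The small-sample correction
is a deliberate choice: the statistic is otherwise biased downward exactly
in the small stands this design cares about. Genome means include
monomorphic markers as zeros, which is what makes `He = 0` for a
monotypic stand rather than undefined.

**1 − Q (interindividual).** `Q` is the probability that two alleles,
one drawn from each of two *distinct* individuals, are identical,
averaged over all pairs and then across markers. Unlike `He` it is a
genotype-level quantity and is insensitive to within-individual identity,
which makes the pair `He`, `1−Q` informative about how diversity is
packaged into individuals.

**F-statistics.** `wc_f_statistics()` implements the Weir–Cockerham
(1984) variance-component estimators: per-locus components `a` (among
stands), `b` (among individuals within stands) and `c` (within
individuals), combined across loci as ratios of component sums.
Monomorphic loci contribute nothing (the Weir–Cockerham convention);
a dataset with no within-stand segregation at any locus has an undefined
`F_IS` and is flagged rather than silently zeroed. The test suite holds
this implementation to agreement within 1e-12 with an independently coded
ANOVA mean-squares oracle (`c = MSG`, `b = (MSI − MSG)/2`,
`a = (MSP − MSI)/(2 n_c)`) on randomised small instances, so the two
classical derivations cross-check each other.

**Effective outcrossing.** At inbreeding equilibrium under partial
selfing, `F = s/(2 − s)`, so an observed `F_IS` implies
`OC = (1 − F_IS)/(1 + F_IS)`. We call this *effective* outcrossing: it
measures the rate at which heterozygotes are generated, not the true
mating rate — near-neighbour pollination among identical or related
genotypes raises `F_IS` at fixed true outcrossing (a Wahlund-type
excess), and the simulator reproduces exactly that (see below). Reported
percentages are rounded to one decimal. Because the question of whether
an "overall" figure should come from the whole-dataset multilocus `F_IS`
or from averaging stand values has no single answer, the transform is a
plain function applied to whichever `F_IS` the caller supplies, and the
pipeline reports both the whole-dataset value and per-stand values.

**Size correction.** Stand sample sizes vary by an order of magnitude,
and comparisons of diversity between stands (or site types) would
otherwise be confounded. `subsampled_stand_stats()` draws `n_reps = 100`
subsamples of `subsample_size = 10` plants without replacement, computes
the per-marker statistics per replicate, averages per marker across
replicates, and only then averages across the genome. The multilocus
`F_IS` is the ratio of sums of the replicate-averaged per-marker `b`, `c`
components — averaging per-marker `F_IS` ratios would be undefined at
every monomorphic marker. Stands smaller than the subsample are excluded
(the `n >= 10` filter). 95% intervals come from 1000 bootstrap draws over
loci (percentile method), the standard multilocus procedure.

A caveat the package makes explicit rather than hiding: under strong
selfing, loci share a genealogy, so locus-bootstrap intervals are
anti-conservative for quantities compared *between datasets*. Where the
independent replicates are stands — e.g. comparing a multilocus `F_IS`
against a theoretical value — `wc_bootstrap_ci(..., unit = "stand")`
resamples stands instead.

**Year-to-year comparison.** `year_pair_fst()` equalises the two sample
sizes by subsampling the larger sample to the smaller one's size, 100
times, averaging the per-locus components across replicates before the
multilocus ratio. Identical compositions give theta near zero (slightly
negative values are an estimator property, not an error).

# Spatial structure

**Between stands.** `mantel_test()` correlates the off-diagonal entries
of a genetic and a geographic distance matrix with a one-sided upper
permutation p-value `(hits + 1)/(n_perms + 1)`. `morans_i_correlogram()`
scores each individual 0/0.5/1 per marker (dosage/2), computes Moran's I
per distance class with binary class-membership weights
(row-unstandardised) and averages over polymorphic markers with equal
weight; `dg_distogram()` bins the pairwise Gregorius distances the same
way. Envelopes come from 500 permutations of genotypes over locations
(the genotype, not the single allele, is the exchangeable unit — plants,
not genes, have positions). The analytic check that the permutation-null
mean of Moran's I per class is `−1/(n−1)` is part of the test suite.
Missing dosages are mean-imputed per marker for the Moran scores, which
keeps `n` and the null mean exact; the distance-based statistics use
pairwise deletion instead. Distance classes are contiguous half-open
intervals from zero (defaults mirror a 10 × 3.84 km and a 30 × 0.5 km
design); pairs beyond the last class are counted and flagged, and class
pair-counts always sum to `n(n−1)/2`.

**Aggregation.** `aggregation_index()` is the Clark–Evans
nearest-neighbour ratio `R = mean NN distance / (0.5/sqrt(n/area))`,
with `R < 1` indicating clumping; significance by Monte-Carlo simulation
of complete spatial randomness in a square of equal area. This is the
aggregation index in the SGS tradition of spatial genetic software; the
full Ripley's K function is out of scope.

**Within stands.** For transect-sampled stands, `C2` is the proportion
of plants with at least one same-MLG neighbour (denominator all `n`;
ends have one neighbour) and `C3` the proportion of interior plants
flanked by two same-MLG neighbours (denominator `n − 2`). The
denominators are our choice — the quantities are defined verbally in the
field literature — and are fixed in the documentation so values are
comparable across datasets. `cluster_vs_fis_regression()` regresses
per-stand `F_IS` on `C3` (and `C2`); a positive slope is the signature of
spatial structure inflating homozygosity.

# Outcrossing and recombination footprints

The mosaic module automates what is traditionally a manual genome scan.
`pairwise_profile()` labels each marker of a genotype pair `identical`,
`divergent` (opposite homozygotes), `het_involved` or `missing`; the
latter two are neutral everywhere downstream — they never break a run and
never count as identity or divergence. `segment_blocks()` reduces the
informative markers to maximal runs, iteratively merging runs shorter
than `min_run` (default 5) into the longer flanking state (left flank on
ties); `min_run = 1` is exactly lossless. Blocks tile each chromosome;
since crossovers are only localisable to inter-marker intervals, block
coordinates are marker indices (0-based, inclusive) with bp spans
attached.

`detect_het_stretches()` finds runs of heterozygous calls allowing
`max_interrupt` (default 1) called homozygous markers inside a run, with
at least `min_run = 3` heterozygous markers. The defaults are
deliberately conservative for a marker density of roughly one per 250 kb:
an isolated heterozygous call is far more likely a genotyping artefact
than a 250 kb outcrossing footprint, and no published rule exists to
borrow.

`assign_f1_parents()` scans pairs of fully homozygous candidate MLGs and
scores the fraction of their differentiating markers at which the
candidate child is heterozygous. A first-generation call requires that
fraction to reach 1.0 (every differentiating marker) *and* the child to
match the parents where they agree; a child compatible with one of the
candidates is a self-descendant and never an F1. Anything in between —
e.g. roughly half the markers heterozygous after one round of selfing —
is reported as `later_generation_or_recombinant`.

`reconstruct_ril()` treats a stand as a natural recombinant-inbred
family: it searches pairs of the stand's distinct fully homozygous MLGs
as candidate founders and paints every genotype by founder origin at the
pair's differentiating markers. The best pair maximises the number of
differentiating markers first, then minimises unexplained markers, then
breakpoints. The first criterion is load-bearing: a recombinant of the
true founders differs from each of them at strictly fewer markers than
they differ from each other, so ranking by breakpoints alone would elect
a recombinant as pseudo-founder and trivialise the painting. Because
origin is determined at every explained marker, counting switches along
the marker order is already the minimum-breakpoint painting; the test
suite confirms equality with an exhaustive search over all paintings on
instances with up to 12 differentiating markers.

# Clustering

The individual-level distance is the allele-sharing distance
`1 − shared/2` averaged over jointly called markers. On dosage data this
coincides with the Gregorius distance (both equal `mean |d1 − d2| / 2`),
so the clustering input and the distogram statistic are one function with
two names — stated here once so nobody hunts for a difference. Trees come
from `stats::hclust` (Ward linkage by default; rows are sorted by label
first so ties break deterministically), exported to Newick via `ape`.
Clustering operates on non-redundant MLGs: one representative per MLG per
stand and year.

`gap_statistic()` selects the number of clusters by comparing the
within-cluster dispersion `W_k` of tree cuts against `B = 100` reference
datasets built by permuting each marker's dosages independently across
individuals — a reference that preserves marker allele frequencies while
destroying both individual relatedness and inter-marker association. The
selection rule is the 1-SE rule (smallest `k` with
`gap(k) ≥ gap(k+1) − se(k+1)`).

A known limitation, found by testing rather than assumed: with this
permutation reference the rule over-splits groups whose internal
variation is itself reducible (for example independent noise spread over
a small subset of markers), because a low-dimensional data cluster loses
dispersion under splitting faster than the high-dimensional reference
blob. It is reliable when within-group relatedness is star-like (members
differ by private markers), which is the typical shape of selfing
lineages diverging from a common ancestor. The validation suite therefore
tests exactly that regime; on diffusely noisy groups the gap curve keeps
rising and `K_hat` should be read as "at least".

`within_between_distributions()` splits all pairwise distances by
same-stand versus different-stand and compares the two sets with a
two-sided Mann–Whitney test (optionally excluding the zero distances of
identical genotypes); `compare_site_types()` applies the same test to
per-stand statistics between rural and urban stands, with `p = 1`
returned for the degenerate all-equal case.

# The simulator

`simulate_stands()` is a forward-in-time model of a selfing
metapopulation with discrete non-overlapping generations — the natural
choice for an annual plant — and fixed per-stand carrying capacity.
Per offspring: the ovule parent is drawn uniformly from the stand; with
probability `t` the pollen parent is a stand-mate (never the mother
herself — "neighbours" excludes self, and with an infinite kernel this
gives clean random-partner mating) weighted by a Gaussian kernel of scale
`mating_kernel_sigma`; otherwise the ovule selfs. Meiosis draws
`Poisson(recomb_rate)` crossovers per chromosome at uniform bp positions;
offspring land a Gaussian `seed_dispersal_sigma` from the mother; with
probability `migration_rate` per stand and generation one immigrant
offspring from another stand replaces a random resident. Everything —
parentage, selfing flags, outcross and migration events, final-generation
crossovers — is logged, so tests can ask exact questions ("was this
individual's father a distinct homozygous MLG?") instead of statistical
ones. Mutation is off: at SNP markers the per-base mutation rate is
negligible against even a very low outcrossing rate, so heterozygosity is
attributable to mating, which is the point of the design.

Defaults are chosen to emulate the motivating survey design: 77 stands,
436 markers spread over five chromosomes with the *A. thaliana* lengths
(30.4, 19.7, 23.5, 18.6, 27.0 Mb), founder minor-allele frequencies in
(0.2, 0.5] ("intermediate frequency" marker ascertainment), outcrossing
of a few percent, tight (~1 m) pollen and (~0.5 m) seed kernels within
~20 m stands, and rare (0.005/stand/generation) migration.
`survey_scale_scenario()` layers the site-type heterogeneity on top —
urban stands small with `t ≤ 0.01`, rural stands larger with `t` up to
0.15 — which reproduces the qualitative regime of monotypic-or-simple
urban stands, diverse rural stands and strong stand differentiation. The
dispersal and migration scales are free parameters: no field estimates
exist for them, and they should be treated as knobs that set a regime,
not as measured quantities.

`sample_survey()` mirrors the field protocol: complete sampling of stands
with at most 20 plants, otherwise a uniform random 20–30; transect order
is the within-stand x-rank.

What the simulator deliberately does not model: selection, seed banks
(a single-generation dormancy would be the natural extension), de novo
mutation, pollinator behaviour, or continuous space beyond Gaussian
kernels. Consequently, passing tests demonstrate estimator correctness
under drift, selfing, spatial structure and migration — not robustness to
selection or to genotyping error beyond the missing-data rules.

## Validation laws the simulator must satisfy

Three closed-form anchors make the simulator falsifiable. Pure selfing
from homozygous founders is a fixed point (descendants identical to
founders, `F_IS = 1` where defined). Random mating (`t = 1`, infinite
kernel) reaches Hardy–Weinberg (`F_IS ≈ 0`). Random-partner outcrossing
at rate `t` settles at `F_IS = (1−t)/(1+t)`; the validation suite checks
this for `t` in {0.02, 0.05, 0.1} on 30 stands of capacity 100 sampled at
20–30 plants and 436 markers after 25 generations (equilibrium is reached
within ~15 generations at these rates; capacity 100 keeps drift from
eroding within-stand polymorphism over the run). The comparison uses the
stand-bootstrap CI for the multilocus `F_IS` — stands, not loci, are the
independent replicates here. The median of per-stand `OC` estimates is
held to ±30% of `t`; at `t = 0.02` this is a genuinely noisy quantity
(the median stand's sample contains on the order of one
heterozygous-lineage plant), which is worth remembering when reading
per-stand outcrossing tables from any survey of this design.

With a tight kernel and spatially clustered MLGs (tight seed dispersal
from distinct founder patches), observed `F_IS` exceeds the
random-partner expectation at the same `t` — the Wahlund excess — and
`C3` co-varies with `F_IS` across a kernel-width sweep. This is the
mechanism by which true outcrossing exceeds effective outcrossing.

# Numerical and interface choices

* **MLG identity with missing data.** Exact call-vector equality always
  merges. Otherwise two samples merge when both have call rates ≥ 95% and
  agree wherever both are called, closed transitively; low-call-rate
  samples cannot wildcard-merge (one bad assay should not bridge two real
  genotypes). Canonical MLG calls are per-marker majorities over members
  (ties to the smaller dosage) because transitive closure can join
  samples that conflict at a marker an intermediate lacks. Monotypy uses
  this rule, so a single missing call cannot break it. The closure is
  verified against a brute-force Warshall oracle in the tests.
* **Coordinates** are planar meters; at a 35 m–40 km scale projection
  error is negligible and all distances are Euclidean (reported in km
  where the quantity is a between-stand distance).
* **GENEPOP export** writes one POP block per stand with 4-digit diploid
  codes (`0101`/`0102`/`0202`, missing `0000`) and round-trips through
  the package's own reader; it exists for interoperability with the
  classical tooling, not as an internal format.
* **Seeds.** Every stochastic routine takes an explicit seed;
  `run_all()` derives per-stage seeds from a master seed (kept below
  2^31) so stages can be rerun independently and the whole bundle is
  byte-reproducible. The pipeline manifest records stage seeds and
  parameters.
* **Problem sizes in the shipped tests** are chosen for a laptop-scale
  run: the equilibrium checks use 30 stands × 436 markers, the
  remaining properties run on 60–150-marker fixtures, and the full test
  suite completes in a few minutes.

# Interface note

The package's surface is its exported functions plus `run_all()`, which
executes the entire analysis (census → diversity → differentiation →
spatial → transect → clustering) from either a simulation config or a
trio of TSV inputs and writes the report tables, Newick tree and JSON
manifest to a directory. These functions and this vignette are the
intended interface; no shell entry point is shipped, since every
operation is a one-liner from R.
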