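---
title: "Spatial population genomics of post-glacial range expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial population genomics of post-glacial range expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Species that survived the last glacial maximum (LGM) in restricted refugia
and then recolonised their range leave a characteristic spatial footprint
in their genomes. Repeated founder events along the expansion axis reduce
genetic diversity with distance from the refuge; small founder groups
create runs of homozygosity (ROH) whose number grows toward the expansion
front; restricted dispersal during and after the expansion produces
isolation by distance (IBD); and drift at the front can shift the frequency
spectrum of deleterious variants (expansion load). `refugia` provides each
link of this analysis chain as a tested, reusable function, together with a
forward-in-time simulator that generates inputs with exactly this
structure, so every statistic can be validated against data whose
generating process is known.

The pipeline mirrors the order of a typical empirical study: per-individual
heterozygosity, ROH detection and age dating, derived-allele genetic load,
pairwise FST with a Mantel IBD test, ordinary kriging of per-individual
statistics onto a map, extraction of a refuge centre from a binary
presence raster (the output of an ecological niche model for the LGM), and
Pearson correlations of each statistic with great-circle distance to that
centre, FDR-corrected as one family per run.

## The simulator

`simulate_expansion()` runs a Wright–Fisher metapopulation on a rectangular
deme grid. The refuge deme drifts for `burn_in` generations; every
`colonization_interval` generations each empty cell adjacent to the
colonized range is founded by `founders` diploids from its nearest
colonized 4-neighbour (ties broken in fixed N, E, S, W order); colonized
neighbours then exchange `floor(migration * deme_size)` individuals per
generation. After the grid is full, a `post_expansion` phase runs with the
range stable before individuals are sampled.

Haplotypes are founder-interval mosaics: each chromosome is a tiling of
intervals labelled by the founder haplotype it descends from, plus new
mutations that arose during the run. Meiosis draws Poisson crossovers and
Poisson(mu·L) mutations per gamete, each mutation assigned a functional
class (SYN/NONSYN/LOF) and an ancestral state (absence). ROH and linkage
disequilibrium therefore arise mechanistically from shared founder
ancestry rather than being painted on.

### Standing refuge variation

A desk-scale forward run cannot generate realistic nucleotide diversity:
at mu = 4.6e-9 and a few hundred generations, the heterozygous-site
density is far too low for ROH boundaries to be observable. Real refuge
populations enter the glaciation carrying the diversity of their long-term
ancestral population (effective sizes of order 10^4 in demographic
reconstructions for alpine vertebrates). The simulator therefore seeds the
refuge with standing variants: `4 * ancestral_Ne * mu * L * a(2N-1)`
sites (Watterson's expectation for a sample of 2N haplotypes), each
carried by a subset of the 2N founder haplotypes drawn from the neutral
1/f frequency spectrum. Because a standing variant is a fixed property of
founder labels, genotypes are resolved from the mosaics only at sampling
time and standing sites cost nothing during reproduction. Identical-
by-descent tracts are then homozygous at standing sites while non-IBD
sequence is heterozygous at density ~pi, which is precisely the structure
ROH detection exploits in real data.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| grid | 8 × 8 demes, origin NE corner | refuge in one corner of the range, expansion along the diagonal |
| `deme_size` N | 100 | smallest N at which `floor(m N) >= 1` migrant moves per edge per generation at m = 0.01 |
| `founders` K | 5 | strong founder effect (per-event inbreeding increment ~1/(2K) = 10%) |
| `migration` m | 0.01 | restricted, stepping-stone gene flow (Nm = 1) |
| `colonization_interval` | 20 | the full 14-step expansion spans ~280 generations, so colonization events differ in age along the axis |
| `post_expansion` | 300 | the expansion is observed long after completion; a founder tract of age g has expected length 100/(2g) cM, so ages of 300+ put tracts inside the 5 kb – 1 Mb band |
| `burn_in` | 10 | the refuge's diversity is the standing pool; a long burn-in at the model's single-deme N would spuriously erase it |
| genome | 2 × 10 Mb, 1 cM/Mb | desk-scale but large enough for ~10^4 segregating sites and stable ROH counts |
| `mu` | 4.6e-9 /bp/gen | mutation-rate convention for the focal taxa |
| `ancestral_Ne` | 10 000 | long-term effective size scale from demographic reconstruction; yields ~1.3e4 segregating sites in a 128-individual sample |
| `class_probs` | 0.60 / 0.35 / 0.05 | synonymous : missense : loss-of-function mutational input with LOF rare |
| `sample_per_deme` | 2 | 128 sampled individuals, comparable to empirical sample sizes (55–68 per species) |

Selection coefficients per class are accepted (`sel_coef`) but default to
zero: the analysis makes no fitness claims, and neutral classes make the
permutation null of the load statistics exact.

With these defaults the simulator reproduces, and the test suite checks,
the qualitative signatures expected of a refuge-origin expansion: negative
correlation of heterozygosity and positive correlation of in-band ROH
count with distance from the refuge centre, IBD under m = 0.01 and its
absence under m = 0.25.

## The statistics

**Heterozygosity.** `H_i` = heterozygous / called genotypes at variant
sites. The denominator is called variant sites, not genome length, so the
statistic matches the ratio-of-sites definition used with genotype data.

**ROH.** `detect_roh()` adapts PLINK's windowed algorithm: a 50-SNP window
passes with at most 1 heterozygote and 5 missing calls; a SNP is
ROH-eligible when at least 5% of the windows covering it pass; maximal
eligible runs, trimmed to non-heterozygous end SNPs, are reported at >= 25
SNPs and >= 5 kb. Isolated heterozygotes absorbed by the window tolerance
do not split a run. `roh_summary()` counts segments in the 5 kb – 1 Mb
band (closed below, open above); `roh_age()` dates a tract as
g = 100/(2·length in cM), so the band corresponds to inbreeding roughly 50
to 10 000 generations ago — the post-glacial window. All parameters are
exposed because only the band itself is fixed by convention.

**Genetic load.** Sites with unknown ancestral state are excluded. Per
individual, `Pn` and `Ps` count nonsynonymous and synonymous sites at
which the individual carries at least one derived allele;
`ratio_ns = Pn/(Pn+Ps)`; `freq_ratio = (Pn·fn̄)/(Ps·fs̄)` with `fn̄`,
`fs̄` the mean population derived frequency over those same carried sites;
`lof_dosage` sums derived-allele dosages at LOF sites (sites for the first
two, alleles for the third, following the usual wording of these
statistics). NONSYN means missense only by default; LOF can be folded in
by flag. `population_load()` provides the per-site-group alternative
(segregating-site counts and group frequency means) for sensitivity
analysis, since per-individual versus per-population computation is a
genuine free choice.

**Differentiation.** `wc_fst()` implements the Weir–Cockerham (1984)
variance components a, b, c for two populations, combined as
sum(a)/sum(a+b+c) over loci polymorphic in the pooled pair; negative
estimates are retained. `ibd_test()` applies the standard filters (MAF
strictly > 10%, then LD pruning with 50-SNP windows advancing by 10 at
r² > 0.2, iterated to a fixed point so the pruned set is stable under
re-pruning), linearizes FST/(1−FST), and runs a seeded permutation Mantel
test against great-circle distances between site mean coordinates
(one-tailed "greater" by default, the IBD alternative). FST = 1 linearizes
to infinity and is replaced by the largest finite value plus a
rank-preserving epsilon rather than clamped. The Mantel p-value is
(1 + #{r_perm >= r_obs})/(1 + n_perm).

**Spatial interpolation.** `empirical_variogram()` bins squared value
differences by great-circle distance (12 lags to half the maximum pair
distance by default). `fit_variogram()` minimises N(h)/h²-weighted least
squares; because the model is linear in (nugget, partial sill) given the
range, the fit profiles the range over a deterministic log-spaced grid
with an exact non-negative inner solve and then polishes the best bracket
by 1-D optimisation — this removes multi-start randomness and recovers a
model's own curve essentially exactly. `ordinary_krige()` solves the
ordinary-kriging system with a Lagrange multiplier per grid node; weights
sum to 1 by construction and the predictor is exact at data points when
the nugget is zero. Duplicate coordinates (co-located individuals) are
jittered by 1e-6 degrees and reported.

**Gradients.** `refuge_center()` is the arithmetic mean of presence-cell
centres — the centroid-of-points reading of a "geographic centre" at
sub-continental extent; a spherical centroid would differ negligibly at
this scale. `gradient_test()` correlates a per-individual statistic with
haversine distance to the centre (two-tailed t-test); `gradient_table()`
adjusts the set of statistics tested in one run with Benjamini–Hochberg
FDR — the correction family is the per-run set of statistics, mirroring a
per-figure correction.

## Numerical and degenerate-input conventions

* All distances are great-circle km on a sphere of radius 6371.0088 km;
  coordinate data are lon/lat degrees. VCF positions are 1-based; internal
  ROH intervals are half-open with the end at last SNP + 1; BED output is
  0-based half-open.
* Missing genotypes are excluded pairwise everywhere (MAF, LD r²,
  heterozygosity, FST sample sizes); this choice is stated rather than
  inherited, since genotype-missingness handling is rarely reported.
* LD pruning removes the member of an offending pair with fewer
  non-missing calls, ties removing the later position; the pass is
  iterated to a fixed point so pruning is idempotent.
* Undefined statistics (zero called sites, Pn+Ps = 0, Ps·fs̄ = 0,
  unpolarizable sites) propagate as `NA` and are dropped, with a reported
  count, before interpolation or correlation.
* Zero-variance inputs are errors for `gradient_test()` (the correlation
  is undefined) but valid for the variogram (a constant field has a zero
  variogram and a degenerate zero-sill model).
* The simulator is bit-reproducible given `seed`; the pipeline reuses one
  seed for simulation and the Mantel permutation stream, and
  `mantel_test(seed=)` restores the caller's RNG state.

## What the synthetic data do and do not show

The generator emulates the joint structure the analysis assumes: a
diversity gradient caused by serial founding, ROH arising from founder
IBD, IBD under restricted migration, functional site classes with known
ancestral states, and a presence raster whose refuge-epoch snapshot
contains the origin. It does not emulate genotyping error or missingness
(the readers handle missing data, but simulated outputs are complete),
unequal sampling effort, landscape heterogeneity in habitat suitability,
selection on the load classes (available but off by default), overlapping
generations, or chromosome-scale recombination-rate variation. Passing
tests therefore demonstrate that the estimators recover known structure
from idealised diploid genotypes at realistic scale — not that any
particular empirical dataset will show these patterns.

Test problem sizes are chosen for a laptop-class run: the full-design
checks use 10 replicate 8 × 8 expansions (~1.3e4 segregating sites, 128
individuals each) for each migration regime, 2000-replicate null
calibrations, and 20-replicate estimator-oracle comparisons; the
unit tests use 4 × 4 grids with reduced ancestral diversity.

## Known limitations

* FST is the two-population Weir–Cockerham estimator; hierarchical designs
  and AMOVA are out of scope.
* Kriging is isotropic ordinary kriging in lon/lat with great-circle
  distances; no co-kriging, anisotropy, or CRS transformation.
* The ROH caller reports a single length band; classification into recent
  vs ancient inbreeding beyond the band, or FROH against callable genome
  length, is left to the caller (an optional callable-length denominator
  for heterozygosity is the only concession).
* The refuge is a single deme: refuge-internal spatial structure is not
  modelled, which is why `burn_in` defaults to a token settling period.
* With 2 individuals per deme, site-level FST estimates are noisy; the
  Mantel test integrates over 2016 site pairs, which is what makes the
  IBD contrast detectable at this sampling depth.
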