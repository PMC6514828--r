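---
title: "Methods: models, estimators and numerical choices in fadsevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices in fadsevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadsevo)
```

This vignette documents the models behind each analysis stage, why the
default parameters are what they are, where the synthetic-data generators
are deliberately unrealistic, and how ambiguous methodological choices were
resolved. It is a methods reference, not a tutorial; see the README for a
worked example.

## The study system

The FADS1/FADS2 region on chromosome 11 carries two deeply diverged
haplotype clusters ("haplogroups") that are tagged by the SNP rs174537 at
chr11:61,552,680: the T allele marks the *ancestral* haplogroup shared with
nonhuman primates, the G allele the human-unique *derived* haplogroup. The
package implements the statistical machinery used to study this region's
history: a selection scan, a divergence-based TMRCA clock, a forward
population-genetic simulator for the Americas founding bottleneck, haplotype
classification and phylogenetics, and a latitude cline regression. All
stages run on synthetic data with known truth.

## Synthetic alignment generator

`simulate_haplogroup_alignment()` produces a phased haplotype alignment over
a region of `length_total` sites (default 48,408, of which 47,820 pass the
high-quality mask, mirroring the size of the FADS haplotype block) with four
clusters: derived, ancestral, and two pairs of archaic-like haplotypes.

**Model.** Mutations arrive along each lineage as a Poisson process with
per-site per-year rate $\mu = A_{HC} / (2\,T_{HC})$, the per-lineage
substitution rate implied by calibrating against a human–chimpanzee
ancestor: divergence fraction $A_{HC} = 0.829\%$ accumulated over
$2 \times 6{,}500{,}000$ years of separating branch. The default derived
cluster age is 688,474 years, chosen so the default data exercise the
estimator at the scale of the real haplogroup split. Every mutation lands
on a distinct high-quality site (strict infinite-sites model); a
configuration whose expected mutation count cannot be placed on distinct
sites is rejected rather than silently violating the model.

Two genealogies are available:

* `genealogy = "star"` (default): each haplotype is an independent lineage
  of length `tmrca_derived`. The cluster founder equals the reconstructed
  ancestor, so the target quantity of the TMRCA estimator is exactly the
  configured age. This is the right geometry for estimator-recovery tests
  because the per-haplotype divergences are i.i.d.
* `genealogy = "coalescent"`: a random coalescent tree (via `ape::rcoal`,
  rescaled to the configured depth) with mutations on internal branches
  shared by descendant tips. More realistic correlation structure, at the
  cost of a noisier mean divergence per replicate.

**Deliberate unrealism.** No recombination (appropriate for a single
haplotype block, wrong for larger scales); no back-mutation; the ancestor
is known without error; site positions are uniform. The tag SNP is *not*
planted by default (`plant_tag_snp = FALSE`): a deterministic fixed
difference would add one guaranteed mutation to every derived haplotype and
bias estimator-recovery experiments upward by roughly one part in 21.
Enable it (plus `stem_mutations_*`) when classification rather than dating
is under test.

## Wright–Fisher simulator and its exact oracle

`simulate_trajectory()` and `fixation_proportion()` implement a discrete
Wright–Fisher population of `2N` alleles: deterministic viability selection
with genotype fitnesses $(1+s,\ 1+hs,\ 1)$ followed by binomial resampling.
The default demography is the Americas founding scenario: 534 generations
total (about 15,500 years at 29 years/generation), the first 10 generations
at a bottleneck size $N_b$ (default 100) and the remainder at an expanded
size (default 2,000). Selection can cover the whole epoch or start after
the bottleneck (`after_bottleneck_only`). The full-scale experiment grid,
`fixation_grid_axes()`, spans $N_b \in \{100,\dots,500\}$, expanded size
$\{2{,}000,\dots,10{,}000\}$, selection durations up to the full epoch,
$s$ up to 0.5 and 14 starting frequencies: 11,200 cells.

**Numerics.** The core loop is C++ (Rcpp). Each (cell, replicate) pair gets
an independent `std::mt19937_64` stream seeded by a splitmix64 hash of
(seed, cell, replicate), so results are bit-reproducible, independent of
R's RNG state, and insensitive to evaluation order.

**Oracle.** `exact_fixation_probability()` propagates the full probability
vector over allele counts $0,\dots,2N$ through the exact binomial
transition kernels of the (time-inhomogeneous) chain. It is exact up to
floating point, refuses $2\max(N) > 200$ (kernel size grows quadratically),
and anchors the simulator tests: the stochastic engine must agree with it
within Monte-Carlo error on small-$N$ lattices, and neutral runs must obey
the martingale property $\Pr[\text{fix}] = p_0$.

## PBS scan

`pbs_scan()` computes per-site Weir–Cockerham $F_{ST}$ from allele counts
for the three population pairs, then the population branch statistic
$\mathrm{PBS} = (T_{AB} + T_{AC} - T_{BC})/2$ with $T = -\ln(1 - F_{ST})$.

Choices that needed resolving:

* **Negative $F_{ST}$** estimates (common at low differentiation) are kept
  as-is; truncating at zero would bias the PBS background upward.
  $F_{ST} \ge 1$ (possible only at complete fixation) is clamped to
  $1 - 10^{-12}$ so $T$ stays finite; the clamp is a parameter.
* **Background**: the Z-score for a focal-window site is computed against
  the mean and SD of PBS over *all* defined sites, window included —
  excluding the window would require a judgment about where the sweep ends.
  A background below 1,000 sites triggers a warning.
* **One-sided p-values** by default: PBS is a directional statistic
  (focal-branch lengthening); a two-sided option exists.
* **Bonferroni denominator**: the number of *defined-PBS* sites inside the
  focal window, i.e. the number of tests actually performed, not the whole
  panel.
* Sites monomorphic across all three populations have undefined $F_{ST}$
  and are dropped with a message.

The null calibration uses the Balding–Nichols generator
(`simulate_frequency_panel()`): per-population allele frequencies drawn
from a Beta distribution around a shared ancestral frequency with drift
parameter $F$ (default 0.01 per population), then binomial sampling at the
configured sample sizes. This is a standard exchangeable null — it has no
linkage and a single $F$ per population, so it underestimates the
heavy-tailed background of real genomes; Bonferroni-corrected inference is
calibrated against exactly this null, not against real-genome tails.

## TMRCA estimator

`estimate_tmrca()` implements the outgroup-calibrated clock
$$\widehat{T}_{\mathrm{MRCA}} = \frac{M}{A_{HC}} \times 2\,T_{HC},$$
where $M$ is the mean per-site divergence of derived haplotypes from the
reconstructed ancestor over usable sites. Usable sites are the high-quality
mask minus sites violating the infinite-sites assumption: any high-quality
variant site where an *ancestral* haplotype carries a non-ancestor allele
is excluded (such sharing implies recurrent mutation or gene flow, either
of which breaks the clock).

* **Dispersion** comes from applying the same formula to each haplotype's
  own divergence; the default 95% interval is normal
  ($\pm 1.96\,\mathrm{SD}/\sqrt{n}$). A `ci = "poisson"` option treats the
  summed difference count as Poisson instead — narrower when between-lineage
  variance exceeds Poisson (e.g. non-star genealogies), and the choice is
  surfaced rather than hidden because neither is uniformly right.
* **Known bias**: excluding filter-flagged sites shrinks the denominator
  slightly (ancestral-lineage mutations knock out roughly 2% of sites at
  the default configuration), inflating estimates by the same factor. This
  is a property of the estimator as defined, reproduced deliberately; the
  recovery tests budget for it.
* `tmrca_sensitivity()` exploits that the estimate is linear in $T_{HC}$
  with $M$ and $A_{HC}$ held fixed: the divergence time at which the
  estimate equals a reference age has the closed form
  $T_{HC}^{*} = \mathrm{age} \times T_{HC} / \widehat{T}_{\mathrm{MRCA}}$.
  The curve is still produced (201 points by default) for plotting.

## Haplogroups and core haplotypes

`classify_haplotypes()` assigns each haplotype by its base at the tag SNP;
anything other than the two expected alleles (including missing) is
`unclassified` and excluded from proportion denominators.
`core_haplotypes()` builds per-category consensus strings: a capital base
where all (or a fraction ≥ `threshold`) of non-missing haplotypes agree,
`"n"` otherwise; positions missing in more than half a category are `"n"`
with a warning. The packaged reference strings
(`fads_core_haplotypes()`) cover the 38 SNPs of the haplogroup block;
`opposite_fixed_sites()` finds positions where two strings are fixed for
different bases — after excluding the tag SNP itself (base 10), exactly one
such site remains (base 12, rs102274), the candidate functional variant.

## Trees and networks

`collapse_haplotypes()` merges identical sequences and drops those observed
three times or fewer (`min_count = 3`, exclusive), except protected ids
(archaic haplotypes, the ancestor outgroup) which survive at any count.
`nj_tree()` is Saitou–Nei neighbor joining on pairwise Hamming differences,
rooted at the `ANCESTOR` row; negative branch lengths — a finite-sample NJ
artifact — are clamped to zero with the deficit moved to the sibling edge,
preserving path lengths. `bootstrap_consensus()` resamples alignment
*columns* (invariant sites included when present), recomputes NJ per
replicate, annotates the full-data tree with replicate support percentages
and reports the >50% majority-rule consensus.

`build_network()` is a **minimum-spanning network**: all MST edges (Prim)
plus every alternative edge whose length ties the bottleneck (largest) edge
weight on the MST path between its endpoints. A statistical-parsimony
network would need a probability cutoff that is not determined by the data
model here; the MSN is a deterministic, documented substitute with the same
output format (nodes with multiplicities, mutation-count edge labels).
Zero-distance pairs are re-added with epsilon weight so identical retained
sequences stay connected.

## Cline regression

`fit_cline()` is ordinary least squares
`lm(proportion ~ admixture + latitude)` on per-population
ancestral-haplogroup proportions, with admixture as a nuisance covariate
and the latitude coefficient's two-sided t-test as the quantity of
interest. Proportions are regressed untransformed by default (matching the
reference analysis); `logit = TRUE` switches scales. Constant proportions
yield a defined flat fit ($R^2 = 0$, $p = 1$) instead of NaNs; constant
latitude and collinear covariates ($|r| > 0.999$) are rejected.
`empirical_outlier_p()` is the genome-wide outlier construction: the count
of background p-values *strictly* smaller than the focal one divided by the
background size, ties counting as not smaller, and the focal site simply
contributing to the denominator when it is part of the background set.

## Problem sizes used in validation

The shipped test suite validates at these scales: the full 11,200-cell
fixation grid at 100 replicates per cell; simulator-versus-oracle lattices
at $N \le 5$ with 20,000 replicates per cell; 10,000-site Balding–Nichols
panels for scan calibration; 200 independent alignments (about 48 kb, 104
haplotypes each) for TMRCA recovery and interval coverage; 500 bootstrap
replicates for tree support and 500 seeded replicates for the
cline-regression null. All randomness is seeded; every reported check is
reproducible bit-for-bit.
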