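---
title: "Models and methods behind sbgevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sbgevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sbgevol` studies how sex-biased gene (SBG) expression evolves across
closely related species that carry different XY sex chromosome systems.
This vignette documents the statistical models, the parameter choices and
their rationale, what the synthetic-data generator does and does not
emulate, and the numerical conventions — the things a maintainer or a
careful user would want written down.

## Sex-bias calling

Counts are TMM-normalized (edgeR's trimmed mean of M-values: 30% trim on
M, 5% on A, precision weights, reference = the sample whose upper
quartile is closest to the mean upper quartile; factors have geometric
mean 1). Normalized values are counts divided by the effective library
size and rescaled by the geometric-mean effective library size, so they
stay on the count scale — this keeps the negative-binomial variance
model and the pseudo-count interpretable, and is invariant to overall
sequencing depth.

The test per species × organ is a negative-binomial Wald test built from
first principles rather than borrowed from a DE package, so that its
contract is fully specified here:

* LFC = log2((mean_M + c) / (mean_F + c)) on normalized counts, with
  pseudo-count c = 0.5 (configurable). Positive LFC = male-biased; the
  sign convention is fixed and documented because the field prints both.
* Per-gene dispersion φ by method of moments from the pooled within-sex
  variance, floored at 1e-8, shrunk towards a fitted a + b/μ
  mean–dispersion trend with weight df/(df + 4) — at three replicates
  per sex the raw estimate has four degrees of freedom and is unusable
  alone.
* Var(mean_g) = (μ_g + φ μ_g²)/n_g; the Wald statistic LFC/SE is
  referred to a t distribution with n_M + n_F − 2 df. The t reference
  (not normal) is a small-sample calibration choice; the test suite
  verifies the resulting false-positive rate is at or below nominal on a
  5000-gene null simulation at the default three replicates per sex.
* BH adjustment within one species × organ family, matching per-species,
  per-organ testing. A gene is sex-biased at padj < 0.05 and |LFC| > 2;
  categories are pure functions of |LFC|: low (2, 2.6), mid [2.6, 4.1),
  high [4.1, 6.5), extreme [6.5, ∞). The bins are applied to |LFC|
  because direction is already carried separately.

Genes with total count < 1 across all samples are removed before
testing. Groups with fewer than two replicates of either sex are skipped
with a logged reason rather than tested. QC flags (median normalized
count below 1; k = 3 nearest-neighbour majority of the opposite sex
within species × organ on log2(normalized + 1) Euclidean distances;
global neighbourhood of another organ) are advisory — exclusion is a
user decision. The log2(x + 1) transform stands in for a
variance-stabilizing transform; QC only needs a monotone variance
damper.

## Intersex population genetics

All statistics are computed from called genotypes with per-sample depth,
not from genotype likelihoods: the inputs here are VCFs, and the
statistics are functions of sample allele frequencies. Sites enter the
general stream when covered in ≥ 3 individuals with total depth ≥ 3, and
the Fst stream when additionally ≥ 2 individuals per sex are covered.

Per site, Hudson's components are
α = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and
β = p₁(1−p₂) + p₂(1−p₁), with n the allele-copy counts of covered
males/females. Per gene, Fst = Σα / Σ(α+β) over the gene's eligible
sites — summing before dividing shrinks noisy per-site ratios towards
the regional value. α may be negative (moment estimator) and negative
per-gene values are retained. All covered individuals per sex are used;
sexes are not down-sampled to equal size.

π per site is 2d(n−d)/(n(n−1)); per gene it is the summed variant-site π
divided by all covered sites (variant + invariant), so coverage
differences between genes do not masquerade as diversity differences.
Tajima's D uses the standard 1989 constants; because the constants need
a single n, sites in a gene are down-sampled to the gene-wise minimum n
via the hypergeometric expectation of the derived count. D is undefined
at S = 0. A site belongs to at most one gene; overlaps resolve to the
earlier gene in sorted order.

## Selection statistics

Pairwise dN/dS is Nei–Gojobori (1986) counting: per codon, the nine
single-nucleotide mutants are classified and each position contributes
syn/3 and nonsyn/3 site fractions; mutations to stop codons are excluded
from the counts (so a codon's N + S is 3 minus its stop-mutant
fraction). Observed differences in multi-hit codons are averaged over
all shortest substitution paths, excluding paths through stop codons
(falling back to all paths only if every path is blocked). Proportions
are Jukes–Cantor corrected, d = −(3/4)ln(1 − 4p/3); p ≥ 3/4 is reported
as saturated (NA). When no nonsynonymous difference is observed but
synonymous ones are, ω is reported as 0 even if the synonymous
correction saturates, since the numerator is exactly zero. This counting
estimator is deliberately simpler than codon-ML; absolute values can
differ from ML estimates, which is acceptable because all comparisons in
the pipeline are internal.

Δx compares a focal species against a reference species used as
ancestral proxy: the difference of mean log2(TPM + 1) across replicates,
divided by the pooled within-species replicate SD on the same scale
(focal-only SD available as an option). |Δx| > 1 in either direction
flags putative directional selection; the bound is read symmetrically
(Δx > 1 or Δx < −1). Zero pooled SD with equal means gives Δx = 0; with
unequal means it is undefined and flagged. Joint candidates are genes
with |Δx| > 1 and ω > 1 (both thresholds configurable).

## Expression phylogenies

Distances between species are 1 − ρ (Spearman, average ranks) between
mean expression profiles — FBG-class trees use female profiles,
MBG-class trees male profiles, unbiased trees sex-averaged profiles.
Trees are neighbour joining (the standard distance method of the `ape`
toolchain); on additive matrices NJ recovers topology and branch lengths
exactly, which the suite asserts against an enumeration oracle. Negative
NJ branches on noisy matrices are clamped to zero with the deficit
transferred to the adjacent descendant branches; clamping never triggers
on additive inputs. Bootstraps resample genes (rows) with replacement;
support of a split is its frequency among replicate trees. Root-to-tip
sums are taken after rooting at the most basal species-tree taxon when
present, else by midpoint. RF distance counts nontrivial bipartitions
present in exactly one tree; the normalized variant divides by the total
nontrivial splits of both trees. Divergence time between two tips is
their path length on the ultrametric species tree (twice the MRCA age),
and the expression rate is (1 − ρ)/t.

## Ancestral reconstruction and turnover

Sex-bias states {U, FBG, MBG} per gene and species (one organ at a time)
evolve under a 3-state equal-rates Mk model,
P_same(t) = 1/3 + (2/3)e^{−3qt}, P_diff(t) = 1/3 − (1/3)e^{−3qt}. One
rate q is fitted by maximizing the summed Felsenstein-pruning
log-likelihood across genes (uniform root prior, per-node rescaling for
numerical stability), with bounded scalar optimization at relative
tolerance 1e-8; monomorphic data report q = 0 with a boundary flag.
Missing species × organ combinations (e.g. organs skipped for lack of
replicates) enter as uniform tip partial likelihoods, preserving tree
shape rather than dropping tips.

Ancestral states are the joint (max-product) assignment per gene, not
per-node marginals; ties break towards U, then FBG, then MBG — a fixed,
documented convention for the measure-zero ties that arise in degenerate
(flat-transition) limits. Turnovers per branch compare parent and child:
any state → MBG is a gain of MBG, MBG → any other state a loss, so a
direct MBG → FBG flip counts one loss of MBG plus one gain of FBG
(symmetrically for FBG); the suite asserts the telescoping identity that
gains − losses along any root-to-tip path equal the state change between
root and tip. PGLS of terminal-branch turnover counts on traits uses a
Brownian covariance from the species tree (nlme::gls, ML); on a star
tree with equal depths it reduces to OLS exactly.

## Genomic distribution tests

The per-LG screen computes the observed MBG − FBG difference on each
linkage group first and then runs the one-sided Fisher's exact test in
that direction (feminized when MBGs are in deficit, masculinized when in
excess); a zero difference reports p = 1 by convention, as does any
empty table margin. Sex-chromosome versus autosome contrasts pool all
autosomes and compare per-gene statistics per bias class with the
Mann–Whitney test: exact p for min(n, m) ≤ 8 without ties, otherwise the
normal approximation with tie and continuity corrections; fully tied
samples report p = 1. BH is plain (unweighted) step-up.

## The synthetic-data generator

The generator's defaults are the study conditions: 14 taxa on a 5-Myr
ultrametric Yule tree; five organs (gonad, brain, liver, gill, jaw);
2 sexes × 3 replicates; gene baselines log2-normal (mean 5, sd 2);
Brownian drift of log2 expression along the tree at 0.05 /Myr per organ;
planted SBGs in 30% of genes in gonads and 1% in somatic organs (the
contrast between gonadal and somatic sex bias the study design relies
on), with |LFC| drawn from a mixture over the four bias categories
(weights 0.25/0.35/0.25/0.15) and a 3× Brownian-rate multiplier so
SBGs also diverge faster in expression; negative-binomial counts with
gene-wise log-normal dispersion (median 0.1) and log-normal library
sizes (CV 0.3, so TMM is exercised nontrivially); genes 300 bp on 22
linkage groups; genotypes for 3 individuals per sex with θ = 0.01, a
1/i neutral frequency spectrum, Poisson depth 10 with 10% dropout, and
30% fixed X/Y-divergent sites (males heterozygous, females homozygous)
on each species' sex-linked linkage groups — one species with a
full-length old system, five with a fused two-LG system, one with a
younger two-LG system, the rest without sex chromosomes; coding
sequences with log-normal target ω (median 0.2) realized by an
accept/reject codon substitution process that cannot create stops;
Brownian traits plus independent noise. Where the emulated study
measures real tissue, these distributions are stand-ins chosen as
standard RNA-seq and population-genetic noise models, not estimates.

Deliberately not emulated: read-level artefacts (mapping bias, genotype
likelihood uncertainty), linkage disequilibrium and coalescent
correlation between sites (sites are independent given the planted
structure), organ-specific baseline correlation, dosage compensation,
and any true association between traits and turnover. Consequently,
passing tests demonstrate the statistics and their plumbing — planted
signals recovered, null rates controlled, oracle equivalence — not that
real tissue data satisfy the generators' assumptions. Two visible
consequences: planted biases are shared across all species unless the
optional bias-state evolution mode is used, so sharing fractions run
near 1; and Brownian drift makes a sizeable fraction of Δx values exceed
|1| between distant species, far more than a within-species selection
scan on real data would show.

Determinism: one integer seed fully determines every output; each
sub-generator derives its own seed from it by fixed offsets, and the
pipeline's manifest records md5 checksums so byte-identical reruns are
checkable.

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make the
Monte-Carlo assertions sharp while keeping a full run in minutes on one
core: 5000 genes for DE calibration and for Mk rate recovery (recovering
q = 0.5 on the 14-taxon tree), 100 replicate datasets for PGLS coverage,
30 000 codons for the neutral ω consistency check, 1100 genes for the
end-to-end pattern-recovery run, and exhaustive enumeration oracles on
trees of up to 6 tips (agreement to 1e-10 in log-likelihood). Ties in
Spearman correlations use average ranks throughout; undefined quantities
(Fst with a zero denominator, D at S = 0, ω at saturated or zero dS,
Δx with fewer than two replicates) are NA with a recorded reason, never
silently zero.

## Known limitations

The DE engine's trended dispersion shrink is simpler than the empirical
Bayes machinery of mature DE packages and is calibrated, not optimal;
power at two or three replicates is modest for |LFC| near the threshold.
NG86 underestimates ω when substitution processes are strongly
non-uniform. The Mk model assumes one rate for all genes and directions;
the joint reconstruction reports a single best history, not uncertainty.
Per-gene Fst inherits the bias of moment estimators at very low
coverage. The generator's independence assumptions make its confidence
statements optimistic relative to real RNA-seq data.
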