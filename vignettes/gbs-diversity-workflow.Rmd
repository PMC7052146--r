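---
title: "Multi-species GBS diversity analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-species GBS diversity analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gbspopgen)
```

`gbspopgen` re-implements, as a tested pipeline, the post-genotyping stage of
a multi-species GBS diversity study: SNP filtering, diversity and
differentiation statistics, species-diagnostic allele panels, admixture
clustering with ΔK model choice, trees and ordination, isolation by
distance, morphology, and GBS-tag redundancy. This vignette records the
models behind each step, the conventions that had to be pinned for
reproducibility, and the reasoning behind the open design choices.

## The synthetic cohort

Field collections cannot ship with a package, so the generator in
`simulate_species_genotypes()` produces cohorts with the statistical
structure the downstream analyses assume, with complete ground truth.

**Allele frequencies.** Each locus draws an ancestral frequency
$p \sim U(0.1, 0.9)$ — the lower bound keeps ancestral loci polymorphic so
that drift, not a degenerate ancestor, controls divergence. Each species
then draws its own frequency from the Balding–Nichols model,
$p_s \sim \mathrm{Beta}\!\big(p\,\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
whose mean is $p$ and variance $F\,p(1-p)$. The drift coefficient $F$ is the
species-level analogue of Fst: two demes simulated at $F$ yield a
Weir–Cockerham theta close to $F$, which is what the parameter-recovery
tests assert. The default $F = 0.85$ matches the strong interspecific
differentiation such studies report (overall Fst above 0.8).

**Genotypes and inbreeding.** With probability equal to the `inbreeding`
parameter an individual is autozygous at a locus (one allele copy drawn and
duplicated), otherwise the two copies are independent. This yields
$E[\mathrm{Ho}] = 2pq(1 - \mathrm{Fis})$ exactly, so the downstream Fis
estimate recovers the parameter (the mean-of-ratios estimator is slightly
biased downward at low He and small n; the recovery test uses n = 40 and
2000 moderately polymorphic loci, where the bias is well inside ±0.05). The
default 0.45 reflects the heterozygote deficits reported for largely
conserved interspecific SNP sets in partially selfing or substructured
species.

**Private-fixed loci.** A fraction of loci per species (default 4%) is
forced to fixation for an allele absent everywhere else — the ground truth
against which the allele classifier is validated exactly when no data are
missing.

**Sampling design.** The default configuration is seven species with uneven
sample sizes (6, 3, 13, 13, 17, 8, 26) at 3002 loci — the shape of a
country-scale germplasm survey. Within-species site structure is not
modelled; the sample-size vector is configuration because no single value
is canonical.

**Geography.** `assign_geography()` orders species along a longitudinal
transect by their genetic similarity (first principal coordinate of the
between-species frequency distance), then interpolates between random and
perfectly ordered longitudes with `cline_strength`. This produces the
positive genetic–geographic correlation that the Mantel analyses expect,
rising from ≈ 0 at strength 0.

**Hybrids.** `simulate_hybrid()` uses an F1/backcross copy-origin scheme:
at proportion 0.5 each locus takes one allele copy from each parental gene
pool (a true F1, 100% heterozygous when parents are fixed for opposite
alleles); at p ≠ 0.5 a locus is homo-parental with probability |2p − 1|.
The expected ancestry fraction equals p, and the heterozygosity of a 0.5
hybrid between strongly diverged, inbred parents exceeds the within-species
level several-fold — the signature used to flag suspect accessions. Note
that with weakly diverged, outbred parents the excess shrinks; the
generator defaults (high F, high inbreeding) are what make the >3× flagging
rule sharp.

**Morphology.** Sixteen named traits with species-modal categorical states;
each observation flips to another state with a per-trait noise rate
(default 0.05, chosen so that a ~90-accession cohort yields tens of
morphotypes rather than one per accession or one per species). States
designed private to a species are excluded from other species' flip
targets, so designed-private characters never leak; under noise they may
drop below fixation in their carrier and are then correctly reported as
diagnostic rather than private.

**Tags.** Fixed-length tag sets per population with a configurable shared
fraction and per-copy point mutations; a one-mismatch 64-mer pair sits at
98.4% identity, straddling the 98% and 95% thresholds the dedup uses.

**What the generator does not model:** linkage between loci, coalescent
genealogies, sequencing reads or errors (quality-depth metadata is
simulated lognormally, independent of genotype, purely to exercise the QD
filter), within-species spatial substructure, and missingness that depends
on genotype (missing calls are completely at random, with an optional
per-accession multiplier emulating low-read samples). Passing tests
therefore certify the statistical machinery, not robustness to structured
artefacts in real GBS data.

## Filtering conventions

The species-tier rule order is pinned and logged: biallelic → adjacent-SNP
removal → QD ≥ 10 → missing < 50% → missing ≤ 30% → MAF > 5%. The order
matters because the MAF denominator depends on which loci and accessions
remain; since the source protocol does not state its order, the pipeline
fixes one and reports per-stage removals rather than guessing. Boundary
conventions: the first missing rule is strict (`< 0.50`), the tightened one
inclusive (`≤ 0.30`), MAF exactly 5% is removed, QD exactly 10 is kept.
"Adjacent" means within 1 bp on the same tag; both members of each adjacent
pair are removed (configurable gap). MAF uses allele counts over non-missing
calls — a heterozygote contributes one copy of each allele.

Sample QC removes accessions with fewer than 600,000 reads first, then
those above 75% missing data, in that order.

A consequence worth knowing: with the pooled-MAF rule, an allele confined
to a species sampled at n = 3 can reach at most 6 of ~172 allele calls
(≈ 3.5%) and is therefore always removed at the 5% cut, so very small
species can lose all their private alleles at the species-SNP tier. The
pipeline reports such species as uncoverable in panel selection rather
than silently relaxing the filter.

## Diversity-index conventions

Per locus and group: `Ne = 1/Σp²`, `I = −Σp ln p`, `Ho` = heterozygote
fraction of non-missing calls, `He = 1 − Σp²`, `Fis = (He − Ho)/He` for
loci with He > 0. Group values are plain means over loci. Two conventions
are deliberate:

* **Untyped loci** (no non-missing call in the group) contribute
  Ne = I = Ho = He = 0 and are excluded from Fis. Zeroing Ne is the only
  convention under which a group's mean Ne can fall below 1, which the
  reference tables of such studies do show; the count of untyped loci is
  reported alongside.
* **Group Fis** is the mean of per-locus Fis, not
  1 − mean(Ho)/mean(He); the two differ materially on drifted data and the
  reference tables are consistent only with the former.

P% is the percentage of polymorphic loci among loci *typed* in the group
(untyped loci excluded from the denominator; the alternative of counting
them as non-polymorphic is not used, and the choice is logged here).

Nei distance uses the classical 1972 formulation by default, with the
small-sample (1978) correction behind a flag. Pairs with no shared alleles
give an infinite distance, reported as `Inf` with a warning — clipping
would silently understate divergence.

Fst follows the `(Ht − Hs)/Ht` per-locus form with unweighted group means
(the convention of the software such studies use), averaged over loci with
Ht > 0. Because the mean of per-locus ratios is not the ratio of means,
this quantity differs from Weir–Cockerham theta; theta
(`pairwise_fst(..., method = "wc")`) is the estimator that recovers the
Balding–Nichols drift coefficient and is used for parameter-recovery
checks. Nm is reported under both conventions — mean of per-locus
`0.25(1 − Fst)/Fst` and the formula applied to mean Fst — because the two
can differ by an order of magnitude when per-locus Fst is variable, which
explains why published Fst/Nm pairs often cannot be reconciled through the
island-model formula alone.

## Allele classification and panels

Classification is allele-level: a heterozygote carries both alleles for
the uniqueness test and contributes one copy of each to frequencies.
Fixation is judged on non-missing calls only, so missing data can never
manufacture a private allele; a locus untyped in a group cannot yield one.
Panel selection takes one private-allele SNP per group (tie-break: least
missing data, then lowest locus ID — pinned purely for determinism). For a
group inside a declared species complex without private alleles, a
diagnostic SNP qualifies as a *separator* when every accession of the
group carries the allele (homozygous or heterozygous) and every complex
partner is homozygous for the opposite allele — the rule that mirrors how
diagnostic markers distinguish two subspecies in practice. Assignment is
rule-based (no likelihood model): carrying private alleles of two or more
targets is a conflict (putative hybrid), carrying none is unresolved, and
a complex-level call refined by a carried separator resolves to the
member, not a conflict.

## Admixture clustering

The sampler implements the standard admixture model with independent
cluster allele frequencies: Beta(λ, λ) priors on frequencies, symmetric
Dirichlet(α) on ancestries, and a Gibbs cycle over allele-copy cluster
assignments Z, then P, then Q. α is fixed (default 1.0) rather than
sampled as in the original tool — simpler, and adequate for recovering
well-separated clusters; the correlated-frequencies prior and linkage
model are intentionally out of scope. Missing genotypes contribute no
likelihood terms and are not imputed. The model evidence is estimated as
`L(K) = mean(lnL) − var(lnL)/2` from the post-burn-in trace; the trace is
returned so alternative estimators can be recomputed.

Desk-scale defaults are 2,000 burn-in and 5,000 retained sweeps — enough
for the recovery tests (ARI ≥ 0.95 on two demes at theta ≈ 0.3 with 300
loci) — while full-scale settings (100,000/100,000) remain plain
arguments. Evanno's ΔK = |L″(K)|/sd(L(K)) is computed exactly as the
spreadsheet convention: ΔK is defined only at interior K, requires ≥ 2
runs per K and non-zero run-to-run spread, and an all-zero second
difference is flagged ambiguous rather than resolved arbitrarily. ΔK
inherits its well-known bias toward the top hierarchical split; on
star-like synthetic radiations the selected K can undershoot the species
count, which is faithful behaviour of the statistic, not a defect of the
sampler. Label switching across runs is repaired by greedy column matching
on Q correlations — adequate for well-separated runs, simpler than full
assignment-problem matching, and pinned as such.

Purity classification is strict: membership must *exceed* 0.90 to be
called pure; exactly 0.90 is admixed.

## Trees, ordination, geography

The dissimilarity between diploid genotypes is allele-sharing:
0 / 0.5 / 1 per locus for identical / one-shared-allele / no-shared-allele,
i.e. |g₁ − g₂|/2 on dosage codes, averaged over co-typed loci (pairwise
deletion, with a configurable minimum co-typed floor, default 50, below
which the pair is an error). The original studies' tree software does not
document its coefficient; allele sharing is pinned as the default with
simple matching behind a flag, and tree results on real data should be
compared at the level of topology and support classes, not digits.

NJ and UPGMA agglomeration are delegated to `ape` and `stats::hclust`
(average linkage): these are standard algorithms, and the package pins
what surrounds them — bootstrap resampling is over loci (never
accessions), drawn by sorted locus ID so supports are invariant to column
order, with supports counted on the full-data tree's bipartitions;
negative NJ branch lengths are clamped to zero with a warning; hclust's
lowest-index tie-break makes UPGMA deterministic.

PCoA uses Gower double-centering with negative eigenvalues excluded from
the percent-variance denominator and reported separately. Geographic
distances are haversine on a 6371 km sphere; at country scale the
difference from Euclidean-degree distances is monotone and does not affect
rank-based conclusions. The Mantel statistic is the Pearson correlation of
upper triangles with joint row/column permutation;
`P = (#{permuted ≥ observed} + 1)/(n_perm + 1)`, one-tailed on positive
association by default (two-tailed available), and the permutation P
converges to the exhaustive-enumeration P (checked exactly at n = 4, 5).

Genotype accumulation counts distinct multilocus genotypes in random locus
subsets. With missing data, "identical" (equal at every co-typed sampled
locus) is not transitive; the count is defined as the number of connected
components of the identity relation, which reduces to exact distinct-row
counting when nothing is missing.

## Morphology

Mixed-trait distances use the Gower coefficient (categorical: 0/1
mismatch; quantitative: range-normalised absolute difference), with an
integer-coded Euclidean alternative. Quantitative traits are binned into
quartile classes for frequency-based indices (configurable bin count).
Morphotypes are distinct complete state vectors; accessions with missing
states are excluded from morphotype enumeration (complete-case policy,
mirroring how reference tables exclude incompletely scored accessions) but
participate everywhere else. The variance partition is the AMOVA
sums-of-squares decomposition of the pairwise distance matrix with
variance components (negative among-group components truncated at zero, so
percentages sum to 100) and a label-permutation P on the pseudo-F. Trait
contributions to PCoA axes are squared correlations (quantitative) or
one-way ANOVA R² (categorical) normalised to 100% per axis; the reference
software's contribution method is undocumented, so this transparent
definition is pinned instead. Per-species SE of H′ is over traits (not a
bootstrap), and labelled as such.

## Tag redundancy

Identity is computed over the full tag length — position-wise for
equal-length tags, via an end-gap-free overlap alignment otherwise — rather
than by a local-alignment search heuristic; for fixed-length GBS tags the
two agree, and the exact computation is deterministic and
parameter-free. Clustering is single linkage because "keep a single tag"
semantics collapse transitively: a chain a~b~c at 98.4% identity merges
even when a~c is below threshold (the caveat is logged). Representatives
are the lexicographically smallest tag ID. A shared 16-mer prefilter
bounds the quadratic scan on large sets. Raising the threshold can only
increase the representative count, which the tests assert.

## Problem sizes

The bundled analyses and checks run at deliberately moderate sizes chosen
as the package's own defaults: the full cohort at 86–87 accessions × 3002
loci for filtering, diversity, trees and morphology; clustering on a
300-SNP subsample with 3 runs per K over K = 1…8 at desk-scale chain
lengths; 200–500 bootstrap replicates; 999 permutations for Mantel and
variance-partition tests; and a 2 × 50 × 2000 two-deme simulation for Fst
parameter recovery. All of these scale up by argument.

## Known limitations

* The admixture sampler omits the correlated-frequencies prior and α
  sampling of the original tool, so its absolute L(K) values are not
  comparable to that tool's — only the within-package comparisons across K
  are meaningful.
* Mean-of-ratios estimators (group Fis, per-locus Fst means) carry small-n
  bias; the package reproduces the field's conventions rather than
  replacing them, and exposes Weir–Cockerham theta where an unbiased
  estimator is needed.
* Single-linkage tag collapse can chain distant tags through
  intermediates; representatives of different clusters are guaranteed
  below threshold only pairwise-directly.
* The generator's independence assumptions (no linkage, MCAR missingness)
  mean test results bound what the methods do under their own model, not
  under real GBS artefacts.
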