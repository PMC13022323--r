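---
title: "Detecting phylosymbiosis in fractions of a microbiome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phylosymbiosis in fractions of a microbiome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofrac)
```

## The problem

Phylosymbiosis is the statistical congruence between the phylogenetic
relationships of host species and the compositional similarity of their
microbiomes. Detecting it in data pooled from independent sequencing studies
is hard for two reasons. First, study ("batch") effects dominate microbiome
dissimilarity: samples cluster by bioproject, not by host species. Second,
even where a signal exists it may be carried by a minority fraction of taxa,
invisible in whole-microbiome tests. `phylofrac` implements a pipeline for
exactly this setting: prepare a cross-study OTU table, quantify the
study-dominated structure, test whole-microbiome congruence with the host
phylogeny, and then use OTU resampling to search for fractions of the
microbiome that do track the host tree.

The package is organised as an analysis workflow (`analysis/01_simulate.R`
... `analysis/05_discovery.R`) over library functions; every computation in
the scripts is a package function, so the same code paths are unit-tested
and reusable.

## Table preparation

The substrate is an `otu_table`: integer counts (samples x OTUs), a
six-rank lineage per OTU, and sample metadata (host species, study, sample
type). Three preparation steps precede every analysis:

* **Agglomeration** (`agglomerate`): features sharing a genus (or other
  rank) annotation are pooled by summing counts. Cross-study comparison
  requires named taxa, because different primer pairs produce
  non-overlapping sequence variants; features unassigned at the chosen rank
  are therefore dropped rather than pooled into an "unclassified" bin,
  which would mix unrelated lineages across studies.
* **Filtering** (`filter_otus`): singletons (total count < 2) and
  contaminant lineages (archaea, chloroplast, mitochondria) are removed.
  Contaminant matching is a case-insensitive substring test at any rank,
  because organellar labels move between ranks across taxonomy database
  versions.
* **Rarefaction** (`rarefy`): each sample is subsampled without replacement
  (a multivariate hypergeometric draw, delegated to `vegan::rrarefy`) to
  the lowest observed sample total, removing sequencing effort — which can
  span two orders of magnitude — as a confounder. OTUs that drop to zero
  everywhere are kept in the matrix so that OTU sets stay aligned between
  analyses; presence-based statistics ignore them through the count > 0
  rule. The seed is a required argument: rarefaction is the first
  stochastic stage of the pipeline.

## Dissimilarity, clustering, and support

Two beta-diversity measures are used, for different questions. The binary
Jaccard distance (1 minus the ratio of shared to observed OTUs) quantifies
OTU *sharing* and is computed over all samples including seawater controls;
the Bray-Curtis dissimilarity (sum of absolute count differences over the
sum of counts) quantifies abundance structure on the rarefied host-sample
panel. Whether an abundance-weighted Jaccard would be preferable is a known
ambiguity; the binary form matches the sharing question and the weighted
variant is available behind a flag for sensitivity analysis.

Dendrograms are built by Ward's minimum-variance clustering in the
"ward.D2" dialect (dissimilarities squared inside the Lance-Williams
recurrence). `stats::hclust` is the reference implementation of this
dialect and is used directly; its tie-breaking is deterministic for a fixed
input, and the test suite verifies the agglomeration path against a naive
Lance-Williams implementation on tie-free random matrices. "ward.D" is
available because published analyses do not always name the dialect.

Branch support is computed by resampling OTU columns with replacement
(`bootstrap_support`), rebuilding the dendrogram, and recording for each
internal branch the proportion of replicates whose *unrooted* split set
contains that branch's bipartition. Unrooted splits, not rooted clades, are
counted so that support is invariant to the cosmetic rerooting applied for
display; this choice matters because outgroup rerooting after clustering
would otherwise shift clade identities.

## Clustering information distance

Topological congruence is scored with the clustering information distance
(CID), an information-theoretic generalisation of the Robinson-Foulds
distance. Each tree is reduced to its nontrivial unrooted splits. A split
dividing n leaves into sides of a and b carries
h = -(a/n) log2(a/n) - (b/n) log2(b/n) bits of clustering information; two
splits share the mutual information of their 2x2 co-membership table. The
distance solves a maximum-weight bipartite matching between the two split
sets (the smaller side padded with zero-weight dummy splits) to obtain the
shared information S, and reports h1 + h2 - 2S bits, normalized by h1 + h2
so that 0 means identical split sets and 1 means no shared clustering
information. The normalization denominator was chosen so the statistic
lies in [0, 1]; assignment is solved exactly by an O(n^3)
shortest-augmenting-path algorithm, validated in the tests against
exhaustive enumeration over all assignments for every pair of 5- and
6-leaf topologies.

Two numerical details deserve note. Per-tree totals h1 and h2 are
accumulated through the same floating-point path as the pairwise mutual
information matrix, and identical split sets are detected exactly, so the
distance between topologically identical trees is exactly 0 rather than
within rounding error of it — "perfect congruence" is a meaningful event
for the discovery procedure below. Multifurcating trees are handled
natively (a polytomy simply contributes fewer splits); dendrograms are
always binary.

Significance uses a tip-shuffle null: the dendrogram's labels are permuted
uniformly at random with the topology fixed, and the p-value is the
proportion of shuffles with *strictly lower* CID than the point estimate.
This plain proportion (no +1 correction) is the convention adopted
throughout; a corrected variant ((# <= obs) + 1)/(n + 1), which cannot
return 0, is available behind a flag. With the strict convention a
perfectly congruent pair has p = 0 at any number of permutations, since no
shuffle can beat a distance of zero.

## Distance-based tests

The Mantel statistic is the Pearson correlation of the lower triangles of
two label-aligned distance matrices; the partial variant is the first-order
partial correlation given a third matrix. Conditioning matters here: a
binary design matrix (0 = same study, 1 = different studies; see
`build_design_matrix`) absorbs the between-study component of microbiome
dissimilarity so that study structure cannot masquerade as phylogenetic
signal. Nulls permute the first matrix jointly in rows and columns — the
design matrix stays fixed — and the default tail is "greater", because
phylosymbiosis predicts a positive association; this also matches reported
negative correlations carrying large p-values. For panels of up to eight
samples an exhaustive mode enumerates all n! relabelings instead of
sampling them.

Single-factor PERMANOVA partitions the squared dissimilarities:
SS_total = sum over pairs of d^2 / n, SS_within accumulates the same
quantity per group, pseudo-F = (SS_model/(k-1))/(SS_within/(n-k)) and
R^2 = SS_model/SS_total, with a label-permutation null. Perfect separation
(zero within-group dissimilarity) yields an infinite pseudo-F and is
flagged rather than masked.

These statistics are implemented in the package rather than delegated, so
that the permutation conventions above and the exhaustive mode are exactly
as documented; the test suite cross-checks every statistic against `vegan`
(`mantel`, `mantel.partial`, `adonis2`) and every exhaustive p-value
against from-scratch enumeration.

## Host trees and sample panels

The host phylogeny is species-level; panels may contain several samples of
one species (replicates across studies). `expand_host_to_samples` replaces
each species tip by a zero-length polytomy of its sample ids and extends
the distance matrix with zeros between conspecific samples. Conspecific
replicates are thus expected to be *sisters* in a congruent dendrogram, and
any between-study separation of conspecifics counts against congruence —
which is precisely the confounding signature of interest.

Analyses run on two panels, reflecting a deliberate two-tier design: the
*core* panel (all host samples of the single best-sampled study, no
between-study confounding, plain Mantel test) and the *full* multi-study
panel (partial Mantel conditioned on the study design matrix). The
outgroup species is excluded from distance-based tests — in a real
application its nucleotide distances are typically unavailable — but kept
in the topological tests, where it anchors the root.

## Fraction discovery

The headline procedure asks whether any fraction of the microbiome is
congruent with the host tree even though the whole microbiome is not.
`score_replicates` resamples OTU columns — bootstrap (with replacement,
full size, duplicated columns retained as a true multiset) or subsample
(10 OTUs without replacement) — 10,000 times and scores each replicate by
(i) the CID between its Bray-Curtis Ward dendrogram and the host tree and
(ii) its (partial) Mantel correlation with host distances. The Mantel score
is the point statistic only: replicates are thresholded on the correlation
coefficient, so inner permutation tests would add nothing but cost.
Replicates that leave a sample with no reads have undefined dissimilarities
and are recorded as failed; they are excluded from the denominator of
qualifying fractions but reported.

A replicate qualifies topologically at perfect congruence (CID = 0,
applied as <= 1e-12) and by distance at r >= 0.9. Each criterion's OTU set
is the union of distinct OTU ids over its qualifying replicates;
`consensus_sets` intersects criteria and reports recovery percentages, and
`reevaluate` subjects any candidate set to the full permutation tests on a
panel that may differ from the discovery panel, keeping discovery and
validation separate.

The union rule deserves a caveat that our synthetic experiments quantify:
every qualifying subsample contributes its whole draw, so OTUs that merely
co-occurred with signal OTUs in a lucky draw ("hitchhikers") accumulate in
the set at roughly k - E[signal per draw] per qualifying replicate. The
union therefore has high recall of genuine signal OTUs but modest
precision, and its enrichment over a random draw weakens as qualifying
replicates accumulate. The frequency-weighted variant
(`qualifying_otus(..., min_replicates = m)`) trades recall for precision
and is the recommended robustness check.

## The synthetic generator

`simulate_table` generates the reference scenario: 9 host species (8
ingroup plus an outgroup) sampled as 17 host-skin samples across 6 studies
— one "core" study holding 6 species from one location, three species
replicated across two studies — plus 5 seawater controls. The abundance
model is log-linear with multinomial read sampling:

* a planted phylosymbiotic OTU j evolves a species trait z_j by Brownian
  motion on the host tree (variance `sigma2_phylo` per unit branch length;
  the tree is scaled to unit height), and contributes
  lambda_ij = a_j + z_j(species(i)) + e_ij in host samples;
* a noise OTU carries a study effect b_{j, study(i)} ~ N(0, `sigma2_study`)
  and a loading u_j on a latent per-sample environmental gradient f_i ~
  N(0, `sigma2_sample`), lambda_ij = a_j + b + u_j f_i + e_ij;
* baselines a_j ~ N(0, `baseline_sd`^2) give a log-normal rank-abundance
  curve, with planted OTUs shifted up by `phylo_baseline_shift` (host
  symbionts sit above transient environmental taxa);
* relative abundances are the softmax of lambda and counts are
  Multinomial(depth_i, p_i), depth_i log-uniform over 30,185-1,677,653
  reads, matching the depth range of real multi-study amplicon surveys.

A species replicated across studies keeps its trait z (a host property)
but draws new study effects — encoding the empirical observation that
conspecific replicates cluster by study. Seawater samples receive
baselines, study effects, gradient and residuals but no species trait.
Singleton OTUs (one read, compensated from the donor sample's top OTU so
totals still equal drawn depths) and contaminant lineages are injected at
5% and 3%; 10% of noise OTUs lack a genus annotation to exercise the
agglomeration-dropping rule.

The latent gradient is the one deliberate extension beyond the minimal
"study effects + residual" model. Without it, within-study noise is
exchangeable, and on a six-sample panel about 1% of random 10-OTU draws
reach Mantel r >= 0.9 by chance alone — 10,000 replicates then flood the
qualifying union with noise OTUs, which no parameter setting can prevent.
Real surveys are not exchangeable: they carry dominant non-phylogenetic
gradients (which is why real dendrograms are bootstrap-supported yet
host-incongruent), and the gradient term reproduces exactly that
behaviour.

Default variances (4, 4, 4, 0.25 for phylo/study/gradient/residual, in
squared log-abundance units) were fixed once on the reasoning that the
three structured components should be of comparable magnitude — study
dominance is the empirical regime of interest — with measurement-scale
residuals well below them. They are testability-oriented defaults, not
estimates of any real effect size, and the generator documents them as
such.

What the generator does *not* emulate: primer and region effects, read-level
error and chimeras, taxonomy misassignment, and ecological interactions
between taxa. Passing tests on synthetic data therefore demonstrate that
the statistics recover a planted log-linear signal under multinomial
sampling and realistic confounding — not that any particular real dataset
contains such a signal.

## Reproducibility and numerical conventions

All randomness flows from explicit seeds. A pipeline run takes one master
seed and derives a child seed per stochastic stage (by drawing from a
seeded integer stream), records every child seed in its report, and writes
only plain-text outputs; a rerun with the same configuration is
byte-identical. Functions restore the caller's RNG state, so library calls
never perturb user scripts.

Numerical conventions: distance matrices are validated symmetric within
1e-12 with zero diagonal; CID qualification uses a 1e-12 tolerance around
zero; assignment dummy padding has weight exactly 0; mutual information
cells with zero counts contribute exactly 0. Degenerate inputs (all-zero
samples, constant distance vectors, |r| = 1 conditioning, groups without
residual degrees of freedom) raise errors rather than propagate NaN.

Test-suite problem sizes are chosen to make the checks sharp but quick:
oracle equivalence runs over every 5- and 6-leaf topology pair and fifty
8x8 Ward matrices; calibration uses 500 no-signal runs of 99 permutations
on 8-sample matrices and 10-leaf trees; the end-to-end recovery experiment
uses the full 10,000-replicate discovery on the reference layout.

## Known limitations

* The union rule's hitchhiker accretion (discussed above) bounds the
  precision of discovered OTU sets; enrichment of the plain union over a
  hypergeometric draw is weak whenever many replicates qualify.
* With six-sample discovery panels the Mantel permutation space is small
  (120 relabelings of five ingroup samples), so p-value resolution is
  coarse; the package reports plain proportions and offers exhaustive
  enumeration rather than pretending to finer resolution.
* Bray-Curtis saturates for strongly diverged compositions, compressing
  the mapping from trait divergence to dissimilarity; very strong planted
  signals therefore do not translate into proportionally higher Mantel
  correlations.
* The CID tip-shuffle test conditions on both topologies; it does not
  model uncertainty in the dendrogram itself (branch support quantifies
  that separately).
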