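---
title: "Methods: tripartite co-expression networks and constrained ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tripartite co-expression networks and constrained ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

symbionet analyses gene-expression interactions among three transcriptomic
"compartments" measured on the same biological samples: a mite host
(*Tyrophagus putrescentiae*, KEGG-annotated genes), a *Solitalea*-like
bacterial symbiont (SOL), and the intracellular symbiont *Cardinium*
(cTPut), which is present in only some mite cultures. The design it targets
is four laboratory cultures (two cTPut-positive, two cTPut-negative) with
seven replicates each, 28 samples in total; the cTPut compartment exists
only for the 14 positive samples and is treated as structurally absent
elsewhere, not as zero counts.

This vignette records the models, the parameters that matter, the numerical
conventions, and the design decisions taken where more than one defensible
choice existed. All empirical statements below are the ones the package's
own tests and `scripts/acceptance.R` compute.

## Standardization and simple summaries

Read counts per gene are the raw measure. Symbiont compartments are
standardized to a fixed per-sample total (3,000 reads for SOL, 5,000 for
cTPut, the package defaults). "Standardize to N reads" admits two readings,
both provided:

* `mode = "scale"` (default): multiply each sample column by
  `target/total`. Deterministic, preserves within-sample proportions
  exactly, produces real-valued "counts".
* `mode = "downsample"`: a seeded multinomial subsample of exactly N
  reads — rarefaction. Used when integer counts or rarefaction semantics
  are required; the output records its seed.

Spearman statistics computed downstream are identical on standardized
values and on per-sample proportions (scaling by a constant is
rank-neutral); they are *not* identical between raw and standardized
counts when library sizes differ — removing that library-size signal is
the purpose of standardizing.

Symbiont load is summarised as the per-sample ratio of symbiont to host
mapped reads (`relative_abundance()`), and expression evenness as Shannon
diversity (natural log by default; the comparisons made with it are
rank-based, so the base is immaterial). qPCR copy numbers are preprocessed
by zeroing values below the detection limit (default 10 copies) and taking
log10(x + 1).

## Permutation Spearman edges

For two genes measured over the same n samples, rho is the Pearson
correlation of average-ranked values. Significance comes from a two-sided
permutation test: all n! permutations are enumerated when n <= 7 (p is
then the exact proportion of permutations at least as extreme, never 0);
otherwise a Monte Carlo test with the add-one correction
p = (1 + extreme) / (1 + n_perm), so p >= 1/(n_perm + 1). The default is
9,999 permutations at alpha 0.05, with no multiplicity adjustment across
the edge matrix — edge calling reproduces a raw-p < 0.05 screen; an
optional Benjamini-Hochberg layer can be applied to the returned `p_perm`
column by the user, and is deliberately not the default.

`correlate_compartments()` tests every cross-compartment pair. One shared
permutation stream reshuffles the sample alignment of the second
compartment for the whole matrix at once; each pairwise p-value remains
marginally valid under exchangeability, and the whole matrix runs as BLAS
operations. Zero-variance genes (all-zero genes are common in real count
tables) are skipped with a warning rather than an error.

## Network scores and hubs

From a called edge set, each focal-compartment gene receives

* `n_partners` (N): distinct partner genes;
* `s_type`: the sum of +1/-1 over counted edges;
* `s_strength`: the total weight of counted edges.

Two strength conventions are shipped because the published definition
("sum of strength") is ambiguous. In `pathway_instance` mode (default)
each (partner gene, pathway membership) is one counted edge, so a partner
annotated to four pathways contributes four counted edges; this is the
reading consistent with published tables in which S_strength exceeds N by
factors of 4-8, impossible for a sum of |rho| under a 0.75 cutoff. In
`abs_rho` mode counted edges are distinct partners and strength is
sum(|rho|). Hub filtering retains genes with `s_strength` strictly greater
than a cutoff; the published analysis used |rho| in [0.75, 1] and strength
> 100 against 5,838 host genes. Because pathway-instance strength scales
with the size of the partner compartment and its annotation multiplicity,
scaled-down analyses must scale the cutoff: the package's synthetic-scale
analyses use 5 (20-gene planted blocks, mean pathway multiplicity ~1.2),
while 100 remains the default for full-size data.

Per-gene positive/negative edge counts are compared between conditions
with a paired t-test by gene (`compare_edge_counts()`); zero-variance
differences return t = 0 (all zero) or +/-Inf with a warning, rather than
failing. Correlation matrices are ordered for heatmaps by Ward linkage
(`ward.D2`) on Euclidean distances between correlation profiles.

## Distances

* Bray-Curtis: d(i,j) = sum|x_i - x_j| / sum(x_i + x_j), a semi-metric for
  abundance data.
* Robust Aitchison: Euclidean distance on rclr-transformed samples, where
  rclr(x)_i = log(x_i) - mean(log over positive entries) for x_i > 0 and 0
  for x_i = 0. Taking the geometric mean over the nonzero parts only, and
  leaving zeros at 0, is a deliberate simplification of
  matrix-completion-based robust Aitchison estimators: it is deterministic,
  exact on complete data, and metric (Euclidean on transformed rows).

## dbRDA

Distance-based redundancy analysis follows the principal-coordinate route:
Gower-center the squared distances (G = -1/2 J D^2 J), eigendecompose, and
regress the positive-eigenvalue coordinates on the predictors.

* R (explained variability) is the multivariate regression R^2 on the
  positive-eigenvalue coordinates: constrained inertia over total positive
  inertia. This keeps R in [0, 1] even for semi-metric distances with
  negative eigenvalues. Negative eigenvalues are reported separately; no
  Lingoes/Cailliez correction is applied by default.
* The pseudo-F is trace-based (McArdle-Anderson): tr(HGH)/q over
  (tr(G) - tr(HGH))/(n - q - 1), computed on the full Gower matrix
  including its negative part. With a single group factor this is exactly
  the PERMANOVA pseudo-F from within/between sums of squared distances,
  which is what the acceptance oracle checks.
* Significance: a Monte Carlo permutation test (default 10,000
  permutations) reshuffling the sample rows of the predictors; all
  distinct permutations are enumerated instead for n <= 7. p uses the
  add-one correction.
* df accounting: df_model = rank of the centered design, df_residual =
  n - df_model - 1, always summing to n - 1. Aliased predictor columns are
  dropped with a warning. A saturated design (df_residual = 0) yields R
  but no F or p.
* Site scores (CAP axes) are the SVD of the fitted coordinate matrix.

On Euclidean distances the whole construction collapses to classical RDA:
R equals the least-squares multivariate R^2 to 1e-8 in the test suite.

## Forward selection

Forward-only greedy selection of predictor columns (typically symbiont
gene vectors). At each step every remaining candidate is scored by its
incremental pseudo-F given the selected set, against one shared
permutation stream. Two entry rules:

* `entry = "maxstat"` (default): the step's best candidate enters only if
  its F exceeds the permutation distribution of the *best-candidate* F
  (max over candidates per permutation) at `alpha_enter`. This
  family-wise gate keeps the probability of admitting pure noise at a
  step near alpha regardless of pool size. With three noise candidates
  the selected set stays empty in about 95% of runs, and with
  gene-sized pools the selected model sizes match the small constrained
  df (2-10 at n = 14) that per-pathway models should have.
* `entry = "marginal"`: the textbook rule (smallest per-candidate p among
  those below alpha). With hundreds of candidate genes the minimum
  marginal p is below alpha at essentially every step, so models saturate
  (df_model -> n - 2); this rule is retained for small curated pools.

Ties are broken by larger incremental explained inertia, then input
order; duplicated (aliased) candidates can never both enter. Selection is
forward-only rather than bidirectional because it is deterministic,
testable, and only selected terms are ever reported.

## ANOSIM and the rank-sum test

ANOSIM ranks all n(n-1)/2 dissimilarities (average ties) and computes
R = (mean between-group rank - mean within-group rank) / (M/2),
M = n(n-1)/2, tested by label permutation (exact enumeration of distinct
labelings for n <= 7). The Mann-Whitney helper reports U = min(U1, U2), a
z statistic from the normal approximation with tie-corrected variance and
0.5 continuity correction, and an exact two-sided p by enumerating all
group assignments when n1 + n2 <= 12.

## The pathway ledger

For each host pathway, the ledger fits
`distance(host pathway genes) ~ forward-selected symbiont genes`
separately on the cTPut-positive and cTPut-negative sample subsets
(robust Aitchison by default) and reports each partial model's R, F and
df together with dR = R_with - R_without, sorted by dR descending. dR > 0
marks pathways whose coupling to the symbiont is stronger in the presence
of *Cardinium*; dR < 0 the reverse. The forward-selection permutation
seed is shared between the two subsets, so identical data produce
identical selections and dR = 0 exactly. Pathways with fewer than two
genes present are skipped with a warning. Symbiont candidates should be
standardized (and the pipeline standardizes them) so that library size
does not masquerade as association.

## Differential expression

Per-gene condition contrasts use Mann-Whitney by default (robust for
counts; Welch t optional), Benjamini-Hochberg adjustment across genes,
and log2 fold changes with a pseudocount of 1 on standardized values.
Pathway-level contrasts sum member-gene expression per sample first (a
gene in several pathways contributes to each) and adjust across pathways.
The output records which test produced it. No negative-binomial GLM is
offered: the upstream study performed none, and the package's contrasts
are deliberately the simple screens it used.

## The synthetic-data generator

`simulate_expression()` emulates the study design so the whole pipeline is
testable without any data download: 2 + 2 cultures x 7 replicates,
compartments of 500 host / 200 SOL / 150 cTPut genes by default (the real
compartments, 5,838 and 1,273 genes, are supported through the
configuration but are not the default because full runs should stay in
the minutes range on one CPU).

Counts are drawn via a latent-factor Gaussian copula with negative
binomial marginals: each planted block shares one N(0,1) factor per
sample; a member gene's latent value is `loading * factor` plus
independent Gaussian noise, mapped through its NB quantile function
(size 3; per-gene baseline means log-normal with meanlog log 30, sdlog 1;
per-sample library-size factors log-normal with sdlog 0.3). The copula
construction makes the *rank* correlation of planted pairs controllable
(approximately sign * loading^2 before count discretization), which is
exactly what the Spearman machinery measures. Blocks can be active in all
samples or only in one condition; the default plants shared,
positive-specific, negative-specific and negative-sign host-SOL blocks
plus a SOL-cTPut block, all at loading 0.9, each inside a single synthetic
pathway. A condition effect multiplies all SOL means by 0.4 in
cTPut-positive samples, reproducing the direction of the published
abundance difference; no published effect size exists for it, so 0.4 is a
package choice large enough to be detectable at n = 14 + 14.

What the generator does *not* emulate: real KEGG annotation structure
(pathways are synthetic overlapping partitions), taxon-specific count
distributions, compositional interactions between compartments beyond
shared library size, or batch effects. Passing recovery tests therefore
demonstrates that the statistical machinery detects the structure it is
pointed at, not that the biological conclusions of any particular dataset
are correct.

## Problem sizes and determinism

The test suite and acceptance script run the generator at its default
scaled-down sizes: recovery uses 10 generator seeds (edge calling at 999
permutations, ledger selection at 199), type-I calibration uses 2,000
independent pairs at 999 permutations, the BH null uses 50 seeds, and
oracle equivalences use 8-sample (least squares) and 6-sample (PERMANOVA,
exact enumeration) instances. Every random stage takes an explicit seed;
`full_run()` derives one child seed per stage from its global seed, and
two runs with the same configuration are byte-identical.

## Known limitations

* The rclr zero convention is the simple one; heavily sparse data are
  better served by matrix-completion robust Aitchison, which is out of
  scope.
* Permutation p-values from shared streams (edge matrices, selection
  steps) are marginally but not jointly independent across pairs.
* The max-F entry gate is conservative for correlated candidate pools; a
  curated small pool with `entry = "marginal"` is the alternative.
* ANOSIM and dbRDA assume exchangeable samples; the replicate structure
  within cultures is not modelled as a restricted permutation design.
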