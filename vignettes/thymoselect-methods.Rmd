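---
title: "Methods: repertoire diversity, CDR3 motifs and promiscuous gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire diversity, CDR3 motifs and promiscuous gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymoselect)
```

# Scope and model

`thymoselect` quantifies how a thymic epithelial compartment shapes (i) the
selected TCRα repertoire and (ii) the breadth of promiscuous,
tissue-restricted-antigen (TRA) gene expression. It covers five analysis
stages — clonotype catalogues, CDR3 self-reactivity motifs, coverage-based
clonotype diversity, repertoire overlap/segment usage, single-cell TRA
breadth, and TSS ChIP/input metaprofiles — plus generators that emulate each
input family with planted parameters.

# Clonotype catalogues

A *clone* is one cell lineage (an "individual"); a *clonotype* is a unique
combination of primary Trav segment and CDR3 amino-acid sequence (a
"species"). Ingested records are filtered to functional CDR3s (no `*` stop
or `_` frameshift sentinel; the sentinel set is configurable because the
rule, not the encoding, is canonical) and to at least 3 reads per sample —
applied per sample, before collapsing, so a sequence poorly supported in one
mouse can still count in another. Within a sample each clonotype is counted
once, irrespective of read count. Pooling all samples of one subset ×
genotype yields a *TCR catalogue* whose abundance is the number of distinct
mice in which each clonotype was detected; samples from the same mouse are
merged first, because abundance is defined per mouse, not per sorted
aliquot. Traj calls are carried as metadata but are not part of the
clonotype key. Where a mouse contributed several sorted subsets we merge
per mouse *within* a subset only; merging across subsets would conflate
developmental stages.

# CDR3 motif scoring

Two self-reactivity-associated features are scored:

* **Position-6/7 doublets.** Position 1 is the conserved N-terminal
  cysteine; the doublet is the residues at positions 6 and 7. CDR3s shorter
  than 7 residues have no doublet but stay in the denominator. Proportions
  are computed over clonotypes (each counted once per sample), and samples
  with fewer than 100 clonotypes are excluded rather than reported. The
  published doublet list is supplied by the user (one doublet per line); it
  is not redistributed here.
* **Central cysteine.** Residues are numbered outward from the loop apex:
  odd length L puts the unique central residue at position 0; even length
  puts the central pair at 0 and +1. This even-length convention is a
  declared design choice — the upstream alignment convention is not defined
  in text form anywhere we could follow — and is configurable. A CDR3 is
  positive if any residue with apex position in [−2, +2] is cysteine.
  Terminal residues are not masked; for very short CDR3s (length ≤ 5) the
  conserved position-1 cysteine can fall inside the window and is evaluated
  as-is.

Group comparisons use a two-sided Fisher exact test on the 2×2
with/without-cysteine table (clonotype-level, catalogue vs catalogue) and an
unpaired two-sided pooled-variance Student *t* test on per-sample doublet
proportions, both Bonferroni-corrected with an explicit family size supplied
by the caller. These tests are implemented in the package from their
textbook definitions and validated in the test suite against the
independent base-R implementations.

# Coverage-based diversity (Hill number q = 0)

Catalogue abundances (mice per clonotype) form the abundance vector
X₁…X_S with n = ΣXᵢ, singletons f₁ and doubletons f₂. *Sample coverage* is
the proportion of all clones — encountered and unencountered — belonging to
clonotypes already encountered. Interpolated richness is the exact expected
clonotype count of an m-clone subsample,

\[ \hat S(m) = S_{obs} - \sum_i \binom{n - X_i}{m} / \binom{n}{m}, \]

and extrapolation uses the Chao1-based form
\( \hat S(n+m^*) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n\hat f_0 + f_1))^{m^*}] \)
with \( \hat f_0 = \frac{n-1}{n} f_1^2/(2f_2) \), falling back to the
bias-corrected \( \frac{n-1}{n} f_1(f_1-1)/2 \) when f₂ = 0 (the standard
fallback; the ratio form is undefined there). Coverage uses the analogous
interpolated/extrapolated estimators. All binomial coefficients are computed
in log space, so n up to 10⁶ is safe.

Confidence intervals redraw n clones multinomially from the bootstrap
assemblage: observed clonotypes with adjusted probabilities plus
⌈f̂₀⌉ unseen clonotypes sharing the estimated coverage deficit 1 − Ĉ(n).
With the study default of B = 10 replicates quantile intervals are
meaningless, so CIs are normal-approximation (±1.96 × bootstrap SD); B is
configurable. Only q = 0 (richness) is implemented; other Hill orders are
rejected explicitly. Relative diversity inverts Ĉ(m) by monotone search
(linear interpolation between adjacent integer m, extrapolation capped at
2n by default) and reports the richness ratio with a paired-bootstrap CI;
a replicate that cannot reach the target coverage is evaluated at the range
end rather than dropped, keeping pairs intact.

**Known limitation.** The asymptote S_obs + f̂₀ is a *lower-bound*
estimator. Its 95% CI covers the true richness at roughly nominal rates
only for mildly skewed communities; as abundance skewness grows the
negative bias comes to dominate the bootstrap SD and CI coverage collapses.
The acceptance test verifies ≥ 80% coverage for standard-lognormal
(sdlog 1) communities of 500 clonotypes sampled at n = 5000 with B = 200;
a green test therefore establishes correct implementation of the
estimators, not their validity for heavily skewed repertoires.

# Overlap and segment usage

Morisita-Horn overlap between catalogues uses abundance = mice detected,
over the union of clonotype keys. Segment usage gives each clonotype weight
one; Trav-ambiguous records should be excluded upstream
(`paralog_policy = "exclude_ambiguous"`). The 8-parameter proximal/distal
feature vector — Trav proximal/distal frequencies plus Traj
proximal/medium/distal frequencies within each Trav stratum — is computed
over transcripts (records), with the zone map supplied as configuration:
which named segments are proximal or distal is locus annotation, not code.
A three-zone Traj map is used; the source phrase "distal, medium, and
distal" only yields eight parameters if read as proximal/medium/distal.

# TRA expression breadth

Cells are first downsampled to a fixed fragment count (default 200,000) by
a multivariate hypergeometric draw; cells below the target are excluded by
default because mixing sequencing depths biases detection. For each cell
number n in a grid, n cells are drawn *without replacement* ("randomly
sampled" is ambiguous; without replacement matches resampling a finite cell
pool and is stated here once), 100 times by default; a gene is *detectable*
in a draw if its summed count is ≥ 1 (threshold configurable; no canonical
definition exists). Per gene category the mean and SD of detectable genes
are reported, and two groups are compared at a grid point (default 130
cells) by two-sided Wilcoxon rank-sum on replicate values with
Benjamini-Hochberg correction across categories. The closed-form
expectation Σ_g [1 − C(N−k_g, n)/C(N, n)] is exposed as
`expected_detectable_genes()` and used as the test oracle.

# TSS metaprofiles

Tracks are bedGraph (0-based half-open; uncovered positions are signal 0,
the format's sparsity convention). For each gene the window
[−4000, +4000) around the TSS is cut into 160 strand-oriented 50-bp bins
(minus-strand windows reversed); the per-gene per-bin ratio is
(chip mean + pseudocount)/(input mean + pseudocount) and the profile is the
per-bin median over genes. The pseudocount (default 1.0) guards zero-input
bins; the per-gene window summary is the *mean of bin ratios* within the
window — a declared choice between mean and sum, made once. Gene sets are
compared by the ratio of median summaries and a Wilcoxon rank-sum test,
BH-corrected across the supplied family.

# Synthetic data: what it emulates, and what not

* **Repertoires.** Per-subset clonotype communities (a shared core plus
  subset-private clonotypes) with lognormal abundance (meanlog 0,
  sdlog 1.5 — TCR repertoires are heavy-tailed), sampled multinomially at
  1000 clones per mouse; 9 control mice (8 for CD4SP) and 14 mutant mice
  per subset; the mutant CD4SP/CD8SP communities are halved, restating the
  observed two-fold diversity reduction as a planted effect. Planted motif
  frequencies are exact by construction: π_doublet = 0.2 from a synthetic
  cysteine-free doublet list, π_cys = 0.1 placed in the apex window away
  from positions 6/7, so the two plants never interact. Read counts of true
  records are ≥ 3; injected error singletons (point-mutated copies, counts
  1–2, 5% of rows) and non-functional rows (stop-codon sentinel, 2%)
  exercise the filters. Not emulated: V(D)J recombination statistics,
  sequencing chemistry, UMI structure.
* **Cell matrices.** Genes express per cell as independent Bernoulli with
  per-category prevalence (AIRE-dependent 2%, AIRE-enhanced 5%,
  AIRE-independent TRA 10%, other 30%); per-population multipliers restate
  the observed breadth folds (0.86/0.96/0.98/0.99 and 0.84/0.94/0.97/0.99)
  as planted effects. Libraries (median 300,000 fragments) are distributed
  multinomially over expressed genes, each receiving at least one fragment,
  so detection equals expression exactly. Not emulated: dropout dependence
  on expression level, batch effects, gene-gene correlation.
* **ChIP tracks.** Input = constant background × per-step gamma noise;
  ChIP = background × rectangular fold profile (default 2.4, the
  TSS-proximal enrichment magnitude this generator emulates) around
  enriched TSSs, with noise independent of the input track — necessary so
  the fold-1 null yields uniform p-values rather than a degenerate
  identical-track comparison. Not emulated: fragment-length smoothing,
  mappability, peak shape.

All generators are pure functions of config + seed, with one RNG stream per
output unit derived by stable string hashing, and never disturb the
caller's RNG state.

# Numerical choices and degenerate inputs

Log-space binomial coefficients throughout; `lchoose` outside the support
is −∞ so impossible subsets contribute 0. f₁ = 0 yields coverage 1 and a
flat extrapolation at S_obs. Ties in the Wilcoxon tests use the normal
approximation; two identical groups short-circuit to p = 1. Bonferroni is
min(1, p·m) with m supplied explicitly. Empty Trav strata report NA
triples. TSS windows extending below position 0 skip the gene with a
warning; an empty remaining set is an error.
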