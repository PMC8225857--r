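# thymoselect

Quantitative tools for studying how the thymic epithelium shapes the T cell
receptor (TCR) α-chain repertoire and the breadth of promiscuous
tissue-restricted-antigen (TRA) expression — the repertoire-narrowing and
antigen-representation phenotypes seen when medullary thymic epithelial cell
(mTEC) development is perturbed (e.g. by loss of PRC2/H3K27me3 activity).

It is written for immunologists and computational biologists who have:

* **TCRα clonotype tables** (MIGEC-style TSVs: read count, CDR3 amino-acid
  sequence, Trav/Traj calls) from sorted thymocyte subsets of several mice;
* **sparse single-cell count matrices** (MatrixMarket + annotations) with
  AIRE-dependent / AIRE-enhanced / AIRE-independent-TRA gene categories;
* **ChIP and input signal tracks** (bedGraph) with TSS annotations (BED6).

## What it computes

**Clonotype catalogues.** Records are filtered to functional CDR3s with ≥ 3
reads per sample; a clonotype (unique Trav × CDR3aa pair) is counted once
per sample; pooling one subset × genotype across mice yields a *TCR
catalogue* with abundance = number of mice carrying the clonotype.

**CDR3 self-reactivity motifs.** Amino-acid doublets at CDR3 positions 6/7
(position 1 = conserved N-terminal cysteine) against a user-supplied
doublet list, and central cysteine within apex-out positions −2…+2; group
comparisons by two-sided Fisher exact and pooled-variance Student *t*
tests, Bonferroni-corrected.

**Coverage-based diversity (Hill q = 0).** Rarefaction of clonotype
richness by the exact hypergeometric form

    Ŝ(m) = S_obs − Σᵢ C(n−Xᵢ, m) / C(n, m)

and Chao1-based extrapolation Ŝ(n+m*) = S_obs + f̂₀[1 − (1 − f₁/(n f̂₀+f₁))^m*],
with sample coverage Ĉ(m), multinomial bootstrap confidence intervals
(default B = 10), and relative diversity of two catalogues at a common
coverage level.

**Overlap and usage.** Morisita-Horn index between catalogues
(abundance = mice), Trav/Traj usage, CDR3-length distributions, and the
8-parameter proximal/distal segment-usage feature vector.

**TRA breadth.** Per-cell downsampling to 200,000 fragments (multivariate
hypergeometric), then repeated resampling of increasing cell numbers
(100× per grid point); mean detectable genes per category, with two-sided
Wilcoxon + Benjamini-Hochberg comparisons at a fixed cell number (default
130).

**TSS metaprofiles.** Median ChIP/input ratio in 160 strand-oriented 50-bp
bins over ±4 kb of each TSS, and gene-set comparisons of the per-gene mean
window ratio.

**Synthetic data.** Generators for all three input families with planted,
recoverable parameters (true richness, motif frequencies π, sharing,
expression prevalences, enrichment folds), so the entire pipeline is
testable without downloads.

## Worked example

Simulate a small repertoire study (two subsets × two genotypes, with the
mutant CD4SP community halved), run the catalogue pipeline and measure
overlap and diversity:

```r
library(thymoselect)

cfg <- repertoire_sim_config(
  n_clonotypes_true = 1000L, depth = 800L,
  subsets = c("pre_selection", "CD4SP"),
  n_mice = list(control = c(pre_selection = 4L, CD4SP = 4L),
                mutant  = c(pre_selection = 4L, CD4SP = 4L)),
  seed = 42)
sim <- simulate_repertoire(cfg, out_dir = "sim/")

meta <- sim$metadata
rec  <- parse_clonotype_tables(file.path("sim", meta$file), meta)
rec  <- filter_records(rec)                       # functional, >= 3 reads
sets <- lapply(split(rec, by = "sample_id"), collapse_to_clonotypes)
groups <- split(sets, vapply(sets, function(s)
  paste(attr(s, "subset"), attr(s, "genotype"), sep = "_"), ""))
cats <- lapply(groups, build_catalogue)

cats$CD4SP_control
#> TCR catalogue: CD4SP / control, 589 clonotypes from 4 mice

round(overlap_matrix(cats), 3)
#>                       CD4SP_control CD4SP_mutant pre_selection_control pre_selection_mutant
#> CD4SP_control                 1.000        0.582                 0.430                0.425
#> CD4SP_mutant                  0.582        1.000                 0.615                0.608
#> pre_selection_control         0.430        0.615                 1.000                0.855
#> pre_selection_mutant          0.425        0.608                 0.855                1.000

rd <- relative_diversity(cats$CD4SP_mutant, cats$CD4SP_control,
                         coverage_level = 0.9, B = 10, seed = 7)
sprintf("mutant/control richness at coverage 0.9: %.3f [%.3f, %.3f]",
        rd$ratio, rd$ci_lo, rd$ci_hi)
#> "mutant/control richness at coverage 0.9: 0.573 [0.535, 0.610]"

doublet_proportion(cats$CD4SP_control, synthetic_doublet_list(),
                   min_clones = 100)$proportion
#> [1] 0.1969…   # planted pi_doublet = 0.2
```

The overlap matrix shows what the planted world contains: the same subset
overlaps across genotypes more than different subsets do, and the relative
diversity recovers the planted two-fold community reduction
(ratio ≈ 0.57, planted factor 0.5 — the deficit is partly masked because
both catalogues are evaluated at equal coverage). The doublet proportion
recovers the planted motif frequency.

A command-line launcher is installed with the package
(`exec/thymoselect`):

```sh
thymoselect simulate repertoire --config cfg.json --out sim/
thymoselect repertoire --tables sim/*.tsv --metadata sim/metadata.tsv \
    --min-reads 3 --paralog-policy first_listed --out catalogues/
thymoselect diversity --abundance ab.tsv --bootstrap 10 --seed 7 --out curve.tsv
thymoselect tss-profile --chip chip.bedGraph --input input.bedGraph \
    --tss tss.bed --out profile.tsv
```

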