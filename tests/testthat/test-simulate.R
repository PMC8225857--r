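small_rep_cfg <- function(...) {
  repertoire_sim_config(
    n_clonotypes_true = 200L, depth = 150L,
    subsets = c("pre_selection", "CD4SP"),
    n_mice = list(control = c(pre_selection = 3L, CD4SP = 3L),
                  mutant = c(pre_selection = 3L, CD4SP = 3L)),
    ...)
}

test_that("simulate_repertoire is deterministic and writes parseable files", {
  r1 <- simulate_repertoire(small_rep_cfg(seed = 9))
  r2 <- simulate_repertoire(small_rep_cfg(seed = 9))
  expect_equal(r1$tables, r2$tables)
  r3 <- simulate_repertoire(small_rep_cfg(seed = 10))
  expect_false(identical(r1$tables, r3$tables))

  dir <- withr::local_tempdir()
  simulate_repertoire(small_rep_cfg(seed = 9), out_dir = dir)
  meta <- data.table::fread(file.path(dir, "metadata.tsv"))
  rec <- parse_clonotype_tables(file.path(dir, meta$file), meta)
  expect_gt(nrow(rec), 0)
  expect_true(all(c("pre_selection", "CD4SP") %in% rec$subset))
  ## the injected errors and non-functional rows are removed by the filters
  kept <- filter_records(rec)
  expect_lt(nrow(kept), nrow(rec))
  expect_false(any(grepl("[*_]", kept$cdr3_aa)))
  expect_true(all(kept$read_count >= 3))
})

test_that("planting contracts: pi_doublet = 0 and pi_cys = 0 are exact", {
  r <- simulate_repertoire(small_rep_cfg(pi_doublet = 0, pi_cys = 0,
                                         seed = 4))
  cdr3 <- unique(unlist(lapply(r$tables, function(t)
    t$CDR3.amino.acid.sequence)))
  cdr3 <- cdr3[!grepl("[*_]", cdr3)]
  dl <- synthetic_doublet_list()
  d <- doublet_at_6_7(cdr3)
  ## point-mutation error rows can create a listed doublet by chance, but
  ## true rows never carry one; allow only the error fraction
  expect_lt(mean(!is.na(d) & d %in% dl), 0.02)
  expect_lt(mean(has_central_cysteine(cdr3)), 0.02)
})

test_that("full sharing gives near-unit Morisita-Horn between subsets", {
  cfg <- small_rep_cfg(sharing_fraction = 1, seed = 6,
                       mutant_diversity_factor = 1)
  r <- simulate_repertoire(cfg)
  rec_all <- data.table::rbindlist(lapply(names(r$tables), function(sid) {
    t <- r$tables[[sid]]
    meta <- r$metadata[r$metadata$sample_id == sid, ]
    make_records(t$CDR3.amino.acid.sequence,
                 count = t$Count,
                 trav = t$V.segments, traj = t$J.segments,
                 sample_id = sid, mouse_id = meta$mouse_id,
                 subset = meta$subset, genotype = meta$genotype)
  }))
  rec_all <- filter_records(rec_all)
  build_for <- function(ss) {
    samples <- lapply(split(rec_all[rec_all$subset == ss &
                                      rec_all$genotype == "control", ],
                            by = "sample_id"), collapse_to_clonotypes)
    build_catalogue(samples)
  }
  mh <- morisita_horn(build_for("pre_selection"), build_for("CD4SP"))
  expect_gt(mh, 0.8)
})

test_that("mutant mature-subset communities are scaled down", {
  r <- simulate_repertoire(small_rep_cfg(seed = 2))
  tr <- r$truth$communities
  expect_equal(tr$CD4SP_mutant$true_richness,
               round(tr$CD4SP_control$true_richness * 0.5))
  expect_equal(tr$pre_selection_mutant$true_richness,
               tr$pre_selection_control$true_richness)
})

test_that("simulate_cell_matrix plants detection prevalences", {
  cfg <- sc_sim_config(
    n_cells = c(control = 400L),
    genes_per_category = c(aire_dependent = 60L, aire_enhanced = 40L,
                           aire_independent_tra = 40L, other = 60L),
    library_size_law = list(meanlog = log(5000), sdlog = 0.1),
    seed = 8)
  s1 <- simulate_cell_matrix(cfg)
  s2 <- simulate_cell_matrix(cfg)
  expect_equal(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  ## per-gene detection frequency within 3 binomial SE of rho
  det <- Matrix::colSums(s1$matrix$counts > 0) / 400
  for (cc in names(cfg$prevalence)) {
    genes <- s1$matrix$gene_meta$category == cc &
      s1$matrix$gene_meta$gene != "Aire"
    rho <- cfg$prevalence[[cc]]
    se <- sqrt(rho * (1 - rho) / (400 * sum(genes)))
    expect_lt(abs(mean(det[genes]) - rho), 3 * se)
  }
  ## prevalence 1 -> every gene detectable in any single cell
  s3 <- simulate_cell_matrix(sc_sim_config(
    n_cells = c(control = 5L),
    genes_per_category = c(aire_dependent = 3L, aire_enhanced = 3L,
                           aire_independent_tra = 3L, other = 3L),
    prevalence = c(aire_dependent = 1, aire_enhanced = 1,
                   aire_independent_tra = 1, other = 1),
    library_size_law = list(meanlog = log(500), sdlog = 0.1),
    aire_prevalence = 1, seed = 3))
  expect_true(all(s3$matrix$counts > 0))
  ## files round-trip
  dir <- withr::local_tempdir()
  simulate_cell_matrix(cfg, out_dir = dir)
  back <- read_cell_matrix(file.path(dir, "matrix.mtx"),
                           file.path(dir, "genes.tsv"),
                           file.path(dir, "cells.tsv"))
  expect_equal(unname(as.matrix(back$counts)),
               unname(as.matrix(s1$matrix$counts)))
})

test_that("simulate_chip_tracks: determinism and planted fold recovery", {
  cfg <- chip_sim_config(chrom_length = 200000L, n_genes = 10L,
                         noise_cv = 0, fold = 3, seed = 12)
  s1 <- simulate_chip_tracks(cfg)
  s2 <- simulate_chip_tracks(cfg)
  expect_equal(as.data.frame(s1$chip), as.data.frame(s2$chip))
  ## noise 0: enriched TSS bins recover fold exactly, background 1.0
  prof <- ratio_metaprofile(s1$chip, s1$input, s1$tss, pseudocount = 0)
  centre <- prof$ratios[, 80]   # bin covering the TSS
  expect_true(all(abs(centre[s1$truth$enriched_genes] - 3) < 1e-9))
  expect_true(all(abs(centre[s1$truth$background_genes] - 1) < 1e-9))
  expect_error(chip_sim_config(chrom_length = 10000L, n_genes = 10L),
               "too short")
})
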