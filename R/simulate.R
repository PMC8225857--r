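## Synthetic-data generators.  Every input family of the pipeline can be
## generated with known, planted parameters (true richness, motif
## frequencies, sharing, expression prevalences, enrichment folds) recorded
## in a truth object, so all downstream stages are testable without external
## downloads.  All generators are pure functions of config + seed: one RNG
## stream per output unit, derived from the master seed by stable hashing.

AA19_NO_C <- setdiff(AA20, "C")

#' Deterministic synthetic self-reactivity doublet list
#'
#' A stand-in for the published list of 175 self-reactivity-promoting CDR3
#' doublets, which is not redistributable here.  The synthetic list is a
#' fixed pseudorandom subset of the cysteine-free doublets (cysteine is
#' excluded so that planted doublet and central-cysteine frequencies stay
#' independent in the generator).
#'
#' @param n list size (default 175, the size of the published list).
#' @return a `doublet_list` of length `n`.
#' @export
synthetic_doublet_list <- function(n = 175L) {
  all2 <- as.vector(outer(AA19_NO_C, AA19_NO_C, paste0))
  if (n > length(all2)) stopf("at most %d cysteine-free doublets exist",
                              length(all2))
  picked <- with_seed(104729L, sample(all2, n))
  as_doublet_list(picked)
}

#' Configuration for the TCR repertoire generator
#'
#' Defaults state the world the generator emulates: four T-cell subsets
#' profiled in control (9 mice; 8 for CD4SP) and mutant (14 mice) animals,
#' a lognormal clonotype abundance law, planted position-6/7 doublet
#' frequency 0.2 and central-cysteine frequency 0.1, and a two-fold smaller
#' clonotype community for the mutant mature (CD4SP/CD8SP) subsets.
#'
#' @param n_clonotypes_true clonotype community size per subset (default 5000).
#' @param abundance_law list: `meanlog`, `sdlog` of the lognormal clonotype
#'   abundance distribution.
#' @param subsets subset names.
#' @param n_mice named list `control`, `mutant` of per-subset mouse counts.
#' @param depth clones sampled per mouse (default 1000).
#' @param sharing_fraction fraction of each subset community shared across
#'   all subsets (default 0.5).
#' @param mutant_diversity_factor community-size multiplier for mutant
#'   CD4SP/CD8SP (default 0.5: two-fold lower diversity).
#' @param trav_pool,traj_pool segment name vectors (first half / thirds are
#'   proximal, remainder distal, with `medium` in between for Traj).
#' @param usage_gradient geometric decay of segment usage along the pool.
#' @param cdr3_lengths,cdr3_length_probs CDR3 amino-acid length law.
#' @param pi_doublet planted probability that a clonotype carries a listed
#'   doublet at positions 6/7 (default 0.2).
#' @param pi_cys planted probability of a central cysteine (apex window
#'   -2..+2; default 0.1).
#' @param doublets doublet list used for planting.
#' @param read_mu negative-binomial read-count mean increment per clone
#'   detected (read counts of true records are >= 3 by construction).
#' @param error_rate fraction of extra singleton-error rows (point-mutated
#'   CDR3 copies with read count 1-2) injected per sample (default 0.05).
#' @param nonfunctional_rate fraction of extra non-functional rows (stop
#'   codon sentinel, read count >= 3) per sample (default 0.02).
#' @param ambiguous_rate probability that a record lists two Trav paralogs
#'   (default 0.05).
#' @param seed master seed.
#' @return config list of class `repertoire_sim_config`.
#' @export
repertoire_sim_config <- function(
    n_clonotypes_true = 5000L,
    abundance_law = list(meanlog = 0, sdlog = 1.5),
    subsets = c("pre_selection", "wave1", "CD4SP", "CD8SP"),
    n_mice = list(
      control = c(pre_selection = 9L, wave1 = 9L, CD4SP = 8L, CD8SP = 9L),
      mutant = c(pre_selection = 14L, wave1 = 14L, CD4SP = 14L, CD8SP = 14L)),
    depth = 1000L,
    sharing_fraction = 0.5,
    mutant_diversity_factor = 0.5,
    trav_pool = sprintf("TRAV%d", 1:20),
    traj_pool = sprintf("TRAJ%d", 1:30),
    usage_gradient = 0.1,
    cdr3_lengths = 9:17,
    cdr3_length_probs = c(2, 5, 10, 18, 25, 18, 12, 7, 3) / 100,
    pi_doublet = 0.2,
    pi_cys = 0.1,
    doublets = synthetic_doublet_list(),
    read_mu = 20,
    error_rate = 0.05,
    nonfunctional_rate = 0.02,
    ambiguous_rate = 0.05,
    seed = 1L) {
  stopifnot(pi_doublet >= 0, pi_doublet <= 1, pi_cys >= 0, pi_cys <= 1,
            sharing_fraction >= 0, sharing_fraction <= 1,
            depth >= 1, n_clonotypes_true >= 1,
            abs(sum(cdr3_length_probs) - 1) < 1e-8,
            min(cdr3_lengths) >= 9)
  structure(as.list(environment()), class = "repertoire_sim_config")
}

## Generate n CDR3 sequences with exactly-planted motif frequencies.
## Positions: 1 = conserved N-terminal C, last = F; interior residues avoid
## cysteine except where planted.  Doublets (positions 6/7) are planted with
## probability pi_doublet from the supplied cysteine-free list; otherwise
## positions 6/7 are guaranteed not to form a listed doublet.  A central
## cysteine (apex window -2..+2) is planted with probability pi_cys at a
## window position away from 6/7.
generate_cdr3 <- function(n, cfg) {
  lens <- sample(cfg$cdr3_lengths, n, replace = TRUE,
                 prob = cfg$cdr3_length_probs)
  plant_d <- runif(n) < cfg$pi_doublet
  plant_c <- runif(n) < cfg$pi_cys
  dl <- as.character(cfg$doublets)
  out <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    ch <- c("C", sample(AA19_NO_C, L - 2, replace = TRUE), "F")
    if (plant_d[i]) {
      ch[6:7] <- strsplit(sample(dl, 1), "")[[1]]
    } else {
      while (paste0(ch[6], ch[7]) %in% dl) {
        ch[6:7] <- sample(AA19_NO_C, 2, replace = TRUE)
      }
    }
    if (plant_c[i]) {
      pos <- apex_positions(L)
      win <- which(pos >= -2 & pos <= 2)
      win <- setdiff(win, c(1L, 6L, 7L, L))
      ch[sample(win, 1)] <- "C"
    }
    out[i] <- paste(ch, collapse = "")
  }
  out
}

#' Simulate per-sample TCR clonotype tables
#'
#' Builds per-subset clonotype communities (a shared core plus
#' subset-private clonotypes), assigns each clonotype a Trav/Traj call and a
#' CDR3 with exactly-planted motif frequencies, then samples each mouse's
#' clones multinomially from its community.  Detected clonotypes receive
#' read counts of at least 3; singleton sequencing errors (point-mutated
#' CDR3 copies, read count 1-2) and non-functional rows (stop-codon
#' sentinel) are injected so the upstream filters have measurable effect.
#'
#' @param config a [repertoire_sim_config()].
#' @param out_dir optional directory; when given, per-sample TSVs,
#'   `metadata.tsv` and `truth.json` are written there.
#' @return list with `tables` (named list of per-sample data.tables in the
#'   MIGEC-style dialect), `metadata` (data.table `file`, `sample_id`,
#'   `mouse_id`, `subset`, `genotype`) and `truth` (planted parameters:
#'   per-community true richness, shared-core size, `pi_doublet`, `pi_cys`).
#' @export
simulate_repertoire <- function(config = repertoire_sim_config(),
                                out_dir = NULL) {
  cfg <- config
  N <- cfg$n_clonotypes_true
  n_shared <- round(cfg$sharing_fraction * N)
  n_private <- N - n_shared
  n_universe <- n_shared + n_private * length(cfg$subsets)
  if (cfg$depth > 10 * N)
    stopf("depth %d is infeasible for a community of %d clonotypes",
          cfg$depth, N)

  universe <- with_seed(child_seed(cfg$seed, "community"), {
    cdr3 <- generate_cdr3(n_universe, cfg)
    while (anyDuplicated(cdr3)) {         # clonotype keys must be unique
      dup <- which(duplicated(cdr3))
      cdr3[dup] <- generate_cdr3(length(dup), cfg)
    }
    k_trav <- length(cfg$trav_pool)
    k_traj <- length(cfg$traj_pool)
    w_trav <- exp(-cfg$usage_gradient * seq_len(k_trav))
    w_traj <- exp(-cfg$usage_gradient * seq_len(k_traj))
    data.table(
      clonotype_id = seq_len(n_universe),
      cdr3_aa = cdr3,
      trav = sample(cfg$trav_pool, n_universe, TRUE, prob = w_trav),
      traj = sample(cfg$traj_pool, n_universe, TRUE, prob = w_traj),
      lambda = rlnorm(n_universe, cfg$abundance_law$meanlog,
                      cfg$abundance_law$sdlog))
  })

  community_ids <- function(subset_idx, genotype, subset) {
    ids <- c(seq_len(n_shared),
             n_shared + (subset_idx - 1L) * n_private + seq_len(n_private))
    if (genotype == "mutant" && subset %in% c("CD4SP", "CD8SP")) {
      ids <- ids[seq_len(round(length(ids) * cfg$mutant_diversity_factor))]
    }
    ids
  }

  tables <- list(); meta <- list(); truth_comms <- list()
  for (gt in names(cfg$n_mice)) {
    for (si in seq_along(cfg$subsets)) {
      ss <- cfg$subsets[si]
      ids <- community_ids(si, gt, ss)
      comm <- universe[ids, ]
      probs <- comm$lambda / sum(comm$lambda)
      nm <- cfg$n_mice[[gt]][[ss]]
      truth_comms[[paste(ss, gt, sep = "_")]] <-
        list(subset = ss, genotype = gt, true_richness = nrow(comm),
             n_mice = nm, shared_core = n_shared)
      for (mi in seq_len(nm)) {
        sid <- sprintf("%s_%s_m%02d", ss, gt, mi)
        tab <- with_seed(child_seed(cfg$seed, sid), {
          cnt <- as.vector(rmultinom(1L, cfg$depth, probs))
          det <- which(cnt > 0)
          reads <- 3L + rnbinom(length(det),
                                mu = cfg$read_mu * cnt[det], size = 2)
          trav_str <- comm$trav[det]
          amb <- runif(length(det)) < cfg$ambiguous_rate
          if (any(amb)) {
            alt <- sample(cfg$trav_pool, sum(amb), TRUE)
            trav_str[amb] <- paste(trav_str[amb], alt, sep = ",")
          }
          rows <- data.table(
            Count = reads,
            CDR3.amino.acid.sequence = comm$cdr3_aa[det],
            V.segments = trav_str,
            J.segments = comm$traj[det])
          ## singleton sequencing errors: point-mutated copies, count 1-2
          n_err <- round(cfg$error_rate * nrow(rows))
          if (n_err > 0) {
            src <- sample(nrow(rows), n_err, replace = TRUE)
            mut <- vapply(rows$CDR3.amino.acid.sequence[src], function(s) {
              p <- sample(2:(nchar(s) - 1L), 1)
              substr(s, p, p) <- sample(AA19_NO_C, 1)
              s
            }, character(1), USE.NAMES = FALSE)
            rows <- rbind(rows, data.table(
              Count = sample(1:2, n_err, TRUE),
              CDR3.amino.acid.sequence = mut,
              V.segments = rows$V.segments[src],
              J.segments = rows$J.segments[src]))
          }
          ## non-functional rows: stop-codon sentinel, count >= 3
          n_nf <- round(cfg$nonfunctional_rate * nrow(rows))
          if (n_nf > 0) {
            src <- sample(nrow(rows), n_nf, replace = TRUE)
            nf <- paste0(substr(rows$CDR3.amino.acid.sequence[src], 1, 4),
                         "*",
                         substr(rows$CDR3.amino.acid.sequence[src], 6,
                                nchar(rows$CDR3.amino.acid.sequence[src])))
            rows <- rbind(rows, data.table(
              Count = 3L + rpois(n_nf, 5),
              CDR3.amino.acid.sequence = nf,
              V.segments = rows$V.segments[src],
              J.segments = rows$J.segments[src]))
          }
          rows[sample(nrow(rows)), ]
        })
        tables[[sid]] <- tab
        meta[[sid]] <- data.table(file = paste0(sid, ".tsv"),
                                  sample_id = sid,
                                  mouse_id = sprintf("%s_m%02d", gt, mi),
                                  subset = ss, genotype = gt)
      }
    }
  }
  metadata <- rbindlist(meta)
  truth <- list(pi_doublet = cfg$pi_doublet, pi_cys = cfg$pi_cys,
                sharing_fraction = cfg$sharing_fraction,
                depth = cfg$depth,
                mutant_diversity_factor = cfg$mutant_diversity_factor,
                communities = truth_comms,
                trav_zone = setNames(
                  rep(c("proximal", "distal"),
                      c(ceiling(length(cfg$trav_pool) / 2),
                        floor(length(cfg$trav_pool) / 2))), cfg$trav_pool),
                traj_zone = setNames(
                  rep(c("proximal", "medium", "distal"),
                      diff(round(seq(0, length(cfg$traj_pool), length.out = 4)))),
                  cfg$traj_pool))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(tables))
      fwrite(tables[[sid]], file.path(out_dir, paste0(sid, ".tsv")),
             sep = "\t")
    fwrite(metadata, file.path(out_dir, "metadata.tsv"), sep = "\t")
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tables = tables, metadata = metadata, truth = truth)
}

#' Configuration for the single-cell count matrix generator
#'
#' Defaults emulate mature mTEC populations profiled at single-cell
#' resolution: a control population and two reporter-defined populations
#' whose tissue-restricted-antigen expression breadth is reduced by the
#' stated per-category factors (strongest for AIRE-dependent genes).
#'
#' @param n_cells named vector of cells per population.
#' @param genes_per_category named vector of gene counts per category.
#' @param prevalence named vector: baseline fraction of cells expressing
#'   each gene of a category (AIRE-dependent TRAs are rare, ~2% of cells;
#'   housekeeping-like genes common, ~30%).
#' @param breadth_factor named list of per-category prevalence multipliers
#'   per population (defaults restate the observed fold reductions 0.86/
#'   0.96/0.98/0.99 and 0.84/0.94/0.97/0.99 as planted effects).
#' @param library_size_law lognormal `meanlog`, `sdlog` of per-cell total
#'   fragments (default median 300000, so cells exceed the 200000-fragment
#'   downsampling target).
#' @param aire_prevalence fraction of cells expressing Aire (default 0.6).
#' @param seed master seed.
#' @return config list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(
    n_cells = c(control = 300L, reporter_positive = 300L,
                reporter_negative = 300L),
    genes_per_category = c(aire_dependent = 300L, aire_enhanced = 200L,
                           aire_independent_tra = 200L, other = 800L),
    prevalence = c(aire_dependent = 0.02, aire_enhanced = 0.05,
                   aire_independent_tra = 0.10, other = 0.30),
    breadth_factor = list(
      control = c(aire_dependent = 1, aire_enhanced = 1,
                  aire_independent_tra = 1, other = 1),
      reporter_positive = c(aire_dependent = 0.86, aire_enhanced = 0.96,
                            aire_independent_tra = 0.98, other = 0.99),
      reporter_negative = c(aire_dependent = 0.84, aire_enhanced = 0.94,
                            aire_independent_tra = 0.97, other = 0.99)),
    library_size_law = list(meanlog = log(3e5), sdlog = 0.2),
    aire_prevalence = 0.6,
    seed = 1L) {
  stopifnot(all(prevalence > 0), all(prevalence <= 1),
            all(genes_per_category >= 1),
            aire_prevalence >= 0, aire_prevalence <= 1)
  structure(as.list(environment()), class = "sc_sim_config")
}

#' Simulate a sparse cell x gene count matrix
#'
#' Per gene g with (population-adjusted) prevalence rho_g, each cell
#' expresses g independently with probability rho_g; the cell's library is
#' then distributed multinomially over its expressed genes (each expressed
#' gene receiving at least one fragment), so totals equal the drawn library
#' size exactly.  The `Aire` gene (category `other`) is appended and drives
#' `aire_count` in the cell annotation.
#'
#' @param config an [sc_sim_config()].
#' @param out_dir optional directory for `matrix.mtx`, `genes.tsv`,
#'   `cells.tsv` and `truth.json`.
#' @return list with `matrix` (a [cell_count_matrix()]) and `truth`
#'   (planted prevalences per category and population).
#' @export
simulate_cell_matrix <- function(config = sc_sim_config(), out_dir = NULL) {
  cfg <- config
  gene_meta <- data.table(
    gene = unlist(lapply(names(cfg$genes_per_category), function(cc)
      sprintf("%s_g%03d", cc, seq_len(cfg$genes_per_category[[cc]])))),
    category = rep(names(cfg$genes_per_category), cfg$genes_per_category))
  gene_meta <- rbind(gene_meta, data.table(gene = "Aire", category = "other"))
  G <- nrow(gene_meta)
  gene_w <- with_seed(child_seed(cfg$seed, "gene_weights"),
                      rlnorm(G, 0, 1))

  mats <- list(); cells <- list()
  for (pop in names(cfg$n_cells)) {
    nc <- cfg$n_cells[[pop]]
    fac <- cfg$breadth_factor[[pop]]
    rho <- cfg$prevalence[gene_meta$category] * fac[gene_meta$category]
    rho[gene_meta$gene == "Aire"] <- cfg$aire_prevalence
    m <- with_seed(child_seed(cfg$seed, paste0("cells_", pop)), {
      libs <- round(rlnorm(nc, cfg$library_size_law$meanlog,
                           cfg$library_size_law$sdlog))
      rows <- matrix(0, nc, G)
      for (i in seq_len(nc)) {
        expr <- which(runif(G) < rho)
        if (length(expr) == 0L) expr <- sample.int(G, 1)
        extra <- max(0L, libs[i] - length(expr))
        cnt <- 1L + as.vector(rmultinom(1L, extra,
                                        gene_w[expr] / sum(gene_w[expr])))
        rows[i, expr] <- cnt
      }
      rows
    })
    rownames(m) <- sprintf("%s_c%04d", pop, seq_len(nc))
    mats[[pop]] <- m
    cells[[pop]] <- data.table(cell = rownames(m), population = pop,
                               aire_count = m[, G])
  }
  counts <- do.call(rbind, mats)
  cell_meta <- rbindlist(cells)
  ccm <- cell_count_matrix(Matrix::Matrix(counts, sparse = TRUE),
                           gene_meta, cell_meta)
  truth <- list(prevalence = as.list(cfg$prevalence),
                breadth_factor = cfg$breadth_factor,
                aire_prevalence = cfg$aire_prevalence,
                n_cells = as.list(cfg$n_cells))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(ccm$counts, file.path(out_dir, "matrix.mtx"))
    fwrite(gene_meta, file.path(out_dir, "genes.tsv"), sep = "\t")
    fwrite(cell_meta, file.path(out_dir, "cells.tsv"), sep = "\t")
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(matrix = ccm, truth = truth)
}

#' Configuration for the ChIP/input track generator
#'
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of TSSs (evenly spaced, alternating strand, with a
#'   full window margin at both chromosome ends).
#' @param enriched_fraction fraction of genes with ChIP enrichment around
#'   the TSS (default 0.5).
#' @param background baseline signal level of the input track.
#' @param fold ChIP/input enrichment fold within the profile (default 2.4,
#'   the magnitude of TSS-proximal H3K27me3 enrichment this generator
#'   emulates).
#' @param profile_halfwidth half width in bp of the rectangular enrichment
#'   profile around the TSS (default 2000).
#' @param noise_cv coefficient of variation of multiplicative gamma noise
#'   per step, independent between the ChIP and input tracks (default 0.2;
#'   0 disables noise).
#' @param step bedGraph step size in bp (default 50).
#' @param half_window metaprofile window the TSS placement must accommodate
#'   (default 4000).
#' @param seed master seed.
#' @return config list of class `chip_sim_config`.
#' @export
chip_sim_config <- function(chrom_length = 400000L, n_genes = 40L,
                            enriched_fraction = 0.5, background = 1.0,
                            fold = 2.4, profile_halfwidth = 2000L,
                            noise_cv = 0.2, step = 50L,
                            half_window = 4000L, seed = 1L) {
  stopifnot(fold > 0, background > 0, noise_cv >= 0,
            chrom_length > 2 * half_window)
  if (chrom_length < n_genes * 2 * half_window)
    stopf("chromosome too short for %d genes with +/-%d bp windows",
          n_genes, half_window)
  structure(as.list(environment()), class = "chip_sim_config")
}

#' Simulate ChIP and input signal tracks plus TSS annotations
#'
#' The input track is `background` with multiplicative gamma noise per step;
#' the ChIP track is `background * fold` within `profile_halfwidth` of
#' enriched TSSs (and `background` elsewhere), with independent noise, so
#' under `fold = 1` enriched and background genes are statistically
#' indistinguishable.
#'
#' @param config a [chip_sim_config()].
#' @param out_dir optional directory for `chip.bedGraph`, `input.bedGraph`,
#'   `tss.bed` and `truth.json`.
#' @return list with `chip`, `input` ([signal_track()]s), `tss`
#'   (data.table `gene`, `chrom`, `tss`, `strand`), `truth` (enriched gene
#'   ids and per-gene expected fold).
#' @export
simulate_chip_tracks <- function(config = chip_sim_config(),
                                 out_dir = NULL) {
  cfg <- config
  chrom <- "chrS"
  nb <- cfg$chrom_length %/% cfg$step
  starts <- (seq_len(nb) - 1L) * cfg$step
  mids <- starts + cfg$step / 2

  margin <- cfg$half_window + cfg$step
  span <- cfg$chrom_length - 2L * margin
  tss_pos <- round(margin + span * (seq_len(cfg$n_genes) - 0.5) / cfg$n_genes)
  strands <- rep(c("+", "-"), length.out = cfg$n_genes)
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  n_enr <- round(cfg$enriched_fraction * cfg$n_genes)
  enriched <- with_seed(child_seed(cfg$seed, "enriched_set"),
                        sort(sample(cfg$n_genes, n_enr)))

  fold_at <- rep(1, nb)
  for (g in enriched) {
    sel <- abs(mids - (tss_pos[g] + 0.5)) <= cfg$profile_halfwidth
    fold_at[sel] <- cfg$fold
  }
  noise <- function(role) {
    if (cfg$noise_cv == 0) return(rep(1, nb))
    shape <- 1 / cfg$noise_cv^2
    with_seed(child_seed(cfg$seed, role), rgamma(nb, shape, rate = shape))
  }
  input_val <- cfg$background * noise("input_noise")
  chip_val <- cfg$background * fold_at * noise("chip_noise")

  input_tr <- signal_track(data.table(chrom = chrom, start = starts,
                                      end = starts + cfg$step,
                                      value = input_val))
  chip_tr <- signal_track(data.table(chrom = chrom, start = starts,
                                     end = starts + cfg$step,
                                     value = chip_val))
  tss <- data.table(gene = genes, chrom = chrom, tss = as.integer(tss_pos),
                    strand = strands)
  truth <- list(enriched_genes = genes[enriched],
                background_genes = genes[-enriched],
                fold = cfg$fold,
                profile_halfwidth = cfg$profile_halfwidth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fwrite(as.data.table(chip_tr), file.path(out_dir, "chip.bedGraph"),
           sep = "\t", col.names = FALSE)
    fwrite(as.data.table(input_tr), file.path(out_dir, "input.bedGraph"),
           sep = "\t", col.names = FALSE)
    bed <- data.table(chrom = chrom,
                      start = ifelse(strands == "+", tss_pos, tss_pos),
                      end = tss_pos + 1L, name = genes, score = 0L,
                      strand = strands)
    fwrite(bed, file.path(out_dir, "tss.bed"), sep = "\t",
           col.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(chip = chip_tr, input = input_tr, tss = tss, truth = truth)
}
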