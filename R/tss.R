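## H3K27me3 ChIP/input metaprofiles in fixed-width bins around transcription
## start sites, and gene-set signal comparisons within the TSS window.
##
## Coordinates are 0-based half-open throughout (BED/bedGraph convention);
## uncovered bedGraph positions count as signal 0, not missing.

#' Construct a signal track
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `value`
#'   (bedGraph semantics: half-open `[start, end)` intervals).
#' @return a `signal_track` data.table, sorted, with non-overlap validated.
#' @export
signal_track <- function(df) {
  tr <- as.data.table(df)[, c("chrom", "start", "end", "value"), with = FALSE]
  if (any(tr$start >= tr$end)) stopf("intervals must satisfy start < end")
  if (any(tr$start < 0)) stopf("negative coordinates")
  setorder(tr, chrom, start)
  ov <- tr[, any(head(end, -1) > tail(start, -1)), by = "chrom"]$V1
  if (any(ov)) stopf("overlapping intervals in signal track")
  structure(tr, class = c("signal_track", class(tr)))
}

#' Read a bedGraph file
#' @param path bedGraph file (no header; track lines ignored).
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  tr <- fread(text = lines, sep = "\t", header = FALSE,
              col.names = c("chrom", "start", "end", "value"))
  signal_track(tr)
}

#' Read TSS annotations from a BED6 file
#'
#' The TSS of a plus-strand feature is its `start`; of a minus-strand
#' feature, `end - 1`.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.table with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
read_bed6_tss <- function(path) {
  bed <- fread(path, sep = "\t", header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score",
                             "strand"))
  if (!all(bed$strand %in% c("+", "-"))) stopf("invalid strand in BED6 file")
  data.table(gene = bed$name, chrom = bed$chrom,
             tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
             strand = bed$strand)
}

## Cumulative-integral lookup for one chromosome of a track: returns a
## function mapping positions to the integral of the signal over [0, pos).
track_cumfun <- function(tr_chr) {
  s <- tr_chr$start; e <- tr_chr$end; v <- tr_chr$value
  cum_end <- cumsum(v * (e - s))
  function(pos) {
    i <- findInterval(pos, s)
    out <- numeric(length(pos))
    hit <- i >= 1L
    ii <- i[hit]
    out[hit] <- cum_end[ii] - v[ii] * pmax(0, e[ii] - pos[hit])
    out
  }
}

## Per-gene bin means over the window [tss - hw, tss + hw), strand-oriented
## (bins ordered 5' -> 3'; minus-strand windows reversed).
gene_bin_means <- function(cumfuns, tss_row, hw, bin) {
  nb <- 2L * hw %/% bin
  cf <- cumfuns[[tss_row$chrom]]
  edges <- tss_row$tss - hw + bin * (0:nb)
  if (is.null(cf)) {
    means <- numeric(nb)        # chromosome absent from track -> signal 0
  } else {
    ci <- cf(edges)
    means <- diff(ci) / bin
  }
  if (tss_row$strand == "-") means <- rev(means)
  means
}

#' ChIP/input ratio metaprofile around TSSs
#'
#' For each gene, the mean ChIP and mean input signal are computed per
#' strand-oriented bin over `[-half_window, +half_window)`; the per-gene
#' per-bin ratio is `(chip_mean + pseudocount) / (input_mean + pseudocount)`
#' and the profile value of a bin is the median of that ratio across genes.
#' Genes whose window extends below position 0 are skipped with a warning.
#'
#' @param chip,input [signal_track()] objects.
#' @param tss_set data.table of TSS annotations (see [read_bed6_tss()]).
#' @param half_window window half width in bp (default 4000).
#' @param bin bin width in bp (default 50); must divide `half_window`.
#' @param pseudocount added to both means before the ratio (default 1.0).
#' @return a `meta_profile`: list with `bins` (data.table `bin_start`
#'   offset, `median_ratio`, `n_genes`), `per_gene` (data.table `gene`,
#'   `mean_ratio` over all bins) and `ratios` (genes x bins matrix).
#' @export
ratio_metaprofile <- function(chip, input, tss_set, half_window = 4000L,
                              bin = 50L, pseudocount = 1.0) {
  if (half_window %% bin != 0L)
    stopf("half_window (%d) must be divisible by bin (%d)", half_window, bin)
  tss_set <- as.data.table(tss_set)
  if (nrow(tss_set) == 0L) stopf("empty TSS set")
  ok <- tss_set$tss - half_window >= 0L
  if (!all(ok)) {
    warnf("skipping %d gene(s) whose window extends below position 0",
          sum(!ok))
    tss_set <- tss_set[ok, ]
    if (nrow(tss_set) == 0L) stopf("no gene with a complete window remains")
  }
  nb <- 2L * half_window %/% bin
  cf_chip <- lapply(split(as.data.table(chip), by = "chrom"), track_cumfun)
  cf_input <- lapply(split(as.data.table(input), by = "chrom"), track_cumfun)
  ratios <- matrix(NA_real_, nrow(tss_set), nb,
                   dimnames = list(tss_set$gene, NULL))
  for (g in seq_len(nrow(tss_set))) {
    row <- tss_set[g, ]
    cm <- gene_bin_means(cf_chip, row, half_window, bin)
    im <- gene_bin_means(cf_input, row, half_window, bin)
    ratios[g, ] <- (cm + pseudocount) / (im + pseudocount)
  }
  bins <- data.table(bin_start = seq(-half_window, half_window - bin, by = bin),
                     median_ratio = apply(ratios, 2, median),
                     n_genes = nrow(tss_set))
  per_gene <- data.table(gene = tss_set$gene, strand = tss_set$strand,
                         mean_ratio = rowMeans(ratios))
  structure(list(bins = bins, per_gene = per_gene, ratios = ratios),
            half_window = half_window, bin = bin, pseudocount = pseudocount,
            class = "meta_profile")
}

#' Compare ChIP/input TSS signal between two gene sets
#'
#' The per-gene statistic is the mean bin ratio within the profiled window
#' (i.e. within +/- half_window of the TSS).  Returns the ratio of medians
#' `median(A) / median(B)` and the two-sided Wilcoxon rank-sum p-value.
#' Use [geneset_signal_table()] to Benjamini-Hochberg-correct a family of
#' such comparisons.
#'
#' @param profile a `meta_profile` from [ratio_metaprofile()].
#' @param genesetA,genesetB character vectors of profiled gene ids.
#' @return list with `fold`, `p_value`, `n_A`, `n_B`.
#' @export
geneset_signal_compare <- function(profile, genesetA, genesetB) {
  pg <- profile$per_gene
  a <- pg$mean_ratio[pg$gene %in% genesetA]
  b <- pg$mean_ratio[pg$gene %in% genesetB]
  if (length(a) == 0L || length(b) == 0L)
    stopf("gene sets must be non-empty subsets of the profiled genes")
  identical_sets <- length(a) == length(b) &&
    isTRUE(all.equal(sort(a), sort(b)))
  p <- if (identical_sets) 1.0 else
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  list(fold = median(a) / median(b), p_value = p,
       n_A = length(a), n_B = length(b))
}

#' Family of gene-set comparisons with BH correction
#'
#' @param profile a `meta_profile`.
#' @param comparisons named list; each element a list with `A` and `B` gene
#'   id vectors.
#' @return data.table with columns `comparison`, `fold`, `p_value`, `p_bh`.
#' @export
geneset_signal_table <- function(profile, comparisons) {
  res <- rbindlist(lapply(names(comparisons), function(nm) {
    cmp <- geneset_signal_compare(profile, comparisons[[nm]]$A,
                                  comparisons[[nm]]$B)
    data.table(comparison = nm, fold = cmp$fold, p_value = cmp$p_value)
  }))
  res[, "p_bh" := bh_adjust(res$p_value)]
  res[]
}
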