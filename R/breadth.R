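## Breadth of promiscuous (tissue-restricted antigen) gene expression from
## sparse single-cell count matrices: per-cell fragment downsampling,
## repeated resampling of increasing cell numbers, mean detectable-gene
## counts per gene category and between-group tests.

GENE_CATEGORIES <- c("aire_dependent", "aire_enhanced",
                     "aire_independent_tra", "other")

#' Construct a cell count matrix container
#'
#' @param counts cells x genes matrix of non-negative integer counts (dense
#'   or `Matrix` sparse); rownames = cells, colnames = genes.
#' @param gene_meta data.frame with columns `gene`, `category`.
#' @param cell_meta data.frame with columns `cell`, `population` and
#'   optionally `aire_count`.
#' @return a `cell_count_matrix` list.
#' @export
cell_count_matrix <- function(counts, gene_meta, cell_meta) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  gene_meta <- as.data.table(gene_meta)
  cell_meta <- as.data.table(cell_meta)
  if (ncol(counts) != nrow(gene_meta))
    stopf("gene_meta rows (%d) do not match matrix columns (%d)",
          nrow(gene_meta), ncol(counts))
  if (nrow(counts) != nrow(cell_meta))
    stopf("cell_meta rows (%d) do not match matrix rows (%d)",
          nrow(cell_meta), nrow(counts))
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (!all(gene_meta$category %in% GENE_CATEGORIES))
    stopf("gene categories must be one of: %s",
          paste(GENE_CATEGORIES, collapse = ", "))
  rownames(counts) <- cell_meta$cell
  colnames(counts) <- gene_meta$gene
  structure(list(counts = counts, gene_meta = gene_meta,
                 cell_meta = cell_meta),
            class = "cell_count_matrix")
}

#' @export
print.cell_count_matrix <- function(x, ...) {
  cat(sprintf("cell count matrix: %d cells x %d genes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$gene_meta$category)),
                            table(x$gene_meta$category)), collapse = ", ")))
  invisible(x)
}

#' Read a cell count matrix from MatrixMarket + annotation TSVs
#'
#' @param mtx_path MatrixMarket file (cells x genes).
#' @param genes_path TSV with columns `gene`, `category`.
#' @param cells_path TSV with columns `cell`, `population` and optionally
#'   `aire_count`.
#' @return a [cell_count_matrix()].
#' @export
read_cell_matrix <- function(mtx_path, genes_path, cells_path) {
  m <- Matrix::readMM(mtx_path)
  cell_count_matrix(m, fread(genes_path, sep = "\t"),
                    fread(cells_path, sep = "\t"))
}

#' Downsample one cell's fragment counts to a fixed depth
#'
#' Multivariate-hypergeometric draw: `target` fragments are sampled without
#' replacement from the cell's pool.  If the cell already has at most
#' `target` fragments it is returned unchanged.
#'
#' @param cell_counts non-negative integer vector of per-gene counts.
#' @param target total fragment target (default 200000).
#' @param seed optional integer seed (draw is deterministic given the seed).
#' @return integer vector summing to `min(target, sum(cell_counts))`, with
#'   each entry at most the original count.
#' @export
downsample_fragments <- function(cell_counts, target = 200000L, seed = NULL) {
  assert_scalar_int(target, "target", lower = 1)
  if (any(cell_counts < 0)) stopf("counts must be non-negative")
  total <- sum(cell_counts)
  if (total <= target) return(cell_counts)
  with_seed(seed, {
    picked <- sample.int(total, target)
    edges <- cumsum(cell_counts)
    idx <- findInterval(picked - 1L, c(0L, edges), rightmost.closed = FALSE)
    out <- tabulate(idx, nbins = length(cell_counts))
    storage.mode(out) <- "integer"
    out
  })
}

#' Downsample every cell of a matrix to a fixed fragment depth
#'
#' Cells with fewer than `target` fragments are excluded by default (mixing
#' sequencing depths biases detection); set `keep_underdepth = TRUE` to keep
#' them unscaled, flagged in the result.
#'
#' @param x a [cell_count_matrix()].
#' @param target fragment target per cell.
#' @param seed integer seed.
#' @param keep_underdepth keep cells below target (default FALSE).
#' @return a [cell_count_matrix()]; `cell_meta` gains a logical
#'   `under_depth` column.
#' @export
downsample_matrix <- function(x, target = 200000L, seed = 1L,
                              keep_underdepth = FALSE) {
  stopifnot(inherits(x, "cell_count_matrix"))
  totals <- Matrix::rowSums(x$counts)
  under <- totals < target
  keep <- if (keep_underdepth) rep(TRUE, length(totals)) else !under
  if (!any(keep)) stopf("no cell reaches the fragment target %d", target)
  m <- as.matrix(x$counts[keep, , drop = FALSE])
  with_seed(child_seed(seed, "downsample_matrix"), {
    for (i in seq_len(nrow(m))) {
      m[i, ] <- downsample_fragments(m[i, ], target)
    }
  })
  meta <- x$cell_meta[keep, ]
  meta[, "under_depth" := under[keep]]
  cell_count_matrix(m, x$gene_meta, meta)
}

#' Select AIRE-expressing cells
#'
#' @param x a [cell_count_matrix()].
#' @param aire_gene gene name holding Aire counts (default `"Aire"`); used
#'   when `cell_meta` has no `aire_count` column.
#' @param threshold minimum Aire count (default 1).
#' @return character vector of cell names.
#' @export
select_aire_cells <- function(x, aire_gene = "Aire", threshold = 1L) {
  stopifnot(inherits(x, "cell_count_matrix"))
  if ("aire_count" %in% names(x$cell_meta)) {
    ac <- x$cell_meta$aire_count
  } else {
    if (!aire_gene %in% colnames(x$counts))
      stopf("gene '%s' not present in the matrix and cell_meta has no aire_count",
            aire_gene)
    ac <- as.numeric(x$counts[, aire_gene])
  }
  cells <- x$cell_meta$cell[ac >= threshold]
  if (length(cells) == 0L) warnf("no cell passes the Aire threshold %d",
                                 threshold)
  cells
}

#' Detectable-gene curve by cell resampling
#'
#' For each cell number n in `n_grid`, draws n cells without replacement
#' `n_rep` times; a gene is detectable in a draw iff its summed count over
#' the drawn cells is at least `detect_threshold`.  Reports the per-category
#' mean and SD of the number of detectable genes.
#'
#' @param x a [cell_count_matrix()].
#' @param n_grid increasing cell numbers, all at most the number of eligible
#'   cells.
#' @param n_rep resampling replicates per grid point (default 100).
#' @param seed integer seed; one child stream per (n, replicate).
#' @param cells optional subset of cell names to resample from (e.g. from
#'   [select_aire_cells()]).
#' @param detect_threshold summed-count detection threshold (default 1).
#' @return a `breadth_curve`: list with `summary` (data.table `category`,
#'   `n_cells`, `mean_genes`, `sd_genes`) and `draws` (data.table `category`,
#'   `n_cells`, `rep`, `genes_detected`); attributes `n_rep`, `seed`.
#' @export
detectable_gene_curve <- function(x, n_grid, n_rep = 100L, seed = 1L,
                                  cells = NULL, detect_threshold = 1L) {
  stopifnot(inherits(x, "cell_count_matrix"))
  assert_scalar_int(n_rep, "n_rep", lower = 1)
  m <- x$counts
  if (!is.null(cells)) m <- m[rownames(m) %in% cells, , drop = FALSE]
  N <- nrow(m)
  if (max(n_grid) > N)
    stopf("n_grid maximum (%d) exceeds the number of eligible cells (%d)",
          max(n_grid), N)
  cats <- x$gene_meta$category
  cat_levels <- unique(cats)
  ## gene x cell incidence; category totals per draw via indicator algebra
  inc <- m >= detect_threshold   # logical sparse cells x genes
  draws <- vector("list", length(n_grid) * n_rep)
  k <- 0L
  for (n in n_grid) {
    for (r in seq_len(n_rep)) {
      idx <- with_seed(child_seed(seed, paste0("draw_", n, "_", r)),
                       sample.int(N, n))
      det <- Matrix::colSums(inc[idx, , drop = FALSE]) > 0
      k <- k + 1L
      draws[[k]] <- data.table(category = cat_levels,
                               n_cells = n, rep = r,
                               genes_detected = vapply(cat_levels, function(cc)
                                 sum(det[cats == cc]), numeric(1)))
    }
  }
  draws <- rbindlist(draws)
  summary <- draws[, list(mean_genes = mean(genes_detected),
                          sd_genes = sd(genes_detected)),
                   by = c("category", "n_cells")]
  structure(list(summary = summary, draws = draws),
            n_rep = as.integer(n_rep), seed = as.integer(seed),
            detect_threshold = detect_threshold,
            class = "breadth_curve")
}

#' Exact expected detectable-gene count
#'
#' Closed form for sampling n of N cells without replacement: a gene present
#' in k of N cells is detected with probability
#' `1 - choose(N - k, n) / choose(N, n)`; the expectation sums this over the
#' genes of each category.
#'
#' @param x a [cell_count_matrix()].
#' @param n cells drawn.
#' @param cells optional eligible-cell subset.
#' @param detect_threshold per-cell detection threshold (default 1).
#' @return named numeric vector of expected counts per category.
#' @export
expected_detectable_genes <- function(x, n, cells = NULL,
                                      detect_threshold = 1L) {
  m <- x$counts
  if (!is.null(cells)) m <- m[rownames(m) %in% cells, , drop = FALSE]
  N <- nrow(m)
  k <- Matrix::colSums(m >= detect_threshold)
  pdet <- 1 - exp(lchoose_safe(N - k, n) - lchoose_safe(N, n))
  vapply(split(pdet, x$gene_meta$category), sum, numeric(1))
}

#' Compare TRA expression breadth between two groups
#'
#' Per gene category, a two-sided Wilcoxon rank-sum test on the
#' replicate-level detectable-gene counts at `n_cells`, Benjamini-Hochberg
#' corrected across categories, plus the fold change of means (A over B).
#'
#' @param curveA,curveB `breadth_curve` objects containing `n_cells` in
#'   their grids.
#' @param n_cells grid point to compare at (default 130).
#' @return data.table with columns `category`, `mean_A`, `mean_B`, `fold`,
#'   `p_value`, `p_bh`.
#' @export
compare_breadth <- function(curveA, curveB, n_cells = 130L) {
  sel_a <- curveA$draws[["n_cells"]] == n_cells
  sel_b <- curveB$draws[["n_cells"]] == n_cells
  da <- curveA$draws[sel_a, ]
  db <- curveB$draws[sel_b, ]
  if (nrow(da) == 0L || nrow(db) == 0L)
    stopf("n_cells = %d is not a grid point of both curves", n_cells)
  cats <- intersect(unique(da$category), unique(db$category))
  res <- rbindlist(lapply(cats, function(cc) {
    va <- da$genes_detected[da$category == cc]
    vb <- db$genes_detected[db$category == cc]
    identical_groups <- length(va) == length(vb) &&
      isTRUE(all.equal(sort(va), sort(vb)))
    p <- if (identical_groups) 1.0 else
      suppressWarnings(wilcox.test(va, vb, exact = FALSE)$p.value)
    data.table(category = cc, mean_A = mean(va), mean_B = mean(vb),
               fold = mean(va) / mean(vb), p_value = p)
  }))
  res[, "p_bh" := bh_adjust(res$p_value)]
  res[]
}
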