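## Shared fixtures and independent oracles for the test suite.
## Oracles are deliberately naive (enumeration / direct formula evaluation)
## and never call the package functions they are used to check.

## Build a clonotype record table in code.
make_records <- function(cdr3, count = 10L, trav = "TRAV1", traj = "TRAJ1",
                         sample_id = "s1", mouse_id = "m1",
                         subset = "CD4SP", genotype = "control") {
  n <- length(cdr3)
  trav <- rep_len(trav, n)
  vs <- strsplit(trav, ",", fixed = TRUE)
  data.table::data.table(
    sample_id = rep_len(sample_id, n), mouse_id = rep_len(mouse_id, n),
    subset = rep_len(subset, n), genotype = rep_len(genotype, n),
    read_count = as.integer(rep_len(count, n)), cdr3_aa = toupper(cdr3),
    trav_primary = vapply(vs, `[[`, character(1), 1L),
    trav_calls = vs, n_trav_calls = lengths(vs),
    traj_call = rep_len(traj, n))
}

## A sample_clonotype_set straight from (trav, cdr3) pairs.
make_sample_set <- function(trav, cdr3, sample_id = "s1", mouse_id = "m1",
                            subset = "CD4SP", genotype = "control") {
  collapse_to_clonotypes(make_records(cdr3, trav = trav,
                                      sample_id = sample_id,
                                      mouse_id = mouse_id, subset = subset,
                                      genotype = genotype))
}

## Exhaustive-enumeration oracle for interpolated richness: the mean number
## of distinct clonotypes over all C(n, m) subsets of the n clones.
oracle_richness <- function(X, m) {
  clones <- rep(seq_along(X), X)
  subsets <- utils::combn(length(clones), m)
  mean(apply(subsets, 2, function(ix) length(unique(clones[ix]))))
}

## Direct textbook Morisita-Horn evaluation on two named vectors.
oracle_mh <- function(x, y) {
  keys <- union(names(x), names(y))
  xv <- sapply(keys, function(k) if (k %in% names(x)) x[[k]] else 0)
  yv <- sapply(keys, function(k) if (k %in% names(y)) y[[k]] else 0)
  X <- sum(xv); Y <- sum(yv)
  2 * sum(xv * yv) / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
}

## Random small abundance vector with n = sum(X) <= n_max.
random_abundance <- function(n_max = 10L) {
  n <- sample(2:n_max, 1)
  parts <- c()
  while (n > 0) {
    k <- sample.int(n, 1)
    parts <- c(parts, k)
    n <- n - k
  }
  parts
}

## Small dense random cell x gene matrix with category labels.
random_cell_matrix <- function(n_cells = 30L, n_genes = 40L) {
  m <- matrix(rpois(n_cells * n_genes, 0.4), n_cells, n_genes)
  cats <- sample(c("aire_dependent", "aire_enhanced",
                   "aire_independent_tra", "other"), n_genes, TRUE)
  cell_count_matrix(
    m,
    data.frame(gene = sprintf("g%03d", seq_len(n_genes)), category = cats),
    data.frame(cell = sprintf("c%03d", seq_len(n_cells)),
               population = "control"))
}

## Constant-valued signal track on [0, len) of one chromosome.
const_track <- function(value, len = 1e5, chrom = "chr1") {
  signal_track(data.frame(chrom = chrom, start = 0, end = len,
                          value = value))
}

## Exact variance of the per-category detectable-gene count when drawing n
## of N cells without replacement (inclusion-exclusion over gene pairs).
oracle_detect_var <- function(ccm, n, detect_threshold = 1L) {
  I <- as.matrix(ccm$counts >= detect_threshold)
  N <- nrow(I)
  k <- colSums(I)
  both <- crossprod(I)                       # cells expressing both g and h
  k_union <- outer(k, k, "+") - both
  lden <- lchoose(N, n)
  Q1 <- exp(lchoose(N - k, n) - lden)        # P(gene undetected)
  Q2 <- exp(lchoose(N - k_union, n) - lden)  # P(both undetected)
  Pg <- 1 - Q1
  Pboth <- 1 - outer(Q1, Q1, "+") + Q2       # P(both detected)
  cov_mat <- Pboth - outer(Pg, Pg)
  vapply(split(seq_along(k), ccm$gene_meta$category), function(ix)
    sum(cov_mat[ix, ix, drop = FALSE]), numeric(1))
}
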