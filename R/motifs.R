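## CDR3 self-reactivity motif scoring: amino-acid doublets at CDR3 positions
## 6/7 and central cysteine under an apex-out alignment, plus the group
## comparisons used to contrast T-cell subsets and genotypes.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a doublet list from a plain-text file
#'
#' One length-2 amino-acid doublet per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @return character vector of doublets (class `doublet_list`).
#' @export
read_doublet_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  as_doublet_list(x)
}

#' Validate a doublet list
#' @param x character vector of length-2 amino-acid strings.
#' @return `x` with class `doublet_list`.
#' @export
as_doublet_list <- function(x) {
  x <- toupper(as.character(x))
  if (length(x) == 0L) stopf("doublet list is empty")
  bad <- nchar(x) != 2L | !grepl("^[ACDEFGHIKLMNPQRSTVWY]{2}$", x)
  if (any(bad))
    stopf("invalid doublet(s): %s", paste(head(x[bad], 5), collapse = ", "))
  structure(unique(x), class = "doublet_list")
}

#' Extract the amino-acid doublet at CDR3 positions 6 and 7
#'
#' Position 1 is the conserved cysteine at the CDR3 N-terminus.  Sequences
#' shorter than 7 residues have no position-6/7 doublet and return `NA`.
#'
#' @param cdr3_aa character vector of functional CDR3 amino-acid sequences.
#' @return character vector of length-2 doublets, `NA` where the CDR3 is too
#'   short.
#' @export
doublet_at_6_7 <- function(cdr3_aa) {
  out <- substr(cdr3_aa, 6L, 7L)
  out[nchar(cdr3_aa) < 7L] <- NA_character_
  out
}

#' Proportion of clonotypes carrying a self-reactivity doublet
#'
#' The proportion of clonotypes in a sample whose position-6/7 doublet is in
#' the supplied list.  Clonotypes with no doublet (CDR3 shorter than 7) stay
#' in the denominator.  Samples with fewer than `min_clones` clonotypes are
#' flagged excluded (`NA` proportion) rather than reported.
#'
#' @param sample a `sample_clonotype_set` (or data.frame with a `cdr3_aa`
#'   column).
#' @param doublets a `doublet_list`.
#' @param min_clones minimum clonotype count for a sample to be reported
#'   (default 100).
#' @return list with `proportion` (`NA` if excluded), `n_clones`,
#'   `n_with_doublet`, `excluded`.
#' @export
doublet_proportion <- function(sample, doublets, min_clones = 100L) {
  doublets <- as_doublet_list(doublets)
  cdr3 <- as.data.table(sample)$cdr3_aa
  n <- length(cdr3)
  hit <- !is.na(doublet_at_6_7(cdr3)) & doublet_at_6_7(cdr3) %in% doublets
  excl <- n < min_clones
  list(proportion = if (excl) NA_real_ else sum(hit) / n,
       n_clones = n, n_with_doublet = sum(hit), excluded = excl)
}

#' Apex-out residue positions of a CDR3
#'
#' Numbers residues outward from the loop centre ("apex").  For odd length L
#' the unique central residue is position 0; for even length the central pair
#' occupies positions 0 and +1.  Residues N-terminal of the apex get negative
#' positions.
#'
#' @param L integer CDR3 length(s).
#' @return for scalar `L`, an integer vector of apex positions of residues
#'   1..L.
#' @export
apex_positions <- function(L) {
  L <- assert_scalar_int(L, "L", lower = 1)
  if (L %% 2L == 1L) {
    seq_len(L) - (L + 1L) %/% 2L
  } else {
    seq_len(L) - L %/% 2L   # central pair -> 0, +1
  }
}

#' Test for a cysteine near the CDR3 apex
#'
#' Uses the apex-out alignment of [apex_positions()] and reports whether any
#' residue with apex position inside `window` is a cysteine.  Terminal
#' residues (including the conserved position-1 cysteine) are not masked; for
#' very short CDR3s they may fall inside the window and are evaluated as-is.
#'
#' @param cdr3_aa character vector of functional CDR3 sequences.
#' @param window integer pair, default `c(-2, 2)`.
#' @return logical vector.
#' @export
has_central_cysteine <- function(cdr3_aa, window = c(-2L, 2L)) {
  if (length(window) != 2L || window[1] > window[2])
    stopf("`window` must be an ordered integer pair")
  vapply(cdr3_aa, function(s) {
    L <- nchar(s)
    if (L < 1L) return(FALSE)
    pos <- apex_positions(L)
    keep <- pos >= window[1] & pos <= window[2]
    any(strsplit(s, "")[[1]][keep] == "C")
  }, logical(1), USE.NAMES = FALSE)
}

#' Compare central-cysteine proportions between two catalogues
#'
#' Builds the 2x2 table (with / without central cysteine) x (catalogue A /
#' B), each clonotype counted once per catalogue, and applies the two-sided
#' Fisher exact test with Bonferroni correction over `n_comparisons`
#' contrasts.
#'
#' @param catA,catB `tcr_catalogue` objects (or data.frames with `cdr3_aa`).
#' @param n_comparisons number of contrasts in the Bonferroni family.
#' @param window apex window, see [has_central_cysteine()].
#' @return a `motif_comparison` with the underlying table in `$table`.
#' @export
compare_cysteine_fisher <- function(catA, catB, n_comparisons = 1L,
                                    window = c(-2L, 2L)) {
  a <- as.data.table(catA)$cdr3_aa
  b <- as.data.table(catB)$cdr3_aa
  if (length(a) == 0L || length(b) == 0L)
    stopf("both catalogues must contain at least one clonotype")
  ca <- sum(has_central_cysteine(a, window))
  cb <- sum(has_central_cysteine(b, window))
  tab <- matrix(c(ca, length(a) - ca, cb, length(b) - cb), nrow = 2L,
                byrow = TRUE,
                dimnames = list(c("A", "B"), c("cys", "no_cys")))
  fe <- fisher_exact_2x2(tab)
  motif_comparison(fe$odds_ratio, fe$p_value,
                   "fisher_exact_two_sided", n_comparisons,
                   extra = list(table = tab))
}

#' Compare per-sample doublet proportions between two groups
#'
#' Classical unpaired two-sided Student's t test (pooled variance) on
#' per-sample proportions, Bonferroni-corrected.  Excluded samples (`NA`)
#' are dropped; each group must retain at least two samples.
#'
#' @param propsA,propsB numeric vectors of per-sample proportions.
#' @param n_comparisons Bonferroni family size.
#' @return a `motif_comparison`.
#' @export
compare_doublet_ttest <- function(propsA, propsB, n_comparisons = 1L) {
  propsA <- propsA[!is.na(propsA)]
  propsB <- propsB[!is.na(propsB)]
  if (length(propsA) < 2L || length(propsB) < 2L)
    stopf("each group needs >= 2 non-excluded samples")
  tt <- student_t_pooled(propsA, propsB)
  motif_comparison(tt$statistic, tt$p_value,
                   "student_t_unpaired_two_sided", n_comparisons,
                   extra = list(df = tt$df))
}
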