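## Clonotype table ingestion, filtering, per-sample collapsing and
## catalogue assembly.
##
## A "clonotype" is a unique combination of primary Trav segment and CDR3
## amino-acid sequence.  A "TCR catalogue" pools the per-mouse clonotype sets
## of one T-cell subset x genotype, with abundance equal to the number of
## mice in which each clonotype was detected.

VALID_SUBSETS <- c("pre_selection", "wave1", "CD4SP", "CD8SP", "other")
VALID_GENOTYPES <- c("control", "mutant", "other")

#' Default column mapping for MIGEC-style clonotype tables
#'
#' @return named list mapping logical fields (`count`, `cdr3_aa`, `v`, `j`)
#'   to the column names expected in input TSVs.
#' @export
default_column_map <- function() {
  list(count = "Count", cdr3_aa = "CDR3.amino.acid.sequence",
       v = "V.segments", j = "J.segments")
}

#' Parse per-sample clonotype tables
#'
#' Reads tab-separated clonotype tables (one per sequenced sample, in the
#' dialect of MIGEC output) and joins them with sample metadata.  Multi-valued
#' V-segment calls are split on `v_delim`, preserving order; the first listed
#' call is recorded as the primary call.  CDR3 sequences are upper-cased on
#' ingest; comparisons downstream are case-sensitive.
#'
#' @param paths character vector of TSV file paths.
#' @param metadata data.frame with columns `file`, `sample_id`, `mouse_id`,
#'   `subset`, `genotype`; `file` values are matched against `basename(paths)`
#'   (or full paths).
#' @param column_map named list as returned by [default_column_map()].
#' @param v_delim delimiter separating multiple V calls (default `","`).
#' @return a `data.table` of clonotype records with columns `sample_id`,
#'   `mouse_id`, `subset`, `genotype`, `read_count`, `cdr3_aa`,
#'   `trav_primary`, `trav_calls` (list column of ordered calls),
#'   `n_trav_calls`, `traj_call`.
#' @export
parse_clonotype_tables <- function(paths, metadata,
                                   column_map = default_column_map(),
                                   v_delim = ",") {
  metadata <- as.data.table(metadata)
  need_meta <- c("file", "sample_id", "mouse_id", "subset", "genotype")
  miss <- setdiff(need_meta, names(metadata))
  if (length(miss))
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))

  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    path <- paths[[i]]
    mrow <- metadata[metadata$file == path | metadata$file == basename(path), ]
    if (nrow(mrow) == 0L)
      stopf("no metadata entry for input file '%s'", basename(path))
    if (nrow(mrow) > 1L)
      stopf("multiple metadata entries for input file '%s'", basename(path))
    tab <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
    for (field in c("count", "cdr3_aa", "v", "j")) {
      col <- column_map[[field]]
      if (is.null(col) || !col %in% names(tab))
        stopf("file '%s' is missing required column '%s' (field '%s')",
              basename(path), if (is.null(col)) "<unmapped>" else col, field)
    }
    counts <- suppressWarnings(as.numeric(tab[[column_map$count]]))
    bad <- is.na(counts) | counts != floor(counts) | counts < 0
    if (any(bad))
      stopf("file '%s': unparseable count value '%s' in row %d",
            basename(path), tab[[column_map$count]][which(bad)[1]],
            which(bad)[1])
    vs <- strsplit(tab[[column_map$v]], v_delim, fixed = TRUE)
    vs <- lapply(vs, trimws)
    if (nrow(tab) > 0 && any(!vapply(vs, length, 1L)))
      stopf("file '%s': empty V segment call", basename(path))
    rec <- data.table(
      sample_id = mrow$sample_id, mouse_id = mrow$mouse_id,
      subset = mrow$subset, genotype = mrow$genotype,
      read_count = as.integer(counts),
      cdr3_aa = toupper(tab[[column_map$cdr3_aa]]),
      trav_primary = vapply(vs, function(v) v[[1L]], character(1)),
      trav_calls = vs,
      n_trav_calls = vapply(vs, length, 1L),
      traj_call = tab[[column_map$j]]
    )
    out[[i]] <- rec
  }
  rbindlist(out)
}

#' Filter clonotype records for functionality and read depth
#'
#' Removes records whose CDR3 is non-functional (contains any sentinel
#' character, by default `*` for a stop codon or `_` for a frameshift) and
#' records detected fewer than `min_reads` times in their sample.  A record
#' with exactly `min_reads` reads is retained.
#'
#' @param records data.table of clonotype records.
#' @param min_reads minimum per-sample read count (default 3).
#' @param sentinels characters marking non-functional CDR3s.
#' @return the surviving records, input order preserved.
#' @export
filter_records <- function(records, min_reads = 3L,
                           sentinels = c("*", "_")) {
  assert_scalar_int(min_reads, "min_reads", lower = 1)
  records <- as.data.table(records)
  if (nrow(records) == 0L) return(records)
  nonfunc <- rep(FALSE, nrow(records))
  for (s in sentinels) {
    nonfunc <- nonfunc | grepl(s, records$cdr3_aa, fixed = TRUE)
  }
  records[!nonfunc & records$read_count >= min_reads, ]
}

#' Collapse records of one sample to its clonotype set
#'
#' Each clonotype -- a unique (primary Trav, CDR3 amino-acid sequence) pair --
#' is counted only once per sample, regardless of read count.  Records whose
#' sequence aligned to more than one Trav paralog are resolved according to
#' `paralog_policy`: `"first_listed"` keeps the first listed paralog (the
#' default), `"exclude_ambiguous"` drops those records entirely (used for
#' segment-usage analyses).
#'
#' @param records clonotype records of a single sample.
#' @param paralog_policy `"first_listed"` or `"exclude_ambiguous"`.
#' @return a `sample_clonotype_set`: data.table with columns `trav`,
#'   `cdr3_aa` (one row per clonotype) and attributes `sample_id`,
#'   `mouse_id`, `subset`, `genotype`.
#' @export
collapse_to_clonotypes <- function(records,
                                   paralog_policy = c("first_listed",
                                                      "exclude_ambiguous")) {
  paralog_policy <- match.arg(paralog_policy)
  records <- as.data.table(records)
  if (nrow(records) == 0L) stopf("no records to collapse")
  if (length(unique(records$sample_id)) != 1L)
    stopf("collapse_to_clonotypes() expects records from a single sample; got %d",
          length(unique(records$sample_id)))
  if (paralog_policy == "exclude_ambiguous")
    records <- records[records$n_trav_calls == 1L, ]
  cl <- unique(data.table(trav = records$trav_primary,
                          cdr3_aa = records$cdr3_aa))
  setkey(cl, trav, cdr3_aa)
  structure(cl,
            sample_id = records$sample_id[1L],
            mouse_id = records$mouse_id[1L],
            subset = records$subset[1L],
            genotype = records$genotype[1L],
            class = c("sample_clonotype_set", class(cl)))
}

#' Pool per-mouse clonotype sets into a TCR catalogue
#'
#' All clonotypes detected in samples of one subset x genotype combination
#' are pooled; the abundance of each clonotype is the number of distinct mice
#' in which it was detected.  Samples sharing a `mouse_id` are merged (union
#' of clonotype sets) before counting, so abundance is per mouse, not per
#' sorted aliquot.
#'
#' @param samples list of `sample_clonotype_set` objects sharing subset and
#'   genotype.
#' @return a `tcr_catalogue`: data.table with columns `trav`, `cdr3_aa`,
#'   `abundance`, and attributes `subset`, `genotype`, `n_mice`.
#' @export
build_catalogue <- function(samples) {
  if (length(samples) == 0L) stopf("at least one sample is required")
  subs <- vapply(samples, function(s) attr(s, "subset"), character(1))
  gens <- vapply(samples, function(s) attr(s, "genotype"), character(1))
  if (length(unique(subs)) != 1L || length(unique(gens)) != 1L)
    stopf("all samples must share one subset and genotype (got %s / %s)",
          paste(unique(subs), collapse = ","),
          paste(unique(gens), collapse = ","))
  mice <- vapply(samples, function(s) attr(s, "mouse_id"), character(1))
  per_mouse <- lapply(split(samples, mice), function(ss) {
    unique(rbindlist(lapply(ss, as.data.table)))
  })
  pooled <- rbindlist(lapply(per_mouse, identity))
  cat <- pooled[, list(abundance = .N), by = c("trav", "cdr3_aa")]
  setkey(cat, trav, cdr3_aa)
  structure(cat,
            subset = subs[1L], genotype = gens[1L],
            n_mice = length(per_mouse),
            class = c("tcr_catalogue", class(cat)))
}

#' @export
print.tcr_catalogue <- function(x, ...) {
  cat(sprintf("TCR catalogue: %s / %s, %d clonotypes from %d mice\n",
              attr(x, "subset"), attr(x, "genotype"), nrow(x),
              attr(x, "n_mice")))
  NextMethod()
}

#' Write a catalogue as TSV plus a JSON sidecar
#'
#' @param catalogue a `tcr_catalogue`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  fwrite(as.data.table(catalogue), path, sep = "\t")
  side <- list(subset = attr(catalogue, "subset"),
               genotype = attr(catalogue, "genotype"),
               n_mice = attr(catalogue, "n_mice"),
               n_clonotypes = nrow(catalogue))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
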