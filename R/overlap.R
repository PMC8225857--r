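## Morisita-Horn overlap between catalogues, Trav/Traj segment usage,
## CDR3-length distributions and the 8-parameter proximal/distal feature
## vector summarising successive rounds of TCRa rearrangement.

#' Morisita-Horn overlap index
#'
#' `MH = 2 sum(x_i y_i) / [(sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) X Y]` over the
#' union of keys, with `X = sum(x)`, `Y = sum(y)`; absent keys count 0.
#' For TCR catalogues the abundances are the number of mice in which each
#' clonotype was detected.
#'
#' @param x,y named numeric vectors of positive abundances, or
#'   `tcr_catalogue` objects.
#' @return overlap in `[0, 1]`.
#' @export
morisita_horn <- function(x, y) {
  x <- .as_abundance_map(x); y <- .as_abundance_map(y)
  keys <- union(names(x), names(y))
  xv <- ifelse(keys %in% names(x), x[keys], 0); xv[is.na(xv)] <- 0
  yv <- ifelse(keys %in% names(y), y[keys], 0); yv[is.na(yv)] <- 0
  X <- sum(xv); Y <- sum(yv)
  2 * sum(xv * yv) / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
}

.as_abundance_map <- function(x) {
  if (inherits(x, "tcr_catalogue")) {
    d <- as.data.table(x)
    x <- setNames(as.numeric(d$abundance), paste(d$trav, d$cdr3_aa, sep = "|"))
  }
  if (is.null(names(x)) || length(x) == 0L)
    stopf("abundance mapping must be a non-empty named vector or tcr_catalogue")
  if (any(x <= 0)) stopf("abundances must be positive")
  x
}

#' Pairwise Morisita-Horn overlap matrix
#'
#' @param catalogues list of `tcr_catalogue` objects (or named abundance
#'   vectors), length >= 2.  Names of the list become dimnames.
#' @return symmetric numeric matrix with unit diagonal, rows/columns in
#'   input order.
#' @export
overlap_matrix <- function(catalogues) {
  k <- length(catalogues)
  if (k < 2L) stopf("at least two catalogues are required")
  maps <- lapply(catalogues, .as_abundance_map)
  M <- diag(1, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      M[i, j] <- M[j, i] <- morisita_horn(maps[[i]], maps[[j]])
    }
  }
  nm <- names(catalogues)
  if (!is.null(nm)) dimnames(M) <- list(nm, nm)
  M
}

#' Trav/Traj segment usage and CDR3-length distribution
#'
#' Relative frequency per Trav segment over clonotypes (each clonotype
#' weight 1), per Traj segment over records when a record table is supplied,
#' and the CDR3 amino-acid length histogram.  Trav-ambiguous sequences should
#' have been excluded upstream (`paralog_policy = "exclude_ambiguous"`).
#'
#' @param clonotypes a `sample_clonotype_set` or `tcr_catalogue`.
#' @param records optional clonotype record table supplying `traj_call`.
#' @return list with data.tables `trav_usage` (`trav`, `freq`), `traj_usage`
#'   (`traj`, `freq`; `NULL` without records) and `cdr3_length` (`length`,
#'   `freq`).  Frequencies each sum to 1.
#' @export
segment_usage <- function(clonotypes, records = NULL) {
  cl <- as.data.table(clonotypes)
  trav_tab <- cl[, list(count = .N), by = "trav"]
  trav_tab[, "freq" := count / sum(count)]
  setorder(trav_tab, trav)
  len <- nchar(cl$cdr3_aa)
  len_tab <- as.data.table(table(length = len))
  len_tab[, "length" := as.integer(as.character(length))]
  len_tab[, "freq" := N / sum(N)]
  traj_tab <- NULL
  if (!is.null(records)) {
    rec <- as.data.table(records)
    traj_tab <- rec[, list(count = .N), by = "traj_call"]
    setnames(traj_tab, "traj_call", "traj")
    traj_tab[, "freq" := count / sum(count)]
    setorder(traj_tab, traj)
  }
  list(trav_usage = trav_tab[, c("trav", "freq"), with = FALSE],
       traj_usage = if (is.null(traj_tab)) NULL else
         traj_tab[, c("traj", "freq"), with = FALSE],
       cdr3_length = len_tab[, c("length", "freq"), with = FALSE])
}

#' Build a segment zone map
#'
#' @param trav_zone named character vector: Trav name -> `"proximal"` or
#'   `"distal"`.
#' @param traj_zone named character vector: Traj name -> `"proximal"`,
#'   `"medium"` or `"distal"`.
#' @return a `zone_map` list.
#' @export
zone_map <- function(trav_zone, traj_zone) {
  if (!all(trav_zone %in% c("proximal", "distal")))
    stopf("trav_zone values must be 'proximal' or 'distal'")
  if (!all(traj_zone %in% c("proximal", "medium", "distal")))
    stopf("traj_zone values must be 'proximal', 'medium' or 'distal'")
  structure(list(trav_zone = trav_zone, traj_zone = traj_zone),
            class = "zone_map")
}

#' Read a zone map from two-column TSVs
#'
#' @param trav_path,traj_path TSV files with columns `segment`, `zone`.
#' @return a `zone_map`.
#' @export
read_zone_map <- function(trav_path, traj_path) {
  tv <- fread(trav_path, sep = "\t", header = TRUE)
  tj <- fread(traj_path, sep = "\t", header = TRUE)
  zone_map(setNames(tv$zone, tv$segment), setNames(tj$zone, tj$segment))
}

#' Eight-parameter proximal/distal usage feature vector
#'
#' Computed over transcripts (records), not clonotypes: the relative
#' frequencies of proximal and distal TRAV segments, and the frequencies of
#' proximal, medium and distal TRAJ elements within proximal- and within
#' distal-TRAV-containing transcripts.  Feature triples of an empty TRAV
#' stratum are reported as `NA`.
#'
#' @param records filtered clonotype record table (columns `trav_primary`,
#'   `traj_call`).
#' @param zones a [zone_map()].
#' @param strict error on segments missing from the zone map (default TRUE);
#'   otherwise unzoned transcripts are dropped with a warning.
#' @return named numeric vector of length 8: `trav_prox_freq`,
#'   `trav_dist_freq`, `traj_{prox,med,dist}_within_trav_prox`,
#'   `traj_{prox,med,dist}_within_trav_dist`.
#' @export
proximal_distal_features <- function(records, zones, strict = TRUE) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) stopf("no records")
  tv_zone <- zones$trav_zone[rec$trav_primary]
  tj_zone <- zones$traj_zone[rec$traj_call]
  unk <- is.na(tv_zone) | is.na(tj_zone)
  if (any(unk)) {
    segs <- unique(c(rec$trav_primary[is.na(tv_zone)],
                     rec$traj_call[is.na(tj_zone)]))
    if (strict)
      stopf("segment(s) missing from zone map: %s",
            paste(head(segs, 10), collapse = ", "))
    warnf("dropping %d transcript(s) with unzoned segment(s): %s",
          sum(unk), paste(head(segs, 5), collapse = ", "))
    tv_zone <- tv_zone[!unk]; tj_zone <- tj_zone[!unk]
  }
  n <- length(tv_zone)
  trav_prox <- sum(tv_zone == "proximal") / n
  triple <- function(sel) {
    if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
    z <- tj_zone[sel]
    c(mean(z == "proximal"), mean(z == "medium"), mean(z == "distal"))
  }
  out <- c(trav_prox_freq = trav_prox,
           trav_dist_freq = 1 - trav_prox,
           setNames(triple(tv_zone == "proximal"),
                    paste0("traj_", c("prox", "med", "dist"),
                           "_within_trav_prox")),
           setNames(triple(tv_zone == "distal"),
                    paste0("traj_", c("prox", "med", "dist"),
                           "_within_trav_dist")))
  out
}
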