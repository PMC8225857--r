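test_that("parse_clonotype_tables maps fields and splits paralogs", {
  path <- system.file("extdata", "toy_clonotypes.tsv",
                      package = "thymoselect")
  meta <- data.frame(file = "toy_clonotypes.tsv", sample_id = "toy_s1",
                     mouse_id = "toy_m1", subset = "CD4SP",
                     genotype = "control")
  rec <- parse_clonotype_tables(path, meta)
  expect_equal(nrow(rec), 12L)
  expect_equal(rec$read_count[1], 12L)
  expect_equal(rec$cdr3_aa[1], "CASSLGGNTGKLIF")
  expect_equal(rec$trav_calls[[1]], c("TRAV6-7", "TRAV6-6"))
  expect_equal(rec$trav_primary[1], "TRAV6-7")
  expect_equal(rec$traj_call[1], "TRAJ33")
  expect_equal(rec$cdr3_aa[8], "CAVSAGGYKVVF")  # upper-cased on ingest
})

test_that("parse errors: missing column, bad count, missing metadata", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Count\tCDR3.amino.acid.sequence\tV.segments", tmp)
  meta <- data.frame(file = basename(tmp), sample_id = "s", mouse_id = "m",
                     subset = "other", genotype = "other")
  expect_error(parse_clonotype_tables(tmp, meta), "J.segments")

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Count\tCDR3.amino.acid.sequence\tV.segments\tJ.segments",
               "abc\tCASSF\tTRAV1\tTRAJ1"), tmp2)
  meta2 <- data.frame(file = basename(tmp2), sample_id = "s",
                      mouse_id = "m", subset = "other", genotype = "other")
  expect_error(parse_clonotype_tables(tmp2, meta2), "unparseable count")
  expect_error(parse_clonotype_tables(tmp2, meta), "no metadata")

  ## empty file with valid header -> empty record list
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Count\tCDR3.amino.acid.sequence\tV.segments\tJ.segments", tmp3)
  meta3 <- data.frame(file = basename(tmp3), sample_id = "s",
                      mouse_id = "m", subset = "other", genotype = "other")
  rec <- parse_clonotype_tables(tmp3, meta3)
  expect_equal(nrow(rec), 0L)
})

test_that("filter_records keeps exactly functional records with count >= 3", {
  rec <- make_records(c("CAAAAAAAAF", "CBBB", "CCCC", "CDD*DDF"),
                      count = c(5L, 2L, 3L, 10L))
  kept <- filter_records(rec)
  expect_equal(kept$cdr3_aa, c("CAAAAAAAAF", "CCCC"))
  ## boundary: exactly min_reads retained
  expect_true("CCCC" %in% kept$cdr3_aa)
  ## min_reads = 1, all functional -> identity
  func <- make_records(c("CAAF", "CTTF"), count = c(1L, 2L))
  expect_equal(filter_records(func, min_reads = 1L), func)
  ## idempotence
  expect_equal(filter_records(kept), kept)
  ## configurable sentinels
  expect_equal(nrow(filter_records(rec, sentinels = character(0))), 3L)
})

test_that("collapse_to_clonotypes honours paralog policy and uniqueness", {
  rec <- make_records(c("CAAS", "CAAS", "CGGS"),
                      trav = c("TRAV1", "TRAV1", "TRAV6-7,TRAV6-6"),
                      count = c(40L, 7L, 9L))
  s1 <- collapse_to_clonotypes(rec, "first_listed")
  expect_equal(nrow(s1), 2L)                      # duplicates collapse
  expect_true(all(c("TRAV1", "TRAV6-7") %in% s1$trav))
  s2 <- collapse_to_clonotypes(rec, "exclude_ambiguous")
  expect_equal(nrow(s2), 1L)                      # ambiguous record dropped
  expect_equal(s2$trav, "TRAV1")
  ## mixed samples rejected
  bad <- rbind(rec, make_records("CTTT", sample_id = "s2"))
  expect_error(collapse_to_clonotypes(bad), "single sample")
})

test_that("build_catalogue counts mice, merges aliquots, validates groups", {
  s1 <- make_sample_set(c("TRAV1", "TRAV2"), c("CAAA", "CBBB"),
                        sample_id = "a", mouse_id = "m1")
  s2 <- make_sample_set(c("TRAV1", "TRAV3"), c("CAAA", "CCCC"),
                        sample_id = "b", mouse_id = "m2")
  s3 <- make_sample_set("TRAV4", "CDDD", sample_id = "c", mouse_id = "m3")
  cat1 <- build_catalogue(list(s1, s2, s3))
  expect_equal(attr(cat1, "n_mice"), 3L)
  expect_equal(cat1[cat1$trav == "TRAV1", ]$abundance, 2L)  # in m1 and m2
  expect_equal(cat1[cat1$trav == "TRAV4", ]$abundance, 1L)  # singleton
  expect_true(all(cat1$abundance <= attr(cat1, "n_mice")))

  ## two aliquots of the same mouse count once
  s1b <- make_sample_set("TRAV1", "CAAA", sample_id = "a2", mouse_id = "m1")
  cat2 <- build_catalogue(list(s1, s1b, s2, s3))
  expect_equal(attr(cat2, "n_mice"), 3L)
  expect_equal(cat2[cat2$trav == "TRAV1", ]$abundance, 2L)

  expect_error(build_catalogue(list(
    s1, make_sample_set("TRAV1", "CAAA", subset = "CD8SP",
                        mouse_id = "m9"))), "subset")
})

test_that("catalogue pipeline invariants hold on random repertoires", {
  set.seed(42)
  for (rep in 1:5) {
    n_mice <- sample(2:4, 1)
    pool_cdr3 <- replicate(30, paste0("C", paste(
      sample(LETTERS[LETTERS %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]],
             8, TRUE), collapse = ""), "F"))
    samples <- lapply(seq_len(n_mice), function(mi) {
      ix <- sample(30, sample(5:15, 1))
      make_sample_set(rep("TRAV1", length(ix)), pool_cdr3[ix],
                      sample_id = paste0("s", mi),
                      mouse_id = paste0("m", mi))
    })
    cat1 <- build_catalogue(samples)
    cat2 <- build_catalogue(rev(samples))       # permutation invariance
    expect_equal(data.table::setkey(data.table::as.data.table(cat1)),
                 data.table::setkey(data.table::as.data.table(cat2)))
    ## sum of abundances = sum of per-mouse set sizes; size bound
    sizes <- vapply(samples, nrow, 1L)
    expect_equal(sum(cat1$abundance), sum(sizes))
    expect_lte(nrow(cat1), sum(sizes))
  }
  ## disjoint per-mouse sets: equality case, all abundance 1
  disj <- lapply(1:3, function(mi)
    make_sample_set(rep("TRAV2", 10),
                    sprintf("CAA%s%02dF", LETTERS[mi], 1:10),
                    sample_id = paste0("d", mi),
                    mouse_id = paste0("dm", mi)))
  catd <- build_catalogue(disj)
  expect_equal(nrow(catd), 30L)
  expect_true(all(catd$abundance == 1L))
})
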