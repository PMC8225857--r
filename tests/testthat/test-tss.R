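tss_one <- function(pos, strand = "+", gene = "g1", chrom = "chr1") {
  data.table::data.table(gene = gene, chrom = chrom, tss = pos,
                         strand = strand)
}

test_that("constant tracks give constant profiles", {
  chip <- const_track(3); input <- const_track(1)
  prof <- ratio_metaprofile(chip, input, tss_one(50000), pseudocount = 0)
  expect_equal(nrow(prof$bins), 160L)
  expect_true(all(prof$bins$median_ratio == 3))
  expect_equal(diff(prof$bins$bin_start)[1], 50)
  expect_equal(range(prof$bins$bin_start), c(-4000, 3950))
  ## chip = input -> all ones
  prof2 <- ratio_metaprofile(chip, chip, tss_one(50000), pseudocount = 0)
  expect_true(all(prof2$bins$median_ratio == 1))
})

test_that("step function at the TSS splits the profile; minus strand mirrors", {
  tss <- 50000
  step_chip <- signal_track(data.frame(chrom = "chr1",
                                       start = c(0, tss),
                                       end = c(tss, 1e5),
                                       value = c(0, 10)))
  input <- const_track(1)
  p_plus <- ratio_metaprofile(step_chip, input, tss_one(tss, "+"),
                              pseudocount = 0)
  expect_equal(p_plus$bins$median_ratio, rep(c(0, 10), each = 80))
  p_minus <- ratio_metaprofile(step_chip, input, tss_one(tss, "-"),
                               pseudocount = 0)
  expect_equal(p_minus$bins$median_ratio, rep(c(10, 0), each = 80))
})

test_that("coordinate correctness over every offset via an identity track", {
  ## per-bp track whose value at genomic position p equals p: the mean of
  ## each 50 bp bin identifies exactly which bases the bin covers
  tss <- 6000
  w <- 4000; bin <- 50
  pos <- (tss - w):(tss + w - 1)
  ident <- signal_track(data.frame(chrom = "chr1", start = pos,
                                   end = pos + 1, value = pos))
  input <- const_track(1, len = 2e4)
  p_plus <- ratio_metaprofile(ident, input, tss_one(tss, "+"),
                              half_window = w, bin = bin, pseudocount = 0)
  expected_plus <- vapply(seq_len(160), function(b) {
    lo <- tss - w + (b - 1) * bin
    mean(lo:(lo + bin - 1))
  }, numeric(1))
  expect_equal(p_plus$bins$median_ratio, expected_plus)
  ## minus strand: bin b covers genomic [tss + w - b*bin, tss + w - (b-1)*bin)
  p_minus <- ratio_metaprofile(ident, input, tss_one(tss, "-"),
                               half_window = w, bin = bin, pseudocount = 0)
  expect_equal(p_minus$bins$median_ratio, rev(expected_plus))
  ## single-delta spot checks: delta at genomic offset d lands in bin
  ## floor(d/50) (plus) and floor((-d-1)/50) (minus), bins indexed from -80
  for (d in c(-4000, -1, 0, 1, 74, 3999)) {
    delta <- signal_track(data.frame(chrom = "chr1", start = tss + d,
                                     end = tss + d + 1, value = 50))
    pp <- ratio_metaprofile(delta, input, tss_one(tss, "+"),
                            half_window = w, bin = bin, pseudocount = 0)
    expect_equal(which(pp$bins$median_ratio == 1) - 81L, floor(d / 50))
    pm <- ratio_metaprofile(delta, input, tss_one(tss, "-"),
                            half_window = w, bin = bin, pseudocount = 0)
    expect_equal(which(pm$bins$median_ratio == 1) - 81L, floor((-d - 1) / 50))
  }
})

test_that("windows below zero are skipped; empty TSS set errors", {
  input <- const_track(1)
  expect_warning(
    prof <- ratio_metaprofile(const_track(2), input,
                              rbind(tss_one(100), tss_one(50000, gene = "g2"))),
    "below position 0")
  expect_equal(prof$bins$n_genes[1], 1L)
  expect_error(ratio_metaprofile(const_track(2), input, tss_one(100)[0, ]),
               "empty")
  expect_error(suppressWarnings(
    ratio_metaprofile(const_track(2), input, tss_one(100))), "no gene")
})

test_that("profiles are invariant to track row order and scaling", {
  set.seed(41)
  n <- 100
  starts <- seq(0, 99000, by = 1000)
  vals <- runif(100, 0, 5)
  tr <- data.frame(chrom = "chr1", start = starts, end = starts + 1000,
                   value = vals)
  input <- const_track(1)
  tsss <- rbind(tss_one(20000), tss_one(60000, "-", "g2"))
  p1 <- ratio_metaprofile(signal_track(tr), input, tsss, pseudocount = 0)
  p2 <- ratio_metaprofile(signal_track(tr[sample(100), ]), input, tsss,
                          pseudocount = 0)
  expect_equal(p1$bins, p2$bins)
  ## scaling both tracks leaves pseudocount-0 ratios unchanged
  p3 <- ratio_metaprofile(signal_track(within(tr, value <- value * 7)),
                          const_track(7), tsss, pseudocount = 0)
  expect_equal(p3$bins$median_ratio, p1$bins$median_ratio)
})

test_that("geneset comparison: identity, constructed fold, BH", {
  ## genes on a track with ratio 4 vs ratio 2
  tr <- signal_track(data.frame(chrom = "chr1", start = c(0, 5e4),
                                end = c(5e4, 1e5), value = c(4, 2)))
  input <- const_track(1)
  tsss <- rbind(tss_one(20000, gene = "a1"), tss_one(30000, gene = "a2"),
                tss_one(70000, gene = "b1"), tss_one(80000, gene = "b2"))
  prof <- ratio_metaprofile(tr, input, tsss, pseudocount = 0)
  cmp <- geneset_signal_compare(prof, c("a1", "a2"), c("b1", "b2"))
  expect_equal(cmp$fold, 2.0)
  same <- geneset_signal_compare(prof, c("a1", "a2"), c("a1", "a2"))
  expect_equal(same$fold, 1.0)
  expect_equal(same$p_value, 1.0)
  expect_error(geneset_signal_compare(prof, "zz", "a1"), "non-empty")
  tab <- geneset_signal_table(prof, list(
    one = list(A = c("a1", "a2"), B = c("b1", "b2")),
    two = list(A = c("a1", "a2"), B = c("a1", "a2"))))
  expect_equal(tab$p_bh, stats::p.adjust(tab$p_value, "BH"))
})

test_that("bedGraph and BED6 round-trip through files", {
  dir <- withr::local_tempdir()
  sim <- simulate_chip_tracks(chip_sim_config(chrom_length = 200000L,
                                              n_genes = 10L, noise_cv = 0.1,
                                              seed = 5), out_dir = dir)
  chip <- read_bedgraph(file.path(dir, "chip.bedGraph"))
  input <- read_bedgraph(file.path(dir, "input.bedGraph"))
  tss <- read_bed6_tss(file.path(dir, "tss.bed"))
  expect_equal(as.data.frame(chip), as.data.frame(sim$chip))
  expect_equal(tss$tss, sim$tss$tss)
  expect_equal(tss$strand, sim$tss$strand)
})
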