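test_that("log2 ratio track normalizes, recenters and drops zero coverage", {
  g <- snps(rep(50, 100), rep(50, 100))
  # identical coverage -> all zero
  tr <- log2_ratio_track(g, g)
  expect_equal(tr$raw_log2, rep(0, 100))

  # uniform 2x tumor coverage: global scaling removed
  t2 <- snps(rep(100, 100), rep(100, 100))
  expect_equal(log2_ratio_track(t2, g)$raw_log2, rep(0, 100))

  # one region at half coverage -> -1 there, 0 elsewhere
  tum_ref <- rep(50, 100); tum_ref[41:60] <- 25
  tum_alt <- rep(50, 100); tum_alt[41:60] <- 25
  tr <- log2_ratio_track(snps(tum_ref, tum_alt), g)
  expect_equal(tr$raw_log2[41:60], rep(-1, 20))
  expect_equal(tr$raw_log2[1:40], rep(0, 40))

  # recentered track has median zero
  set.seed(3)
  tum <- snps(rpois(100, 60), rpois(100, 60))
  expect_equal(median(log2_ratio_track(tum, g)$raw_log2), 0)

  # zero-coverage positions dropped with a count
  tum0 <- snps(c(0, rep(50, 99)), rep(0, 100))
  tr <- log2_ratio_track(tum0, g)
  expect_equal(nrow(tr), 99)
  expect_equal(attr(tr, "n_dropped"), 1)

  # no common positions -> empty track with warning
  expect_warning(
    empty <- log2_ratio_track(snps(50, 50, chrom = "chrX"), g),
    "no common positions")
  expect_equal(nrow(empty), 0)
})

test_that("moving average smooths within chromosomes", {
  g <- snps(rep(50, 40), rep(50, 40))
  tr <- log2_ratio_track(g, g)

  # constant track stays constant; window 1 is the identity
  tr$raw_log2 <- rep(0.7, 40)
  expect_equal(moving_average(tr, 10)$smoothed_log2, rep(0.7, 40))
  tr$raw_log2 <- rnorm(40)
  expect_equal(moving_average(tr, 1)$smoothed_log2, tr$raw_log2)

  # impulse of height 1, window 10, interior position -> 0.1
  tr$raw_log2 <- c(rep(0, 19), 1, rep(0, 20))
  sm <- moving_average(tr, 10)$smoothed_log2
  expect_equal(sm[20], 0.1)
  expect_equal(sum(sm > 0), 10)

  # linearity: smoothing commutes with scaling
  tr$raw_log2 <- rnorm(40)
  tr3 <- tr; tr3$raw_log2 <- 3 * tr$raw_log2
  expect_equal(moving_average(tr3, 7)$smoothed_log2,
               3 * moving_average(tr, 7)$smoothed_log2)

  # chromosome boundaries break windows
  two <- rbind(tr, within(tr, chrom <- "chr2"))
  two$raw_log2 <- c(rep(0, 40), rep(1, 40))
  sm2 <- moving_average(two, 10)$smoothed_log2
  expect_equal(sm2, c(rep(0, 40), rep(1, 40)))

  expect_error(moving_average(tr, 0), "window")
})

test_that("segment calling respects thresholds, run length and merging", {
  g <- snps(rep(60, 200), rep(60, 200))
  tr <- moving_average(log2_ratio_track(g, g), 10)
  expect_equal(nrow(call_segments(tr)), 0)

  # injected 50-SNP region at smoothed -1
  tr$smoothed_log2 <- rep(0, 200); tr$smoothed_log2[101:150] <- -1
  segs <- call_segments(tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$call, "deletion")
  expect_equal(segs$n_snps, 50)
  expect_equal(segs$start, tr$pos[101] - 1)
  expect_equal(segs$end, tr$pos[150])

  # 5-SNP dip below threshold with min_snps 10 -> no segment
  tr$smoothed_log2 <- rep(0, 200); tr$smoothed_log2[101:105] <- -1
  expect_equal(nrow(call_segments(tr)), 0)

  # runs separated by a 1-SNP gap merge
  tr$smoothed_log2 <- rep(0, 200)
  tr$smoothed_log2[c(101:110, 112:121)] <- 0.8
  segs <- call_segments(tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$call, "amplification")

  expect_error(call_segments(tr, del_threshold = 0.5, amp_threshold = 0.3),
               "del_threshold")
})

test_that("loci are annotated by overlapping segment calls", {
  segs <- data.frame(chrom = c("chr6", "chr6"),
                     start = c(151500000, 130000000),
                     end = c(151800000, 130450000),
                     call = c("deletion", "amplification"),
                     mean_smoothed_log2 = c(-0.8, 0.6),
                     n_snps = c(40, 30))
  loci <- load_fixture("akap_cnv")$loci
  ann <- annotate_loci(segs, loci)
  expect_equal(ann$call[ann$locus == "AKAP12"], "deletion")
  expect_equal(ann$call[ann$locus == "AKAP7"], "amplification")
  expect_equal(ann$call[ann$locus == "AKAP1"], "neutral")

  # locus spanned by both calls reports a conflict listing both
  segs2 <- rbind(segs, data.frame(chrom = "chr6", start = 151600000,
                                  end = 151700000, call = "amplification",
                                  mean_smoothed_log2 = 0.5, n_snps = 20))
  ann2 <- annotate_loci(segs2, loci)
  expect_equal(ann2$call[ann2$locus == "AKAP12"], "conflict")
  expect_equal(ann2$calls[ann2$locus == "AKAP12"],
               "amplification,deletion")
})

test_that("injected deletions are recovered from simulated coverage", {
  inj <- region_set("chr2", 0, 120000)  # 40 SNPs at 3000 bp spacing
  cs <- simulate_case(simulation_params(
    n_snps = 1000, mean_depth = 60,
    cnv_segments = data.frame(chrom = "chr2", start = 0, end = 120000,
                              copy_number = 1),
    seed = 21))
  tr <- moving_average(log2_ratio_track(cs$primary, cs$germline), 10)
  segs <- call_segments(tr)
  dels <- segs[segs$call == "deletion", , drop = FALSE]
  expect_gte(nrow(dels), 1)
  hits <- regions_overlap <- any(dels$chrom == "chr2" &
                                   dels$start < 120000 & dels$end > 0)
  expect_true(hits)
})
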