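test_that("build_positive_set maps anchors to distal/promoter regions with exclusions", {
  enh <- data.frame(chrom = "chr1", start = c(20000, 900000),
                    end = c(21000, 901000))
  prom <- data.frame(chrom = "chr1", start = 7500, end = 12500,
                     gene_id = "gA")
  ints <- data.frame(
    chrom1 = "chr1",
    start1 = c(20000, 7600, 20000, 900000),
    end1 = c(20500, 7700, 20500, 900400),
    chrom2 = "chr1",
    start2 = c(8000, 8000, 20500, 7600),
    end2 = c(8100, 8100, 20800, 7700))
  # rows: (distal, promoter) ok; (promoter, promoter); (distal, distal);
  # (distal, promoter) but ~888 kb apart -> kept (< 1 Mb)
  pos <- build_positive_set(ints, enh, prom)
  expect_equal(nrow(pos), 2)
  excl <- attr(pos, "exclusions")
  expect_equal(unname(excl["both_promoter"]), 1L)
  expect_equal(unname(excl["both_distal"]), 1L)

  # a pair spanning > 1 Mb is dropped
  enh2 <- data.frame(chrom = "chr1", start = 1600000, end = 1601000)
  ints2 <- data.frame(chrom1 = "chr1", start1 = 1600000, end1 = 1600400,
                      chrom2 = "chr1", start2 = 8000, end2 = 8100)
  pos2 <- build_positive_set(ints2, enh2, prom)
  expect_equal(nrow(pos2), 0)
  expect_equal(unname(attr(pos2, "exclusions")["too_far"]), 1L)
})

test_that("matched negatives come from the positives' distance bins", {
  pos <- data.frame(e_chrom = "chr1", e_start = c(0, 0), e_end = c(100, 100),
                    p_chrom = "chr1", p_start = c(3100, 15100),
                    p_end = c(3200, 15200), gene_id = "g",
                    distance = c(3000, 15000), label = 1L)
  cand <- data.frame(e_chrom = "chr1", e_start = 0, e_end = 100,
                     p_chrom = "chr1",
                     p_start = 100 + c(2000, 7000, 12000, 18000, 25000),
                     p_end = 200 + c(2000, 7000, 12000, 18000, 25000),
                     gene_id = "g",
                     distance = c(2000, 7000, 12000, 18000, 25000))
  neg <- sample_matched_negatives(pos, cand, ratio = 1, rng_seed = 4)
  expect_equal(nrow(neg), 2)
  expect_setequal(neg$distance %/% 10000, c(0, 1))
  expect_equal(nrow(attr(neg, "fallbacks")), 0)
})

test_that("negative distance histograms equal ratio x positive histograms", {
  sim <- small_sim()
  pos <- sim$truth$interactions[["CL1"]]
  pos$label <- 1L
  for (ratio in c(1, 2)) {
    neg <- sample_matched_negatives(pos, sim$candidates, ratio = ratio,
                                    rng_seed = 42)
    if (nrow(attr(neg, "fallbacks")) == 0) {
      expect_equal(table(neg$distance %/% 10000),
                   table(rep(pos$distance %/% 10000, ratio)),
                   ignore_attr = TRUE)
    }
    expect_equal(nrow(neg), ratio * nrow(pos))
    # disjoint from positives as pairs
    expect_length(intersect(paste(neg$e_start, neg$p_start),
                            paste(pos$e_start, pos$p_start)), 0)
  }
  # reproducibility under the seed
  n1 <- sample_matched_negatives(pos, sim$candidates, rng_seed = 42)
  n2 <- sample_matched_negatives(pos, sim$candidates, rng_seed = 42)
  expect_identical(n1, n2)
})

test_that("bin exhaustion falls back to adjacent bins and is logged", {
  pos <- data.frame(e_chrom = "chr1", e_start = 0, e_end = 100,
                    p_chrom = "chr1", p_start = 3100, p_end = 3200,
                    gene_id = "g", distance = 3000, label = 1L)
  cand <- data.frame(e_chrom = "chr1", e_start = 0, e_end = 100,
                     p_chrom = "chr1", p_start = 15100, p_end = 15200,
                     gene_id = "g", distance = 15000)
  neg <- sample_matched_negatives(pos, cand, ratio = 1, rng_seed = 1)
  expect_equal(nrow(neg), 1)
  fb <- attr(neg, "fallbacks")
  expect_equal(nrow(fb), 1)
  expect_gte(fb$radius[1], 1)
})

test_that("expression matching restricts candidates for expressed promoters", {
  pos <- data.frame(e_chrom = "chr1", e_start = 0, e_end = 100,
                    p_chrom = "chr1", p_start = 3100, p_end = 3200,
                    gene_id = "gOn", distance = 3000, label = 1L)
  cand <- data.frame(e_chrom = "chr1", e_start = c(0, 0), e_end = c(100, 100),
                     p_chrom = "chr1", p_start = c(4100, 5100),
                     p_end = c(4200, 5200), gene_id = c("gOff", "gOn2"),
                     distance = c(4000, 5000))
  expr <- c(gOn = 9.0, gOff = 0.0, gOn2 = 3.0)
  for (s in 1:5) {
    neg <- sample_matched_negatives(pos, cand, match_expression = TRUE,
                                    expression = expr, rng_seed = s)
    expect_equal(neg$gene_id, "gOn2")
  }
})

test_that("build_hic_examples enumerates loop-supported promoter-distal bin pairs", {
  chrom_lengths <- c(chr1 = 200000L)
  tss <- data.frame(gene_id = "gA", chrom = "chr1", position = 5000,
                    strand = "+")
  # one track covering the whole chromosome so no bin is featureless
  tracks <- list(CTCF = make_track("chr1", 0, 200000),
                 H3K4me3 = make_track("chr1", 0, 200000,
                                      dataset = "H3K4me3"))
  loops <- list(data.frame(chrom1 = "chr1", start1 = 0, end1 = 10000,
                           chrom2 = "chr1", start2 = 100000, end2 = 110000))
  ex <- build_hic_examples(loops, bin_size = 5000, tss = tss,
                           tracks = tracks, expression = c(gA = 4),
                           chrom_lengths = chrom_lengths, rng_seed = 2)
  pos <- ex[ex$label == 1, ]
  # TSS at 5000: bins [0,5k) and [5k,10k) are promoters (within 2500 bp);
  # far anchor contributes distal bins [100k,105k) and [105k,110k)
  expect_equal(nrow(pos), 4)
  expect_setequal(unique(pos$e_start), c(100000, 105000))
  expect_setequal(unique(pos$p_start), c(0, 5000))
  expect_equal(sum(ex$label == 0), 4)

  # a loop between two promoter-only anchors yields no positives
  loops2 <- list(data.frame(chrom1 = "chr1", start1 = 0, end1 = 5000,
                            chrom2 = "chr1", start2 = 5000, end2 = 10000))
  ex2 <- build_hic_examples(loops2, bin_size = 5000, tss = tss,
                            tracks = tracks, expression = c(gA = 4),
                            chrom_lengths = chrom_lengths, rng_seed = 2)
  expect_equal(nrow(ex2), 0)
})

test_that("hi-c positives equal exhaustive bin-pair enumeration on planted loops", {
  chrom_lengths <- c(chr1 = 500000L)
  withr::with_seed(31, {
    tss <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                      position = sort(sample(seq(5000, 495000, by = 1000), 8)),
                      strand = "+")
    anchors <- sample(seq(0, 490000, by = 5000), 40)
    loops <- list(data.frame(
      chrom1 = "chr1", start1 = anchors[1:20], end1 = anchors[1:20] + 5000,
      chrom2 = "chr1", start2 = anchors[21:40], end2 = anchors[21:40] + 5000))
  })
  tracks <- list(CTCF = make_track("chr1", 0, 500000))
  expr <- stats::setNames(rep(5, 8), tss$gene_id)
  ex <- build_hic_examples(loops, bin_size = 5000, tss = tss, tracks = tracks,
                           expression = expr, chrom_lengths = chrom_lengths,
                           rng_seed = 3)
  # oracle: brute force over all bin pairs
  bins <- tile_genome(chrom_lengths, 5000)
  kind <- classify_region(bins, tss)
  lp <- loops[[1]]
  n_expected <- 0
  for (i in seq_len(nrow(bins))) {
    for (j in seq_len(nrow(bins))) {
      if (kind[i] != "PROMOTER" || kind[j] != "DISTAL") next
      gap <- max(bins$start[j] - bins$end[i], bins$start[i] - bins$end[j], 0)
      if (gap >= 1e6) next
      hit <- any(
        (bins$start[i] < lp$end1 & bins$end[i] > lp$start1 &
           bins$start[j] < lp$end2 & bins$end[j] > lp$start2) |
        (bins$start[i] < lp$end2 & bins$end[i] > lp$start2 &
           bins$start[j] < lp$end1 & bins$end[j] > lp$start1))
      if (hit) n_expected <- n_expected + 1
    }
  }
  expect_equal(sum(ex$label == 1), n_expected)
})
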