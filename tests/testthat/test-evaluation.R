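test_that("fold enrichment arithmetic and the self-enrichment identity", {
  # direct arithmetic: (10/100)/(50/1000) = 2.0
  enh <- data.frame(chrom = "chr1", start = seq(0, 99) * 10000,
                    end = seq(0, 99) * 10000 + 1000)
  prom <- data.frame(chrom = "chr1", start = seq(0, 99) * 10000 + 5000,
                     end = seq(0, 99) * 10000 + 6000,
                     gene_id = paste0("g", 1:100))
  # experimental set: 50 interactions (enhancer i, promoter i)
  exp_i <- 1:50
  experimental <- data.frame(
    chrom1 = "chr1", start1 = enh$start[exp_i], end1 = enh$end[exp_i],
    chrom2 = "chr1", start2 = prom$start[exp_i], end2 = prom$end[exp_i])
  # predictions: 100 edges of which exactly 10 are experimental pairs
  # ((i,i) for i <= 10); the other 90 are shifted pairs (i, i+1)
  pe <- c(1:10, 1:90)
  pp <- c(1:10, 2:91)
  pred <- data.frame(
    enhancer_id = sprintf("chr1:%d-%d", enh$start[pe], enh$end[pe]),
    promoter_id = sprintf("chr1:%d-%d", prom$start[pp], prom$end[pp]))
  res <- fold_enrichment(pred, experimental, enh, prom, universe_size = 1000)
  expect_equal(res$n1, 10)
  expect_equal(res$n2, 100)
  expect_equal(res$m1, 50)
  expect_equal(res$fold, (10 / 100) / (50 / 1000))

  # predicted = experimental = universe: fold exactly 1
  pred_self <- data.frame(
    enhancer_id = sprintf("chr1:%d-%d", enh$start[exp_i], enh$end[exp_i]),
    promoter_id = sprintf("chr1:%d-%d", prom$start[exp_i], prom$end[exp_i]))
  self <- fold_enrichment(pred_self, experimental, enh, prom,
                          universe_size = 50)
  expect_equal(self$fold, 1.0)
  expect_equal(self$n1, self$n2)
  expect_error(fold_enrichment(pred[0, ], experimental, enh, prom, 100),
               "undefined")
})

test_that("fold enrichment counts match brute-force anchor overlap", {
  withr::with_seed(51, {
    enh <- data.frame(chrom = "chr1", start = sample.int(1e6, 30) + 2e6)
    enh$end <- enh$start + 800
    prom <- data.frame(chrom = "chr1", start = sample.int(1e6, 12))
    prom$end <- prom$start + 5000
    prom$gene_id <- paste0("g", 1:12)
    experimental <- data.frame(
      chrom1 = "chr1", start1 = sample(enh$start, 8) + 100,
      chrom2 = "chr1", start2 = sample(prom$start, 8) + 100)
    experimental$end1 <- experimental$start1 + 200
    experimental$end2 <- experimental$start2 + 200
  })
  mapped <- build_positive_set(experimental, enh, prom, max_distance = Inf)
  oracle_pairs <- character()
  for (k in seq_len(nrow(experimental))) {
    for (i in seq_len(nrow(enh))) {
      for (j in seq_len(nrow(prom))) {
        o1 <- experimental$start1[k] < enh$end[i] &&
          experimental$end1[k] > enh$start[i]
        o2 <- experimental$start2[k] < prom$end[j] &&
          experimental$end2[k] > prom$start[j]
        o3 <- experimental$start2[k] < enh$end[i] &&
          experimental$end2[k] > enh$start[i]
        o4 <- experimental$start1[k] < prom$end[j] &&
          experimental$end1[k] > prom$start[j]
        if ((o1 && o2) || (o3 && o4)) {
          oracle_pairs <- c(oracle_pairs, paste(i, j))
        }
      }
    }
  }
  expect_equal(nrow(mapped), length(unique(oracle_pairs)))
})

test_that("contact annotation maps anchors to midpoint bins and contrasts deciles", {
  edges <- data.frame(
    enhancer_id = "chr1:5000-6000", promoter_id = "chr1:105000-106000",
    percentile = 1.0)
  contacts <- data.frame(chrom = "chr1", bin_i = 0L, bin_j = 10L, count = 42)
  attr(contacts, "bin_size") <- 10000
  ann <- annotate_contacts(edges, contacts)
  expect_equal(ann$annotated$bin_i, 0)
  expect_equal(ann$annotated$bin_j, 10)
  expect_equal(ann$annotated$count, 42)

  # identical top and bottom distributions: KS statistic 0
  edges2 <- data.frame(
    enhancer_id = sprintf("chr1:%d-%d", 0:19 * 10000 + 1000, 0:19 * 10000 + 2000),
    promoter_id = sprintf("chr1:%d-%d", 0:19 * 10000 + 201000, 0:19 * 10000 + 202000),
    percentile = rep(c(0.05, 0.95), 10))
  contacts2 <- data.frame(chrom = "chr1", bin_i = 0:19, bin_j = 20:39,
                          count = 7)
  attr(contacts2, "bin_size") <- 10000
  ann2 <- annotate_contacts(edges2, contacts2)
  expect_equal(unname(ann2$ks$statistic), 0)
})

test_that("region ON/OFF status matches its boolean definition exhaustively", {
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (r in seq_len(nrow(combos))) {
    e_sig <- c(DNase = combos$a[r], H3K27ac = combos$b[r],
               H3K9ac = combos$c[r])
    expect_equal(region_on_status("ENHANCER", e_sig),
                 if (any(e_sig == 1)) "ON" else "OFF")
    p_sig <- c(H3K4me3 = combos$a[r], DNase = combos$b[r],
               H3K27me3 = combos$c[r])
    expect_equal(region_on_status("PROMOTER", p_sig),
                 if ((combos$a[r] || combos$b[r]) && !combos$c[r]) "ON"
                 else "OFF")
  }
  expect_equal(region_on_status("PROMOTER",
                                c(DNase = 1, H3K4me3 = 0, H3K27me3 = 1)),
               "OFF")
  expect_error(region_on_status("ENHANCER", c(DNase = 1)), "H3K27ac")
})

test_that("pairwise categorization assigns SHARED and ON/OFF classes", {
  ids <- paste0("p", 1:6)
  e_ids <- sprintf("chr1:%d-%d", 1:6 * 1000, 1:6 * 1000 + 500)
  p_ids <- sprintf("chr1:%d-%d", 1:6 * 100000, 1:6 * 100000 + 5000)
  mk_net <- function(score) {
    structure(list(edges = data.frame(
      pair_id = ids, enhancer_id = e_ids, promoter_id = p_ids,
      gene_id = "g", score = score,
      percentile = rank(score) / length(score))), class = "ScoredNetwork")
  }
  net_A <- mk_net(c(0.95, 0.9, 0.92, 0.2, 0.3, 0.96))
  net_B <- mk_net(c(0.9, 0.1, 0.2, 0.9, 0.2, 0.3))
  sig <- matrix(0, 12, 5,
                dimnames = list(c(e_ids, p_ids),
                                c("DNase", "H3K27ac", "H3K9ac", "H3K4me3",
                                  "H3K27me3")))
  sig[e_ids[2], "DNase"] <- 1    # enhancer ON
  sig[p_ids[2], "H3K4me3"] <- 1  # promoter ON
  sig[p_ids[3], "H3K4me3"] <- 1  # promoter ON, enhancer OFF
  out <- categorize_pairwise(net_A, net_B, sig, use_probability = TRUE)
  expect_setequal(out$pair_id, c("p1", "p2", "p3", "p6"))
  expect_equal(out$category[out$pair_id == "p1"], "SHARED")
  expect_equal(out$category[out$pair_id == "p2"], "BOTH_ON")
  expect_equal(out$category[out$pair_id == "p3"], "ENH_OFF_PROM_ON")
  expect_equal(out$category[out$pair_id == "p6"], "BOTH_OFF")
})

test_that("categorization partitions A-specific edges per a brute-force oracle", {
  withr::with_seed(61, {
    n <- 120
    ids <- paste0("p", seq_len(n))
    e_ids <- sprintf("chr1:%d-%d", 1:n * 1000, 1:n * 1000 + 500)
    p_ids <- sprintf("chr1:%d-%d", 1:n * 100000, 1:n * 100000 + 5000)
    sA <- runif(n); sB <- runif(n)
    sig <- matrix(rbinom(2 * n * 5, 1, 0.4), 2 * n, 5,
                  dimnames = list(c(e_ids, p_ids),
                                  c("DNase", "H3K27ac", "H3K9ac", "H3K4me3",
                                    "H3K27me3")))
  })
  mk_net <- function(score) {
    structure(list(edges = data.frame(
      pair_id = ids, enhancer_id = e_ids, promoter_id = p_ids, gene_id = "g",
      score = score, percentile = rank(score) / length(score))),
      class = "ScoredNetwork")
  }
  net_A <- mk_net(sA); net_B <- mk_net(sB)
  out <- categorize_pairwise(net_A, net_B, sig, high = 0.9, low = 0.8)
  pct_A <- rank(sA) / n; pct_B <- rank(sB) / n
  oracle <- character(0)
  for (i in which(pct_A > 0.9)) {
    oracle[[as.character(i)]] <- if (pct_B[i] > 0.9) "SHARED"
    else if (pct_B[i] > 0.8) "AMBIGUOUS"
    else {
      e_on <- sum(sig[e_ids[i], c("DNase", "H3K27ac", "H3K9ac")]) > 0
      p_on <- (sig[p_ids[i], "H3K4me3"] > 0 || sig[p_ids[i], "DNase"] > 0) &&
        sig[p_ids[i], "H3K27me3"] == 0
      if (e_on && p_on) "BOTH_ON" else if (!e_on && p_on) "ENH_OFF_PROM_ON"
      else if (e_on && !p_on) "ENH_ON_PROM_OFF" else "BOTH_OFF"
    }
  }
  expect_equal(nrow(out), length(oracle))
  m <- match(out$pair_id, paste0("p", names(oracle)))
  expect_equal(out$category, unname(unlist(oracle))[m])
  spec_cats <- c("BOTH_OFF", "ENH_OFF_PROM_ON", "ENH_ON_PROM_OFF", "BOTH_ON")
  n_specific <- sum(out$category %in% spec_cats)
  expect_equal(n_specific, sum(table(out$category[out$category %in% spec_cats])))
})

test_that("per-category F-scores follow the confusion-table formula", {
  ref <- c(a = "X", b = "X", c = "Y", d = "Z")
  idn <- category_fscore(ref, ref)
  expect_true(all(idn$f_score == 1))
  pred <- c(a = "X", b = "Y", c = "Y", d = "Y")
  fs <- category_fscore(pred, ref)
  # X: TP=1 FP=0 FN=1 -> P=1, R=0.5, F=2/3; Z: no predictions -> F=0
  expect_equal(fs$f_score[fs$category == "X"], 2 / 3)
  expect_equal(fs$f_score[fs$category == "Z"], 0)
  y_tab <- fs[fs$category == "Y", ]
  expect_equal(y_tab$precision, 1 / 3)
  expect_equal(y_tab$recall, 1)
})
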