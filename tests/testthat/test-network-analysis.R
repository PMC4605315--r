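test_that("k-means recovers well-separated clouds and honors the restart contract", {
  withr::with_seed(41, {
    X <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 5, 0.1), 20, 2),
               matrix(rnorm(40, 10, 0.1), 20, 2))
    rownames(X) <- paste0("n", 1:60)
  })
  cl <- kmeans_cluster(X, K = 3, rng_seed = 1)
  truth <- rep(1:3, each = 20)
  # same partition up to label permutation
  expect_equal(length(unique(paste(cl$cluster, truth))), 3)

  # identical points, K = 1: zero inertia
  X0 <- matrix(1, 10, 3, dimnames = list(paste0("n", 1:10), NULL))
  expect_equal(kmeans_cluster(X0, K = 1, rng_seed = 1)$inertia, 0)
  expect_error(kmeans_cluster(X0, K = 2), "distinct")

  # best-of-restarts inertia is no worse than any single restart
  withr::with_seed(42, {
    Y <- matrix(runif(200), 50, 4, dimnames = list(paste0("n", 1:50), NULL))
  })
  best <- kmeans_cluster(Y, K = 5, restarts = 10, rng_seed = 3)$inertia
  singles <- vapply(1:10, function(s)
    kmeans_cluster(Y, K = 5, restarts = 1, rng_seed = s)$inertia, 0.0)
  expect_lte(best, min(singles) + 1e-9)
})

test_that("cluster matching recovers permutations exactly and resists noise", {
  withr::with_seed(45, {
    C <- matrix(runif(25, 0, 10), 5, 5)
  })
  a_ref <- structure(list(centroids = C, cluster = NULL),
                     class = "ClusterAssignment")
  perm <- c(3, 1, 4, 5, 2)
  a_perm <- structure(list(centroids = C[perm, ],
                           cluster = stats::setNames(1:5, paste0("n", 1:5))),
                      class = "ClusterAssignment")
  out <- match_clusters_across_cell_lines(list(ref = a_ref, p = a_perm))
  expect_equal(unname(out$maps$ref), 1:5)       # identity for the reference
  expect_equal(unname(out$maps$p), perm)        # inverse permutation recovered
  # small perturbation leaves the matching unchanged
  withr::with_seed(46, {
    a_noisy <- a_perm
    a_noisy$centroids <- a_noisy$centroids + matrix(rnorm(25, 0, 0.01), 5, 5)
  })
  out2 <- match_clusters_across_cell_lines(list(ref = a_ref, p = a_noisy))
  expect_equal(out2$maps$p, out$maps$p)
  expect_error(match_clusters_across_cell_lines(list(
    a_ref, structure(list(centroids = C[1:4, ]), class = "ClusterAssignment"))),
    "differing K")
})

test_that("cluster-pair enrichment reproduces the fold formula and exact hypergeometric", {
  # direct arithmetic instance: p=5, n=10, m=100, T=1000 -> fold 5.0
  # construct edges: 1000 total; enhancer cluster 1 emits 100; promoter
  # cluster 1 receives 10; overlap 5
  ec <- stats::setNames(c(rep(1, 100), rep(2, 900)), paste0("e", 1:1000))
  pc <- stats::setNames(c(rep(1, 10), rep(2, 990)), paste0("p", 1:1000))
  # edge i connects e_i to p_i; arrange overlap of 5
  e_ids <- paste0("e", c(1:100, 101:1000))
  p_ids <- paste0("p", c(1:5, 16:110, 111:1000, 6:15))
  edges <- data.frame(enhancer_id = e_ids, promoter_id = p_ids)
  tab <- cluster_pair_enrichment(edges, ec, pc)
  row <- tab[tab$ec == 1 & tab$pc == 1, ]
  expect_equal(row$p, 5)
  expect_equal(row$fold, (5 / 10) / (100 / 1000))
  expect_equal(row$p_value,
               stats::phyper(4, 100, 900, 10, lower.tail = FALSE))
  # row sums: interactions from EC_i across PC_j equal m; totals equal T
  for (i in unique(ec)) {
    expect_equal(sum(tab$p[tab$ec == i]), unique(tab$m[tab$ec == i]))
  }
  expect_equal(sum(tab$p), nrow(edges))

  # exact pmf summation on a small instance (T = 20)
  withr::with_seed(47, {
    ec2 <- stats::setNames(sample(1:2, 20, TRUE), paste0("e", 1:20))
    pc2 <- stats::setNames(sample(1:2, 20, TRUE), paste0("p", 1:20))
  })
  edges2 <- data.frame(enhancer_id = names(ec2), promoter_id = names(pc2))
  tab2 <- cluster_pair_enrichment(edges2, ec2, pc2)
  for (r in seq_len(nrow(tab2))) {
    ks <- tab2$p[r]:min(tab2$n[r], tab2$m[r])
    exact <- sum(stats::dhyper(ks, tab2$m[r], tab2$T[r] - tab2$m[r], tab2$n[r]))
    expect_equal(tab2$p_value[r], exact, tolerance = 1e-12)
  }
})

test_that("edges distributed proportionally to cluster sizes give folds of 1", {
  ec <- stats::setNames(rep(1:2, each = 50), paste0("e", 1:100))
  # every enhancer connects to one promoter of each cluster
  edges <- data.frame(
    enhancer_id = rep(names(ec), 2),
    promoter_id = c(paste0("pA", 1:100), paste0("pB", 1:100)))
  pc <- stats::setNames(rep(1:2, each = 100),
                        c(paste0("pA", 1:100), paste0("pB", 1:100)))
  tab <- cluster_pair_enrichment(edges, ec, pc)
  expect_true(all(abs(tab$fold - 1) < 1e-12))
})

test_that("component taxonomy classifies and matches the BFS oracle", {
  expect_equal(component_taxonomy(data.frame(
    enhancer_id = "e1", promoter_id = "p1"))$components$class, "SINGLE")
  expect_equal(component_taxonomy(data.frame(
    enhancer_id = c("e1", "e2"),
    promoter_id = c("p1", "p1")))$components$class, "MI")
  expect_equal(component_taxonomy(data.frame(
    enhancer_id = c("e1", "e1"),
    promoter_id = c("p1", "p2")))$components$class, "MO")

  withr::with_seed(52, {
    for (g in 1:30) {
      edges <- unique(data.frame(
        enhancer_id = paste0("e", sample.int(12, 25, TRUE)),
        promoter_id = paste0("p", sample.int(12, 25, TRUE))))
      tax <- component_taxonomy(edges)
      oracle <- bfs_taxonomy(edges)
      expect_equal(table(tax$components$class), oracle$class_counts,
                   ignore_attr = TRUE)
      # per-class edge counts sum to the total
      expect_equal(sum(tax$edge_class_counts), nrow(edges))
      expect_equal(as.vector(tax$edge_class_counts[
        names(oracle$edge_class_counts)]),
        as.vector(oracle$edge_class_counts))
    }
  })
})

test_that("gene-set enrichment applies the exact hypergeometric and BH correction", {
  universe <- paste0("g", 1:40)
  annotation <- list(termA = paste0("g", 1:8), termB = paste0("g", 30:40))
  res <- geneset_enrichment(paste0("g", 1:8), annotation, universe)
  rowA <- res[res$term == "termA", ]
  expect_equal(rowA$p_value,
               stats::phyper(7, 8, 32, 8, lower.tail = FALSE))
  expect_true(rowA$significant)
  # disjoint term: overlap 0 -> upper tail includes 0, raw p = 1
  expect_equal(res$p_value[res$term == "termB"], 1)
  expect_error(geneset_enrichment("g1", annotation, character()), "universe")
})

test_that("BH correction in enrichment reproduces the step-up procedure", {
  # three terms engineered so the raw p-values are distinct; the adjusted
  # values must equal the hand-worked step-up: p_(i) * m / i capped by the
  # running minimum from the largest p down
  universe <- paste0("g", 1:30)
  annotation <- list(t1 = paste0("g", 1:6), t2 = paste0("g", 1:12),
                     t3 = paste0("g", 25:30))
  res <- geneset_enrichment(paste0("g", 1:6), annotation, universe)
  p <- res$p_value
  m <- length(p)
  hand <- rev(cummin(rev(p[order(p)] * m / seq_len(m))))[order(order(p))]
  expect_equal(res$adj_p, pmin(hand, 1))
})

test_that("read_gmt parses term records", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("termA\tdesc\tg1\tg2\tg3", "termB\tdesc\tg9"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$termA, c("g1", "g2", "g3"))
  expect_equal(sets$termB, "g9")
})
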