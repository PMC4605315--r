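# Characterization of high-confidence networks: K-means signal clusters,
# cross-cell-line cluster matching, cluster-pair interaction enrichment,
# connected-component taxonomy, and generic hypergeometric gene-set
# enrichment with Benjamini-Hochberg correction.

#' Best-of-restarts K-means clustering of region feature vectors
#'
#' Lloyd's algorithm with `restarts` seed-controlled restarts (initial
#' centers drawn from distinct data vectors); the restart with minimal
#' total within-cluster squared Euclidean distance is returned.
#'
#' @param vectors numeric matrix (regions x features), row names are node
#'   ids.
#' @param K number of clusters (default 5).
#' @param restarts restarts (default 10).
#' @param rng_seed integer seed.
#' @return A `ClusterAssignment`: `cluster` (named vector of 1..K),
#'   `centroids`, `inertia`, `restarts_used`.
#' @export
kmeans_cluster <- function(vectors, K = 5, restarts = 10, rng_seed = 1L) {
  vectors <- as.matrix(vectors)
  distinct <- vectors[!duplicated(vectors), , drop = FALSE]
  if (K > nrow(distinct)) {
    stop("K exceeds the number of distinct vectors", call. = FALSE)
  }
  best <- NULL
  .with_seed(rng_seed, {
    r <- 0L
    while (r < restarts) {
      centers <- distinct[sample.int(nrow(distinct), K), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(vectors, centers = centers,
                                       iter.max = 100, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next  # degenerate start (e.g. emptied cluster): redraw
      r <- r + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(cluster = stats::setNames(best$cluster, rownames(vectors)),
                 centroids = best$centers, inertia = best$tot.withinss,
                 restarts_used = restarts),
            class = "ClusterAssignment")
}

.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(n - 1)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Match cluster labels across cell lines
#'
#' Finds, for each non-reference cell line, the one-to-one centroid
#' matching to the reference cell line minimizing the total Euclidean
#' distance between matched centroids, solved exactly by enumeration over
#' all K! matchings (K <= 8). Returns relabeling maps so cluster i has as
#' close as possible a signal pattern in every cell line.
#'
#' @param assignments named list of `ClusterAssignment`s with equal K and a
#'   shared feature panel.
#' @param reference index or name of the reference cell line (default 1).
#' @return Named list of integer maps `map` (old label -> new label, i.e.
#'   reference label) per cell line, along with relabeled assignments in
#'   `relabeled`.
#' @export
match_clusters_across_cell_lines <- function(assignments, reference = 1) {
  Ks <- vapply(assignments, function(a) nrow(a$centroids), 0L)
  if (length(unique(Ks)) != 1) stop("differing K across cell lines", call. = FALSE)
  K <- Ks[1]
  stopifnot(K <= 8)
  ref <- assignments[[reference]]$centroids
  perms <- .permutations(K)
  maps <- lapply(assignments, function(a) {
    cost <- vapply(perms, function(pm) {
      sum(vapply(seq_len(K), function(i) {
        sqrt(sum((a$centroids[i, ] - ref[pm[i], ])^2))
      }, 0.0))
    }, 0.0)
    pm <- perms[[which.min(cost)]]
    stats::setNames(pm, seq_len(K))  # old label i -> reference label pm[i]
  })
  relabeled <- mapply(function(a, map) {
    a$cluster <- stats::setNames(map[a$cluster], names(a$cluster))
    a$centroids <- a$centroids[order(map), , drop = FALSE]
    rownames(a$centroids) <- NULL
    a
  }, assignments, maps, SIMPLIFY = FALSE)
  list(maps = maps, relabeled = relabeled)
}

#' Enhancer-cluster x promoter-cluster interaction enrichment
#'
#' For each (enhancer cluster EC_i, promoter cluster PC_j): with T total
#' interactions, m interactions leaving EC_i, n interactions associated
#' with PC_j, and p interactions from EC_i to PC_j, fold enrichment is
#' `(p/n)/(m/T)` and the p-value is the upper-tail hypergeometric
#' probability of observing p or more of n draws from a population of T
#' with m successes.
#'
#' @param edges data.frame with `enhancer_id`, `promoter_id`.
#' @param ec,pc named cluster assignments (node id -> cluster).
#' @return data.frame: `ec`, `pc`, `p`, `n`, `m`, `T`, `fold`, `p_value`
#'   (`fold` is NA, flagged, for empty clusters).
#' @export
cluster_pair_enrichment <- function(edges, ec, pc) {
  e_cl <- ec[edges$enhancer_id]
  p_cl <- pc[edges$promoter_id]
  if (any(is.na(e_cl)) || any(is.na(p_cl))) {
    stop("every edge endpoint must have a cluster assignment", call. = FALSE)
  }
  Tn <- nrow(edges)
  rows <- list()
  for (i in sort(unique(ec))) {
    for (j in sort(unique(pc))) {
      m <- sum(e_cl == i)
      n <- sum(p_cl == j)
      p <- sum(e_cl == i & p_cl == j)
      empty <- m == 0 || n == 0
      rows[[length(rows) + 1L]] <- data.frame(
        ec = i, pc = j, p = p, n = n, m = m, T = Tn,
        fold = if (empty) NA_real_ else (p / n) / (m / Tn),
        p_value = stats::phyper(p - 1, m, Tn - m, n, lower.tail = FALSE),
        empty = empty
      )
    }
  }
  do.call(rbind, rows)
}

#' Connected-component taxonomy of a bipartite interaction network
#'
#' Components are classified by their enhancer and promoter counts:
#' (1,1) SINGLE, (>1,1) MI (multi-input), (1,>1) MO (multi-output),
#' (>1,>1) MIMO. Also reports enhancer out-degrees (genes per enhancer) and
#' promoter in-degrees (enhancers per promoter).
#'
#' @param edges data.frame with `enhancer_id`, `promoter_id` and optionally
#'   `gene_id`.
#' @return List: `components` (data.frame: `component`, `n_enhancers`,
#'   `n_promoters`, `n_edges`, `class`, `genes`), `membership` (data.frame
#'   node/kind/component), `mean_out_degree`, `mean_in_degree`,
#'   `edge_class_counts`.
#' @export
component_taxonomy <- function(edges) {
  enh <- unique(edges$enhancer_id)
  prom <- unique(edges$promoter_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("E|", edges$enhancer_id),
               to = paste0("P|", edges$promoter_id)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  nodes <- names(comp)
  kind <- ifelse(startsWith(nodes, "E|"), "enhancer", "promoter")
  id <- sub("^[EP]\\|", "", nodes)
  membership <- data.frame(node_id = id, node_kind = kind,
                           component = as.integer(comp))
  edge_comp <- comp[paste0("E|", edges$enhancer_id)]
  comp_rows <- lapply(sort(unique(as.integer(comp))), function(cid) {
    ne <- sum(kind == "enhancer" & comp == cid)
    np <- sum(kind == "promoter" & comp == cid)
    cls <- if (ne == 1 && np == 1) "SINGLE"
      else if (ne > 1 && np == 1) "MI"
      else if (ne == 1 && np > 1) "MO"
      else "MIMO"
    genes <- if (!is.null(edges$gene_id)) {
      paste(sort(unique(unlist(strsplit(
        as.character(edges$gene_id[edge_comp == cid]), ",")))), collapse = ",")
    } else NA_character_
    data.frame(component = cid, n_enhancers = ne, n_promoters = np,
               n_edges = sum(edge_comp == cid), class = cls, genes = genes)
  })
  components <- do.call(rbind, comp_rows)
  out_deg <- table(edges$enhancer_id)
  in_deg <- table(edges$promoter_id)
  cls_of_edge <- components$class[match(edge_comp, components$component)]
  list(components = components, membership = membership,
       mean_out_degree = mean(as.integer(out_deg)),
       mean_in_degree = mean(as.integer(in_deg)),
       edge_class_counts = table(cls_of_edge))
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (term, description, genes...).
#' @return Named list of gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t")
  stats::setNames(lapply(f, function(x) unique(x[-(1:2)])),
                  vapply(f, `[`, "", 1))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each annotation term, the upper-tail hypergeometric p-value of the
#' overlap between the query set and the term's genes within the universe;
#' Benjamini-Hochberg correction across terms; terms with corrected
#' p < `alpha` flagged.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param annotation named list of term gene sets.
#' @param universe character vector of all genes.
#' @param alpha significance level (default 0.05).
#' @return data.frame: `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`, `adj_p`, `significant`.
#' @export
geneset_enrichment <- function(query, annotation, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe", call. = FALSE)
  stopifnot(all(query %in% universe))
  query <- unique(query)
  N <- length(unique(universe))
  rows <- lapply(names(annotation), function(term) {
    gs <- intersect(annotation[[term]], universe)
    ov <- length(intersect(query, gs))
    p <- stats::phyper(ov - 1, length(gs), N - length(gs), length(query),
                       lower.tail = FALSE)
    data.frame(term = term, overlap = ov, term_size = length(gs),
               query_size = length(query), universe_size = N, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adj_p < alpha
  out[order(out$p_value), ]
}
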