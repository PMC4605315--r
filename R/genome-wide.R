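# Genome-wide maps: candidate pair enumeration over universal region sets,
# ensemble scoring, and percentile thresholding to high-confidence
# cell-line-specific networks.

#' Enumerate candidate enhancer-promoter pairs
#'
#' All same-chromosome (enhancer, promoter) pairs whose gap between closest
#' edges is strictly less than `max_distance`. Enumeration is per
#' chromosome; cross-chromosome pairs are never materialized. With
#' `feature_vectors` given, regions whose feature rows are all zero are
#' dropped first.
#'
#' @param enhancers,promoters region data.frames (`promoters` may carry
#'   `gene_id`).
#' @param max_distance maximum gap in bp (default 1e6).
#' @param feature_vectors optional region-id-named matrix used for the
#'   featureless filter.
#' @return data.frame of candidate pairs (`e_*`, `p_*`, `gene_id`,
#'   `distance`).
#' @export
enumerate_candidates <- function(enhancers, promoters, max_distance = 1e6,
                                 feature_vectors = NULL) {
  .check_regions(enhancers); .check_regions(promoters)
  if (!is.null(feature_vectors)) {
    ok <- rownames(feature_vectors)[rowSums(abs(feature_vectors)) > 0]
    enhancers <- enhancers[.region_id(enhancers) %in% ok, , drop = FALSE]
    promoters <- promoters[.region_id(promoters) %in% ok, , drop = FALSE]
  }
  out <- vector("list", 0)
  for (chr in intersect(unique(enhancers$chrom), unique(promoters$chrom))) {
    E <- enhancers[enhancers$chrom == chr, , drop = FALSE]
    P <- promoters[promoters$chrom == chr, , drop = FALSE]
    E <- E[order(E$start), , drop = FALSE]
    P <- P[order(P$start), , drop = FALSE]
    # windowed sweep: promoters with start < e_end + max_distance and
    # end > e_start - max_distance
    for (i in seq_len(nrow(E))) {
      j <- which(P$start < E$end[i] + max_distance &
                 P$end > E$start[i] - max_distance)
      if (!length(j)) next
      d <- .interval_gap(E$start[i], E$end[i], P$start[j], P$end[j])
      j <- j[d < max_distance]
      if (!length(j)) next
      out[[length(out) + 1L]] <- data.frame(
        e_chrom = chr, e_start = E$start[i], e_end = E$end[i],
        p_chrom = chr, p_start = P$start[j], p_end = P$end[j],
        gene_id = P$gene_id[j] %||% NA_character_,
        distance = .interval_gap(E$start[i], E$end[i], P$start[j], P$end[j])
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(e_chrom = character(), e_start = integer(), e_end = integer(),
               p_chrom = character(), p_start = integer(), p_end = integer(),
               gene_id = character(), distance = numeric())
  rownames(res) <- NULL
  res
}

#' Score a candidate network with an ensemble of classifiers
#'
#' Each encoded pair is scored by every classifier; the per-classifier
#' probabilities are combined by the chosen method, and every edge gets a
#' percentile rank of its combined score within this run (average ranks for
#' ties, maximum 1), which is the scale the high-confidence threshold is
#' applied on.
#'
#' @param examples encoded pair data.frame (the target cell line's
#'   signals).
#' @param classifiers list of `TrainedModel`s (K >= 1).
#' @param method `"PERCENTILE"`, `"SML"`, or `"SINGLE"` (first classifier
#'   alone).
#' @param cell_line name recorded on the network.
#' @return A `ScoredNetwork`: list with `edges` (pair table plus `score`,
#'   `percentile`), `cell_line`, `method`, and the raw probability matrix
#'   `P`.
#' @export
score_network <- function(examples, classifiers, method = c("PERCENTILE", "SML",
                                                            "SINGLE"),
                          cell_line = NA_character_) {
  method <- match.arg(method)
  P <- vapply(classifiers, function(m) predict_prob(m, examples),
              numeric(nrow(examples)))
  P <- matrix(P, nrow = nrow(examples))
  colnames(P) <- names(classifiers) %||%
    paste0("classifier", seq_along(classifiers))
  score <- switch(method,
    PERCENTILE = percentile_ensemble(P)$scores,
    SML = sml_ensemble(P)$scores,
    SINGLE = P[, 1]
  )
  edges <- data.frame(
    pair_id = examples$pair_id,
    enhancer_id = .region_id(data.frame(chrom = examples$e_chrom,
                                        start = examples$e_start,
                                        end = examples$e_end)),
    promoter_id = .region_id(data.frame(chrom = examples$p_chrom,
                                        start = examples$p_start,
                                        end = examples$p_end)),
    gene_id = examples$gene_id,
    score = score,
    percentile = rank(score, ties.method = "average") / length(score)
  )
  structure(list(edges = edges, cell_line = cell_line, method = method, P = P),
            class = "ScoredNetwork")
}

#' @export
print.ScoredNetwork <- function(x, ...) {
  cat(sprintf("ScoredNetwork [%s, %s]: %d edges\n",
              x$cell_line, x$method, nrow(x$edges)))
  invisible(x)
}

#' Threshold a scored network to its high-confidence subset
#'
#' Retains edges with percentile rank strictly above `high`.
#'
#' @param net a `ScoredNetwork`.
#' @param high percentile cutoff (default 0.90).
#' @return A `ScoredNetwork` restricted to the retained edges.
#' @export
threshold_network <- function(net, high = 0.90) {
  keep <- net$edges$percentile > high
  structure(list(edges = net$edges[keep, , drop = FALSE],
                 cell_line = net$cell_line, method = net$method,
                 P = net$P[keep, , drop = FALSE]),
            class = "ScoredNetwork")
}

#' Query a scored network by region or gene
#'
#' @param net a `ScoredNetwork`.
#' @param gene optional gene id (matches any of a promoter's genes).
#' @param chrom,start,end optional region; edges whose enhancer or promoter
#'   overlaps it are returned.
#' @return The matching edge rows.
#' @export
query_network <- function(net, gene = NULL, chrom = NULL, start = NULL,
                          end = NULL) {
  edges <- net$edges
  keep <- rep(TRUE, nrow(edges))
  if (!is.null(gene)) {
    keep <- keep & vapply(strsplit(as.character(edges$gene_id), ","),
                          function(g) gene %in% g, TRUE)
  }
  if (!is.null(chrom)) {
    parse_locus <- function(id) {
      m <- regmatches(id, regexec("^(.+):(\\d+)-(\\d+)$", id))
      t(vapply(m, function(x) x[2:4], character(3)))
    }
    overlaps <- function(ids) {
      loc <- parse_locus(ids)
      loc[, 1] == chrom & as.integer(loc[, 2]) < end & as.integer(loc[, 3]) > start
    }
    keep <- keep & (overlaps(edges$enhancer_id) | overlaps(edges$promoter_id))
  }
  edges[keep, , drop = FALSE]
}
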