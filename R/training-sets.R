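# Labeled example construction: mapping measured interactions onto
# enhancer/promoter regions, distance-matched (optionally
# expression-matched) negative sampling, and the binned Hi-C-style variant.

# Map anchors of interactions onto region sets; returns index pairs.
.map_anchor <- function(anchors, regions) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(.regions_gr(anchors), .regions_gr(regions),
                                minoverlap = 1L))
  split(S4Vectors::subjectHits(hits), factor(S4Vectors::queryHits(hits),
                                             levels = seq_len(nrow(anchors))))
}

#' Build the positive pair set from measured interactions
#'
#' Each retained interaction maps one anchor onto a distal (enhancer) region
#' and the other onto a promoter region by >= 1 bp overlap, in either anchor
#' orientation. Interactions whose anchors both map to promoters, both to
#' distal regions, or fail to map, and pairs farther apart than
#' `max_distance`, are excluded and counted.
#'
#' @param interactions BEDPE-like data.frame (`chrom1`..`end2`).
#' @param enhancers,promoters region data.frames; `promoters` carries
#'   `gene_id`.
#' @param max_distance maximum pair gap in bp (default 1e6).
#' @param feature_vectors optional matrix of region feature vectors (rows
#'   named by region id); regions with all-zero rows are dropped when given.
#' @return data.frame of positive pairs (`e_*`, `p_*`, `gene_id`,
#'   `distance`, `label = 1`) with attribute `exclusions`, a named count
#'   vector.
#' @export
build_positive_set <- function(interactions, enhancers, promoters,
                               max_distance = 1e6, feature_vectors = NULL) {
  if (!is.null(feature_vectors)) {
    ok_ids <- rownames(feature_vectors)[rowSums(abs(feature_vectors)) > 0]
    enhancers <- enhancers[.region_id(enhancers) %in% ok_ids, , drop = FALSE]
    promoters <- promoters[.region_id(promoters) %in% ok_ids, , drop = FALSE]
  }
  a1 <- data.frame(chrom = interactions$chrom1, start = interactions$start1,
                   end = interactions$end1)
  a2 <- data.frame(chrom = interactions$chrom2, start = interactions$start2,
                   end = interactions$end2)
  e1 <- .map_anchor(a1, enhancers); p1 <- .map_anchor(a1, promoters)
  e2 <- .map_anchor(a2, enhancers); p2 <- .map_anchor(a2, promoters)

  excl <- c(unmapped = 0L, both_promoter = 0L, both_distal = 0L,
            too_far = 0L)
  rows <- vector("list", nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    combos <- rbind(
      if (length(e1[[i]]) && length(p2[[i]]))
        expand.grid(e = e1[[i]], p = p2[[i]]),
      if (length(e2[[i]]) && length(p1[[i]]))
        expand.grid(e = e2[[i]], p = p1[[i]])
    )
    if (is.null(combos) || !nrow(combos)) {
      has_p <- length(p1[[i]]) && length(p2[[i]])
      has_e <- length(e1[[i]]) && length(e2[[i]])
      if (has_p) excl["both_promoter"] <- excl["both_promoter"] + 1L
      else if (has_e) excl["both_distal"] <- excl["both_distal"] + 1L
      else excl["unmapped"] <- excl["unmapped"] + 1L
      next
    }
    combos <- unique(combos)
    d <- .interval_gap(enhancers$start[combos$e], enhancers$end[combos$e],
                       promoters$start[combos$p], promoters$end[combos$p])
    keep <- d <= max_distance
    if (!any(keep)) { excl["too_far"] <- excl["too_far"] + 1L; next }
    combos <- combos[keep, , drop = FALSE]
    rows[[i]] <- data.frame(
      e_chrom = enhancers$chrom[combos$e], e_start = enhancers$start[combos$e],
      e_end = enhancers$end[combos$e],
      p_chrom = promoters$chrom[combos$p], p_start = promoters$start[combos$p],
      p_end = promoters$end[combos$p],
      gene_id = promoters$gene_id[combos$p] %||% NA_character_,
      distance = d[keep]
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(e_chrom = character(), e_start = integer(),
                      e_end = integer(), p_chrom = character(),
                      p_start = integer(), p_end = integer(),
                      gene_id = character(), distance = numeric())
  }
  out <- unique(out)
  out$label <- if (nrow(out)) 1L else integer()
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

.pair_key <- function(df) {
  paste(df$e_chrom, df$e_start, df$e_end, df$p_chrom, df$p_start, df$p_end,
        sep = ":")
}

#' Sample distance-matched negative pairs
#'
#' Pairs are binned by genomic distance into `bin_width` bins. For each
#' positive in bin b, `ratio` negatives are drawn uniformly at random
#' without replacement from the candidate pairs of the same bin, so the
#' per-bin distance histogram of negatives equals `ratio` times that of the
#' positives. When a bin is exhausted, the search expands symmetrically to
#' adjacent bins and each such event is recorded. With
#' `match_expression = TRUE`, a positive whose promoter gene has RPKM > 0 is
#' matched only against candidates whose promoter gene also has RPKM > 0.
#'
#' @param positives positive pair data.frame with a `distance` column (and
#'   `gene_id` if expression matching is on).
#' @param candidates candidate pair data.frame (same columns); positives are
#'   removed from it internally.
#' @param ratio negatives per positive (1 or 10 in the original protocol).
#' @param bin_width distance bin width in bp (default 10000).
#' @param match_expression logical; requires `expression`.
#' @param expression named RPKM vector (needed when `match_expression`).
#' @param rng_seed integer seed; sampling is reproducible given it.
#' @return data.frame of negatives (`label = 0`) with attribute `fallbacks`
#'   (data.frame of positives whose bin was exhausted and the bin radius
#'   used).
#' @export
sample_matched_negatives <- function(positives, candidates, ratio = 1,
                                     bin_width = 10000,
                                     match_expression = FALSE,
                                     expression = NULL, rng_seed = 1L) {
  stopifnot(nrow(positives) >= 1)
  if (match_expression && is.null(expression)) {
    stop("expression table required when match_expression = TRUE", call. = FALSE)
  }
  candidates <- candidates[!(.pair_key(candidates) %in% .pair_key(positives)), ,
                           drop = FALSE]
  pos_bin <- positives$distance %/% bin_width
  cand_bin <- candidates$distance %/% bin_width
  gene_expr <- function(df) {
    if (is.null(expression)) return(rep(NA_real_, nrow(df)))
    vapply(strsplit(as.character(df$gene_id), ","), function(g) {
      g <- g[g %in% names(expression)]
      if (!length(g)) 0 else max(expression[g])
    }, 0.0)
  }
  pos_expr <- if (match_expression) gene_expr(positives) else NULL
  cand_expr <- if (match_expression) gene_expr(candidates) else NULL

  available <- rep(TRUE, nrow(candidates))
  fallbacks <- list()
  picked <- integer()
  max_radius <- max(c(pos_bin, cand_bin, 0L)) + 1L
  .with_seed(rng_seed, {
    for (i in seq_len(nrow(positives))) {
      need <- ratio
      radius <- 0L
      sel <- integer()
      repeat {
        pool <- which(available & abs(cand_bin - pos_bin[i]) <= radius)
        if (match_expression && pos_expr[i] > 0) pool <- pool[cand_expr[pool] > 0]
        pool <- setdiff(pool, sel)
        if (length(pool) >= need) {
          sel <- c(sel, pool[sample.int(length(pool), need)])
          need <- 0L
          break
        }
        sel <- c(sel, pool)
        need <- need - length(pool)
        radius <- radius + 1L
        if (radius > max_radius) break
      }
      if (radius > 0L) {
        fallbacks[[length(fallbacks) + 1L]] <-
          data.frame(positive = i, bin = pos_bin[i], radius = radius,
                     drawn = length(sel))
      }
      available[sel] <- FALSE
      picked <- c(picked, sel)
    }
  })
  out <- candidates[picked, , drop = FALSE]
  out$label <- 0L
  rownames(out) <- NULL
  attr(out, "fallbacks") <- if (length(fallbacks)) do.call(rbind, fallbacks)
                            else data.frame(positive = integer(), bin = integer(),
                                            radius = integer(), drawn = integer())
  out
}

#' Tile chromosomes into fixed-size bins
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param bin_size bin size in bp.
#' @return Region data.frame covering each chromosome.
#' @export
tile_genome <- function(chrom_lengths, bin_size) {
  do.call(rbind, lapply(names(chrom_lengths), function(chr) {
    starts <- seq(0L, chrom_lengths[[chr]] - 1L, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, chrom_lengths[[chr]]))
  }))
}

#' Build labeled examples from loop calls on a binned genome
#'
#' The genome is tiled into `bin_size` regions, bins are classified
#' promoter/distal by the TSS-distance rule, and a positive is any
#' (promoter bin, distal bin) pair whose bins lie on opposite anchors of a
#' loop at any input resolution. Featureless bins (all-zero signal over the
#' track panel) are removed. Negatives are drawn distance-matched with
#' expression matching on.
#'
#' @param loops list of BEDPE-like data.frames, one per resolution; anchor
#'   resolutions must be multiples of `bin_size`.
#' @param bin_size bin size in bp (default 5000).
#' @param tss TSS table.
#' @param tracks named list of [peak_track()]s for the cell line.
#' @param expression named RPKM vector.
#' @param chrom_lengths named chromosome lengths.
#' @param spec an [encoding_spec()].
#' @param max_distance maximum pair gap (default 1e6).
#' @param ratio negatives per positive.
#' @param rng_seed integer seed.
#' @return Encoded example data.frame (see [batch_encode()]) with label 1
#'   positives and matched label 0 negatives; attribute `provenance` records
#'   the construction parameters.
#' @export
build_hic_examples <- function(loops, bin_size = 5000, tss, tracks, expression,
                               chrom_lengths, spec = encoding_spec(),
                               max_distance = 1e6, ratio = 1, rng_seed = 1L) {
  bins <- tile_genome(chrom_lengths, bin_size)
  kind <- classify_region(bins, tss)
  sig <- region_signal_matrix(bins, tracks, spec$mode)
  keep <- rowSums(abs(sig)) > 0
  bins <- bins[keep, , drop = FALSE]
  kind <- kind[keep]
  bins$id <- .region_id(bins)

  prom_bins <- bins[kind == "PROMOTER", , drop = FALSE]
  dist_bins <- bins[kind == "DISTAL", , drop = FALSE]
  # attach the nearest-gene id to promoter bins for the expression feature
  gene_of <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      cand <- tss[tss$chrom == df$chrom[i], , drop = FALSE]
      p0 <- cand$position - 1L
      d <- ifelse(p0 >= df$start[i] & p0 < df$end[i], 0,
                  pmax(df$start[i] - p0, p0 - (df$end[i] - 1L)))
      cand$gene_id[which.min(d)]
    }, "")
  }
  if (nrow(prom_bins)) prom_bins$gene_id <- gene_of(prom_bins)

  # positives: (promoter bin, distal bin) on opposite loop anchors at any
  # resolution
  pos_keys <- character()
  for (lp in loops) {
    a1 <- data.frame(chrom = lp$chrom1, start = lp$start1, end = lp$end1)
    a2 <- data.frame(chrom = lp$chrom2, start = lp$start2, end = lp$end2)
    p1 <- .map_anchor(a1, prom_bins); d1 <- .map_anchor(a1, dist_bins)
    p2 <- .map_anchor(a2, prom_bins); d2 <- .map_anchor(a2, dist_bins)
    for (i in seq_len(nrow(lp))) {
      combos <- rbind(
        if (length(p1[[i]]) && length(d2[[i]]))
          expand.grid(p = p1[[i]], d = d2[[i]]),
        if (length(p2[[i]]) && length(d1[[i]]))
          expand.grid(p = p2[[i]], d = d1[[i]])
      )
      if (is.null(combos) || !nrow(combos)) next
      pos_keys <- c(pos_keys,
                    paste(prom_bins$id[combos$p], dist_bins$id[combos$d]))
    }
  }
  pos_keys <- unique(pos_keys)

  # candidate universe: all (distal, promoter) bin pairs within max_distance
  cand <- enumerate_candidates(dist_bins, prom_bins, max_distance = max_distance)
  cand_key <- paste(.region_id(data.frame(chrom = cand$p_chrom,
                                          start = cand$p_start,
                                          end = cand$p_end)),
                    .region_id(data.frame(chrom = cand$e_chrom,
                                          start = cand$e_start,
                                          end = cand$e_end)))
  positives <- cand[cand_key %in% pos_keys, , drop = FALSE]
  negatives_pool <- cand[!(cand_key %in% pos_keys), , drop = FALSE]
  if (!nrow(positives)) {
    out <- data.frame()
    attr(out, "provenance") <- list(bin_size = bin_size, n_positive = 0L)
    return(out)
  }
  positives$label <- 1L
  negs <- sample_matched_negatives(positives, negatives_pool, ratio = ratio,
                                   match_expression = TRUE,
                                   expression = expression,
                                   rng_seed = rng_seed)
  pairs <- rbind(positives, negs[, names(positives), drop = FALSE])
  ex <- batch_encode(pairs, tracks, expression, spec)
  attr(ex, "provenance") <- list(
    bin_size = bin_size, ratio = ratio, rng_seed = rng_seed,
    n_positive = nrow(positives), n_negative = nrow(negs),
    fallbacks = attr(negs, "fallbacks")
  )
  ex
}
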