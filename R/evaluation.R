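# Validation of predicted networks: fold enrichment against independent
# interaction lists, contact-count contrasts on binned matrices, ON/OFF
# region status, cell-line-specific interaction categories, and
# per-category F-scores.

#' Fold enrichment of predictions in an experimental interaction set
#'
#' Experimental interactions are first mapped onto the prediction's region
#' sets (one anchor overlapping an enhancer by >= 1 bp and the other a
#' promoter, either orientation). Fold enrichment is
#' `(n1/n2) / (m1/m2)`: `n1` predicted interactions overlapping the mapped
#' experimental set, `n2` total predicted, `m1` mapped experimental
#' interactions, `m2` the total number of possible interactions (the
#' candidate pair universe used for prediction).
#'
#' @param predicted data.frame of predicted edges with `enhancer_id`,
#'   `promoter_id` (as in a `ScoredNetwork`).
#' @param experimental BEDPE-like data.frame of measured interactions.
#' @param enhancers,promoters region data.frames that define the prediction
#'   universe.
#' @param universe_size `m2`.
#' @return An `EnrichmentResult` list: `n1`, `n2`, `m1`, `m2`, `fold`.
#' @export
fold_enrichment <- function(predicted, experimental, enhancers, promoters,
                            universe_size) {
  stopifnot(universe_size > 0)
  mapped <- build_positive_set(experimental, enhancers, promoters,
                               max_distance = Inf)
  m1 <- nrow(mapped)
  n2 <- nrow(predicted)
  if (n2 == 0 || m1 == 0) {
    stop("fold enrichment undefined: no predictions or no mapped experimental interactions",
         call. = FALSE)
  }
  mapped_key <- paste(
    .region_id(data.frame(chrom = mapped$e_chrom, start = mapped$e_start,
                          end = mapped$e_end)),
    .region_id(data.frame(chrom = mapped$p_chrom, start = mapped$p_start,
                          end = mapped$p_end)))
  pred_key <- paste(predicted$enhancer_id, predicted$promoter_id)
  n1 <- sum(pred_key %in% mapped_key)
  list(n1 = n1, n2 = n2, m1 = m1, m2 = universe_size,
       fold = (n1 / n2) / (m1 / universe_size))
}

# midpoint bin of a region at the given bin size
.midpoint_bin <- function(start, end, bin_size) {
  ((start + end) %/% 2L) %/% bin_size
}

#' Contact-count annotation and top/bottom contrast
#'
#' Maps each predicted edge to the contact-matrix bin pair containing the
#' midpoints of its two anchors, then compares the contact-count
#' distributions of the top (`percentile >= top_q`) and bottom
#' (`percentile <= bottom_q`) edges with a two-sample Kolmogorov-Smirnov
#' test. Edges outside the matrix extent are excluded and counted.
#'
#' @param edges data.frame with `enhancer_id`, `promoter_id`, `percentile`
#'   (as in a `ScoredNetwork`'s edge table).
#' @param contacts contact data.frame from [read_contact_matrix()] (or with
#'   a `bin_size` attribute).
#' @param top_q,bottom_q percentile cutoffs (defaults 0.90, 0.10).
#' @return List: `annotated` (edges plus `bin_i`, `bin_j`, `count`),
#'   `top_counts`, `bottom_counts`, `ks` (htest), `n_excluded`.
#' @export
annotate_contacts <- function(edges, contacts, top_q = 0.90, bottom_q = 0.10) {
  bin_size <- attr(contacts, "bin_size")
  stopifnot(!is.null(bin_size))
  parse_locus <- function(id) {
    m <- regmatches(id, regexec("^(.+):(\\d+)-(\\d+)$", id))
    data.frame(chrom = vapply(m, `[`, "", 2),
               start = as.integer(vapply(m, `[`, "", 3)),
               end = as.integer(vapply(m, `[`, "", 4)))
  }
  e <- parse_locus(edges$enhancer_id)
  p <- parse_locus(edges$promoter_id)
  bi <- .midpoint_bin(e$start, e$end, bin_size)
  bj <- .midpoint_bin(p$start, p$end, bin_size)
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  key <- paste(e$chrom, lo, hi)
  ckey <- paste(if (all(is.na(contacts$chrom))) e$chrom[1] else contacts$chrom,
                pmin(contacts$bin_i, contacts$bin_j),
                pmax(contacts$bin_i, contacts$bin_j))
  counts <- contacts$count[match(key, ckey)]
  inside <- lo >= 0 & hi <= max(c(contacts$bin_i, contacts$bin_j)) &
    e$chrom == p$chrom
  counts[!inside] <- NA
  counts[inside & is.na(counts)] <- 0  # bin pair absent from a sparse matrix
  annotated <- cbind(edges, bin_i = lo, bin_j = hi, count = counts)
  ok <- !is.na(counts)
  top <- counts[ok & edges$percentile >= top_q]
  bottom <- counts[ok & edges$percentile <= bottom_q]
  ks <- if (length(top) && length(bottom)) {
    suppressWarnings(stats::ks.test(top, bottom))
  } else NULL
  list(annotated = annotated, top_counts = top, bottom_counts = bottom,
       ks = ks, n_excluded = sum(!ok))
}

#' ON/OFF status of a region from its binary signals
#'
#' An enhancer is ON if it has a peak for any of DNase I, H3K27ac or
#' H3K9ac. A promoter is ON if it has H3K4me3 or DNase I but not H3K27me3.
#'
#' @param region_kind `"ENHANCER"` or `"PROMOTER"`.
#' @param signals named binary vector (or 0/1 logical) of per-data-set
#'   presence; must contain the data sets the rule needs
#'   (DNase, H3K27ac, H3K9ac for enhancers; H3K4me3, DNase, H3K27me3 for
#'   promoters).
#' @return `"ON"` or `"OFF"`.
#' @export
region_on_status <- function(region_kind = c("ENHANCER", "PROMOTER"), signals) {
  region_kind <- match.arg(region_kind)
  need <- if (region_kind == "ENHANCER") c("DNase", "H3K27ac", "H3K9ac")
          else c("H3K4me3", "DNase", "H3K27me3")
  missing <- setdiff(need, names(signals))
  if (length(missing)) {
    stop("required signal missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  s <- as.logical(signals[need] > 0)
  on <- if (region_kind == "ENHANCER") any(s) else (s[1] || s[2]) && !s[3]
  if (on) "ON" else "OFF"
}

#' Categorize interactions between two cell lines
#'
#' Over a shared pair universe, an edge is SHARED if it passes the
#' high-confidence rule in both cell lines, and A-specific if it passes in
#' A but is below the low cutoff in B. A-specific edges are subdivided by
#' the ON/OFF status of their enhancer and promoter in cell line B into
#' BOTH_OFF, ENH_OFF_PROM_ON, ENH_ON_PROM_OFF and BOTH_ON. With percentile
#' scoring, edges between the low and high cutoffs in B are AMBIGUOUS
#' (neither shared nor A-specific). With `use_probability = TRUE`, a single
#' probability cutoff is used for both cell lines and no ambiguous band
#' exists.
#'
#' @param net_A,net_B `ScoredNetwork`s over the same pair universe.
#' @param signals_B region-id-named binary signal matrix for cell line B
#'   (columns are data sets; needs the [region_on_status()] panels).
#' @param high,low percentile cutoffs (defaults 0.90, 0.80).
#' @param use_probability use `prob_cutoff` on raw scores instead of
#'   percentile bands.
#' @param prob_cutoff probability cutoff (default 0.5).
#' @return data.frame of cell-line-A interactions (edges passing in A) with
#'   a `category` column in {SHARED, BOTH_OFF, ENH_OFF_PROM_ON,
#'   ENH_ON_PROM_OFF, BOTH_ON, AMBIGUOUS}.
#' @export
categorize_pairwise <- function(net_A, net_B, signals_B, high = 0.90,
                                low = 0.80, use_probability = FALSE,
                                prob_cutoff = 0.5) {
  a <- net_A$edges; b <- net_B$edges
  if (!identical(sort(a$pair_id), sort(b$pair_id))) {
    stop("pair universes differ between the two networks", call. = FALSE)
  }
  b <- b[match(a$pair_id, b$pair_id), , drop = FALSE]
  if (use_probability) {
    in_A <- a$score > prob_cutoff
    in_B <- b$score > prob_cutoff
    ambiguous <- rep(FALSE, nrow(a))
  } else {
    in_A <- a$percentile > high
    in_B <- b$percentile > high
    ambiguous <- !in_B & b$percentile > low
  }
  out <- a[in_A, , drop = FALSE]
  shared <- in_B[in_A]
  amb <- ambiguous[in_A]
  category <- character(nrow(out))
  category[shared] <- "SHARED"
  category[!shared & amb] <- "AMBIGUOUS"
  spec_idx <- which(!shared & !amb)
  for (i in spec_idx) {
    e_on <- region_on_status("ENHANCER",
                             signals_B[out$enhancer_id[i], ]) == "ON"
    p_on <- region_on_status("PROMOTER",
                             signals_B[out$promoter_id[i], ]) == "ON"
    category[i] <- if (e_on && p_on) "BOTH_ON"
      else if (!e_on && p_on) "ENH_OFF_PROM_ON"
      else if (e_on && !p_on) "ENH_ON_PROM_OFF"
      else "BOTH_OFF"
  }
  out$category <- category
  rownames(out) <- NULL
  out
}

#' Per-category F-score between two categorizations
#'
#' For each category c, precision and recall of membership in c are
#' computed over the shared edge universe and combined as
#' `F = 2PR/(P+R)` (0 when P + R = 0).
#'
#' @param predicted,reference named character vectors of categories keyed
#'   by the same edge ids (or equal-length vectors in the same order).
#' @return data.frame: `category`, `precision`, `recall`, `f_score`.
#' @export
category_fscore <- function(predicted, reference) {
  if (!is.null(names(predicted)) && !is.null(names(reference))) {
    ids <- union(names(predicted), names(reference))
    predicted <- predicted[ids]
    reference <- reference[ids]
  }
  stopifnot(length(predicted) == length(reference))
  cats <- sort(unique(c(predicted, reference)))
  cats <- cats[!is.na(cats)]
  rows <- lapply(cats, function(cc) {
    tp <- sum(predicted == cc & reference == cc, na.rm = TRUE)
    fp <- sum(predicted == cc & (reference != cc | is.na(reference)), na.rm = TRUE)
    fn <- sum((predicted != cc | is.na(predicted)) & reference == cc, na.rm = TRUE)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(category = cc, precision = prec, recall = rec, f_score = f)
  })
  do.call(rbind, rows)
}
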