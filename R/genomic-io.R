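# Readers for peak calls, TSS tables and expression tables, plus region-level
# operations: promoter/distal classification, peak-signal summaries, and
# construction of the universal enhancer and promoter region sets.

.read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Construct a peak track
#'
#' A peak track holds the peak calls of one data set (e.g. a ChIP-seq factor
#' or histone mark, or DNase I) in one cell line. Scores are the
#' \eqn{-\log_{10}(P)} enrichment of each peak and must be non-negative.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `score` (defaults to 1).
#' @param dataset data-set name, e.g. `"CTCF"` or `"H3K27ac"`.
#' @param cell_line cell-line name.
#' @return An object of class `PeakTrack`.
#' @export
peak_track <- function(peaks, dataset, cell_line) {
  if (is.null(peaks$score)) peaks$score <- 1.0
  .check_regions(peaks, "peak")
  if (any(peaks$score < 0)) stop("peak scores must be non-negative", call. = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(dataset = dataset, cell_line = cell_line, peaks = peaks),
            class = "PeakTrack")
}

#' @export
print.PeakTrack <- function(x, ...) {
  cat(sprintf("PeakTrack %s [%s]: %d peaks\n",
              x$dataset, x$cell_line, nrow(x$peaks)))
  invisible(x)
}

#' Read a BED / narrowPeak file of peak calls
#'
#' Accepts BED3+ or narrowPeak. Header lines starting with `#`, `track` or
#' `browser` are skipped. Malformed lines (missing columns, non-numeric
#' coordinates or scores, `start >= end`) raise an error naming the line.
#'
#' @param path file path.
#' @param dataset,cell_line names attached to the track.
#' @param score_column 1-based column index of the peak score
#'   (\eqn{-\log_{10} P}); if `NULL`, all scores default to 1.0. Column 8 is
#'   the narrowPeak \eqn{-\log_{10}(P)} column.
#' @return A [peak_track()] object.
#' @export
read_peak_bed <- function(path, dataset, cell_line, score_column = NULL) {
  src <- .read_table_lines(path)
  if (!length(src$lines)) {
    return(peak_track(data.frame(chrom = character(), start = integer(),
                                 end = integer(), score = numeric()),
                      dataset, cell_line))
  }
  fields <- strsplit(src$lines, "\t| +")
  parse_one <- function(f, ln) {
    if (length(f) < 3) stop(sprintf("line %d: fewer than 3 columns", ln), call. = FALSE)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop(sprintf("line %d: non-numeric coordinates", ln), call. = FALSE)
    }
    if (start >= end) {
      stop(sprintf("line %d: start (%d) must be < end (%d)", ln, start, end),
           call. = FALSE)
    }
    score <- 1.0
    if (!is.null(score_column)) {
      if (length(f) < score_column) {
        stop(sprintf("line %d: no column %d", ln, score_column), call. = FALSE)
      }
      score <- suppressWarnings(as.numeric(f[score_column]))
      if (is.na(score)) stop(sprintf("line %d: non-numeric score", ln), call. = FALSE)
    }
    list(chrom = f[1], start = start, end = end, score = score)
  }
  rows <- mapply(parse_one, fields, src$lineno, SIMPLIFY = FALSE)
  peaks <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    score = vapply(rows, `[[`, 0.0, "score")
  )
  peak_track(peaks, dataset, cell_line)
}

#' Read a TSS annotation table
#'
#' Accepts BED6 (`chrom start end name score strand`; the TSS is the strand
#' 5' end, converted to a 1-based position) or a 4-column TSV
#' (`gene_id chrom position strand`, position 1-based). Header lines starting
#' with `#` or `track` are skipped.
#'
#' @param path file path.
#' @param format `"auto"`, `"bed6"` or `"tsv"`.
#' @return data.frame with columns `gene_id`, `chrom`, `position` (1-based),
#'   `strand`.
#' @export
read_tss <- function(path, format = c("auto", "bed6", "tsv")) {
  format <- match.arg(format)
  src <- .read_table_lines(path)
  fields <- strsplit(src$lines, "\t| +")
  if (format == "auto") {
    n <- length(fields[[1]])
    format <- if (n >= 6 &&
                  !is.na(suppressWarnings(as.integer(fields[[1]][3])))) "bed6" else "tsv"
  }
  if (format == "bed6") {
    strand <- vapply(fields, function(f) f[6], "")
    start <- vapply(fields, function(f) as.integer(f[2]), 0L)
    end <- vapply(fields, function(f) as.integer(f[3]), 0L)
    pos <- ifelse(strand == "-", end, start + 1L)
    out <- data.frame(
      gene_id = vapply(fields, function(f) f[4], ""),
      chrom = vapply(fields, function(f) f[1], ""),
      position = as.integer(pos), strand = strand
    )
  } else {
    out <- data.frame(
      gene_id = vapply(fields, function(f) f[1], ""),
      chrom = vapply(fields, function(f) f[2], ""),
      position = vapply(fields, function(f) as.integer(f[3]), 0L),
      strand = vapply(fields, function(f) if (length(f) >= 4) f[4] else "+", "")
    )
  }
  if (any(is.na(out$position)) || any(out$position < 1)) {
    stop("TSS positions must be 1-based integers >= 1", call. = FALSE)
  }
  out
}

#' Read a gene expression table
#'
#' Two-column TSV (`gene_id`, RPKM). RPKM values must be non-negative.
#'
#' @param path file path.
#' @return Named numeric vector of RPKM keyed by gene id.
#' @export
read_expression <- function(path) {
  src <- .read_table_lines(path)
  fields <- strsplit(src$lines, "\t| +")
  rpkm <- vapply(fields, function(f) as.numeric(f[2]), 0.0)
  if (any(is.na(rpkm)) || any(rpkm < 0)) {
    stop("RPKM values must be non-negative numbers", call. = FALSE)
  }
  stats::setNames(rpkm, vapply(fields, function(f) f[1], ""))
}

# Distance in bp from each region to the nearest TSS (0 if a TSS falls
# inside the region). Regions 0-based half-open, TSS positions 1-based.
.tss_distance <- function(regions, tss) {
  dist <- rep(Inf, nrow(regions))
  for (chr in unique(as.character(regions$chrom))) {
    ri <- which(regions$chrom == chr)
    p0 <- tss$position[tss$chrom == chr] - 1L  # 0-based point
    if (!length(p0)) next
    p0 <- sort(p0)
    for (i in ri) {
      s <- regions$start[i]; e <- regions$end[i]
      inside <- any(p0 >= s & p0 < e)
      dist[i] <- if (inside) 0 else min(pmax(s - p0, p0 - (e - 1L)))
    }
  }
  dist
}

#' Classify regions as promoter or distal
#'
#' A region is a PROMOTER if it contains a TSS or the nearest TSS is
#' strictly closer than `promoter_distance` bp; otherwise it is DISTAL
#' (a candidate enhancer). Chromosomes with no TSS yield DISTAL.
#'
#' @param regions data.frame of regions (`chrom`, `start`, `end`).
#' @param tss TSS table as from [read_tss()].
#' @param promoter_distance bp threshold (default 2500).
#' @return Character vector `"PROMOTER"`/`"DISTAL"`, one per region.
#' @export
classify_region <- function(regions, tss, promoter_distance = 2500) {
  .check_regions(regions)
  d <- .tss_distance(regions, tss)
  ifelse(d < promoter_distance, "PROMOTER", "DISTAL")
}

#' Summarize a track's signal on a region
#'
#' BINARY: 1 if any peak overlaps the region by at least 1 bp, else 0.
#' CONTINUOUS: the maximum score among overlapping peaks, 0 if none.
#'
#' @param region single-row data.frame (`chrom`, `start`, `end`).
#' @param track a [peak_track()].
#' @param mode `"BINARY"` or `"CONTINUOUS"`.
#' @return A single number.
#' @export
region_signal <- function(region, track, mode = c("BINARY", "CONTINUOUS")) {
  mode <- match.arg(mode)
  unname(region_signal_matrix(region, list(track), mode)[1, 1])
}

#' Signal matrix for many regions over many tracks
#'
#' @param regions data.frame of regions.
#' @param tracks list of [peak_track()] objects (same cell line); names are
#'   taken from each track's `dataset`.
#' @param mode `"BINARY"` or `"CONTINUOUS"`.
#' @return Numeric matrix, regions x data sets.
#' @export
region_signal_matrix <- function(regions, tracks, mode = c("BINARY", "CONTINUOUS")) {
  mode <- match.arg(mode)
  .check_regions(regions)
  gr <- .regions_gr(regions)
  out <- matrix(0, nrow(regions), length(tracks),
                dimnames = list(NULL, vapply(tracks, `[[`, "", "dataset")))
  for (j in seq_along(tracks)) {
    pk <- tracks[[j]]$peaks
    if (!nrow(pk)) next
    # disjoint seqlevels (no peaks on a queried chromosome) are a normal
    # no-overlap case, not a user-facing condition
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, .regions_gr(pk), minoverlap = 1L))
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    if (mode == "BINARY") {
      out[unique(qi), j] <- 1
    } else {
      sc <- pk$score[S4Vectors::subjectHits(hits)]
      agg <- tapply(sc, qi, max)
      out[as.integer(names(agg)), j] <- as.numeric(agg)
    }
  }
  out
}

#' Build the universal enhancer set
#'
#' Unions per-cell-line enhancer interval sets, merges overlapping or
#' adjacent intervals (adjacent means `end_i == start_j` under half-open
#' coordinates), and drops merged intervals shorter than `min_length` bp.
#'
#' @param per_cell_line_enhancers list of region data.frames.
#' @param min_length minimum merged length in bp (default 200).
#' @return Sorted, non-overlapping region data.frame.
#' @export
build_universal_enhancers <- function(per_cell_line_enhancers, min_length = 200) {
  all <- do.call(rbind, lapply(per_cell_line_enhancers, function(df) {
    .check_regions(df)
    df[, c("chrom", "start", "end")]
  }))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  merged <- GenomicRanges::reduce(.regions_gr(all))  # merges overlap + abutting
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged)
  )
  out <- out[(out$end - out$start) >= min_length, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build promoter regions around TSS annotations
#'
#' One interval `[position - flank, position + flank)` per TSS, clipped at
#' the chromosome start. Overlapping promoter intervals are kept distinct
#' (one record per TSS); identical intervals from multiple genes are
#' collapsed into one record carrying all gene ids (comma-separated).
#'
#' @param tss TSS table as from [read_tss()].
#' @param flank flank in bp (default 2500).
#' @return Region data.frame with a `gene_id` column.
#' @export
build_promoter_regions <- function(tss, flank = 2500) {
  out <- data.frame(
    chrom = tss$chrom,
    start = pmax(tss$position - flank, 0L),
    end = tss$position + flank,
    gene_id = tss$gene_id
  )
  key <- .region_id(out)
  if (anyDuplicated(key)) {
    genes <- tapply(out$gene_id, key, function(g) paste(unique(g), collapse = ","))
    out <- out[!duplicated(key), , drop = FALSE]
    out$gene_id <- as.character(genes[.region_id(out)])
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BEDPE interaction file
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 [name score]. Header lines
#' starting with `#` or `track` are skipped.
#'
#' @param path file path.
#' @param cell_line optional cell-line name attached to every record.
#' @return data.frame of paired anchors.
#' @export
read_bedpe <- function(path, cell_line = NA_character_) {
  src <- .read_table_lines(path)
  f <- strsplit(src$lines, "\t| +")
  get <- function(i, as = as.character) vapply(f, function(x) as(x[i]), as(NA))
  out <- data.frame(
    chrom1 = get(1), start1 = get(2, as.integer), end1 = get(3, as.integer),
    chrom2 = get(4), start2 = get(5, as.integer), end2 = get(6, as.integer)
  )
  out$name <- vapply(f, function(x) if (length(x) >= 7) x[7] else NA_character_, "")
  out$score <- vapply(f, function(x)
    if (length(x) >= 8) suppressWarnings(as.numeric(x[8])) else NA_real_, 0.0)
  out$cell_line <- cell_line
  out
}

#' Write interactions as BEDPE
#'
#' @param interactions data.frame with the six anchor columns and optionally
#'   `name` and `score`.
#' @param path output path.
#' @export
write_bedpe <- function(interactions, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  df <- interactions[, cols, drop = FALSE]
  df$name <- interactions$name %||% "."
  df$score <- interactions$score %||% 0
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a binned contact matrix
#'
#' Three-column TSV `bin_i bin_j count` (bin indices are 0-based bin numbers
#' at the stated resolution) with an optional header line
#' `# bin_size=<bp>` and optional `chrom` first column
#' (`chrom bin_i bin_j count`).
#'
#' @param path file path.
#' @param bin_size bin size in bp; overrides any header value if given.
#' @return data.frame `chrom`, `bin_i`, `bin_j`, `count` with attribute
#'   `bin_size`.
#' @export
read_contact_matrix <- function(path, bin_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("bin_size=\\d+", hdr))
  if (is.null(bin_size)) {
    if (length(m)) bin_size <- as.integer(sub("bin_size=", "", m[1]))
    else stop("bin_size not given and no '# bin_size=' header", call. = FALSE)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- strsplit(body, "\t| +")
  ncol1 <- length(f[[1]])
  if (ncol1 >= 4) {
    out <- data.frame(
      chrom = vapply(f, `[`, "", 1),
      bin_i = vapply(f, function(x) as.integer(x[2]), 0L),
      bin_j = vapply(f, function(x) as.integer(x[3]), 0L),
      count = vapply(f, function(x) as.numeric(x[4]), 0.0)
    )
  } else {
    out <- data.frame(
      chrom = NA_character_,
      bin_i = vapply(f, function(x) as.integer(x[1]), 0L),
      bin_j = vapply(f, function(x) as.integer(x[2]), 0L),
      count = vapply(f, function(x) as.numeric(x[3]), 0.0)
    )
  }
  attr(out, "bin_size") <- bin_size
  out
}
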