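`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
.regions_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.check_regions <- function(df, what = "region") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start < df$end) | !nzchar(as.character(df$chrom)))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: start must be < end and chrom non-empty",
                 what, bad[1]), call. = FALSE)
  }
  invisible(df)
}

.region_id <- function(df) {
  sprintf("%s:%d-%d", as.character(df$chrom), df$start, df$end)
}

# Gap in bp between two 0-based half-open intervals on the same chromosome
# (0 if they overlap or touch).
.interval_gap <- function(s1, e1, s2, e2) {
  pmax(pmax(s2 - e1, s1 - e2), 0L)
}

# Seed-scoped evaluation: leaves the caller's RNG state untouched.
.with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
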