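# Pair feature encodings: CONCAT and PRODUCT schemes with optional Pearson
# correlation and promoter-gene expression extras.

#' Define a feature encoding scheme
#'
#' CONCAT concatenates the enhancer and promoter region vectors (2n
#' dimensions, suffixes `_E` / `_P`); PRODUCT multiplies them elementwise
#' (n dimensions). Under PRODUCT with continuous signals, a small correction
#' is added to each region value before multiplying so that a pair keeps a
#' nonzero value when only one side carries signal. Optional extras: the
#' Pearson correlation of the two n-vectors (`include_correlation`) and the
#' promoter gene's RPKM (`include_expression`).
#'
#' @param scheme `"CONCAT"` or `"PRODUCT"`.
#' @param include_correlation,include_expression logical flags.
#' @param mode `"BINARY"` or `"CONTINUOUS"` region signals.
#' @param product_correction correction added to each region value before
#'   the PRODUCT with continuous signals (default 0.01; unused otherwise).
#' @return An `EncodingSpec` object.
#' @export
encoding_spec <- function(scheme = c("CONCAT", "PRODUCT"),
                          include_correlation = TRUE,
                          include_expression = TRUE,
                          mode = c("BINARY", "CONTINUOUS"),
                          product_correction = 0.01) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  if (scheme == "PRODUCT" && mode == "CONTINUOUS" && product_correction <= 0) {
    stop("product_correction must be > 0 for continuous PRODUCT encoding",
         call. = FALSE)
  }
  structure(list(scheme = scheme, include_correlation = include_correlation,
                 include_expression = include_expression, mode = mode,
                 product_correction = product_correction),
            class = "EncodingSpec")
}

#' Encode one region against a panel of tracks
#'
#' @param region single-row region data.frame.
#' @param tracks named list of [peak_track()]s from one cell line; order
#'   fixes the feature order.
#' @param spec an [encoding_spec()].
#' @return Named numeric vector, one value per data set.
#' @export
encode_region <- function(region, tracks, spec) {
  drop(region_signal_matrix(region, tracks, spec$mode)[1, ])
}

# Pearson correlation with the zero-variance convention: a constant operand
# carries no co-variation signal, so the correlation feature is 0.
.safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Encode an (enhancer, promoter) pair
#'
#' @param enh,prom named numeric region vectors built under the same
#'   data-set order and mode.
#' @param prom_expression RPKM of the promoter's gene.
#' @param spec an [encoding_spec()].
#' @return Named numeric feature vector (`<dataset>_E`, `<dataset>_P` for
#'   CONCAT or `<dataset>` for PRODUCT, plus `correlation` and `expression`
#'   when enabled).
#' @export
encode_pair <- function(enh, prom, prom_expression, spec) {
  stopifnot(length(enh) == length(prom))
  if (spec$scheme == "CONCAT") {
    v <- c(stats::setNames(enh, paste0(names(enh), "_E")),
           stats::setNames(prom, paste0(names(prom), "_P")))
  } else {
    if (spec$mode == "CONTINUOUS") {
      cc <- spec$product_correction
      v <- (enh + cc) * (prom + cc)
    } else {
      v <- enh * prom
    }
    names(v) <- names(enh)
  }
  if (spec$include_correlation) v <- c(v, correlation = .safe_cor(enh, prom))
  if (spec$include_expression) v <- c(v, expression = unname(prom_expression))
  v
}

#' Names of the features an encoding produces
#'
#' @param datasets character vector of data-set names.
#' @param spec an [encoding_spec()].
#' @return Character vector of feature names in encoding order.
#' @export
encoding_feature_names <- function(datasets, spec) {
  base <- if (spec$scheme == "CONCAT") {
    c(paste0(datasets, "_E"), paste0(datasets, "_P"))
  } else datasets
  c(base,
    if (spec$include_correlation) "correlation",
    if (spec$include_expression) "expression")
}

#' Encode a batch of candidate pairs
#'
#' Vectorized composition of [encode_region()] and [encode_pair()] over a
#' candidate pair list. Pairs whose enhancer and promoter vectors are both
#' all-zero are flagged `featureless`. A promoter gene missing from the
#' expression table gets expression 0 with a warning.
#'
#' @param pairs data.frame with enhancer columns (`e_chrom`, `e_start`,
#'   `e_end`), promoter columns (`p_chrom`, `p_start`, `p_end`), `gene_id`,
#'   and optionally `label`.
#' @param tracks named list of [peak_track()]s (one cell line).
#' @param expression named RPKM vector as from [read_expression()].
#' @param spec an [encoding_spec()].
#' @return data.frame: `pair_id`, locus columns, `gene_id`, `distance`,
#'   `label`, `featureless`, then one column per feature. Attribute
#'   `feature_names` lists the feature columns.
#' @export
batch_encode <- function(pairs, tracks, expression, spec) {
  stopifnot(nrow(pairs) >= 1)
  enh <- data.frame(chrom = pairs$e_chrom, start = pairs$e_start, end = pairs$e_end)
  prom <- data.frame(chrom = pairs$p_chrom, start = pairs$p_start, end = pairs$p_end)
  # encode each distinct region once, then index per pair
  e_key <- .region_id(enh); p_key <- .region_id(prom)
  regs <- rbind(enh, prom)
  keys <- c(e_key, p_key)
  uniq <- !duplicated(keys)
  sig <- region_signal_matrix(regs[uniq, , drop = FALSE], tracks, spec$mode)
  rownames(sig) <- keys[uniq]
  E <- sig[e_key, , drop = FALSE]
  P <- sig[p_key, , drop = FALSE]

  # promoter expression: max RPKM over the promoter's gene(s)
  genes <- strsplit(as.character(pairs$gene_id), ",")
  missing <- character()
  expr <- vapply(genes, function(g) {
    known <- g %in% names(expression)
    if (!all(known)) missing <<- c(missing, g[!known])
    if (!any(known)) 0 else max(expression[g[known]])
  }, 0.0)
  if (length(missing)) {
    warning("genes absent from expression table (expression set to 0): ",
            paste(unique(missing), collapse = ", "), call. = FALSE)
  }

  if (spec$scheme == "CONCAT") {
    M <- cbind(E, P)
  } else if (spec$mode == "CONTINUOUS") {
    M <- (E + spec$product_correction) * (P + spec$product_correction)
  } else {
    M <- E * P
  }
  if (spec$include_correlation) {
    n <- ncol(E)
    se <- sqrt(rowSums(E^2) - rowSums(E)^2 / n)
    sp <- sqrt(rowSums(P^2) - rowSums(P)^2 / n)
    num <- rowSums(E * P) - rowSums(E) * rowSums(P) / n
    corr <- ifelse(se == 0 | sp == 0, 0, num / (se * sp))
    M <- cbind(M, corr)
  }
  if (spec$include_expression) M <- cbind(M, expr)
  fn <- encoding_feature_names(colnames(E), spec)
  colnames(M) <- fn

  out <- data.frame(
    pair_id = paste(e_key, p_key, sep = "|"),
    e_chrom = enh$chrom, e_start = enh$start, e_end = enh$end,
    p_chrom = prom$chrom, p_start = prom$start, p_end = prom$end,
    gene_id = as.character(pairs$gene_id),
    distance = .interval_gap(enh$start, enh$end, prom$start, prom$end),
    label = if (!is.null(pairs$label)) pairs$label else NA_integer_,
    featureless = rowSums(abs(E)) == 0 & rowSums(abs(P)) == 0
  )
  out <- cbind(out, as.data.frame(M, optional = TRUE))
  attr(out, "feature_names") <- fn
  rownames(out) <- NULL
  out
}

#' Extract the feature matrix from an encoded example table
#'
#' @param examples data.frame from [batch_encode()] (or with the same
#'   `feature_names` attribute).
#' @return Numeric matrix (examples x features).
#' @export
feature_matrix <- function(examples) {
  fn <- attr(examples, "feature_names")
  if (is.null(fn)) {
    meta <- c("pair_id", "e_chrom", "e_start", "e_end", "p_chrom", "p_start",
              "p_end", "gene_id", "distance", "label", "featureless")
    fn <- setdiff(names(examples), meta)
  }
  as.matrix(examples[, fn, drop = FALSE])
}
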