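# Synthetic multi-cell-line regulatory landscapes with planted structure:
# block-correlated peak tracks, expression tables coupled to promoter
# marks, true interactions following an architectural+activating rule with
# exponential distance decay, and contact matrices with elevated counts on
# true interactions.

.default_panel <- function() {
  list(
    histone = c("H3K27ac", "H3K27me3", "H3K36me3", "H3K4me2", "H3K4me3",
                "H3K79me2", "H3K9ac", "H4K20me1"),
    tf = c("CTCF", "RAD21", "SMC3", "POL2", "TBP", "CMYC", "MAX", "JUND",
           "USF2", "TAF1", "EGR1", "SIX5", "SRF"),
    open = "DNase"
  )
}

#' Configure a synthetic regulatory landscape
#'
#' The defaults define the package's reference simulation: four cell lines
#' over a 20 Mb two-chromosome genome with 500 TSS and 2000 enhancer
#' candidates; a 22-track peak panel (8 histone marks, 13 transcription
#' factors, DNase I) with a correlated architectural block
#' CTCF/RAD21/SMC3; and a planted interaction rule requiring CTCF and
#' H3K27ac on the enhancer and H3K4me3 on the promoter, thinned by
#' exponential distance decay (scale 100 kb). Cell-line specificity comes
#' from per-cell-line signal dropout (enhancer/promoter-OFF interactions)
#' and independent interaction dropout among rule-satisfying pairs
#' (both-ON interactions).
#'
#' @param n_cell_lines number of cell lines (default 4).
#' @param chrom_lengths named chromosome lengths in bp.
#' @param n_tss,n_enhancers numbers of TSS and enhancer candidates.
#' @param datasets character vector of peak data-set names.
#' @param base_rates named per-data-set presence probabilities; data sets
#'   not named fall back to 0.3.
#' @param blocks list of character vectors of co-occurring data sets.
#' @param block_rho within-block co-occurrence probability (default 0.8).
#' @param rule list with `enhancer` and `promoter` character vectors of
#'   required data sets (all must be present).
#' @param decay_scale exponential distance-decay scale in bp (default
#'   1e5).
#' @param max_distance candidate pair cap in bp (default 1e6).
#' @param cell_dropout per-cell-line signal dropout rate (default 0.15).
#' @param interaction_dropout per-cell-line dropout among rule-satisfying,
#'   distance-accepted pairs (default 0.1).
#' @param false_peak_rate,peak_dropout_rate observation noise on peaks
#'   (defaults 0.02, 0.05).
#' @param rng_seed integer seed.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_cell_lines = 4,
                              chrom_lengths = c(chr1 = 12e6, chr2 = 8e6),
                              n_tss = 500, n_enhancers = 2000,
                              datasets = unlist(.default_panel(),
                                                use.names = FALSE),
                              base_rates = NULL,
                              blocks = list(c("CTCF", "RAD21", "SMC3")),
                              block_rho = 0.8,
                              rule = list(enhancer = c("CTCF", "H3K27ac"),
                                          promoter = "H3K4me3"),
                              decay_scale = 1e5, max_distance = 1e6,
                              cell_dropout = 0.15, interaction_dropout = 0.1,
                              false_peak_rate = 0.02, peak_dropout_rate = 0.05,
                              rng_seed = 1L) {
  rates <- stats::setNames(rep(0.3, length(datasets)), datasets)
  defaults <- c(CTCF = 0.45, RAD21 = 0.45, SMC3 = 0.45, DNase = 0.55,
                H3K27ac = 0.5, H3K9ac = 0.4, H3K4me3 = 0.55, H3K4me2 = 0.45,
                H3K27me3 = 0.25, POL2 = 0.35, TBP = 0.3)
  rates[names(defaults)[names(defaults) %in% datasets]] <-
    defaults[names(defaults) %in% datasets]
  if (!is.null(base_rates)) rates[names(base_rates)] <- base_rates
  stopifnot(all(rates >= 0 & rates <= 1), all(chrom_lengths > 0),
            block_rho >= 0, block_rho <= 1)
  structure(list(
    n_cell_lines = n_cell_lines, chrom_lengths = chrom_lengths,
    n_tss = n_tss, n_enhancers = n_enhancers, datasets = datasets,
    base_rates = rates, blocks = blocks, block_rho = block_rho, rule = rule,
    decay_scale = decay_scale, max_distance = max_distance,
    cell_dropout = cell_dropout, interaction_dropout = interaction_dropout,
    false_peak_rate = false_peak_rate,
    peak_dropout_rate = peak_dropout_rate, rng_seed = rng_seed),
    class = "SimulationConfig")
}

# binary state matrix (regions x data sets) with block co-occurrence
.draw_states <- function(n, cfg) {
  S <- matrix(0L, n, length(cfg$datasets),
              dimnames = list(NULL, cfg$datasets))
  in_block <- unlist(cfg$blocks)
  for (d in setdiff(cfg$datasets, in_block)) {
    S[, d] <- stats::rbinom(n, 1, cfg$base_rates[d])
  }
  for (bl in cfg$blocks) {
    z <- stats::rbinom(n, 1, cfg$base_rates[bl[1]])
    for (d in bl) {
      follow <- stats::rbinom(n, 1, cfg$block_rho) == 1
      S[, d] <- ifelse(follow, z, stats::rbinom(n, 1, cfg$base_rates[d]))
    }
  }
  S
}

#' Simulate a multi-cell-line regulatory landscape
#'
#' Places TSS uniformly and enhancer candidates at least 2500 bp from any
#' TSS; draws a shared block-correlated binary signal landscape, applies
#' per-cell-line signal dropout, and derives observed peak tracks
#' (with false-peak and peak-dropout noise and exponential-tail
#' \eqn{-\log_{10} P} scores), expression tables (high RPKM for promoters
#' with active marks), and true interaction sets per cell line from the
#' planted rule with shared exponential distance-decay acceptance and
#' per-cell-line interaction dropout.
#'
#' @param cfg a [simulation_config()].
#' @return A list: `tss`, `enhancers`, `promoters`, per-cell-line `tracks`
#'   (named list of lists of [peak_track()]), `expression` (named list of
#'   RPKM vectors), `truth` (a `GroundTruth`: per-cell-line true
#'   interaction data.frames, true signal state matrices, the planted
#'   `panel`), and `config`.
#' @export
simulate_regulatory_landscape <- function(cfg = simulation_config()) {
  .with_seed(cfg$rng_seed, {
    genome <- sum(cfg$chrom_lengths)
    if ((cfg$n_tss + cfg$n_enhancers) * 5000 > genome) {
      stop("too many regions for the genome size", call. = FALSE)
    }
    chroms <- names(cfg$chrom_lengths)
    # TSS uniform over the genome, proportional to chromosome length
    tss_chrom <- sample(chroms, cfg$n_tss, replace = TRUE,
                        prob = cfg$chrom_lengths / genome)
    tss <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_tss)),
      chrom = tss_chrom,
      position = vapply(tss_chrom, function(ch)
        sample.int(cfg$chrom_lengths[[ch]] - 10000L, 1) + 5000L, 0L),
      strand = sample(c("+", "-"), cfg$n_tss, replace = TRUE)
    )
    tss <- tss[order(tss$chrom, tss$position), ]
    rownames(tss) <- NULL
    promoters <- build_promoter_regions(tss)

    # enhancer candidates: uniform, >= 2500 bp from every TSS
    enh <- list()
    tries <- 0
    while (length(enh) < cfg$n_enhancers && tries < 50 * cfg$n_enhancers) {
      tries <- tries + 1
      ch <- sample(chroms, 1, prob = cfg$chrom_lengths / genome)
      w <- sample(500:1500, 1)
      s <- sample.int(cfg$chrom_lengths[[ch]] - w - 1L, 1)
      cand <- data.frame(chrom = ch, start = s, end = s + w)
      if (classify_region(cand, tss) == "DISTAL") {
        enh[[length(enh) + 1L]] <- cand
      }
    }
    enhancers <- do.call(rbind, enh)
    enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ]
    rownames(enhancers) <- NULL

    regions <- rbind(enhancers[, c("chrom", "start", "end")],
                     promoters[, c("chrom", "start", "end")])
    region_ids <- .region_id(regions)
    base_state <- .draw_states(nrow(regions), cfg)
    rownames(base_state) <- region_ids

    cell_lines <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
    states <- lapply(cell_lines, function(cl) {
      drop_mask <- matrix(stats::rbinom(length(base_state), 1,
                                        cfg$cell_dropout),
                          nrow(base_state))
      st <- base_state * (1L - drop_mask)
      dimnames(st) <- dimnames(base_state)
      st
    })
    names(states) <- cell_lines

    # observed peak tracks: observation noise + -log10 P scores
    tracks <- lapply(states, function(st) {
      obs <- st
      flip0 <- stats::rbinom(length(obs), 1, cfg$false_peak_rate)
      flip1 <- stats::rbinom(length(obs), 1, cfg$peak_dropout_rate)
      obs <- ifelse(obs == 1L, 1L - flip1, flip0)
      out <- lapply(cfg$datasets, function(d) {
        idx <- which(obs[, d] == 1L)
        peak_track(data.frame(
          chrom = regions$chrom[idx], start = regions$start[idx],
          end = regions$end[idx],
          score = 2 + stats::rexp(length(idx), 1 / 3)
        ), dataset = d, cell_line = NA_character_)
      })
      stats::setNames(out, cfg$datasets)
    })
    for (cl in cell_lines) {
      for (d in cfg$datasets) tracks[[cl]][[d]]$cell_line <- cl
    }

    # expression: promoters with active marks express their gene
    prom_ids <- .region_id(promoters)
    expression <- lapply(states, function(st) {
      act <- st[prom_ids, "H3K4me3"] == 1L | st[prom_ids, "DNase"] == 1L
      rpkm <- ifelse(act, stats::rlnorm(length(act), meanlog = 3, sdlog = 1),
                     ifelse(stats::rbinom(length(act), 1, 0.2) == 1,
                            stats::runif(length(act), 0, 1), 0))
      stats::setNames(rpkm, promoters$gene_id)
    })

    # true interactions: planted rule + shared distance-decay coin +
    # per-cell-line interaction dropout
    cand <- enumerate_candidates(enhancers, promoters,
                                 max_distance = cfg$max_distance)
    e_ids <- .region_id(data.frame(chrom = cand$e_chrom, start = cand$e_start,
                                   end = cand$e_end))
    p_ids <- .region_id(data.frame(chrom = cand$p_chrom, start = cand$p_start,
                                   end = cand$p_end))
    accept <- stats::runif(nrow(cand)) < exp(-cand$distance / cfg$decay_scale)
    truth_sets <- lapply(cell_lines, function(cl) {
      st <- states[[cl]]
      sat_e <- rowSums(st[e_ids, cfg$rule$enhancer, drop = FALSE] == 1L) ==
        length(cfg$rule$enhancer)
      sat_p <- rowSums(st[p_ids, cfg$rule$promoter, drop = FALSE] == 1L) ==
        length(cfg$rule$promoter)
      keep <- sat_e & sat_p & accept &
        stats::runif(nrow(cand)) >= cfg$interaction_dropout
      cand[keep, , drop = FALSE]
    })
    names(truth_sets) <- cell_lines

    list(tss = tss, enhancers = enhancers, promoters = promoters,
         tracks = tracks, expression = expression,
         truth = list(interactions = truth_sets, states = states,
                      panel = unique(c(cfg$rule$enhancer, cfg$rule$promoter))),
         candidates = cand, config = cfg)
  })
}

#' Simulate a binned contact matrix around planted interactions
#'
#' Background counts follow a Poisson model with exponential distance
#' decay; bin pairs containing a true interaction get their expected count
#' multiplied by `signal_mult`. The matrix is symmetric by construction
#' (entries stored once with `bin_i <= bin_j`).
#'
#' @param truth_interactions data.frame of true interactions (`e_*`, `p_*`
#'   columns) for one cell line.
#' @param chrom_lengths named chromosome lengths.
#' @param bin_size bin size in bp (default 10000).
#' @param signal_mult multiplier on true-interaction bin pairs (> 1 for a
#'   planted contrast; 1 gives a pure background matrix).
#' @param background expected background count at distance 0 (default 20).
#' @param decay_scale distance-decay scale in bp (default 2e5).
#' @param rng_seed integer seed.
#' @return Contact data.frame (`chrom`, `bin_i`, `bin_j`, `count`) with a
#'   `bin_size` attribute, as from [read_contact_matrix()].
#' @export
simulate_contact_matrix <- function(truth_interactions, chrom_lengths,
                                    bin_size = 10000, signal_mult = 10,
                                    background = 20, decay_scale = 2e5,
                                    rng_seed = 1L) {
  stopifnot(signal_mult >= 1)
  .with_seed(rng_seed, {
    out <- list()
    for (chr in names(chrom_lengths)) {
      nb <- ceiling(chrom_lengths[[chr]] / bin_size)
      tr <- truth_interactions[truth_interactions$e_chrom == chr, ,
                               drop = FALSE]
      tb_i <- .midpoint_bin(tr$e_start, tr$e_end, bin_size)
      tb_j <- .midpoint_bin(tr$p_start, tr$p_end, bin_size)
      true_key <- unique(paste(pmin(tb_i, tb_j), pmax(tb_i, tb_j)))
      # enumerate bin pairs within the decay horizon (counts beyond are ~0)
      horizon <- ceiling(10 * decay_scale / bin_size)
      ij <- do.call(rbind, lapply(0:(nb - 1), function(i) {
        j <- i:min(nb - 1, i + horizon)
        cbind(i, j)
      }))
      d <- (ij[, 2] - ij[, 1]) * bin_size
      mu <- background * exp(-d / decay_scale)
      key <- paste(ij[, 1], ij[, 2])
      mu[key %in% true_key] <- mu[key %in% true_key] * signal_mult
      cnt <- stats::rpois(length(mu), mu)
      keep <- cnt > 0 | key %in% true_key
      out[[chr]] <- data.frame(chrom = chr, bin_i = ij[keep, 1],
                               bin_j = ij[keep, 2], count = cnt[keep])
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "bin_size") <- bin_size
    res
  })
}

#' Export a simulated landscape as standard-format files
#'
#' Writes, per cell line, narrowPeak tracks, an expression TSV and a truth
#' BEDPE; plus a genome-wide TSS TSV, enhancer BED, and a JSON manifest
#' with the configuration and seed. Files round-trip through the package's
#' readers.
#'
#' @param sim result of [simulate_regulatory_landscape()].
#' @param directory output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
export_fixture <- function(sim, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_bed <- function(df, path, score = NULL) {
    out <- df[, c("chrom", "start", "end")]
    if (!is.null(score)) {
      out$name <- "."
      out$score <- 0
      out$strand <- "."
      out$signalValue <- 0
      out$pValue <- score  # narrowPeak -log10 P column (7 cols here + 1)
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(sim$enhancers, file.path(directory, "enhancers.bed"))
  utils::write.table(sim$tss, file.path(directory, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (cl in names(sim$tracks)) {
    cl_dir <- file.path(directory, cl)
    dir.create(cl_dir, showWarnings = FALSE)
    for (d in names(sim$tracks[[cl]])) {
      pk <- sim$tracks[[cl]][[d]]$peaks
      write_bed(pk, file.path(cl_dir, paste0(d, ".narrowPeak")),
                score = pk$score)
    }
    expr <- sim$expression[[cl]]
    utils::write.table(data.frame(gene = names(expr), rpkm = expr),
                       file.path(cl_dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    tr <- sim$truth$interactions[[cl]]
    write_bedpe(data.frame(chrom1 = tr$e_chrom, start1 = tr$e_start,
                           end1 = tr$e_end, chrom2 = tr$p_chrom,
                           start2 = tr$p_start, end2 = tr$p_end),
                file.path(cl_dir, "truth.bedpe"))
  }
  manifest <- file.path(directory, "manifest.json")
  cfg <- sim$config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$base_rates <- as.list(cfg$base_rates)
  jsonlite::write_json(unclass(cfg), manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Build labeled training examples from a simulated landscape
#'
#' Convenience wrapper tying the simulator to the training-set machinery:
#' for one cell line, takes the true interactions as positives, samples
#' distance-matched negatives from the candidate universe, and encodes
#' both.
#'
#' @param sim result of [simulate_regulatory_landscape()].
#' @param cell_line cell-line name (e.g. `"CL1"`).
#' @param spec an [encoding_spec()].
#' @param ratio negatives per positive (default 1).
#' @param rng_seed integer seed for negative sampling.
#' @return Encoded labeled example data.frame (attribute `cell_line` set).
#' @export
simulated_examples <- function(sim, cell_line, spec = encoding_spec(),
                               ratio = 1, rng_seed = 1L) {
  pos <- sim$truth$interactions[[cell_line]]
  pos$label <- 1L
  negs <- sample_matched_negatives(pos, sim$candidates, ratio = ratio,
                                   rng_seed = rng_seed)
  pairs <- rbind(pos, negs[, names(pos), drop = FALSE])
  ex <- batch_encode(pairs, sim$tracks[[cell_line]],
                     sim$expression[[cell_line]], spec)
  attr(ex, "cell_line") <- cell_line
  ex
}
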