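# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written as a different algorithm from the one it
# checks.

# AUPR oracle: brute-force threshold enumeration. For every integer true-
# positive count t = 1..P, scan all thresholds to find the segment
# containing t and linearly interpolate the false-positive count; the area
# is the trapezoidal sum over (recall, precision) at those points, with the
# recall-0 precision taken as the first point's precision when no false
# positive precedes it and 0 otherwise.
aupr_oracle <- function(probabilities, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  stopifnot(P >= 1)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp_at <- c(0L, vapply(thr, function(t)
    sum(labels == 1 & probabilities >= t), 0L))
  fp_at <- c(0L, vapply(thr, function(t)
    sum(labels == 0 & probabilities >= t), 0L))
  # build the full interpolated curve point list in threshold order:
  # recall-increasing segments get unit-TP interpolated points, vertical
  # segments append the (same-recall, lower-precision) achievable point
  R <- numeric(); Pr <- numeric()
  for (k in 2:length(tp_at)) {
    dt <- tp_at[k] - tp_at[k - 1]
    if (dt == 0) {
      if (tp_at[k] > 0) {
        R <- c(R, tp_at[k] / P)
        Pr <- c(Pr, tp_at[k] / (tp_at[k] + fp_at[k]))
      }
      next
    }
    s <- (fp_at[k] - fp_at[k - 1]) / dt
    for (x in seq_len(dt)) {
      R <- c(R, (tp_at[k - 1] + x) / P)
      Pr <- c(Pr, (tp_at[k - 1] + x) /
                (tp_at[k - 1] + x + fp_at[k - 1] + s * x))
    }
  }
  first_seg <- which(diff(tp_at) > 0)[1]  # segment adding the first TP
  prec0 <- if (fp_at[first_seg] == 0) Pr[1] else 0
  R <- c(0, R); Pr <- c(prec0, Pr)
  sum(diff(R) * (Pr[-1] + Pr[-length(Pr)]) / 2)
}

# power iteration on a covariance matrix; returns the dominant eigenvector
power_iteration <- function(S, iters = 100000, tol = 1e-13) {
  v <- rep(1 / sqrt(ncol(S)), ncol(S))
  for (i in seq_len(iters)) {
    w <- drop(S %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) { v <- w; break }
    v <- w
  }
  v
}

# BFS connected components of a bipartite edge list; returns the
# SINGLE/MI/MO/MIMO class counts and per-class edge counts
bfs_taxonomy <- function(edges) {
  nodes <- unique(c(paste0("E|", edges$enhancer_id),
                    paste0("P|", edges$promoter_id)))
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    e <- paste0("E|", edges$enhancer_id[i])
    p <- paste0("P|", edges$promoter_id[i])
    adj[[e]] <- c(adj[[e]], p)
    adj[[p]] <- c(adj[[p]], e)
  }
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (n in nodes) {
    if (!is.na(comp[n])) next
    cid <- cid + 1L
    queue <- n
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      queue <- c(queue, adj[[cur]])
    }
  }
  cls <- vapply(seq_len(cid), function(k) {
    members <- names(comp)[comp == k]
    ne <- sum(startsWith(members, "E|"))
    np <- sum(startsWith(members, "P|"))
    if (ne == 1 && np == 1) "SINGLE" else if (ne > 1 && np == 1) "MI"
    else if (ne == 1 && np > 1) "MO" else "MIMO"
  }, "")
  edge_cls <- cls[comp[paste0("E|", edges$enhancer_id)]]
  list(class_counts = table(cls), edge_class_counts = table(edge_cls))
}

# per-base occupancy union of 0-based half-open intervals on one chromosome
per_base_union <- function(starts, ends) {
  lim <- max(ends)
  occ <- logical(lim)
  for (i in seq_along(starts)) occ[(starts[i] + 1):ends[i]] <- TRUE
  runs <- rle(occ)
  pos <- cumsum(c(0, runs$lengths))
  idx <- which(runs$values)
  data.frame(start = pos[idx], end = pos[idx + 1])
}
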