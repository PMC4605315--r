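# Cross-cell-line ensembles: percentile-rank averaging, the Spectral Meta
# Learner (leading eigenvector of the prediction covariance), and the
# pooled-training SimpleMerge baseline.

.check_prediction_matrix <- function(P) {
  P <- as.matrix(P)
  stopifnot(is.numeric(P), nrow(P) >= 1)
  if (any(P < -1e-12 | P > 1 + 1e-12)) {
    stop("prediction matrix entries must be probabilities in [0, 1]",
         call. = FALSE)
  }
  P
}

#' Percentile-rank averaging ensemble
#'
#' Within each classifier column, probabilities are converted to percentile
#' ranks (average ranks for ties, divided by the number of pairs so the
#' maximum is 1); the ensemble score of a pair is the mean of its percentile
#' ranks across classifiers. Invariant to any strictly monotone
#' per-classifier transform.
#'
#' @param P pairs x classifiers probability matrix.
#' @return List with `scores` (in (0, 1]), `method = "PERCENTILE"`, and the
#'   per-classifier `percentiles` matrix.
#' @export
percentile_ensemble <- function(P) {
  P <- .check_prediction_matrix(P)
  pct <- apply(P, 2, function(col) rank(col, ties.method = "average") / length(col))
  pct <- matrix(pct, nrow = nrow(P), dimnames = dimnames(P))
  list(scores = rowMeans(pct), method = "PERCENTILE", percentiles = pct)
}

#' Spectral Meta Learner ensemble
#'
#' Computes the K x K covariance matrix of the classifier probability
#' columns and scores each pair by the dot product of its probability
#' vector with the unit eigenvector of the largest eigenvalue. Eigenvectors
#' are sign-ambiguous; the orientation with non-negative entry sum is used
#' (ties broken toward a positive first coordinate), corresponding to
#' better-than-chance classifiers receiving positive weight.
#'
#' @param P pairs x classifiers probability matrix (K >= 2, at least one
#'   column with nonzero variance).
#' @return List with `scores`, `method = "SML"`, covariance `sigma`,
#'   eigenvector `e`, and `weights` (= e).
#' @export
sml_ensemble <- function(P) {
  P <- .check_prediction_matrix(P)
  stopifnot(ncol(P) >= 2)
  if (all(apply(P, 2, stats::sd) == 0)) {
    stop("degenerate prediction matrix: all classifier columns constant",
         call. = FALSE)
  }
  sigma <- stats::cov(P)
  es <- eigen(sigma, symmetric = TRUE)
  e <- es$vectors[, 1]
  s <- sum(e)
  if (s < 0 || (s == 0 && e[1] < 0)) e <- -e
  list(scores = drop(P %*% e), method = "SML", sigma = sigma, e = e,
       weights = e)
}

#' Pooled-training SimpleMerge ensemble
#'
#' Concatenates the labeled examples of all source cell lines, trains one
#' Random Forest on the merged set, and scores the target pairs with it.
#'
#' @param training_sets list of encoded labeled example data.frames
#'   (source cell lines; identical feature panels).
#' @param target_examples encoded pair data.frame to score.
#' @param n_trees trees (default 500).
#' @param rng_seed integer seed.
#' @return List with `scores`, `method = "SIMPLE_MERGE"`, and the trained
#'   `model`.
#' @export
simple_merge <- function(training_sets, target_examples, n_trees = 500,
                         rng_seed = 1L) {
  stopifnot(length(training_sets) >= 1)
  fn <- attr(training_sets[[1]], "feature_names")
  for (ts in training_sets) {
    if (!identical(attr(ts, "feature_names"), fn)) {
      stop("feature names differ across source cell lines", call. = FALSE)
    }
  }
  merged <- do.call(rbind, training_sets)
  attr(merged, "feature_names") <- fn
  model <- train_rf(merged, n_trees = n_trees, rng_seed = rng_seed)
  list(scores = predict_prob(model, target_examples), method = "SIMPLE_MERGE",
       model = model)
}
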