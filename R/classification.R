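# Per-cell-line predictive models and their evaluation. Random Forests are
# the primary model; L1-regularized linear (labels recoded -1/+1) and
# logistic regressions are baselines. Performance is measured by the area
# under the precision-recall curve with nonlinear (unit-true-positive)
# interpolation between achievable points.

.label_vector <- function(examples) {
  y <- examples$label
  if (any(is.na(y))) stop("examples carry missing labels", call. = FALSE)
  as.integer(y)
}

#' Train a Random Forest interaction classifier
#'
#' 500 trees by default; remaining hyperparameters are the standard Random
#' Forest defaults (sqrt(d) features per split, unlimited depth). The fit
#' keeps out-of-bag bookkeeping so permutation importance can be read off.
#'
#' @param examples encoded example data.frame with a binary `label` column.
#' @param n_trees number of trees (default 500).
#' @param rng_seed integer seed; training is deterministic given it.
#' @param importance keep out-of-bag permutation-importance bookkeeping
#'   (needed by [permutation_importance()]; off by default since it roughly
#'   doubles training time).
#' @return A `TrainedModel` (kind `"RF"`).
#' @export
train_rf <- function(examples, n_trees = 500, rng_seed = 1L,
                     importance = FALSE) {
  X <- feature_matrix(examples)
  y <- .label_vector(examples)
  if (length(unique(y)) < 2) stop("training set has a single class", call. = FALSE)
  fit <- .with_seed(rng_seed, {
    randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                               ntree = n_trees, importance = importance,
                               keep.forest = TRUE)
  })
  structure(list(kind = "RF", fit = fit, feature_names = colnames(X),
                 cell_line = attr(examples, "cell_line"),
                 n_trees = n_trees, rng_seed = rng_seed),
            class = "TrainedModel")
}

.lambda_grid <- function(X, y, family, nlambda = 50) {
  # from lambda_max (all-zero model) down to 1e-4 * lambda_max, log-spaced
  n <- nrow(X)
  r <- if (family == "binomial") y - mean(y) else y
  lmax <- max(abs(crossprod(scale(X, scale = FALSE), r))) / n
  lmax <- max(lmax, .Machine$double.eps)
  exp(seq(log(lmax), log(1e-4 * lmax), length.out = nlambda))
}

#' Train an L1-regularized regression baseline
#'
#' `kind = "LASSO"` is linear regression on labels recoded to -1/+1; its
#' continuous output is min-max mapped to [0, 1] at prediction time.
#' `kind = "GLMLASSO"` is L1-penalized logistic regression. `lambda` is
#' chosen by 5-fold cross-validation minimizing prediction error unless
#' supplied.
#'
#' @param examples encoded example data.frame with `label`.
#' @param kind `"LASSO"` or `"GLMLASSO"`.
#' @param lambda optional fixed penalty; chosen by inner CV when `NULL`.
#' @param rng_seed integer seed (inner CV folds).
#' @return A `TrainedModel`.
#' @export
train_lasso <- function(examples, kind = c("LASSO", "GLMLASSO"), lambda = NULL,
                        rng_seed = 1L) {
  kind <- match.arg(kind)
  X <- feature_matrix(examples)
  y01 <- .label_vector(examples)
  family <- if (kind == "LASSO") "gaussian" else "binomial"
  y <- if (kind == "LASSO") 2 * y01 - 1 else y01
  grid <- .lambda_grid(X, y, family)
  fit <- .with_seed(rng_seed, {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(X, y, family = family, lambda = grid, nfolds = 5)
      lambda <- cv$lambda.min
      cv$glmnet.fit
    } else {
      glmnet::glmnet(X, y, family = family, lambda = grid)
    }
  })
  structure(list(kind = kind, fit = fit, lambda = lambda,
                 feature_names = colnames(X), rng_seed = rng_seed),
            class = "TrainedModel")
}

#' Predict interaction probabilities
#'
#' @param model a `TrainedModel`.
#' @param examples encoded example data.frame (features must match the
#'   model's feature panel).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_prob <- function(model, examples) {
  X <- feature_matrix(examples)
  if (!identical(colnames(X), model$feature_names)) {
    stop("feature panel mismatch between model and examples", call. = FALSE)
  }
  switch(model$kind,
    RF = unname(stats::predict(model$fit, X, type = "prob")[, "1"]),
    GLMLASSO = as.numeric(stats::predict(model$fit, X, s = model$lambda,
                                         type = "response")),
    LASSO = {
      raw <- as.numeric(stats::predict(model$fit, X, s = model$lambda))
      rng <- range(raw)
      if (diff(rng) == 0) rep(0.5, length(raw))
      else (raw - rng[1]) / diff(rng)
    },
    stop("unknown model kind: ", model$kind)
  )
}

# Pooled-tie PR points: for each distinct score threshold (descending),
# cumulative true and false positives among examples scoring >= it.
.pr_points <- function(probabilities, labels) {
  o <- order(probabilities, decreasing = TRUE)
  p <- probabilities[o]; y <- labels[o]
  n <- length(p)
  idx <- if (n == 1) 1L else which(c(p[-1] != p[-n], TRUE))
  data.frame(tp = cumsum(y)[idx], fp = cumsum(1 - y)[idx])
}

#' Area under the precision-recall curve
#'
#' Computed from the achievable PR points (ties pooled into one threshold
#' step) with nonlinear interpolation: between consecutive achievable
#' points, intermediate points are created at unit true-positive increments
#' with false positives interpolated linearly, and the area is the
#' trapezoidal sum over all points. Precision at recall 0 is taken as the
#' first segment's precision when no false positive precedes it, 0
#' otherwise.
#'
#' @param probabilities numeric scores.
#' @param labels binary labels (at least one positive).
#' @return AUPR in [0, 1].
#' @export
compute_aupr <- function(probabilities, labels) {
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels))
  P <- sum(labels == 1)
  if (P == 0) stop("AUPR undefined: no positive labels", call. = FALSE)
  pts <- .pr_points(probabilities, labels)
  # walk segments, accumulating trapezoids at unit-TP interpolated points
  area <- 0
  tp_prev <- 0; fp_prev <- 0
  prec_prev <- NA_real_  # precision at the previous curve point
  for (k in seq_len(nrow(pts))) {
    tp <- pts$tp[k]; fp <- pts$fp[k]
    dtp <- tp - tp_prev
    if (dtp > 0) {
      slope <- (fp - fp_prev) / dtp
      xs <- seq_len(dtp)
      tps <- tp_prev + xs
      fps <- fp_prev + slope * xs
      precs <- tps / (tps + fps)
      if (is.na(prec_prev)) {
        # start of the curve: constant precision when the segment starts
        # clean (fp_prev == 0), else the limiting precision 0
        prec_prev <- if (fp_prev == 0) precs[1] else 0
      }
      all_prec <- c(prec_prev, precs)
      area <- area + sum((all_prec[-1] + all_prec[-length(all_prec)]) / 2) / P
      prec_prev <- precs[dtp]
    } else if (tp > 0) {
      # vertical segment: recall unchanged, precision drops; subsequent
      # interpolation starts from the lowered precision
      prec_prev <- tp / (tp + fp)
    }
    tp_prev <- tp; fp_prev <- fp
  }
  area
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label. Each example is scored exactly once while
#' held out; AUPR is computed on the pooled out-of-fold probabilities and
#' per fold. For the regularized baselines, lambda is chosen within each
#' fold by an inner 5-fold cross-validation on the training split.
#'
#' @param examples encoded example data.frame with `label`.
#' @param model_kind `"RF"`, `"LASSO"` or `"GLMLASSO"`.
#' @param k number of folds (default 10).
#' @param n_trees trees per RF fit.
#' @param rng_seed integer seed (fold assignment and model training).
#' @return A `CVResult`: list with `probabilities`, `labels`, `fold`,
#'   `aupr` (pooled), `fold_aupr`, `model_kind`.
#' @export
cross_validate <- function(examples, model_kind = "RF", k = 10, n_trees = 500,
                           rng_seed = 1L) {
  y <- .label_vector(examples)
  n <- length(y)
  stopifnot(k <= n)
  fold <- integer(n)
  .with_seed(rng_seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  prob <- numeric(n)
  for (f in seq_len(k)) {
    train <- examples[fold != f, , drop = FALSE]
    attr(train, "feature_names") <- attr(examples, "feature_names")
    test <- examples[fold == f, , drop = FALSE]
    attr(test, "feature_names") <- attr(examples, "feature_names")
    model <- if (model_kind == "RF") {
      train_rf(train, n_trees = n_trees, rng_seed = rng_seed + f)
    } else {
      train_lasso(train, kind = model_kind, rng_seed = rng_seed + f)
    }
    prob[fold == f] <- predict_prob(model, test)
  }
  fold_aupr <- vapply(seq_len(k), function(f) {
    if (sum(y[fold == f]) == 0) NA_real_
    else compute_aupr(prob[fold == f], y[fold == f])
  }, 0.0)
  structure(list(probabilities = prob, labels = y, fold = fold,
                 aupr = compute_aupr(prob, y), fold_aupr = fold_aupr,
                 model_kind = model_kind, k = k, rng_seed = rng_seed),
            class = "CVResult")
}

#' Out-of-bag permutation importance of a Random Forest
#'
#' The importance of feature j is the mean decrease in out-of-bag
#' classification accuracy when feature j is permuted (the Random Forest
#' out-of-bag permutation measure, unscaled). A constant feature has
#' importance exactly 0.
#'
#' @param model a `TrainedModel` of kind `"RF"` trained with importance
#'   bookkeeping (as [train_rf()] does).
#' @return Named numeric vector of importances.
#' @export
permutation_importance <- function(model) {
  stopifnot(model$kind == "RF")
  if (!"MeanDecreaseAccuracy" %in% colnames(model$fit$importance)) {
    stop("model was trained without importance bookkeeping; use train_rf(..., importance = TRUE)",
         call. = FALSE)
  }
  imp <- randomForest::importance(model$fit, type = 1, scale = FALSE)
  stats::setNames(as.numeric(imp), rownames(imp))
}

#' Null AUPR distribution by probability shuffling
#'
#' Shuffles the probabilities among the pairs `n_shuffles` times and
#' recomputes the AUPR each time, giving the random-prediction baseline
#' whose mean is close to the positive fraction.
#'
#' @param probabilities numeric scores.
#' @param labels binary labels.
#' @param n_shuffles number of shuffles (default 100).
#' @param rng_seed integer seed.
#' @return List with `auprs`, `mean`, and the central 95% `band`.
#' @export
shuffled_baseline <- function(probabilities, labels, n_shuffles = 100,
                              rng_seed = 1L) {
  stopifnot(n_shuffles >= 1)
  auprs <- .with_seed(rng_seed, {
    vapply(seq_len(n_shuffles), function(i) {
      compute_aupr(sample(probabilities), labels)
    }, 0.0)
  })
  list(auprs = auprs, mean = mean(auprs),
       band = unname(stats::quantile(auprs, c(0.025, 0.975))))
}
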