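# Hybrid minimal-panel selection: multi-task Group Lasso across cell-line
# tasks (proximal gradient with block soft-thresholding of feature rows),
# Random Forest importance consensus, their intersection, and a
# correlation-guided greedy refinement of the data-set panel.

#' Bundle per-cell-line classification tasks
#'
#' @param X list of K design matrices (examples x N features, identical
#'   feature names and order across tasks).
#' @param Y list of K binary label vectors (0/1; recoded -1/+1 internally
#'   for the linear losses).
#' @return A `TaskBundle`.
#' @export
task_bundle <- function(X, Y) {
  stopifnot(length(X) == length(Y), length(X) >= 1)
  fn <- colnames(X[[1]])
  for (c in seq_along(X)) {
    stopifnot(identical(colnames(X[[c]]), fn), nrow(X[[c]]) == length(Y[[c]]))
  }
  structure(list(X = X, Y = lapply(Y, function(y) 2 * as.numeric(y > 0) - 1),
                 K = length(X), feature_names = fn,
                 N = length(fn)),
            class = "TaskBundle")
}

.gl_penalty <- function(B, squared) {
  rn <- sqrt(rowSums(B^2))
  if (squared) sum(rn^2) else sum(rn)
}

.gl_loss <- function(B, bundle, loss) {
  total <- 0
  for (c in seq_len(bundle$K)) {
    eta <- drop(bundle$X[[c]] %*% B[, c])
    total <- total + if (loss == "SQUARED") {
      sum((bundle$Y[[c]] - eta)^2)
    } else {
      sum(log1p(exp(-bundle$Y[[c]] * eta)))
    }
  }
  total
}

.gl_grad <- function(B, bundle, loss) {
  G <- matrix(0, bundle$N, bundle$K)
  for (c in seq_len(bundle$K)) {
    eta <- drop(bundle$X[[c]] %*% B[, c])
    y <- bundle$Y[[c]]
    G[, c] <- if (loss == "SQUARED") {
      -2 * crossprod(bundle$X[[c]], y - eta)
    } else {
      -crossprod(bundle$X[[c]], y / (1 + exp(y * eta)))
    }
  }
  G
}

#' Multi-task Group Lasso objective
#'
#' Sum over tasks of the data loss plus `lambda` times the L1/L2 row norm
#' of the coefficient matrix, `sum_j ||B_j||_2` (rows are features, columns
#' are tasks). The squared-row-norm variant is available for comparison but
#' is a ridge-type penalty that does not zero rows.
#'
#' @param B N x K coefficient matrix.
#' @param bundle a [task_bundle()].
#' @param lambda penalty weight.
#' @param loss `"SQUARED"` or `"LOGISTIC"`.
#' @param squared_penalty use `sum_j ||B_j||_2^2` instead of the row-sparsity
#'   norm.
#' @return Objective value.
#' @export
group_lasso_objective <- function(B, bundle, lambda, loss = "SQUARED",
                                  squared_penalty = FALSE) {
  .gl_loss(B, bundle, loss) + lambda * .gl_penalty(B, squared_penalty)
}

#' Smallest penalty that zeroes the whole model
#'
#' For `lambda >= lambda_max` the all-zero coefficient matrix is optimal:
#' `lambda_max` is the largest row norm of the data-loss gradient at B = 0.
#'
#' @inheritParams group_lasso_objective
#' @return `lambda_max`.
#' @export
group_lasso_lambda_max <- function(bundle, loss = "SQUARED") {
  G0 <- .gl_grad(matrix(0, bundle$N, bundle$K), bundle, loss)
  max(sqrt(rowSums(G0^2)))
}

#' Fit the multi-task Group Lasso by proximal gradient
#'
#' Monotone proximal-gradient descent: a gradient step on the data loss
#' followed by block soft-thresholding of each feature row
#' `B_j <- B_j * max(0, 1 - t*lambda / ||B_j||_2)`, with backtracking line
#' search on the step size. Converges when the relative objective decrease
#' falls below `tol`.
#'
#' @param bundle a [task_bundle()].
#' @param lambda penalty weight (>= 0).
#' @param loss `"SQUARED"` or `"LOGISTIC"` (the classification default).
#' @param tol relative objective tolerance (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @param squared_penalty ridge-type variant flag (no row sparsity).
#' @return A `GroupLassoFit`: `B`, `lambda`, `objective` trace,
#'   `selected_rows` (features with row norm > 1e-8), `converged`.
#' @export
fit_multitask_group_lasso <- function(bundle, lambda,
                                      loss = c("LOGISTIC", "SQUARED"),
                                      tol = 1e-8, max_iter = 500,
                                      squared_penalty = FALSE) {
  loss <- match.arg(loss)
  stopifnot(lambda >= 0)
  B <- matrix(0, bundle$N, bundle$K,
              dimnames = list(bundle$feature_names, NULL))
  # analytic shutdown: B = 0 is optimal whenever every gradient row norm at
  # zero is within lambda (the row-sparsity penalty's subdifferential)
  if (!squared_penalty &&
      lambda >= group_lasso_lambda_max(bundle, loss) * (1 - 1e-12)) {
    return(structure(list(B = B, lambda = lambda, loss = loss,
                          objective = .gl_loss(B, bundle, loss),
                          converged = TRUE, selected_rows = character()),
                     class = "GroupLassoFit"))
  }
  # Lipschitz bound on the data-loss gradient
  L <- 0
  for (c in seq_len(bundle$K)) {
    s <- svd(bundle$X[[c]], nu = 0, nv = 0)$d[1]^2
    L <- max(L, if (loss == "SQUARED") 2 * s else 0.25 * s)
  }
  t0 <- 1 / max(L, .Machine$double.eps)

  prox <- function(Z, thr) {
    if (squared_penalty) return(Z / (1 + 2 * thr))
    rn <- sqrt(rowSums(Z^2))
    shrink <- pmax(0, 1 - thr / pmax(rn, .Machine$double.eps))
    Z * shrink
  }
  obj <- function(B) .gl_loss(B, bundle, loss) + lambda * .gl_penalty(B, squared_penalty)

  trace <- obj(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- .gl_grad(B, bundle, loss)
    f_B <- .gl_loss(B, bundle, loss)
    t <- t0
    repeat {  # backtracking on the majorization of the data loss
      Bn <- prox(B - t * G, t * lambda)
      D <- Bn - B
      if (.gl_loss(Bn, bundle, loss) <=
            f_B + sum(G * D) + sum(D^2) / (2 * t) + 1e-12) break
      t <- t / 2
      if (t < 1e-16) { Bn <- B; break }
    }
    B <- Bn
    trace <- c(trace, obj(B))
    m <- length(trace)
    if (abs(trace[m - 1] - trace[m]) <= tol * max(1, abs(trace[m - 1]))) {
      converged <- TRUE
      break
    }
  }
  rn <- sqrt(rowSums(B^2))
  structure(list(B = B, lambda = lambda, loss = loss,
                 objective = trace, converged = converged,
                 selected_rows = bundle$feature_names[rn > 1e-8]),
            class = "GroupLassoFit")
}

# center and unit-scale each task's columns (constant columns stay zero);
# puts binary peak indicators and continuous RPKM on a common penalty scale
.standardize_bundle <- function(bundle) {
  X <- lapply(bundle$X, function(x) {
    s <- apply(x, 2, stats::sd)
    s[s == 0] <- 1
    scale(x, center = TRUE, scale = s)
  })
  task_bundle(X, lapply(bundle$Y, function(y) (y + 1) / 2))
}

.subset_bundle <- function(bundle, idx_list) {
  task_bundle(
    X = lapply(seq_len(bundle$K), function(c) bundle$X[[c]][idx_list[[c]], , drop = FALSE]),
    Y = lapply(seq_len(bundle$K), function(c) (bundle$Y[[c]][idx_list[[c]]] + 1) / 2)
  )
}

#' Fold-consensus feature selection by multi-task Group Lasso
#'
#' Per cross-validation fold, the Group Lasso is fit on the fold's training
#' split with lambda chosen by inner validation over `lambda_grid` (an 80/20
#' split of the fold's training data, minimizing held-out loss). A feature
#' is selected if its row is nonzero in at least `consensus` of the
#' `n_folds` folds; survivors are ranked by the sum over folds and tasks of
#' the absolute regression weights, and the top `top_k` are returned.
#' Columns are centered and unit-scaled per task first so binary peak
#' indicators and continuous features share a common penalty scale.
#'
#' @param bundle a [task_bundle()].
#' @param lambda_grid penalty grid; default 10 values log-spaced over
#'   `[1e-3, 0.5] * lambda_max`.
#' @param n_folds folds (default 10).
#' @param consensus minimum folds a feature must appear in (default 8).
#' @param top_k maximum number of features returned (default 20).
#' @param loss `"LOGISTIC"` (default) or `"SQUARED"`.
#' @param rng_seed integer seed.
#' @return List: `selected` (ranked feature names, length <= top_k),
#'   `fold_counts`, `weights` (summed |beta|), `lambda_by_fold`.
#' @export
select_features_mtl <- function(bundle, lambda_grid = NULL, n_folds = 10,
                                consensus = 8, top_k = 20,
                                loss = c("LOGISTIC", "SQUARED"),
                                rng_seed = 1L) {
  loss <- match.arg(loss)
  if (consensus > n_folds) stop("consensus cannot exceed n_folds", call. = FALSE)
  bundle <- .standardize_bundle(bundle)
  if (is.null(lambda_grid)) {
    lmax <- group_lasso_lambda_max(bundle, loss)
    lambda_grid <- exp(seq(log(0.5 * lmax), log(1e-3 * lmax), length.out = 10))
  }
  folds <- .with_seed(rng_seed, {
    lapply(seq_len(bundle$K), function(c) {
      y <- bundle$Y[[c]]
      f <- integer(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      f
    })
  })
  counts <- stats::setNames(integer(bundle$N), bundle$feature_names)
  weights <- stats::setNames(numeric(bundle$N), bundle$feature_names)
  lambda_by_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train_idx <- lapply(folds, function(ff) which(ff != f))
    # inner validation split of the fold's training data
    inner <- .with_seed(rng_seed + f, {
      lapply(train_idx, function(ti) {
        v <- sample(ti, max(1, floor(0.2 * length(ti))))
        list(fit = setdiff(ti, v), val = v)
      })
    })
    fit_bundle <- .subset_bundle(bundle, lapply(inner, `[[`, "fit"))
    val_bundle <- .subset_bundle(bundle, lapply(inner, `[[`, "val"))
    val_err <- vapply(lambda_grid, function(lm) {
      ft <- fit_multitask_group_lasso(fit_bundle, lm, loss = loss,
                                      max_iter = 200, tol = 1e-6)
      .gl_loss(ft$B, val_bundle, loss)
    }, 0.0)
    lambda_by_fold[f] <- lambda_grid[which.min(val_err)]
    full_bundle <- .subset_bundle(bundle, train_idx)
    ft <- fit_multitask_group_lasso(full_bundle, lambda_by_fold[f],
                                    loss = loss, max_iter = 300, tol = 1e-7)
    nz <- sqrt(rowSums(ft$B^2)) > 1e-8
    counts[nz] <- counts[nz] + 1L
    weights <- weights + rowSums(abs(ft$B))
  }
  surv <- names(counts)[counts >= consensus]
  surv <- surv[order(weights[surv], decreasing = TRUE)]
  list(selected = utils::head(surv, top_k), fold_counts = counts,
       weights = weights, lambda_by_fold = lambda_by_fold)
}

#' Collapse feature names to data-set names
#'
#' Strips the `_E` / `_P` side suffix; `correlation` and `expression` map to
#' themselves.
#'
#' @param features character vector of feature names.
#' @return Character vector of data-set names.
#' @export
feature_dataset <- function(features) {
  sub("_(E|P)$", "", features)
}

#' Data sets passing the Random Forest importance rule
#'
#' A feature qualifies if it is among the top `top_k` features by
#' out-of-bag permutation importance in at least `min_cell_lines` cell
#' lines; features are then collapsed to data sets over the `_E`/`_P`
#' suffix (a data set qualifies if either side does).
#'
#' @param importances list (one per cell line) of named importance vectors.
#' @param top_k rank cutoff (default 20).
#' @param min_cell_lines minimum cell lines (default 2).
#' @return Character vector of selected data-set names.
#' @export
rank_rf_features <- function(importances, top_k = 20, min_cell_lines = 2) {
  fn <- names(importances[[1]])
  stopifnot(all(vapply(importances, function(x) identical(names(x), fn), TRUE)))
  in_top <- sapply(importances, function(imp) {
    rank(-imp, ties.method = "min") <= top_k
  })
  qual <- fn[rowSums(in_top) >= min_cell_lines]
  unique(feature_dataset(qual))
}

# connected blocks of data sets with pairwise |r| above the threshold;
# uncorrelated data sets form singleton blocks
.correlation_blocks <- function(correlation_matrix, threshold) {
  A <- abs(correlation_matrix) > threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(split(names(comp), comp))
}

# mean cross-validated AUPR over cell lines using only features whose data
# set belongs to `panel`
.panel_aupr <- function(panel, example_sets, cv_folds, n_trees, rng_seed) {
  mean(vapply(seq_along(example_sets), function(i) {
    ex <- example_sets[[i]]
    fn <- attr(ex, "feature_names")
    keep <- fn[feature_dataset(fn) %in% panel]
    sub <- ex
    attr(sub, "feature_names") <- keep
    cross_validate(sub, "RF", k = cv_folds, n_trees = n_trees,
                   rng_seed = rng_seed + i)$aupr
  }, 0.0))
}

#' Correlation-guided refinement of a data-set panel
#'
#' Greedy search over the data-set panel: (1) correlated blocks are
#' identified (pairwise |r| above `cor_threshold`; uncorrelated data sets
#' form singleton blocks, so every panel member is examined); (2) removal
#' of each single, pair and triplet within a block is evaluated by mean
#' cross-validated AUPR over all cell lines, and the largest removal whose
#' mean AUPR drop from the initial panel is at most `tolerance` is applied;
#' (3) one pass re-adds excluded candidates that improve mean AUPR by more
#' than `tolerance`. The full evaluation ledger is returned.
#'
#' @param initial_set starting data-set panel (character).
#' @param candidate_pool all data sets eligible for re-adding (superset of
#'   `initial_set`).
#' @param example_sets list of encoded example data.frames, one per cell
#'   line (features named `<dataset>_E/_P`, plus `correlation`,
#'   `expression`).
#' @param correlation_matrix data-set level correlation matrix (named).
#' @param cor_threshold block threshold on |r| (default 0.7).
#' @param tolerance maximum tolerated mean AUPR drop (default 0.01).
#' @param cv_folds,n_trees evaluation settings (defaults 5 folds, 100
#'   trees: the evaluation only compares panels against each other).
#' @param rng_seed integer seed.
#' @return List: `refined_set`, `initial_aupr`, `final_aupr`, `ledger`
#'   (data.frame of every evaluated panel with its mean AUPR), `blocks`.
#' @export
refine_feature_set <- function(initial_set, candidate_pool, example_sets,
                               correlation_matrix, cor_threshold = 0.7,
                               tolerance = 0.01, cv_folds = 5, n_trees = 100,
                               rng_seed = 1L) {
  stopifnot(all(initial_set %in% candidate_pool))
  blocks <- .correlation_blocks(correlation_matrix, cor_threshold)
  ledger <- list()
  note <- function(panel, aupr, action) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      panel = paste(sort(panel), collapse = "+"), mean_aupr = aupr,
      action = action)
  }
  base_aupr <- .panel_aupr(initial_set, example_sets, cv_folds, n_trees, rng_seed)
  note(initial_set, base_aupr, "initial")

  current <- initial_set
  for (bl in blocks) {
    members <- intersect(bl, current)
    if (!length(members)) next
    sizes <- seq_len(min(3, length(members)))
    # evaluate larger removals first: prefer the most parsimonious panel
    for (sz in rev(sizes)) {
      removed <- FALSE
      for (combo in utils::combn(members, sz, simplify = FALSE)) {
        trial <- setdiff(current, combo)
        if (!length(trial)) next
        a <- .panel_aupr(trial, example_sets, cv_folds, n_trees, rng_seed)
        note(trial, a, paste0("remove:", paste(combo, collapse = "+")))
        if (base_aupr - a <= tolerance) {
          current <- trial
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
  }
  # re-add pass over excluded candidates
  cur_aupr <- .panel_aupr(current, example_sets, cv_folds, n_trees, rng_seed)
  for (ds in setdiff(candidate_pool, current)) {
    trial <- c(current, ds)
    a <- .panel_aupr(trial, example_sets, cv_folds, n_trees, rng_seed)
    note(trial, a, paste0("add:", ds))
    if (a - cur_aupr > tolerance) {
      current <- trial
      cur_aupr <- a
    }
  }
  list(refined_set = sort(current), initial_aupr = base_aupr,
       final_aupr = cur_aupr, ledger = do.call(rbind, ledger),
       blocks = blocks)
}
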