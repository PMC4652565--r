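#' Rank features by coefficient of variation
#'
#' Descending CV order; ties broken by lexicographic feature id so the
#' ranking is deterministic.
#'
#' @param mat Features x samples matrix with positive feature means.
#' @return A data frame of class `xpc_ranking` with columns `rank`,
#'   `feature_id`, `score` and attribute `method = "cv"`.
#' @export
rank_by_cv <- function(mat) {
  scores <- cv_scores(mat)
  ord <- order(-scores$cv, scores$feature_id)
  new_ranking(scores$feature_id[ord], scores$cv[ord], "cv")
}

new_ranking <- function(feature_ids, scores, method) {
  structure(data.frame(rank = seq_along(feature_ids),
                       feature_id = feature_ids,
                       score = scores, stringsAsFactors = FALSE),
            class = c("xpc_ranking", "data.frame"), method = method)
}

# sum of squared linear-SVM weights over all one-vs-one class pairs; the
# multiclass extension of the squared-weight elimination criterion
ovo_weight_criterion <- function(x, y, cost = 1) {
  classes <- levels(droplevels(y))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  crit <- numeric(ncol(x))
  for (pr in pairs) {
    idx <- y %in% pr
    fit <- e1071::svm(x[idx, , drop = FALSE], droplevels(y[idx]),
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)        # 1 x p weight vector
    crit <- crit + as.numeric(w)^2
  }
  structure(stats::setNames(crit, colnames(x)), n_pairs = length(pairs))
}

#' Multiclass SVM recursive feature elimination
#'
#' Iteratively trains linear one-vs-one SVMs on the surviving features,
#' scores each feature by the sum over the `C(C-1)/2` binary classifiers
#' of its squared weight, and removes the `ceiling(step_fraction * m)`
#' (at least one) lowest-scoring features per iteration. The ranking is
#' the reverse elimination order: the last survivor ranks first. Features
#' are standardized internally (zero mean, unit variance on the training
#' data) before fitting.
#'
#' @param x Samples x features numeric matrix with column names.
#' @param y Factor of class labels (>= 2 classes present).
#' @param step_fraction Fraction of survivors eliminated per iteration;
#'   a value small enough to remove one feature at a time reproduces
#'   strict one-at-a-time elimination.
#' @param cost Linear SVM regularization constant.
#' @return An `xpc_ranking` (see [rank_by_cv()]); `score` is each
#'   feature's criterion at the iteration it was eliminated.
#' @export
svm_rfe <- function(x, y, step_fraction = 0.1, cost = 1) {
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2)
    stop("svm_rfe needs at least 2 classes in y", call. = FALSE)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  xs <- standardize_columns(x)
  surviving <- colnames(xs)
  eliminated <- character(0)   # worst first
  elim_score <- numeric(0)
  last_crit <- stats::setNames(rep(NA_real_, ncol(xs)), colnames(xs))
  while (length(surviving) > 1) {
    crit <- ovo_weight_criterion(xs[, surviving, drop = FALSE], y, cost = cost)
    n_drop <- min(max(1L, ceiling(step_fraction * length(surviving))),
                  length(surviving) - 1L)
    ord <- order(crit, surviving)            # ascending criterion, ties by id
    drop_ids <- surviving[ord][seq_len(n_drop)]
    eliminated <- c(eliminated, drop_ids)
    elim_score <- c(elim_score, crit[drop_ids])
    surviving <- setdiff(surviving, drop_ids)
    last_crit <- crit
  }
  eliminated <- c(eliminated, surviving)
  elim_score <- c(elim_score, last_crit[surviving])
  ord <- rev(seq_along(eliminated))
  new_ranking(eliminated[ord], unname(elim_score[ord]), "svm_rfe")
}

#' Random-forest backward feature elimination with OOB error
#'
#' Fits a forest on all features, records the out-of-bag error, then
#' iteratively discards the `drop_fraction` least-important features —
#' using the initial forest's (unscaled) permutation importances, never
#' recomputed — and refits, recording the OOB error of each visited set
#' down to two features. The chosen set is the smallest visited set whose
#' OOB error is within one standard error of the minimum OOB error, the
#' rule that returns very small feature sets while retaining accuracy.
#'
#' @param x Samples x features numeric matrix with column names.
#' @param y Factor of class labels.
#' @param drop_fraction Fraction of surviving features dropped per
#'   iteration, in (0, 1).
#' @param n_trees Trees per forest; fewer than 50 triggers a warning.
#' @param seed Integer seed controlling all forest randomness.
#' @return A list with `features` (the chosen subset, in importance
#'   order), `trace` (data frame of `size`, `oob_error`, `oob_se`, sizes
#'   strictly decreasing) and `importance` (the initial ranking).
#' @export
rf_backward_elimination <- function(x, y, drop_fraction = 0.2,
                                    n_trees = 500, seed = 1) {
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in (0, 1)", call. = FALSE)
  if (n_trees < 50)
    warning("n_trees < 50 gives unstable OOB estimates", call. = FALSE)
  n <- nrow(x)
  withr::with_seed(seed, {
    fit <- randomForest::randomForest(x, y, ntree = n_trees,
                                      importance = TRUE)
    imp <- fit$importance[, "MeanDecreaseAccuracy"]
    ranking <- colnames(x)[order(-imp, colnames(x))]
    oob <- unname(fit$err.rate[n_trees, "OOB"])
    sizes <- ncol(x)
    oobs <- oob
    current <- length(ranking)
    while (current > 2) {
      nxt <- max(2L, current - max(1L, round(drop_fraction * current)))
      keep <- ranking[seq_len(nxt)]
      refit <- randomForest::randomForest(x[, keep, drop = FALSE], y,
                                          ntree = n_trees)
      sizes <- c(sizes, nxt)
      oobs <- c(oobs, unname(refit$err.rate[n_trees, "OOB"]))
      current <- nxt
    }
  })
  ses <- sqrt(oobs * (1 - oobs) / n)
  i_min <- which.min(oobs)
  threshold <- oobs[i_min] + ses[i_min]
  eligible <- which(oobs <= threshold)
  i_chosen <- eligible[which.min(sizes[eligible])]
  list(features = ranking[seq_len(sizes[i_chosen])],
       trace = data.frame(size = sizes, oob_error = oobs, oob_se = ses),
       importance = new_ranking(ranking, unname(imp[ranking]), "rf"))
}

#' Rank features by random-forest permutation importance
#'
#' The ranking used for feature-count sweeps with the random-forest
#' selector: the initial forest's unscaled mean decrease in accuracy,
#' descending, ties broken by feature id. This is the same importance
#' ordering [rf_backward_elimination()] eliminates along.
#'
#' @inheritParams rf_backward_elimination
#' @return An `xpc_ranking`.
#' @export
rank_by_rf_importance <- function(x, y, n_trees = 500, seed = 1) {
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  withr::with_seed(seed, {
    fit <- randomForest::randomForest(x, y, ntree = n_trees,
                                      importance = TRUE)
  })
  imp <- fit$importance[, "MeanDecreaseAccuracy"]
  ord <- order(-imp, colnames(x))
  new_ranking(colnames(x)[ord], unname(imp[ord]), "rf")
}

# ---- shared helpers ---------------------------------------------------------

as_sample_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  x
}

# column-wise zero mean / unit variance; constant columns become 0
standardize_columns <- function(x, center = colMeans(x),
                                scale = apply(x, 2, stats::sd)) {
  scale[scale == 0] <- 1
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "xpc_center") <- center
  attr(out, "xpc_scale") <- scale
  out
}
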