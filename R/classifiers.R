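#' Train a multi-class classifier
#'
#' One entry point for the four classifiers benchmarked by the pipeline:
#' * `svm` — linear-kernel one-vs-one support vector machine with majority
#'   voting over the `C(C-1)/2` binary classifiers (via e1071), features
#'   standardized internally;
#' * `rf` — random forest of binary-split trees on bootstrap samples with
#'   random predictor subsets (via randomForest);
#' * `nb` — naive Bayes: categorical with additive smoothing on
#'   discretized (integer-bin) input, Gaussian per-class densities on
#'   continuous input (via e1071);
#' * `pam` — nearest shrunken centroids ([pam_fit()]), with the shrinkage
#'   threshold chosen by internal cross-validation.
#'
#' Discretized inputs are passed to SVM/RF as ordinal integers: bins carry
#' a natural expression ordering that one-hot coding would discard.
#'
#' @param x Samples x features numeric matrix with column names.
#' @param y Factor (or character) of class labels; every present class
#'   needs at least 2 samples.
#' @param method `"svm"`, `"rf"`, `"nb"` or `"pam"`.
#' @param representation Tag recording what representation `x` is in
#'   (e.g. `"fc"`, `"equal_f"`); enforced again at prediction time.
#' @param params Optional list of method parameters (`cost`, `n_trees`,
#'   `alpha`, `n_bins`, `n_thresholds`, `cv_folds`, `delta`).
#' @param seed Integer seed for the stochastic methods.
#' @return An object of class `xpc_model`.
#' @export
train_classifier <- function(x, y, method = c("svm", "rf", "nb", "pam"),
                             representation = "fc", params = list(),
                             seed = 1) {
  method <- match.arg(method)
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  small <- table(y)[table(y) < 2]
  if (length(small) > 0)
    stop("every class needs >= 2 training samples; offending: ",
         paste(names(small), collapse = ", "), call. = FALSE)

  fit <- switch(method,
    svm = {
      xs <- standardize_columns(x)
      m <- e1071::svm(xs, y, kernel = "linear",
                      cost = params$cost %||% 1, scale = FALSE)
      list(svm = m, center = attr(xs, "xpc_center"),
           scale = attr(xs, "xpc_scale"))
    },
    rf = withr::with_seed(seed,
      randomForest::randomForest(x, y, ntree = params$n_trees %||% 500)),
    nb = {
      discrete_input <- !identical(representation, "fc") &&
        all(x == round(x)) && all(x >= 1)
      if (discrete_input) {
        nb_fit_discrete(x, y, alpha = params$alpha %||% 1,
                        n_bins = params$n_bins %||% max(x))
      } else {
        list(gaussian = e1071::naiveBayes(x, y))
      }
    },
    pam = pam_fit(x, y,
                  n_thresholds = params$n_thresholds %||% 30,
                  cv_folds = params$cv_folds %||% 5,
                  seed = seed, delta = params$delta))

  structure(list(method = method, fit = fit,
                 features = colnames(x),
                 representation = representation,
                 levels = levels(y), params = params, seed = seed),
            class = "xpc_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels from a trained classifier
#'
#' Rejects inputs whose feature list does not match the training feature
#' list, and — when the caller states the representation of `newdata` —
#' inputs in a different representation than the model was trained on
#' (e.g. a model trained on equal-frequency bins applied to fold-change
#' values).
#'
#' @param object An `xpc_model` from [train_classifier()].
#' @param newdata Samples x features matrix with the training features.
#' @param representation Optional representation tag of `newdata`;
#'   must equal the model's if given.
#' @param ... Unused.
#' @return Factor of predicted labels with the training label levels.
#' @export
predict.xpc_model <- function(object, newdata, representation = NULL, ...) {
  if (!is.null(representation) &&
      !identical(representation, object$representation))
    stop(sprintf(
      "representation mismatch: model trained on '%s', input is '%s'",
      object$representation, representation), call. = FALSE)
  x <- as_sample_matrix(newdata)
  if (!setequal(colnames(x), object$features))
    stop("feature list mismatch between model and prediction input",
         call. = FALSE)
  x <- x[, object$features, drop = FALSE]
  pred <- switch(object$method,
    svm = {
      xs <- standardize_columns(x, center = object$fit$center,
                                scale = object$fit$scale)
      stats::predict(object$fit$svm, xs)
    },
    rf = stats::predict(object$fit, x),
    nb = {
      if (!is.null(object$fit$gaussian))
        stats::predict(object$fit$gaussian, x)
      else
        nb_predict_discrete(object$fit, x, type = "class")
    },
    pam = pam_predict(object$fit, x))
  factor(as.character(pred), levels = object$levels)
}

# ---- categorical naive Bayes on integer bins --------------------------------

#' Fit categorical naive Bayes on discretized data
#'
#' Per-class, per-feature categorical likelihood tables over bins
#' `1..n_bins` with additive (Laplace-style) smoothing `alpha`:
#' `P(bin b | class c, feature j) = (count + alpha) / (n_c + alpha * n_bins)`.
#' The class-conditional likelihood of a sample is the product of its
#' per-feature probabilities (conditional independence).
#'
#' @param x Samples x features matrix of integer bins in `1..n_bins`.
#' @param y Factor of class labels.
#' @param alpha Additive smoothing pseudo-count (> 0 recommended).
#' @param n_bins Bin count of the discretization.
#' @return A fitted model list (`tables`, `log_priors`, `levels`,
#'   `n_bins`, `alpha`) consumed by [nb_predict_discrete()].
#' @export
nb_fit_discrete <- function(x, y, alpha = 1, n_bins = max(x)) {
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (any(x != round(x)) || any(x < 1) || any(x > n_bins))
    stop("nb_fit_discrete expects integer bins in 1..n_bins", call. = FALSE)
  classes <- levels(y)
  n_bins <- as.integer(n_bins)
  # tables[[j]] is an n_bins x n_classes matrix of log probabilities
  tables <- lapply(seq_len(ncol(x)), function(j) {
    tab <- vapply(classes, function(cl) {
      counts <- tabulate(x[y == cl, j], nbins = n_bins)
      log((counts + alpha) / (sum(y == cl) + alpha * n_bins))
    }, numeric(n_bins))
    dimnames(tab) <- list(NULL, classes)
    tab
  })
  names(tables) <- colnames(x)
  priors <- as.numeric(table(y)) / length(y)
  list(tables = tables, log_priors = stats::setNames(log(priors), classes),
       levels = classes, n_bins = n_bins, alpha = alpha,
       features = colnames(x))
}

#' Predict from a categorical naive Bayes model
#'
#' @param model Fit from [nb_fit_discrete()].
#' @param x Samples x features matrix of integer bins.
#' @param type `"class"` for labels, `"raw"` for the posterior matrix
#'   (rows sum to 1).
#' @return Factor of labels or a samples x classes posterior matrix.
#' @export
nb_predict_discrete <- function(model, x, type = c("class", "raw")) {
  type <- match.arg(type)
  x <- as_sample_matrix(x)[, model$features, drop = FALSE]
  x[x < 1] <- 1L
  x[x > model$n_bins] <- model$n_bins
  logpost <- matrix(rep(model$log_priors, each = nrow(x)),
                    nrow = nrow(x),
                    dimnames = list(rownames(x), model$levels))
  for (j in seq_along(model$tables))
    logpost <- logpost + model$tables[[j]][x[, j], , drop = FALSE]
  if (type == "raw") {
    m <- apply(logpost, 1, max)
    post <- exp(logpost - m)
    return(post / rowSums(post))
  }
  factor(model$levels[max.col(logpost, ties.method = "first")],
         levels = model$levels)
}

# ---- nearest shrunken centroids (PAM) ---------------------------------------

#' Fit a nearest shrunken centroid (PAM) model
#'
#' Implements the shrunken-centroid classifier from its defining
#' equations. For feature `i` and class `k`:
#' `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class standard
#' deviation and `s0` the median of the `s_i` (fudge constant). Each
#' `d_ik` is soft-thresholded toward zero,
#' `d'_ik = sign(d_ik) * max(|d_ik| - Delta, 0)`, which moves every class
#' centroid toward the overall centroid and silences features whose
#' standardized deviation is below the threshold.
#'
#' `Delta` is chosen over a grid of `n_thresholds` values from 0 to
#' `max |d_ik|` by stratified internal cross-validation, ties resolved
#' toward the larger threshold (fewer surviving features).
#'
#' @param x Samples x features numeric matrix.
#' @param y Factor of class labels.
#' @param n_thresholds Size of the `Delta` grid.
#' @param cv_folds Internal cross-validation folds.
#' @param seed Seed for the fold assignment.
#' @param delta Optional fixed threshold; skips cross-validation.
#' @return An `xpc_pam` model list.
#' @export
pam_fit <- function(x, y, n_thresholds = 30, cv_folds = 5, seed = 1,
                    delta = NULL) {
  x <- as_sample_matrix(x)
  y <- droplevels(as.factor(y))
  if (any(table(y) < 2))
    stop("every class needs >= 2 samples for PAM", call. = FALSE)
  stats <- pam_statistics(x, y)
  if (is.null(delta)) {
    grid <- seq(0, max(abs(stats$d)), length.out = n_thresholds)
    cv_err <- pam_cv_errors(x, y, grid, cv_folds, seed,
                            n_thresholds = n_thresholds)
    # minimize CV error; ties -> larger Delta (fewer features)
    best <- which(cv_err == min(cv_err))
    delta <- grid[max(best)]
  }
  pam_shrink(stats, delta)
}

# centroid / dispersion statistics shared by fitting and cross-validation
pam_statistics <- function(x, y) {
  classes <- levels(y)
  n <- nrow(x)
  nk <- as.numeric(table(y)[classes])
  overall <- colMeans(x)
  centroids <- vapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x)))
  # pooled within-class SD with n - C denominator
  ss <- Reduce(`+`, lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    colSums(sweep(xi, 2, colMeans(xi), "-")^2)
  }))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / nk - 1 / n)
  denom <- outer(s + s0, mk)                      # p x C
  dev <- centroids - overall                      # p x C
  d <- dev / denom
  d[denom == 0] <- 0
  list(overall = overall, centroids = centroids, s = s, s0 = s0,
       mk = mk, d = d, priors = nk / n, levels = classes,
       features = colnames(x))
}

pam_shrink <- function(stats, delta) {
  dprime <- sign(stats$d) * pmax(abs(stats$d) - delta, 0)
  shrunk <- stats$overall + sweep(dprime, 1, stats$s + stats$s0, "*") %*%
    diag(stats$mk, nrow = length(stats$mk))
  dimnames(shrunk) <- list(stats$features, stats$levels)
  structure(c(stats, list(dprime = dprime, shrunk_centroids = shrunk,
                          delta = delta)),
            class = "xpc_pam")
}

pam_cv_errors <- function(x, y, grid, cv_folds, seed, n_thresholds) {
  folds <- withr::with_seed(seed, stratified_folds(y, cv_folds))
  errs <- numeric(length(grid))
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    if (any(table(y[!test]) < 2) || !any(test)) next
    st <- pam_statistics(x[!test, , drop = FALSE], droplevels(y[!test]))
    for (g in seq_along(grid)) {
      model <- pam_shrink(st, grid[g])
      pred <- pam_predict(model, x[test, , drop = FALSE])
      errs[g] <- errs[g] + sum(as.character(pred) != as.character(y[test]))
    }
  }
  errs
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Predict from a nearest shrunken centroid model
#'
#' The discriminant score of sample `x` for class `k` is
#' `sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 * log(prior_k)`, the
#' standardized squared distance to the shrunken class centroid penalized
#' by the class prior; the minimizing class wins, ties going to the first
#' class in label order.
#'
#' @param model An `xpc_pam` from [pam_fit()].
#' @param x Samples x features matrix aligned to the training features.
#' @return Factor of predicted labels.
#' @export
pam_predict <- function(model, x) {
  x <- as_sample_matrix(x)
  if (!setequal(colnames(x), model$features))
    stop("feature list mismatch between PAM model and input", call. = FALSE)
  x <- x[, model$features, drop = FALSE]
  w <- (model$s + model$s0)^2
  ok <- w > 0                                  # fully degenerate features carry no signal
  scores <- vapply(seq_along(model$levels), function(k) {
    diff2 <- sweep(x[, ok, drop = FALSE], 2,
                   model$shrunk_centroids[ok, k], "-")^2
    rowSums(sweep(diff2, 2, w[ok], "/")) - 2 * log(model$priors[k])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  factor(model$levels[max.col(-scores, ties.method = "first")],
         levels = model$levels)
}

#' Count of features surviving PAM shrinkage
#'
#' Number of features with any nonzero shrunken deviation `d'_ik`;
#' non-increasing in `Delta`.
#'
#' @param model An `xpc_pam`.
#' @return Integer count.
#' @export
pam_active_features <- function(model) {
  sum(rowSums(abs(model$dprime)) > 0)
}
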