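#' Overall classification accuracy in percent
#'
#' `ACC = 100 * correct / total`, reported to one decimal on the percent
#' scale (69 of 76 correct gives 90.8).
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @return Accuracy percent, rounded to one decimal.
#' @export
accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  round(100 * mean(as.character(y_true) == as.character(y_pred)), 1)
}

#' Confusion matrix in fixed class order
#'
#' Rows are true classes, columns predicted classes, both in the order of
#' `classes`.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class order; defaults to [gbm_subtypes()].
#' @return Integer matrix of counts.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = gbm_subtypes()) {
  t_f <- factor(as.character(y_true), levels = classes)
  p_f <- factor(as.character(y_pred), levels = classes)
  if (anyNA(t_f) || anyNA(p_f))
    stop("labels outside the declared class set", call. = FALSE)
  as.matrix(table(true = t_f, predicted = p_f))
}

#' Per-class sensitivity and specificity
#'
#' One-vs-rest collapse of the confusion matrix: for each class,
#' `Sn = tp / (tp + fn)` and `Sp = tn / (tn + fp)`, to three decimals. A
#' class absent from `y_true` has undefined sensitivity and is reported as
#' `NA`, not 0.
#'
#' @inheritParams confusion_matrix
#' @return Data frame with columns `class`, `sn`, `sp`.
#' @export
per_class_sn_sp <- function(y_true, y_pred, classes = gbm_subtypes()) {
  cm <- confusion_matrix(y_true, y_pred, classes)
  total <- sum(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    sn <- if (tp + fn == 0) NA_real_ else round(tp / (tp + fn), 3)
    sp <- if (tn + fp == 0) NA_real_ else round(tn / (tn + fp), 3)
    data.frame(class = classes[i], sn = sn, sp = sp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Stratified train/test split
#'
#' Per-class proportional allocation: each class contributes
#' `ceiling(n_class * train_fraction)` samples to the training set (drawn
#' at random under `seed`) and the remainder to the test set. The two id
#' sets are disjoint and exhaustive.
#'
#' @param labels Label table (data frame with `sample_id`, `subtype`) or a
#'   factor named by sample id.
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.75, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  if (is.data.frame(labels)) {
    ids <- labels$sample_id
    y <- labels$subtype
  } else {
    ids <- names(labels)
    y <- labels
  }
  y <- droplevels(as.factor(y))
  counts <- table(y)
  if (any(counts < 2))
    stop("every class needs >= 2 samples to split; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  train <- withr::with_seed(seed, unlist(lapply(levels(y), function(cl) {
    cl_ids <- ids[y == cl]
    n_train <- ceiling(length(cl_ids) * train_fraction)
    sample(cl_ids, n_train)
  }), use.names = FALSE))
  list(train = train, test = setdiff(ids, train))
}

#' Configure a benchmark run
#'
#' @param representations Subset of `"fc"`, `"equal_w"`, `"equal_f"`,
#'   `"kmeans"`; `"fc"` is the undiscretized baseline.
#' @param selectors Subset of `"cv"`, `"svm_rfe"`, `"rf"`.
#' @param classifiers Subset of `"svm"`, `"rf"`, `"nb"`, `"pam"`.
#' @param k Bin count for the discretized representations.
#' @param grid Feature-count grid swept per cell; defaults to
#'   10..100 by 10 then 150..1000 by 50 (clipped to the feature pool at
#'   run time).
#' @param train_fraction Training fraction for same-platform splits.
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param params Optional per-method parameter list passed through to the
#'   selectors/classifiers.
#' @return An object of class `xpc_run_config`.
#' @export
run_config <- function(representations = c("fc", "equal_f"),
                       selectors = "cv",
                       classifiers = "svm",
                       k = 10,
                       grid = c(seq(10, 100, by = 10), seq(150, 1000, by = 50)),
                       train_fraction = 0.75,
                       seed = 1,
                       params = list()) {
  representations <- match.arg(representations,
                               c("fc", "equal_w", "equal_f", "kmeans"),
                               several.ok = TRUE)
  selectors <- match.arg(selectors, c("cv", "svm_rfe", "rf"),
                         several.ok = TRUE)
  classifiers <- match.arg(classifiers, c("svm", "rf", "nb", "pam"),
                           several.ok = TRUE)
  if (any(representations != "fc")) check_bins(k)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(representations = representations, selectors = selectors,
                 classifiers = classifiers, k = as.integer(k),
                 grid = sort(unique(as.integer(grid))),
                 train_fraction = train_fraction,
                 seed = as.integer(seed), params = params),
            class = "xpc_run_config")
}

rep_method <- function(representation) {
  switch(representation, equal_w = "equal_width", equal_f = "equal_freq",
         kmeans = "kmeans",
         stop("no binning method for representation ", representation))
}

# Build the representation matrices for one dataset. Bins are always
# re-fitted on the dataset at hand (never carried over from another split
# or platform): rank-based refitting is what harmonizes scales.
represent <- function(fc, representation, k) {
  if (representation == "fc") return(fc)
  suppressWarnings(
    discretize_matrix(fc, method = rep_method(representation), k = k)$bins)
}

# Rank training features for one selector. CV ranks on the raw (positive)
# tumor expression of the training samples; svm_rfe and rf rank on the
# representation the classifier will consume.
select_features <- function(selector, train_rep, tumor_train, y_train,
                            config, seed) {
  switch(selector,
    cv = rank_by_cv(tumor_train),
    svm_rfe = svm_rfe(t(train_rep), y_train,
                      step_fraction = config$params$step_fraction %||% 0.1,
                      cost = config$params$cost %||% 1),
    rf = rank_by_rf_importance(t(train_rep), y_train,
                               n_trees = config$params$n_trees %||% 500,
                               seed = seed))
}

sweep_cells <- function(train_rep, y_train, test_rep, y_test, ranking,
                        selector, representation, config, seed) {
  grid <- config$grid[config$grid <= nrow(ranking)]
  if (length(grid) < length(config$grid))
    warning("feature-count grid clipped to the ", nrow(ranking),
            " available features", call. = FALSE)
  cells <- list()
  for (clf in config$classifiers) {
    for (n in grid) {
      feats <- ranking$feature_id[seq_len(n)]
      model <- train_classifier(t(train_rep[feats, , drop = FALSE]), y_train,
                                method = clf,
                                representation = representation,
                                params = c(config$params,
                                           list(n_bins = config$k)),
                                seed = seed)
      pred <- predict(model, t(test_rep[feats, , drop = FALSE]),
                      representation = representation)
      cells[[length(cells) + 1]] <- data.frame(
        classifier = clf, selector = selector,
        representation = representation, n_features = as.integer(n),
        accuracy = accuracy(y_test, pred), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cells)
}

run_benchmark <- function(fc_train, fc_test, tumor_train, y_train, y_test,
                          config, snsp_n = NULL) {
  cells <- list()
  snsp <- NULL
  for (representation in config$representations) {
    train_rep <- represent(fc_train, representation, config$k)
    test_rep <- represent(fc_test, representation, config$k)
    for (selector in config$selectors) {
      seed <- config$seed + stage_offset(representation, selector)
      ranking <- select_features(selector, train_rep, tumor_train, y_train,
                                 config, seed)
      cells[[length(cells) + 1]] <-
        sweep_cells(train_rep, y_train, test_rep, y_test, ranking,
                    selector, representation, config, seed)
      if (!is.null(snsp_n) && snsp_n <= nrow(ranking)) {
        feats <- ranking$feature_id[seq_len(snsp_n)]
        for (clf in config$classifiers) {
          model <- train_classifier(t(train_rep[feats, , drop = FALSE]),
                                    y_train, method = clf,
                                    representation = representation,
                                    params = c(config$params,
                                               list(n_bins = config$k)),
                                    seed = seed)
          pred <- predict(model, t(test_rep[feats, , drop = FALSE]),
                          representation = representation)
          tab <- per_class_sn_sp(y_test, pred)
          tab$classifier <- clf
          tab$selector <- selector
          tab$representation <- representation
          snsp <- rbind(snsp, tab)
        }
      }
    }
  }
  eval_report(do.call(rbind, cells), snsp = snsp)
}

# deterministic per-stage seed fan-out from the master seed
stage_offset <- function(representation, selector) {
  reps <- c(fc = 0L, equal_w = 1L, equal_f = 2L, kmeans = 3L)
  sels <- c(cv = 0L, svm_rfe = 10L, rf = 20L)
  unname(reps[representation] + sels[selector])
}

#' Same-platform benchmark
#'
#' Splits the samples into stratified train/test sets, computes fold
#' change against the platform's normal reference, fits each
#' representation independently on the train and on the test split, ranks
#' features on the training representation, and sweeps every configured
#' classifier over the feature-count grid. Best cell per (classifier,
#' selector, representation) is the maximum test accuracy, ties going to
#' the smaller feature count.
#'
#' @param tumor Features x samples expression matrix.
#' @param normals Normal reference matrix for the same platform.
#' @param labels Label table covering the tumor samples.
#' @param config An `xpc_run_config`.
#' @param snsp_n Optional feature count at which to also record per-class
#'   sensitivity/specificity (e.g. 100).
#' @return An `xpc_report`.
#' @export
run_same_platform <- function(tumor, normals, labels, config = run_config(),
                              snsp_n = NULL) {
  tumor <- expression_matrix(tumor)
  labels <- label_table(labels$sample_id, as.character(labels$subtype),
                        samples = colnames(tumor))
  fc <- fold_change(tumor, normals)
  split <- stratified_split(labels, config$train_fraction, config$seed)
  y <- stats::setNames(labels$subtype, labels$sample_id)
  run_benchmark(fc_train = fc[, split$train, drop = FALSE],
                fc_test = fc[, split$test, drop = FALSE],
                tumor_train = tumor[, split$train, drop = FALSE],
                y_train = droplevels(y[split$train]),
                y_test = droplevels(y[split$test]),
                config = config, snsp_n = snsp_n)
}

#' Cross-platform benchmark
#'
#' Trains on platform A and tests on platform B. Fold change is computed
#' per platform against that platform's own normal reference; every
#' discretized representation is fitted independently per platform (bins
#' re-fitted on B); feature selection and classifier training use platform
#' A only; accuracy is measured on platform B.
#'
#' @param tumor_A,normals_A Training-platform tumor and normal matrices.
#' @param labels_A Label table for the training samples.
#' @param tumor_B,normals_B Test-platform tumor and normal matrices
#'   (same feature ids as platform A).
#' @param labels_B Label table for the test samples.
#' @param config An `xpc_run_config`.
#' @param snsp_n Optional feature count for the per-class Sn/Sp table.
#' @return An `xpc_report`.
#' @export
run_cross_platform <- function(tumor_A, normals_A, labels_A,
                               tumor_B, normals_B, labels_B,
                               config = run_config(), snsp_n = NULL) {
  tumor_A <- expression_matrix(tumor_A)
  tumor_B <- expression_matrix(tumor_B)
  if (!identical(rownames(tumor_A), rownames(tumor_B)))
    stop("platforms must share identical feature ids", call. = FALSE)
  labels_A <- label_table(labels_A$sample_id,
                          as.character(labels_A$subtype),
                          samples = colnames(tumor_A))
  labels_B <- label_table(labels_B$sample_id,
                          as.character(labels_B$subtype),
                          samples = colnames(tumor_B))
  fc_A <- fold_change(tumor_A, normals_A)
  fc_B <- fold_change(tumor_B, normals_B)
  run_benchmark(fc_train = fc_A, fc_test = fc_B,
                tumor_train = tumor_A,
                y_train = droplevels(labels_A$subtype),
                y_test = droplevels(labels_B$subtype),
                config = config, snsp_n = snsp_n)
}

#' Cross-platform benchmark on a simulated paired dataset
#'
#' Convenience wrapper: trains on all platform-A tumors and tests on the
#' dataset's designated matched platform-B test subset.
#'
#' @param dataset An `xpc_paired_dataset` from [generate_paired_dataset()].
#' @param config An `xpc_run_config`.
#' @param snsp_n Optional feature count for the per-class Sn/Sp table.
#' @return An `xpc_report`.
#' @export
run_cross_platform_paired <- function(dataset, config = run_config(),
                                      snsp_n = NULL) {
  stopifnot(inherits(dataset, "xpc_paired_dataset"))
  test_ids <- dataset$test_ids
  labels_B <- dataset$labels[match(test_ids, dataset$labels$sample_id), ]
  run_cross_platform(dataset$tumor_A, dataset$normals_A, dataset$labels,
                     dataset$tumor_B[, test_ids, drop = FALSE],
                     dataset$normals_B, labels_B,
                     config = config, snsp_n = snsp_n)
}
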