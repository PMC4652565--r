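#' Log2 fold change against a normal reference
#'
#' For every feature `f` and tumor sample `s`,
#' `FC[f, s] = log2(T[f, s] / median_j N[f, j])` where `N` holds the
#' platform-matched normal reference samples. Fold change is the continuous
#' representation every downstream representation is derived from.
#'
#' Nonpositive values are hard errors: silently adding pseudo-counts would
#' distort cross-platform comparisons.
#'
#' @param tumor Features x samples expression matrix (strictly positive).
#' @param normals Features x samples matrix of normal reference samples
#'   with identical feature ids.
#' @return Matrix of log2 fold changes, same shape and ids as `tumor`.
#' @export
fold_change <- function(tumor, normals) {
  tumor <- expression_matrix(tumor)
  normals <- expression_matrix(normals)
  if (!identical(rownames(tumor), rownames(normals)))
    stop("tumor and normal matrices must share identical feature ids",
         call. = FALSE)
  if (any(tumor <= 0) || any(normals <= 0))
    stop("fold_change requires strictly positive expression values",
         call. = FALSE)
  ref <- apply(normals, 1, stats::median)
  fc <- log2(sweep(tumor, 1, ref, "/"))
  dimnames(fc) <- dimnames(tumor)
  fc
}

#' Coefficient of variation per feature
#'
#' `CV = sigma / mu` with the sample (n-1 denominator) standard deviation
#' across samples. A scale-free variability score used as a filter-type
#' feature selector.
#'
#' @param mat Features x samples matrix; every feature must have mean > 0.
#' @return Data frame with columns `feature_id` and `cv`, in input feature
#'   order.
#' @export
cv_scores <- function(mat) {
  mat <- expression_matrix(mat)
  mu <- rowMeans(mat)
  if (any(mu <= 0))
    stop("cv_scores requires positive feature means; offending feature(s): ",
         paste(utils::head(rownames(mat)[mu <= 0], 5), collapse = ", "),
         call. = FALSE)
  sigma <- apply(mat, 1, stats::sd)
  data.frame(feature_id = rownames(mat), cv = sigma / mu,
             stringsAsFactors = FALSE)
}

#' Greedy Pearson redundancy filter
#'
#' Scans features in ranking order and keeps a feature only if its absolute
#' Pearson correlation with every already-kept feature is at or below the
#' cutoff, so the higher-ranked member of each correlated group survives.
#' Zero-variance features have undefined correlations and are dropped with
#' a warning.
#'
#' @param mat Features x samples matrix.
#' @param ranking Character vector of feature ids, best first, covering the
#'   features to scan.
#' @param cutoff Absolute-correlation cutoff in (0, 1]; 0.8 is the
#'   conventional choice for expression data.
#' @return Character vector of kept feature ids, in ranking order.
#' @export
correlation_redundancy_filter <- function(mat, ranking, cutoff = 0.8) {
  mat <- expression_matrix(mat)
  if (cutoff <= 0 || cutoff > 1)
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  if (!all(ranking %in% rownames(mat)))
    stop("ranking contains features absent from the matrix", call. = FALSE)
  x <- t(mat[ranking, , drop = FALSE])      # samples x features
  sds <- apply(x, 2, stats::sd)
  degenerate <- ranking[sds == 0]
  if (length(degenerate) > 0) {
    warning("dropping ", length(degenerate),
            " zero-variance feature(s) with undefined correlation: ",
            paste(utils::head(degenerate, 5), collapse = ", "), call. = FALSE)
  }
  kept <- character(0)
  for (f in ranking) {
    if (sds[f] == 0) next
    if (length(kept) == 0) {
      kept <- f
      next
    }
    r <- abs(stats::cor(x[, f], x[, kept, drop = FALSE]))
    # exact linear duplicates (|r| = 1) are redundant even at cutoff 1
    if (all(r <= cutoff) && all(r < 1 - 1e-12)) kept <- c(kept, f)
  }
  kept
}

#' Select the top variable features
#'
#' The standard variability pre-filter: rank all features by CV
#' (descending, ties broken by feature id), remove redundant features with
#' the greedy Pearson filter, and keep the `k` surviving features with the
#' largest CV.
#'
#' @param mat Features x samples matrix with positive feature means.
#' @param k Number of features to keep.
#' @param cutoff Pearson redundancy cutoff passed to
#'   [correlation_redundancy_filter()].
#' @return Character vector of `k` feature ids in descending-CV order.
#' @export
select_top_variable <- function(mat, k, cutoff = 0.8) {
  mat <- expression_matrix(mat)
  if (k > nrow(mat))
    stop("k exceeds the number of available features", call. = FALSE)
  ranking <- rank_by_cv(mat)$feature_id
  kept <- correlation_redundancy_filter(mat, ranking, cutoff = cutoff)
  if (k > length(kept))
    stop(sprintf(
      "k = %d exceeds the %d features surviving the redundancy filter",
      k, length(kept)), call. = FALSE)
  kept[seq_len(k)]
}
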