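#' Dougherty heuristic for the maximum bin number
#'
#' `k = max(1, floor(2 * ln(l)))` where `l` is the number of distinct
#' values of the attribute. At l = 342 this gives k = 11.
#'
#' @param n_distinct Number of distinct attribute values (>= 1), possibly a
#'   vector.
#' @return Integer bin count(s).
#' @export
dougherty_max_bins <- function(n_distinct) {
  if (any(n_distinct < 1))
    stop("n_distinct must be >= 1", call. = FALSE)
  as.integer(pmax(1, floor(2 * log(n_distinct))))
}

#' Fit equal-width bins on one feature
#'
#' Divides the observed range into `k` intervals of width
#' `(max - min) / k`. A value `v` maps to bin `floor((v - min) / width) + 1`,
#' clamped so the maximum lands in bin `k`. A constant feature collapses to
#' a single bin (all values -> bin 1).
#'
#' @param values Numeric vector.
#' @param k Bin count (>= 2).
#' @return A per-feature binning rule (list with `method`, `k`,
#'   `boundaries` = the k-1 interior cut points, and assignment
#'   parameters).
#' @export
fit_equal_width <- function(values, k) {
  check_bins(k)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    return(list(method = "equal_width", k = as.integer(k), degenerate = TRUE,
                boundaries = numeric(0), min = lo, width = 0))
  }
  width <- (hi - lo) / k
  list(method = "equal_width", k = as.integer(k), degenerate = FALSE,
       boundaries = lo + seq_len(k - 1) * width, min = lo, width = width)
}

#' Fit equal-frequency bins on one feature
#'
#' Sorts the values and assigns the value with (stable) ordinal rank `r`
#' (1-based, ties ordered by original position) to bin `ceiling(r * k / n)`,
#' so every bin holds the same number of sorted values up to rounding.
#' Tied values all receive the bin of their smallest ordinal rank, which
#' makes the assignment a function of the value alone and therefore exactly
#' invariant under any strictly increasing transform of the feature.
#'
#' @param values Numeric vector of length `n >= k`.
#' @param k Bin count (2 <= k <= n).
#' @return A per-feature binning rule; `boundaries` records the upper value
#'   threshold of each of the first k-1 bins (NA for bins emptied by tie
#'   collapse), for audit.
#' @export
fit_equal_freq <- function(values, k) {
  check_bins(k)
  n <- length(values)
  if (k > n)
    stop(sprintf("equal-frequency binning needs k <= n (k = %d, n = %d)",
                 k, n), call. = FALSE)
  if (max(values) == min(values)) {
    return(list(method = "equal_freq", k = as.integer(k), degenerate = TRUE,
                boundaries = numeric(0),
                bins = rep.int(1L, n)))
  }
  r <- rank(values, ties.method = "first")   # stable ordinal ranks
  bins <- as.integer(ceiling(r * k / n))
  # ties: every member of a tied group takes the bin of its smallest rank
  bins <- as.integer(stats::ave(bins, values, FUN = min))
  boundaries <- vapply(seq_len(k - 1), function(j) {
    if (any(bins == j)) max(values[bins == j]) else NA_real_
  }, numeric(1))
  list(method = "equal_freq", k = as.integer(k), degenerate = FALSE,
       boundaries = boundaries, bins = bins)
}

#' Fit 1-D k-means bins on one feature
#'
#' One-dimensional k-means admits an exact solution: because optimal
#' clusters are contiguous runs of the sorted values, the globally
#' minimal within-cluster sum of squares is found by dynamic programming
#' over the sorted order. The fitter uses that exact solver, so the
#' result is deterministic, free of the usual sensitivity to random
#' centroid seeding, and its WCSS is a lower bound on every Lloyd run.
#' Clusters are labeled 1..k by ascending centroid.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Cluster count (>= 2).
#' @return A per-feature binning rule with the `k` ascending `centroids`,
#'   the per-value `bins`, and the achieved `wcss`.
#' @export
fit_kmeans_1d <- function(values, k) {
  check_bins(k)
  n_distinct <- length(unique(values))
  if (k > n_distinct)
    stop(sprintf("k-means needs k <= number of distinct values (k = %d, distinct = %d)",
                 k, n_distinct), call. = FALSE)
  ord <- order(values)
  s <- values[ord]
  n <- length(s)
  S <- cumsum(s)
  S2 <- cumsum(s * s)
  S0 <- c(0, S)
  S20 <- c(0, S2)
  # within-segment sum of squares for segments [j, i], vectorized over j
  seg_cost <- function(j, i) {
    len <- i - j + 1
    tot <- S[i] - S0[j]
    pmax((S2[i] - S20[j]) - tot * tot / len, 0)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1, ] <- pmax(S2 - S * S / seq_len(n), 0)
  if (k > 1) {
    for (m in 2:k) {
      for (i in m:n) {
        j <- m:i
        cand <- D[m - 1, j - 1] + seg_cost(j, i)
        wm <- which.min(cand)
        D[m, i] <- cand[wm]
        B[m, i] <- j[wm]
      }
    }
  }
  bins_sorted <- integer(n)
  i <- n
  for (m in k:1) {
    j <- B[m, i]
    bins_sorted[j:i] <- m
    i <- j - 1L
  }
  bins <- integer(n)
  bins[ord] <- bins_sorted
  centroids <- as.numeric(tapply(s, bins_sorted, mean))
  list(method = "kmeans", k = as.integer(k), degenerate = FALSE,
       centroids = centroids, bins = bins, wcss = D[k, n])
}

# plain Lloyd iterations in one dimension; ties in distance go to the
# lower-index centroid; empty clusters keep their previous centroid
lloyd_1d <- function(values, centers, max_iter = 200L) {
  assign_prev <- integer(length(values))
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    d <- abs(outer(values, centers, "-"))
    assign_cur <- max.col(-d, ties.method = "first")
    iterations <- it
    if (identical(assign_cur, assign_prev)) break
    for (j in seq_along(centers)) {
      if (any(assign_cur == j)) centers[j] <- mean(values[assign_cur == j])
    }
    assign_prev <- assign_cur
  }
  wcss <- sum((values - centers[assign_cur])^2)
  list(centers = centers, assign = assign_cur, iterations = iterations,
       wcss = wcss)
}

apply_binning_rule <- function(rule, values) {
  if (isTRUE(rule$degenerate)) return(rep.int(1L, length(values)))
  switch(rule$method,
    equal_width = {
      b <- floor((values - rule$min) / rule$width) + 1
      as.integer(pmin(pmax(b, 1L), rule$k))
    },
    equal_freq = rule$bins,
    kmeans = rule$bins,
    stop("unknown binning method: ", rule$method, call. = FALSE))
}

check_bins <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 2 || k != as.integer(k))
    stop("bin count k must be a single integer >= 2", call. = FALSE)
  invisible(k)
}

#' Discretize a continuous matrix per feature
#'
#' Fits one binning rule per feature (local discretization) on the given
#' dataset and returns the integer bin matrix together with the fitted
#' model for audit. Rules are always re-fitted on the dataset at hand:
#' refitting per dataset is what lets rank-based bins harmonize platforms
#' with different scales. Constant features collapse to bin 1 with a
#' warning.
#'
#' @param mat Features x samples numeric matrix (typically fold changes).
#' @param method One of `"equal_width"`, `"equal_freq"`, `"kmeans"`.
#' @param k Bin count (default 10, the conventional default bin number).
#' @param seed Unused by the deterministic fitters; accepted for interface
#'   stability.
#' @return A list of class `xpc_discretized`: `bins` (integer matrix in
#'   1..k, same shape and ids as `mat`), `model` (an `xpc_binning_model`
#'   with per-feature rules), `method`, `k`.
#' @export
discretize_matrix <- function(mat, method = c("equal_freq", "equal_width", "kmeans"),
                              k = 10, seed = NULL) {
  method <- match.arg(method)
  mat <- expression_matrix(mat)
  check_bins(k)
  fitter <- switch(method,
    equal_width = function(v) fit_equal_width(v, k),
    equal_freq = function(v) fit_equal_freq(v, k),
    kmeans = function(v) fit_kmeans_1d(v, k))
  rules <- vector("list", nrow(mat))
  bins <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  n_degenerate <- 0L
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (max(v) == min(v)) {
      n_degenerate <- n_degenerate + 1L
      rules[[i]] <- list(method = method, k = as.integer(k),
                         degenerate = TRUE, boundaries = numeric(0))
      bins[i, ] <- 1L
      next
    }
    rules[[i]] <- fitter(v)
    bins[i, ] <- apply_binning_rule(rules[[i]], v)
  }
  if (n_degenerate > 0)
    warning(n_degenerate,
            " constant feature(s) collapsed to a single bin", call. = FALSE)
  names(rules) <- rownames(mat)
  structure(list(bins = bins,
                 model = structure(list(method = method, k = as.integer(k),
                                        features = rules),
                                   class = "xpc_binning_model"),
                 method = method, k = as.integer(k)),
            class = "xpc_discretized")
}

#' @export
print.xpc_binning_model <- function(x, ...) {
  cat(sprintf("Per-feature %s binning model: k = %d, %d features\n",
              x$method, x$k, length(x$features)))
  invisible(x)
}
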