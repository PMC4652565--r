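#' Run the full cross-platform pipeline end to end
#'
#' Executes the proposed procedure in order — fold change against each
#' platform's normal reference, per-platform discretization, feature
#' selection on the training platform, classifier training, and
#' cross-platform evaluation — and optionally writes every artifact
#' (report JSON + TSV grid, per-class Sn/Sp, manifest) to a directory.
#' Given the same inputs, config and seed, outputs are byte-identical.
#'
#' @param dataset An `xpc_paired_dataset`, or a directory previously
#'   written by [write_paired_dataset()].
#' @param config An `xpc_run_config`; its `seed` drives every stochastic
#'   stage through fixed per-stage offsets.
#' @param outdir Optional output directory for `report.json`,
#'   `report.tsv`, `snsp.tsv` and `manifest.json`.
#' @param snsp_n Feature count at which the per-class Sn/Sp table is
#'   recorded (default 100, clipped if the grid/selector pool is smaller).
#' @param verbose Emit one progress line per stage to standard error.
#' @return The `xpc_report`, invisibly carrying the manifest as attribute
#'   `"manifest"`.
#' @export
run_pipeline <- function(dataset, config = run_config(), outdir = NULL,
                         snsp_n = 100, verbose = FALSE) {
  t0 <- Sys.time()
  if (is.character(dataset)) dataset <- read_paired_dataset(dataset)
  stopifnot(inherits(dataset, "xpc_paired_dataset"),
            inherits(config, "xpc_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  say("pipeline: %d features, %d tumors, %d test samples",
      nrow(dataset$tumor_A), ncol(dataset$tumor_A), length(dataset$test_ids))
  report <- run_cross_platform_paired(dataset, config = config,
                                      snsp_n = snsp_n)
  manifest <- list(
    package_version = as.character(utils::packageVersion("xplatclass")),
    seed = config$seed,
    config = list(representations = config$representations,
                  selectors = config$selectors,
                  classifiers = config$classifiers,
                  k = config$k, grid = config$grid,
                  train_fraction = config$train_fraction),
    n_features = nrow(dataset$tumor_A),
    n_train = ncol(dataset$tumor_A),
    n_test = length(dataset$test_ids),
    elapsed_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  attr(report, "manifest") <- manifest
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(outdir, "report.json"),
                 file.path(outdir, "report.tsv"))
    if (!is.null(report$snsp))
      utils::write.table(report$snsp, file.path(outdir, "snsp.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("pipeline: artifacts written to %s", outdir)
  }
  invisible(report)
}

#' Read a paired dataset written by [write_paired_dataset()]
#'
#' @param dir Directory holding `tumor_A.tsv`, `tumor_B.tsv`,
#'   `normals_A.tsv`, `normals_B.tsv`, `labels.tsv`, `truth.json`.
#' @return An `xpc_paired_dataset`.
#' @export
read_paired_dataset <- function(dir) {
  tumor_A <- read_expression_matrix(file.path(dir, "tumor_A.tsv"))
  tumor_B <- read_expression_matrix(file.path(dir, "tumor_B.tsv"))
  normals_A <- read_expression_matrix(file.path(dir, "normals_A.tsv"))
  normals_B <- read_expression_matrix(file.path(dir, "normals_B.tsv"))
  labels <- read_labels(file.path(dir, "labels.tsv"), colnames(tumor_A))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  structure(list(tumor_A = tumor_A, tumor_B = tumor_B,
                 normals_A = normals_A, normals_B = normals_B,
                 labels = labels, truth = as.list(meta$truth),
                 test_ids = meta$test_ids, config = NULL),
            class = "xpc_paired_dataset")
}

#' Fast invariant self-check
#'
#' Runs the package's core invariants in a few seconds: equal-frequency
#' bin balance and monotone-transform invariance, equal-width affine
#' invariance, the PAM zero-threshold nearest-centroid identity, the
#' accuracy/confusion-matrix identity, and the bin-number heuristic.
#'
#' @return Data frame with columns `check` and `pass`; printed summary.
#' @export
selfcheck <- function() {
  checks <- list()
  add <- function(name, expr) {
    ok <- tryCatch(isTRUE(expr), error = function(e) FALSE)
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = ok,
                                                stringsAsFactors = FALSE)
  }

  v <- withr::with_seed(7, stats::rnorm(60))
  ef <- fit_equal_freq(v, 10)
  occ <- tabulate(ef$bins, nbins = 10)
  add("equal-frequency bin occupancy balanced on tie-free input",
      max(occ) - min(occ) <= 1)

  g <- function(z) 3 * z^3 + 2 * z   # strictly increasing
  add("equal-frequency bins invariant under strictly monotone transform",
      identical(fit_equal_freq(g(v), 10)$bins, ef$bins))

  ew <- fit_equal_width(v, 8)
  add("equal-width bins invariant under positive affine transform",
      identical(apply_binning_rule(fit_equal_width(2.5 * v + 1, 8), 2.5 * v + 1),
                apply_binning_rule(ew, v)))

  xy <- withr::with_seed(11, {
    x <- matrix(stats::rnorm(40 * 6), 40, 6,
                dimnames = list(NULL, sprintf("f%d", 1:6)))
    y <- factor(rep(gbm_subtypes(), each = 10))
    list(x = x, y = y)
  })
  pam0 <- pam_fit(xy$x, xy$y, delta = 0)
  centroid_pred <- {
    w <- (pam0$s + pam0$s0)^2
    sc <- vapply(seq_along(pam0$levels), function(k)
      rowSums(sweep(sweep(xy$x, 2, pam0$centroids[, k], "-")^2, 2, w, "/")) -
        2 * log(pam0$priors[k]), numeric(nrow(xy$x)))
    factor(pam0$levels[max.col(-sc, ties.method = "first")],
           levels = pam0$levels)
  }
  add("PAM at zero threshold equals standardized nearest centroid",
      identical(as.character(pam_predict(pam0, xy$x)),
                as.character(centroid_pred)))

  yt <- factor(rep(gbm_subtypes(), times = c(5, 6, 7, 8)))
  yp <- withr::with_seed(3, sample(yt))
  cm <- confusion_matrix(yt, yp)
  add("accuracy equals confusion-matrix trace over total",
      isTRUE(all.equal(accuracy(yt, yp),
                       round(100 * sum(diag(cm)) / sum(cm), 1))))

  add("bin-number heuristic floor(2 ln l) at l = 342 gives 11",
      dougherty_max_bins(342) == 11L)

  out <- do.call(rbind, checks)
  status <- if (all(out$pass)) "all checks passed" else "FAILURES present"
  message(sprintf("selfcheck: %d/%d passed (%s)", sum(out$pass), nrow(out),
                  status))
  out
}
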