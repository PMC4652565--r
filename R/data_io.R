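#' The four glioblastoma transcriptional subtypes
#'
#' Class labels used throughout the package, in their fixed report order:
#' proneural (PN), neural (N), classical (CL) and mesenchymal (M).
#'
#' @return Character vector `c("PN", "N", "CL", "M")`.
#' @export
gbm_subtypes <- function() c("PN", "N", "CL", "M")

#' Construct and validate an expression matrix
#'
#' Expression matrices are plain numeric matrices with features in rows and
#' samples in columns; row and column names carry the identifiers. This
#' helper checks the container invariants once so downstream code can assume
#' them.
#'
#' @param values Numeric matrix, features x samples.
#' @param feature_ids,sample_ids Identifier vectors; default to the dimnames
#'   of `values`.
#' @return The validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required", call. = FALSE)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_ids))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds sample ids and whose
#' first column holds feature ids; all remaining cells must be numeric and
#' finite. Ids are preserved in file order.
#'
#' @param path Path to a TSV file.
#' @return A features x samples numeric matrix (see [expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression matrix file needs a feature-id column plus >= 1 sample",
         call. = FALSE)
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals) | is.nan(vals) | is.infinite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-numeric or non-finite cell at feature '%s' (row %d), sample '%s' (column %d): '%s'",
      feature_ids[bad[1, 1]], bad[1, 1], sample_ids[bad[1, 2]], bad[1, 2],
      raw[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  expression_matrix(vals, feature_ids, sample_ids)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; values are written with full
#' double precision so a read/write cycle round-trips to at least 6
#' significant digits.
#'
#' @param mat Features x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  mat <- expression_matrix(mat)
  df <- data.frame(feature_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' Reads a two-column TSV (`sample_id`, `subtype`) and aligns it to a given
#' sample order. Every requested sample must be labeled exactly once and
#' every subtype must belong to the closed four-class set.
#'
#' @param path Path to the label TSV.
#' @param samples Character vector of sample ids defining the output order.
#' @return A data frame with columns `sample_id` and `subtype` (factor with
#'   levels [gbm_subtypes()]), one row per requested sample, in order.
#' @export
read_labels <- function(path, samples) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "subtype") %in% colnames(df)))
    stop("label file must have columns 'sample_id' and 'subtype'", call. = FALSE)
  label_table(df$sample_id, df$subtype, samples = samples)
}

#' Build a validated label table
#'
#' @param sample_id Character vector of sample ids.
#' @param subtype Character (or factor) vector of subtype labels.
#' @param samples Optional sample order to align to; defaults to `sample_id`
#'   order.
#' @return Data frame with `sample_id` and `subtype` columns.
#' @export
label_table <- function(sample_id, subtype, samples = sample_id) {
  sample_id <- as.character(sample_id)
  subtype <- as.character(subtype)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in label table: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(subtype), gbm_subtypes())
  if (length(unknown) > 0)
    stop("unknown subtype label(s): ", paste(unknown, collapse = ", "),
         "; expected one of ", paste(gbm_subtypes(), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(samples, sample_id)
  if (length(missing) > 0)
    stop("label table does not cover sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(samples, sample_id)
  data.frame(sample_id = sample_id[idx],
             subtype = factor(subtype[idx], levels = gbm_subtypes()),
             stringsAsFactors = FALSE)
}

#' Write a label table to TSV
#'
#' @param labels Data frame as returned by [label_table()].
#' @param path Output path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = labels$sample_id,
               subtype = as.character(labels$subtype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- benchmark reports ------------------------------------------------------

#' Assemble an evaluation report
#'
#' A report is the benchmark grid of one experiment: one row ("cell") per
#' (classifier, selector, representation, feature count) combination with
#' its test accuracy in percent, plus the best cell per combination
#' (maximum accuracy, ties broken by fewer features).
#'
#' @param cells Data frame with columns `classifier`, `selector`,
#'   `representation`, `n_features` (integer) and `accuracy` (percent,
#'   0-100).
#' @param snsp Optional per-class sensitivity/specificity table
#'   (see [per_class_sn_sp()]).
#' @return An object of class `xpc_report`.
#' @export
eval_report <- function(cells, snsp = NULL) {
  needed <- c("classifier", "selector", "representation", "n_features", "accuracy")
  if (!all(needed %in% colnames(cells)))
    stop("report cells need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (nrow(cells) > 0 && any(cells$accuracy < 0 | cells$accuracy > 100))
    stop("accuracies must be on the 0-100 percent scale", call. = FALSE)
  best <- best_cells(cells)
  structure(list(cells = cells, best = best, snsp = snsp),
            class = "xpc_report")
}

best_cells <- function(cells) {
  if (nrow(cells) == 0) return(cells)
  key <- interaction(cells$classifier, cells$selector, cells$representation,
                     drop = TRUE)
  picked <- unlist(lapply(split(seq_len(nrow(cells)), key), function(i) {
    sub <- cells[i, ]
    # max accuracy, ties -> smallest feature count
    i[order(-sub$accuracy, sub$n_features)][1]
  }))
  out <- cells[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.xpc_report <- function(x, ...) {
  cat("Cross-representation benchmark report\n")
  cat(sprintf("  %d cells; best per (classifier, selector, representation):\n",
              nrow(x$cells)))
  if (nrow(x$best) > 0) {
    b <- x$best
    for (i in seq_len(nrow(b)))
      cat(sprintf("  %-4s %-8s %-8s %s\n", b$classifier[i], b$selector[i],
                  b$representation[i], format_cell(b$accuracy[i], b$n_features[i])))
  }
  invisible(x)
}

format_cell <- function(acc, n) sprintf("%.1f (%d)", acc, as.integer(n))

#' Write an evaluation report to JSON and TSV
#'
#' Emits the full report as machine-readable JSON and the best-cell grid as
#' a TSV (rows = classifiers, columns = selector x representation) whose
#' cells read `"ACC (N)"` with accuracy in percent to one decimal, e.g.
#' `"97.6 (1000)"`.
#'
#' @param report An `xpc_report`.
#' @param json_path Output path for the JSON report.
#' @param tsv_path Output path for the TSV grid; defaults to `json_path`
#'   with a `.tsv` extension.
#' @export
write_report <- function(report, json_path,
                         tsv_path = sub("\\.json$", ".tsv", json_path)) {
  stopifnot(inherits(report, "xpc_report"))
  payload <- list(cells = report$cells, best = report$best)
  if (!is.null(report$snsp)) payload$snsp <- report$snsp
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")

  b <- report$best
  if (nrow(b) == 0) {
    utils::write.table(data.frame(classifier = character(0)), tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(json_path))
  }
  cols <- unique(paste(b$selector, b$representation, sep = ":"))
  classifiers <- unique(b$classifier)
  grid <- matrix("", nrow = length(classifiers), ncol = length(cols),
                 dimnames = list(classifiers, cols))
  for (i in seq_len(nrow(b))) {
    grid[b$classifier[i], paste(b$selector[i], b$representation[i], sep = ":")] <-
      format_cell(b$accuracy[i], b$n_features[i])
  }
  df <- data.frame(classifier = classifiers, grid, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' Read an evaluation report back from JSON
#'
#' @param json_path Path written by [write_report()].
#' @return An `xpc_report`.
#' @export
read_report <- function(json_path) {
  payload <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  cells <- as.data.frame(payload$cells, stringsAsFactors = FALSE)
  if (length(cells) == 0)
    cells <- data.frame(classifier = character(0), selector = character(0),
                        representation = character(0),
                        n_features = integer(0), accuracy = numeric(0))
  snsp <- if (!is.null(payload$snsp)) as.data.frame(payload$snsp) else NULL
  eval_report(cells, snsp = snsp)
}
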