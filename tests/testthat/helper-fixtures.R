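# small deterministic fixtures shared across test files

random_expression <- function(n_features, n_samples, seed = 1,
                              prefix = "iso") {
  withr::with_seed(seed, {
    m <- matrix(2^rnorm(n_features * n_samples, mean = 8, sd = 2),
                n_features, n_samples)
    expression_matrix(m,
                      sprintf("%s%03d", prefix, seq_len(n_features)),
                      sprintf("s%03d", seq_len(n_samples)))
  })
}

balanced_labels <- function(n_per_class, ids = NULL) {
  subs <- rep(gbm_subtypes(), each = n_per_class)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_along(subs))
  label_table(ids, subs)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# four well-separated classes in a handful of features
separable_xy <- function(n_per_class = 10, n_noise = 3, seed = 5, sd = 0.1) {
  withr::with_seed(seed, {
    y <- factor(rep(gbm_subtypes(), each = n_per_class),
                levels = gbm_subtypes())
    n <- length(y)
    x <- cbind(sig = rep(c(0, 3, 6, 9), each = n_per_class) + rnorm(n, 0, sd),
               matrix(rnorm(n * n_noise), n, n_noise))
    colnames(x) <- c("sig", sprintf("noise%d", seq_len(n_noise)))
    list(x = x, y = y)
  })
}
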