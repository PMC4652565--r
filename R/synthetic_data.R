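#' Specify a strictly monotone platform transform
#'
#' Platform transforms model how two measurement technologies observe the
#' same latent log2 expression on different scales and magnitudes. All
#' transforms are strictly increasing, so they preserve per-feature sample
#' ranks — the property rank-based discretization exploits.
#'
#' Supported kinds:
#' * `identity`
#' * `affine`: `a * x + b`, `a > 0`
#' * `power`: `x^gamma`, `gamma > 0`, domain `x >= 0`
#' * `log_shift`: `log2(x + c)`, domain `x > -c`
#' * `piecewise`: monotone piecewise-linear interpolation through strictly
#'   increasing knots `(x, y)`, with linear extrapolation beyond the first
#'   and last knot
#' * `compose`: sequential application of a list of transforms
#'
#' @param kind One of `"identity"`, `"affine"`, `"power"`, `"log_shift"`,
#'   `"piecewise"`, `"compose"`.
#' @param a,b Affine slope (positive) and intercept.
#' @param gamma Positive exponent for the power transform.
#' @param c Shift for the log transform.
#' @param knots Data frame or list with numeric `x` and `y`, both strictly
#'   increasing, for the piecewise transform.
#' @param transforms List of transform specs for `compose`.
#' @return An object of class `xpc_transform`.
#' @export
transform_spec <- function(kind = c("identity", "affine", "power", "log_shift",
                                    "piecewise", "compose"),
                           a = 1, b = 0, gamma = 1, c = 0,
                           knots = NULL, transforms = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    identity = list(),
    affine = {
      if (!is.finite(a) || a <= 0)
        stop("affine transform needs slope a > 0 to be strictly increasing",
             call. = FALSE)
      list(a = a, b = b)
    },
    power = {
      if (!is.finite(gamma) || gamma <= 0)
        stop("power transform needs gamma > 0 to be strictly increasing",
             call. = FALSE)
      list(gamma = gamma)
    },
    log_shift = list(c = c),
    piecewise = {
      kx <- as.numeric(knots$x); ky <- as.numeric(knots$y)
      if (length(kx) < 2 || length(kx) != length(ky))
        stop("piecewise transform needs >= 2 (x, y) knots", call. = FALSE)
      if (any(diff(kx) <= 0) || any(diff(ky) <= 0))
        stop("piecewise knots must be strictly increasing in x and y",
             call. = FALSE)
      list(x = kx, y = ky)
    },
    compose = {
      if (!length(transforms) || !all(vapply(transforms, inherits,
                                             logical(1), "xpc_transform")))
        stop("compose needs a list of xpc_transform objects", call. = FALSE)
      list(transforms = transforms)
    })
  structure(list(kind = kind, params = spec), class = "xpc_transform")
}

#' Apply a platform transform to a numeric vector
#'
#' Vectorized and deterministic; strict monotonicity means output order
#' statistics equal input order statistics.
#'
#' @param values Numeric vector within the transform's domain.
#' @param spec An `xpc_transform` from [transform_spec()].
#' @return Transformed numeric vector of the same length.
#' @export
apply_transform <- function(values, spec) {
  stopifnot(inherits(spec, "xpc_transform"))
  p <- spec$params
  switch(spec$kind,
    identity = values,
    affine = p$a * values + p$b,
    power = {
      if (any(values < 0))
        stop("power transform domain violation: negative input", call. = FALSE)
      values^p$gamma
    },
    log_shift = {
      if (any(values <= -p$c))
        stop("log_shift transform domain violation: value <= -c", call. = FALSE)
      log2(values + p$c)
    },
    piecewise = piecewise_monotone(values, p$x, p$y),
    compose = {
      for (tr in p$transforms) values <- apply_transform(values, tr)
      values
    })
}

# linear interpolation inside the knot range, slope-extrapolated outside so
# the map stays strictly increasing on the whole real line
piecewise_monotone <- function(v, kx, ky) {
  n <- length(kx)
  out <- stats::approx(kx, ky, xout = v, rule = 2)$y
  lo <- v < kx[1]
  hi <- v > kx[n]
  if (any(lo)) {
    s <- (ky[2] - ky[1]) / (kx[2] - kx[1])
    out[lo] <- ky[1] + s * (v[lo] - kx[1])
  }
  if (any(hi)) {
    s <- (ky[n] - ky[n - 1]) / (kx[n] - kx[n - 1])
    out[hi] <- ky[n] + s * (v[hi] - kx[n])
  }
  out
}

#' Configure the paired-platform simulation
#'
#' Defines a two-platform tumor + normal study with four balanced subtypes
#' and class-specific differential expression on disjoint (by default)
#' blocks of informative features. Matched tumor samples share one latent
#' log2-expression profile that each platform observes through its own
#' strictly monotone transform plus independent technical noise.
#'
#' @param n_features Total number of features (isoforms).
#' @param n_informative_per_class Number of informative features per
#'   subtype; scalar or length-4 vector (order [gbm_subtypes()]).
#' @param n_tumor_per_class Matched tumor samples per subtype.
#' @param n_test_per_class Of those, how many per subtype form the
#'   designated platform-B test subset (<= n_tumor_per_class).
#' @param n_normals Normal reference samples simulated per platform.
#' @param effect_size Latent log2 shift added to a class's informative
#'   features in samples of that class.
#' @param sigma_bio Biological noise SD (latent scale), shared by both
#'   platforms for matched samples.
#' @param sigma_platform Technical noise SD added independently per
#'   platform after the transform.
#' @param transform_A,transform_B Platform observation transforms
#'   ([transform_spec()]).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return An object of class `xpc_sim_config`.
#' @export
simulation_config <- function(n_features = 500,
                              n_informative_per_class = 10,
                              n_tumor_per_class = 50,
                              n_test_per_class = 19,
                              n_normals = 8,
                              effect_size = 1.5,
                              sigma_bio = 0.5,
                              sigma_platform = 0.3,
                              transform_A = transform_spec("identity"),
                              transform_B = transform_spec("identity"),
                              seed = 42) {
  n_inf <- rep_len(as.integer(n_informative_per_class), 4L)
  if (sum(n_inf) > n_features)
    stop("informative features across the 4 classes exceed n_features",
         call. = FALSE)
  if (effect_size < 0 || sigma_bio < 0 || sigma_platform < 0)
    stop("effect_size and noise SDs must be >= 0", call. = FALSE)
  if (n_test_per_class > n_tumor_per_class)
    stop("n_test_per_class cannot exceed n_tumor_per_class", call. = FALSE)
  stopifnot(inherits(transform_A, "xpc_transform"),
            inherits(transform_B, "xpc_transform"))
  structure(list(n_features = as.integer(n_features),
                 n_informative_per_class = n_inf,
                 n_tumor_per_class = as.integer(n_tumor_per_class),
                 n_test_per_class = as.integer(n_test_per_class),
                 n_normals = as.integer(n_normals),
                 effect_size = effect_size,
                 sigma_bio = sigma_bio,
                 sigma_platform = sigma_platform,
                 transform_A = transform_A,
                 transform_B = transform_B,
                 seed = as.integer(seed)),
            class = "xpc_sim_config")
}

#' The documented acceptance scenario
#'
#' A scaled-down analogue of a paired exon-array/RNA-seq tumor study:
#' 500 features with 10 informative per subtype, 50 matched tumors per
#' subtype (the 19 per subtype designated as the platform-B test subset
#' give a 76-sample test set), 8 normals per platform, effect size 1.5
#' latent log2 units, biological noise SD 0.5, platform noise SD 0.3.
#' Platform A observes the latent scale directly; platform B applies the
#' nonlinear monotone map `3 * x^1.8 + 10`, so fold changes are not
#' numerically comparable across platforms but per-feature ranks are.
#'
#' @return An `xpc_sim_config`.
#' @export
default_scenario <- function() {
  simulation_config(
    n_features = 500,
    n_informative_per_class = 10,
    n_tumor_per_class = 50,
    n_test_per_class = 19,
    n_normals = 8,
    effect_size = 1.5,
    sigma_bio = 0.5,
    sigma_platform = 0.3,
    transform_A = transform_spec("affine", a = 1, b = 0),
    transform_B = transform_spec("compose", transforms = list(
      transform_spec("power", gamma = 1.8),
      transform_spec("affine", a = 3, b = 10))),
    seed = 42)
}

#' Generate a matched two-platform tumor + normal dataset
#'
#' Latent log2 expression for tumor sample `s` and feature `f` is
#' `baseline_f + effect_size * [f informative for class(s)] + N(0, sigma_bio)`,
#' with baselines drawn uniformly on `[4, 12]` latent log2 units. Each
#' platform observes `2^(T_p(latent) + N(0, sigma_platform))`, i.e. its
#' monotone transform of the latent profile plus independent technical
#' noise, back-transformed to a positive expression scale. Normal reference
#' samples carry no class effect and are drawn independently per platform.
#'
#' @param config An `xpc_sim_config` from [simulation_config()].
#' @return A list of class `xpc_paired_dataset` with elements `tumor_A`,
#'   `tumor_B` (matrices over identical features and samples), `normals_A`,
#'   `normals_B`, `labels` (a label table), `truth` (named list of
#'   informative feature ids per subtype) and `test_ids` (the designated
#'   matched test subset, `n_test_per_class` per subtype).
#' @export
generate_paired_dataset <- function(config) {
  stopifnot(inherits(config, "xpc_sim_config"))
  withr::with_seed(config$seed, {
    F <- config$n_features
    classes <- gbm_subtypes()
    n_tum <- config$n_tumor_per_class
    n <- n_tum * 4L
    feature_ids <- sprintf("iso%04d", seq_len(F))
    sample_ids <- sprintf("tumor_%s_%02d", rep(classes, each = n_tum),
                          rep(seq_len(n_tum), times = 4L))
    y <- factor(rep(classes, each = n_tum), levels = classes)

    # disjoint informative blocks at the head of the feature list
    n_inf <- config$n_informative_per_class
    stops <- cumsum(n_inf)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    truth <- stats::setNames(lapply(seq_len(4L), function(k) {
      if (n_inf[k] == 0) character(0)
      else feature_ids[starts[k]:stops[k]]
    }), classes)

    baseline <- stats::runif(F, 4, 12)
    latent <- matrix(baseline, nrow = F, ncol = n)
    for (k in seq_len(4L)) {
      if (n_inf[k] > 0)
        latent[starts[k]:stops[k], y == classes[k]] <-
          latent[starts[k]:stops[k], y == classes[k], drop = FALSE] +
          config$effect_size
    }
    latent <- latent + matrix(stats::rnorm(F * n, 0, config$sigma_bio), F, n)

    observe <- function(lat, tr) {
      obs <- apply_transform(as.numeric(lat), tr)
      obs <- obs + stats::rnorm(length(obs), 0, config$sigma_platform)
      matrix(2^obs, nrow = nrow(lat), ncol = ncol(lat))
    }
    tumor_A <- observe(latent, config$transform_A)
    tumor_B <- observe(latent, config$transform_B)

    nnorm <- config$n_normals
    normal_latent <- function() {
      matrix(baseline, F, nnorm) +
        matrix(stats::rnorm(F * nnorm, 0, config$sigma_bio), F, nnorm)
    }
    normals_A <- observe(normal_latent(), config$transform_A)
    normals_B <- observe(normal_latent(), config$transform_B)

    tumor_A <- expression_matrix(tumor_A, feature_ids, sample_ids)
    tumor_B <- expression_matrix(tumor_B, feature_ids, sample_ids)
    normals_A <- expression_matrix(normals_A, feature_ids,
                                   sprintf("normal_A_%02d", seq_len(nnorm)))
    normals_B <- expression_matrix(normals_B, feature_ids,
                                   sprintf("normal_B_%02d", seq_len(nnorm)))

    # matched test subset: the last n_test_per_class samples of each class
    test_ids <- unlist(lapply(classes, function(cl) {
      ids <- sample_ids[y == cl]
      ids[seq.int(length(ids) - config$n_test_per_class + 1L, length(ids))]
    }), use.names = FALSE)
    if (config$n_test_per_class == 0L) test_ids <- character(0)

    structure(list(tumor_A = tumor_A, tumor_B = tumor_B,
                   normals_A = normals_A, normals_B = normals_B,
                   labels = label_table(sample_ids, as.character(y)),
                   truth = truth, test_ids = test_ids,
                   config = config),
              class = "xpc_paired_dataset")
  })
}

#' @export
print.xpc_paired_dataset <- function(x, ...) {
  cat(sprintf(
    "Paired two-platform dataset: %d features x %d matched tumors (%d test), %d normals/platform\n",
    nrow(x$tumor_A), ncol(x$tumor_A), length(x$test_ids), ncol(x$normals_A)))
  invisible(x)
}

#' Write a paired dataset to a directory of TSV/JSON files
#'
#' Emits `tumor_A.tsv`, `tumor_B.tsv`, `normals_A.tsv`, `normals_B.tsv`,
#' `labels.tsv` and `truth.json`.
#'
#' @param dataset An `xpc_paired_dataset`.
#' @param outdir Output directory (created if missing).
#' @export
write_paired_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "xpc_paired_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$tumor_A, file.path(outdir, "tumor_A.tsv"))
  write_expression_matrix(dataset$tumor_B, file.path(outdir, "tumor_B.tsv"))
  write_expression_matrix(dataset$normals_A, file.path(outdir, "normals_A.tsv"))
  write_expression_matrix(dataset$normals_B, file.path(outdir, "normals_B.tsv"))
  write_labels(dataset$labels, file.path(outdir, "labels.tsv"))
  jsonlite::write_json(list(truth = dataset$truth,
                            test_ids = dataset$test_ids),
                       file.path(outdir, "truth.json"))
  invisible(outdir)
}
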