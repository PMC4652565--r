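test_that("accuracy is percent correct to one decimal", {
  expect_equal(accuracy(rep("PN", 76), c(rep("PN", 69), rep("M", 7))), 90.8)
  expect_equal(accuracy(c("PN", "M"), c("PN", "M")), 100)
  expect_equal(accuracy(c("PN", "M"), c("M", "PN")), 0)
  expect_error(accuracy(c("PN"), c("PN", "M")), "equal length")
})

test_that("accuracy equals the confusion-matrix trace over its total", {
  withr::with_seed(70, {
    for (i in 1:20) {
      y <- factor(sample(gbm_subtypes(), 60, replace = TRUE),
                  levels = gbm_subtypes())
      p <- factor(sample(gbm_subtypes(), 60, replace = TRUE),
                  levels = gbm_subtypes())
      cm <- confusion_matrix(y, p)
      expect_equal(accuracy(y, p), round(100 * sum(diag(cm)) / sum(cm), 1))
    }
  })
})

test_that("per-class Sn/Sp reproduce a hand-built one-vs-rest oracle", {
  # true counts 10 per class, diagonal (8, 9, 7, 10), errors placed by hand
  y <- rep(gbm_subtypes(), each = 10)
  p <- y
  p[1:2] <- c("N", "CL")      # two PN errors
  p[11] <- "M"                # one N error
  p[21:23] <- c("PN", "PN", "M")  # three CL errors
  tab <- per_class_sn_sp(y, p)
  expect_equal(tab$sn, c(0.8, 0.9, 0.7, 1.0))
  # specificity by hand: tn/(tn+fp) per one-vs-rest collapse
  expect_equal(tab$sp[1], round(28 / 30, 3))   # PN predicted for 2 CL errors
  expect_equal(tab$sp[2], round(29 / 30, 3))
  expect_equal(tab$sp[3], round(29 / 30, 3))
  expect_equal(tab$sp[4], round(28 / 30, 3))
})

test_that("degenerate prediction patterns give the expected Sn/Sp extremes", {
  y <- rep(gbm_subtypes(), each = 5)
  perfect <- per_class_sn_sp(y, y)
  expect_equal(perfect$sn, rep(1, 4))
  expect_equal(perfect$sp, rep(1, 4))

  allpn <- per_class_sn_sp(y, rep("PN", 20))
  expect_equal(allpn$sn[1], 1)
  expect_equal(allpn$sp[1], 0)

  # class absent from truth -> sensitivity undefined, reported as NA
  missing <- per_class_sn_sp(rep(c("PN", "N", "CL"), each = 5),
                             rep(c("PN", "N", "CL"), each = 5))
  expect_true(is.na(missing$sn[4]))
})

test_that("stratified splits are disjoint, exhaustive and per-class ceilinged", {
  lab <- balanced_labels(12)
  sp <- stratified_split(lab, 0.75, seed = 5)
  expect_setequal(c(sp$train, sp$test), lab$sample_id)
  expect_length(intersect(sp$train, sp$test), 0)
  y <- setNames(lab$subtype, lab$sample_id)
  expect_equal(unname(table(y[sp$train])), rep(9L, 4), ignore_attr = TRUE)

  # the study-scale composition: 342 samples at 3/4 -> 257 train / 85 test
  big <- label_table(sprintf("s%03d", 1:342),
                     rep(gbm_subtypes(), times = c(85, 85, 84, 88)))
  sp2 <- stratified_split(big, 0.75, seed = 2)
  expect_length(sp2$train, 257)
  expect_length(sp2$test, 85)

  tiny <- label_table(sprintf("s%d", 1:4), gbm_subtypes())
  expect_error(stratified_split(tiny, 0.75), ">= 2 samples")
})

test_that("same-platform benchmark reports a full deterministic grid", {
  cfg <- simulation_config(n_features = 60, n_informative_per_class = 4,
                           n_tumor_per_class = 10, n_test_per_class = 0,
                           n_normals = 4, effect_size = 2, seed = 80)
  ds <- generate_paired_dataset(cfg)
  rc <- run_config(representations = c("fc", "equal_f"), selectors = "cv",
                   classifiers = c("svm", "nb"), grid = c(10, 20), k = 4,
                   seed = 80)
  r1 <- run_same_platform(ds$tumor_A, ds$normals_A, ds$labels, rc)
  expect_s3_class(r1, "xpc_report")
  expect_equal(nrow(r1$cells), 2 * 2 * 2)     # reps x classifiers x grid
  expect_true(all(r1$cells$accuracy >= 0 & r1$cells$accuracy <= 100))
  r2 <- run_same_platform(ds$tumor_A, ds$normals_A, ds$labels, rc)
  expect_identical(r1$cells, r2$cells)
})

test_that("cross-platform equals same data when platforms are identical", {
  cfg <- simulation_config(n_features = 50, n_informative_per_class = 4,
                           n_tumor_per_class = 10, n_test_per_class = 4,
                           n_normals = 4, effect_size = 2,
                           sigma_platform = 0, seed = 81)
  ds <- generate_paired_dataset(cfg)   # identity transforms, no platform noise
  expect_identical(ds$tumor_A, ds$tumor_B)
  rc <- run_config(representations = "equal_f", selectors = "cv",
                   classifiers = "svm", grid = 10, k = 5, seed = 81)
  r_ab <- run_cross_platform_paired(ds, rc)
  # testing platform A against itself on the same matched subset
  labels_B <- ds$labels[match(ds$test_ids, ds$labels$sample_id), ]
  r_aa <- run_cross_platform(ds$tumor_A, ds$normals_A, ds$labels,
                             ds$tumor_A[, ds$test_ids], ds$normals_A,
                             labels_B, rc)
  expect_identical(r_ab$cells, r_aa$cells)
})

test_that("rank-preserved platforms give identical bins hence identical accuracy", {
  cfg <- simulation_config(n_features = 80, n_informative_per_class = 5,
                           n_tumor_per_class = 12, n_test_per_class = 5,
                           n_normals = 4, effect_size = 1.5,
                           sigma_platform = 0,
                           transform_B = transform_spec("compose", transforms = list(
                             transform_spec("power", gamma = 1.8),
                             transform_spec("affine", a = 3, b = 10))),
                           seed = 82)
  ds <- generate_paired_dataset(cfg)
  fa <- fold_change(ds$tumor_A[, ds$test_ids], ds$normals_A)
  fb <- fold_change(ds$tumor_B[, ds$test_ids], ds$normals_B)
  da <- discretize_matrix(fa, "equal_freq", k = 10)$bins
  db <- discretize_matrix(fb, "equal_freq", k = 10)$bins
  expect_identical(da, db)
  rc <- run_config(representations = "equal_f", selectors = "cv",
                   classifiers = "svm", grid = 20, seed = 82)
  r_b <- run_cross_platform_paired(ds, rc)
  labels_B <- ds$labels[match(ds$test_ids, ds$labels$sample_id), ]
  r_a <- run_cross_platform(ds$tumor_A, ds$normals_A, ds$labels,
                            ds$tumor_A[, ds$test_ids], ds$normals_A,
                            labels_B, rc)
  expect_identical(r_b$cells$accuracy, r_a$cells$accuracy)
})

test_that("the feature-count grid is clipped to the available pool with a warning", {
  cfg <- simulation_config(n_features = 30, n_informative_per_class = 3,
                           n_tumor_per_class = 8,
                           n_test_per_class = 0, n_normals = 4, seed = 83)
  ds <- generate_paired_dataset(cfg)
  rc <- run_config(representations = "fc", selectors = "cv",
                   classifiers = "svm", grid = c(10, 100), seed = 83)
  expect_warning(r <- run_same_platform(ds$tumor_A, ds$normals_A, ds$labels, rc),
                 "clipped")
  expect_equal(r$cells$n_features, 10L)
})

test_that("per-class Sn/Sp panel is recorded at the requested model size", {
  cfg <- simulation_config(n_features = 40, n_informative_per_class = 4,
                           n_tumor_per_class = 10, n_test_per_class = 4,
                           n_normals = 4, effect_size = 2, seed = 84)
  ds <- generate_paired_dataset(cfg)
  rc <- run_config(representations = "equal_f", selectors = "cv",
                   classifiers = c("svm", "rf"), grid = 10, k = 5, seed = 84)
  r <- run_cross_platform_paired(ds, rc, snsp_n = 20)
  expect_false(is.null(r$snsp))
  expect_setequal(unique(r$snsp$classifier), c("svm", "rf"))
  expect_equal(nrow(r$snsp), 8)   # 4 classes x 2 classifiers
})
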