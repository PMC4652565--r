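test_that("all four classifiers separate a cleanly separable one-feature problem", {
  d <- separable_xy(n_per_class = 10, n_noise = 0, seed = 40)
  for (method in c("svm", "rf", "nb", "pam")) {
    model <- train_classifier(d$x, d$y, method = method, seed = 7)
    pred <- predict(model, d$x)
    expect_equal(accuracy(d$y, pred), 100, info = method)
  }
})

test_that("training refuses classes with fewer than two samples", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c("PN", "PN", "N", "N", "M"))
  expect_error(train_classifier(x, y, "svm"), "2 training samples.*M")
})

test_that("prediction enforces the feature and representation contracts", {
  d <- separable_xy(seed = 41)
  model <- train_classifier(d$x, d$y, "svm", representation = "equal_f")
  bad <- d$x[, -1, drop = FALSE]
  expect_error(predict(model, bad), "feature list mismatch")
  expect_error(predict(model, d$x, representation = "fc"),
               "representation mismatch.*equal_f.*fc")
  expect_silent(predict(model, d$x, representation = "equal_f"))
})

test_that("prediction is equivariant to sample order and handles single samples", {
  d <- separable_xy(seed = 42)
  model <- train_classifier(d$x, d$y, "svm")
  p <- predict(model, d$x)
  perm <- withr::with_seed(43, sample(nrow(d$x)))
  expect_identical(as.character(predict(model, d$x[perm, ])),
                   as.character(p)[perm])
  expect_length(predict(model, d$x[1, , drop = FALSE]), 1L)
})

test_that("random-forest training is reproducible under a fixed seed", {
  d <- separable_xy(n_per_class = 8, n_noise = 5, seed = 44, sd = 2)
  m1 <- train_classifier(d$x, d$y, "rf", seed = 11)
  m2 <- train_classifier(d$x, d$y, "rf", seed = 11)
  expect_identical(as.character(predict(m1, d$x)),
                   as.character(predict(m2, d$x)))
})

test_that("deterministic classifiers are invariant to joint feature permutation", {
  d <- separable_xy(n_per_class = 8, n_noise = 4, seed = 45)
  perm <- c(3, 1, 5, 2, 4)
  for (method in c("svm", "nb", "pam")) {
    m1 <- train_classifier(d$x, d$y, method)
    m2 <- train_classifier(d$x[, perm], d$y, method)
    expect_identical(as.character(predict(m2, d$x)),
                     as.character(predict(m1, d$x)), info = method)
  }
})

# ---- categorical naive Bayes ------------------------------------------------

test_that("smoothed categorical NB matches a hand-computed posterior", {
  x <- matrix(c(rep(1L, 10), rep(2L, 10)), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- factor(rep(c("PN", "M"), each = 10), levels = gbm_subtypes())
  fit <- nb_fit_discrete(x, y, alpha = 0.01, n_bins = 2)
  post <- nb_predict_discrete(fit, x, type = "raw")
  # by hand: P(bin1|PN) = 10.01/10.02, P(bin1|M) = 0.01/10.02, priors 1/2
  p1_pn <- 10.01 / 10.02
  p1_m <- 0.01 / 10.02
  expect_equal(unname(post[1, "PN"]), p1_pn / (p1_pn + p1_m), tolerance = 1e-12)
  expect_true(all(post[1:10, "PN"] >= 0.99))
  expect_true(all(post[11:20, "M"] >= 0.99))
})

test_that("NB posteriors sum to one and degrade to priors as alpha grows", {
  withr::with_seed(46, {
    x <- matrix(sample(1:4, 60, replace = TRUE), 20, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- factor(rep(c("PN", "N", "CL", "M"), each = 5), levels = gbm_subtypes())
  })
  fit <- nb_fit_discrete(x, y, alpha = 1, n_bins = 4)
  post <- nb_predict_discrete(fit, x, type = "raw")
  expect_equal(unname(rowSums(post)), rep(1, 20), tolerance = 1e-12)

  fit_big <- nb_fit_discrete(x, y, alpha = 1e9, n_bins = 4)
  post_big <- nb_predict_discrete(fit_big, x, type = "raw")
  expect_equal(unname(post_big[1, ]), rep(0.25, 4), tolerance = 1e-6)
})

test_that("NB likelihood factorizes over independent features", {
  x <- matrix(c(1L, 2L, 1L, 2L, 1L, 1L, 2L, 2L), 4, 2,
              dimnames = list(NULL, c("a", "b")))
  y <- factor(c("PN", "PN", "M", "M"), levels = gbm_subtypes())
  both <- nb_fit_discrete(x, y, alpha = 0.5, n_bins = 2)
  fa <- nb_fit_discrete(x[, 1, drop = FALSE], y, alpha = 0.5, n_bins = 2)
  fb <- nb_fit_discrete(x[, 2, drop = FALSE], y, alpha = 0.5, n_bins = 2)
  # joint log-likelihood = sum of single-feature log-likelihoods
  expect_equal(both$tables$a + both$tables$b,
               fa$tables$a + fb$tables$b, tolerance = 1e-12)
})

test_that("categorical NB rejects non-integer input", {
  x <- matrix(c(1.5, 2, 1, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(c("PN", "M"))
  expect_error(nb_fit_discrete(x, y, n_bins = 2), "integer bins")
})

# ---- nearest shrunken centroids ---------------------------------------------

test_that("PAM at zero threshold equals brute-force standardized nearest centroid", {
  for (i in 1:10) {
    withr::with_seed(50 + i, {
      x <- matrix(rnorm(48 * 6), 48, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
      y <- factor(rep(gbm_subtypes(), each = 12), levels = gbm_subtypes())
      xt <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, sprintf("f%d", 1:6)))
    })
    model <- pam_fit(x, y, delta = 0)
    w <- (model$s + model$s0)^2
    oracle <- apply(xt, 1, function(row) {
      sc <- vapply(seq_along(model$levels), function(k)
        sum((row - model$centroids[, k])^2 / w) - 2 * log(model$priors[k]),
        numeric(1))
      model$levels[which.min(sc)]
    })
    expect_identical(as.character(pam_predict(model, xt)), unname(oracle))
  }
})

test_that("total shrinkage collapses centroids and predicts the dominant class", {
  withr::with_seed(60, {
    x <- matrix(rnorm(35 * 5), 35, 5, dimnames = list(NULL, sprintf("f%d", 1:5)))
    y <- factor(rep(gbm_subtypes(), times = c(20, 5, 5, 5)),
                levels = gbm_subtypes())
  })
  d_max <- max(abs(pam_fit(x, y, delta = 0)$d))
  model <- pam_fit(x, y, delta = d_max + 1)
  expect_equal(unname(model$shrunk_centroids[, 1]),
               unname(model$shrunk_centroids[, 4]))
  expect_true(all(pam_predict(model, x) == "PN"))
  expect_equal(pam_active_features(model), 0L)
})

test_that("a feature with class centroids at the overall centroid never matters", {
  withr::with_seed(61, {
    x <- matrix(rnorm(24 * 3), 24, 3, dimnames = list(NULL, c("a", "b", "flat")))
    y <- factor(rep(gbm_subtypes(), each = 6), levels = gbm_subtypes())
    x[, "flat"] <- rep(c(-1, 1), 12)   # identical distribution in every class
  })
  model <- pam_fit(x, y, delta = 0)
  expect_equal(unname(model$d["flat", ]), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(model$dprime["flat", ]), rep(0, 4))
})

test_that("the count of shrinkage-surviving features is non-increasing in the threshold", {
  withr::with_seed(62, {
    x <- matrix(rnorm(40 * 20), 40, 20,
                dimnames = list(NULL, sprintf("f%02d", 1:20)))
    y <- factor(rep(gbm_subtypes(), each = 10), levels = gbm_subtypes())
    x[y == "PN", 1:4] <- x[y == "PN", 1:4] + 2
  })
  base <- pam_fit(x, y, delta = 0)
  grid <- seq(0, max(abs(base$d)), length.out = 12)
  counts <- vapply(grid, function(dl)
    pam_active_features(pam_fit(x, y, delta = dl)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cross-validated threshold selection is deterministic and sparsifying", {
  withr::with_seed(63, {
    x <- matrix(rnorm(60 * 15), 60, 15,
                dimnames = list(NULL, sprintf("f%02d", 1:15)))
    y <- factor(rep(gbm_subtypes(), each = 15), levels = gbm_subtypes())
    for (k in 1:4) x[y == gbm_subtypes()[k], k] <- x[y == gbm_subtypes()[k], k] + 3
  })
  m1 <- pam_fit(x, y, n_thresholds = 20, cv_folds = 5, seed = 9)
  m2 <- pam_fit(x, y, n_thresholds = 20, cv_folds = 5, seed = 9)
  expect_identical(m1$delta, m2$delta)
  expect_gt(m1$delta, 0)                       # ties resolved toward sparsity
  expect_gte(accuracy(y, pam_predict(m1, x)), 95)
})
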