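test_that("make_dummy encodes the fixed (MSC, nonMSC) column order", {
  Y <- make_dummy(c("MSC", "nonMSC", "MSC"))
  expect_identical(colnames(Y), c("MSC", "nonMSC"))
  expect_equal(unname(Y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_true(all(rowSums(Y) == 1))
  expect_warning(make_dummy(c("MSC", "MSC")), "single class")
  expect_error(make_dummy(character(0)), "empty")
  expect_error(make_dummy(c("MSC", "stroma")), "unknown class label")
})

test_that("soft_threshold_select applies the shrinkage formula", {
  # hand evaluation: lambda = third-largest |v| = 1, shrunk to (2, -1, 0)
  out <- soft_threshold_select(c(3, -2, 1), 2)
  expect_equal(out, c(2, -1, 0) / sqrt(5))
  # keepX = p reduces to plain normalization
  v <- c(1.5, -0.5, 2)
  expect_equal(soft_threshold_select(v, 3), v / sqrt(sum(v^2)))
  expect_error(soft_threshold_select(v, 0), "keepX")
  expect_error(soft_threshold_select(v, 4), "keepX")
})

test_that("soft_threshold support equals brute-force top-keepX magnitudes", {
  withr::with_seed(10, {
    for (i in 1:200) {
      p <- sample(2:15, 1)
      v <- rnorm(p)
      keepX <- sample(p, 1)
      out <- soft_threshold_select(v, keepX)
      expect_equal(sum(out^2), 1)
      top <- order(-abs(v), seq_len(p))[seq_len(keepX)]
      expect_setequal(which(out != 0), top)
    }
  })
})

test_that("tied magnitudes fall back to deterministic top-keepX", {
  out <- soft_threshold_select(c(2, -2, 2, 2), 2)
  expect_equal(which(out != 0), c(1, 2))
  expect_equal(out, c(2, -2, 0, 0) / sqrt(8))
})

test_that("with keepX = p, H = 1 the loading matches the SVD oracle", {
  withr::with_seed(20, {
    for (i in 1:10) {
      X <- matrix(rnorm(200), 20, 10)
      labels <- rep(c("MSC", "nonMSC"), each = 10)
      Y <- make_dummy(labels)
      fit <- fit_splsda(X, Y, H = 1, keepX = 10)
      Xc <- scale(X)
      Yc <- scale(Y, scale = FALSE)
      u_ref <- svd(crossprod(Xc, Yc))$u[, 1]
      cosine <- abs(sum(fit$components[[1]]$loading * u_ref))
      expect_gt(cosine, 1 - 1e-8)
    }
  })
})

test_that("component-1 loading agrees with an independent sPLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  withr::with_seed(21, {
    X <- matrix(rnorm(300), 30, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
    labels <- rep(c("MSC", "nonMSC"), each = 15)
    X[labels == "MSC", 1:3] <- X[labels == "MSC", 1:3] + 2
    ours <- fit_splsda(X, make_dummy(labels), H = 1, keepX = 10)
    ref <- mixOmics::splsda(X, factor(labels), ncomp = 1,
                            keepX = 10, scale = TRUE)
    u_ref <- ref$loadings$X[, 1]
    cosine <- abs(sum(ours$components[[1]]$loading * u_ref) /
                    sqrt(sum(u_ref^2)))
    expect_gt(cosine, 1 - 1e-6)
  })
})

test_that("a perfectly separating gene is found by keepX = 1", {
  withr::with_seed(22, {
    X <- matrix(rnorm(200), 20, 10,
                dimnames = list(NULL, paste0("g", 1:10)))
    labels <- rep(c("MSC", "nonMSC"), each = 10)
    X[labels == "MSC", 7] <- X[labels == "MSC", 7] + 10
    fit <- fit_splsda(X, make_dummy(labels), H = 1, keepX = 1)
    # brute-force oracle: the gene maximizing |cross-covariance with Y|
    Xc <- scale(X)
    Yc <- scale(make_dummy(labels), scale = FALSE)
    best <- which.max(rowSums(crossprod(Xc, Yc)^2))
    expect_equal(unname(which(fit$components[[1]]$loading != 0)),
                 unname(best))
    expect_equal(unname(best), 7L)
  })
})

test_that("fitted models are invariant to sample permutation", {
  withr::with_seed(23, {
    X <- matrix(rnorm(150), 15, 10)
    labels <- rep(c("MSC", "nonMSC", "MSC"), each = 5)
    fit1 <- fit_splsda(X, make_dummy(labels), H = 2, keepX = 5)
    perm <- sample(15)
    fit2 <- fit_splsda(X[perm, ], make_dummy(labels[perm]), H = 2,
                       keepX = 5)
    expect_equal(fit1$components[[1]]$loading,
                 fit2$components[[1]]$loading)
    expect_equal(fit1$components[[2]]$loading,
                 fit2$components[[2]]$loading)
  })
})

test_that("component scores are mutually orthogonal after deflation", {
  withr::with_seed(24, {
    X <- matrix(rnorm(400), 20, 20)
    labels <- rep(c("MSC", "nonMSC"), each = 10)
    fit <- fit_splsda(X, make_dummy(labels), H = 4, keepX = 8)
    for (a in 1:3) for (b in (a + 1):4) {
      ta <- fit$components[[a]]$score
      tb <- fit$components[[b]]$score
      expect_lt(abs(sum(ta * tb)),
                1e-8 * sqrt(sum(ta^2)) * sqrt(sum(tb^2)))
    }
  })
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(40), 4, 10)
  expect_error(fit_splsda(X[1:2, ], make_dummy(c("MSC", "nonMSC"))),
               "at least 3")
  expect_error(
    suppressWarnings(fit_splsda(X, make_dummy(rep("MSC", 4)), H = 1)),
    "both classes")
  # zero-variance gene gets scale 1 and a forced-zero loading
  X[, 3] <- 5
  fit <- fit_splsda(X, make_dummy(c("MSC", "MSC", "nonMSC", "nonMSC")),
                    H = 1, keepX = 10)
  expect_equal(fit$scale[[3]], 1)
  expect_equal(fit$components[[1]]$loading[[3]], 0)
})

test_that("predict_score has the indicator-regression properties", {
  d <- toy_design(p = 20, k = 4, n_per = 10, effect = 3, seed = 30)
  fit <- fit_splsda(d$X, make_dummy(d$samples$class_label), H = 2,
                    keepX = 10)
  sc <- predict_score(fit, d$X)
  expect_true(all(sc >= 0 & sc <= 1))
  # the global training mean scores the MSC class proportion
  expect_equal(predict_score(fit, colMeans(d$X)), 0.5, tolerance = 1e-8)
  # the MSC centroid scores above 0.5
  msc_centroid <- colMeans(d$X[d$samples$class_label == "MSC", ])
  expect_gt(predict_score(fit, msc_centroid), 0.5)
  # determinism
  expect_identical(sc, predict_score(fit, d$X))
})

test_that("prediction handles missing genes by center imputation", {
  d <- toy_design(p = 10, k = 2, n_per = 8, effect = 3, seed = 31)
  fit <- fit_splsda(d$X, make_dummy(d$samples$class_label), H = 1,
                    keepX = 10)
  # dropping one uninformative gene barely changes scores
  x1 <- d$X[, -10, drop = FALSE]
  expect_warning(s1 <- predict_score(fit, x1), "missing")
  expect_equal(s1, predict_score(fit, d$X), tolerance = 0.05)
  # manual projection oracle: a missing gene contributes exactly zero
  # after centering
  xa <- d$X[1, , drop = FALSE]
  xa[1, 10] <- fit$center[[10]]
  expect_equal(suppressWarnings(predict_score(fit, x1[1, , drop = FALSE])),
               predict_score(fit, xa))
  # more than half missing is an error
  expect_error(
    suppressWarnings(predict_score(fit, d$X[, 1:4])), "insufficient")
})

test_that("tune_keepX honours its grid and finds sparse informative fits", {
  d <- toy_design(p = 30, k = 1, n_per = 10, effect = 4, seed = 32)
  # singleton grid
  expect_identical(
    tune_keepX(d$X, d$samples$class_label, grid = 1, folds = 3, H = 2),
    c(1L, 1L))
  # one informative gene: keepX = 1 wins or ties against a dense model
  pick <- tune_keepX(d$X, d$samples$class_label, grid = c(1, 30),
                     folds = 4, H = 1, seed = 7)
  expect_identical(pick, 1L)
  expect_error(tune_keepX(d$X, d$samples$class_label, grid = integer(0)),
               "non-empty")
  expect_error(tune_keepX(d$X, d$samples$class_label, grid = 1, folds = 1),
               "folds")
})
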