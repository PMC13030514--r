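test_that("all five algorithms separate two well-separated classes", {
  d <- separable_classes()
  for (algo in c("rf", "svm", "nn", "maxent", "simca")) {
    m <- train_classifier(d$x, algo, y = d$y, seed = 1)
    pred <- predict(m, d$x, type = "class")
    expect_equal(mean(as.character(pred) == as.character(d$y)), 1,
                 info = algo)
    prob <- predict(m, d$x, type = "prob")
    expect_equal(unname(rowSums(prob)), rep(1, nrow(d$x)), tolerance = 1e-6)
  }
})

test_that("training is deterministic given the seed", {
  d <- separable_classes(gap = 2)
  for (algo in c("rf", "nn")) {
    m1 <- train_classifier(d$x, algo, y = d$y, seed = 7)
    m2 <- train_classifier(d$x, algo, y = d$y, seed = 7)
    expect_identical(predict(m1, d$x), predict(m2, d$x), info = algo)
  }
})

test_that("single-class input is rejected except for SIMCA", {
  d <- separable_classes()
  one <- d$y == "A"
  expect_error(train_classifier(d$x[one, ], "rf", y = d$y[one]),
               "at least 2 classes")
  m <- train_classifier(d$x[one, ], "simca", y = droplevels(d$y[one]))
  pred <- predict(m, d$x, type = "class")
  expect_true(all(pred == "A"))
})

test_that("the RF feature-per-split rule falls back when features are few", {
  d <- separable_classes(p = 4)
  expect_message(train_classifier(d$x, "rf", y = d$y, seed = 1),
                 "using all features")
})

test_that("SIMCA distances match the brute-force projection oracle", {
  set.seed(12)
  x <- matrix(rnorm(60 * 7), 60, 7)
  y <- factor(rep(c("A", "B", "C"), each = 20))
  m <- simca_fit(x, y, ncomp = 2)
  xt <- matrix(rnorm(15 * 7), 15, 7)
  d <- simca_classify(m, xt)$distances
  for (ci in seq_along(levels(y))) {
    sub <- m$models[[ci]]
    for (i in 1:15) {
      xc <- xt[i, ] - sub$mean
      resid <- xc - sub$loadings %*% (t(sub$loadings) %*% xc)
      expect_equal(unname(d[i, ci]), sqrt(sum(resid^2)), tolerance = 1e-10)
    }
  }
})

test_that("a point on a class plane has zero orthogonal distance", {
  set.seed(13)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- factor(rep(c("A", "B"), each = 20))
  m <- simca_fit(x, y, ncomp = 2)
  a <- m$models[["A"]]
  onplane <- a$mean + 3 * a$loadings[, 1] - 2 * a$loadings[, 2]
  res <- simca_classify(m, onplane)
  expect_equal(unname(res$distances[1, "A"]), 0, tolerance = 1e-10)
  expect_equal(as.character(res$class), "A")
  expect_error(simca_classify(m, rnorm(4)), "dimension")
})

test_that("SIMCA separates distant Gaussian classes completely", {
  set.seed(14)
  p <- 10
  xa <- matrix(rnorm(100 * p), ncol = p)
  xb <- matrix(rnorm(100 * p, mean = 10), ncol = p)  # 10 sd apart
  m <- simca_fit(rbind(xa, xb), factor(rep(c("A", "B"), each = 100)))
  test <- rbind(matrix(rnorm(100 * p), ncol = p),
                matrix(rnorm(100 * p, mean = 10), ncol = p))
  pred <- simca_classify(m, test)$class
  expect_equal(as.character(pred), rep(c("A", "B"), each = 100))
  expect_true(all(vapply(m$models, `[[`, 0, "threshold") > 0))
})

test_that("SIMCA ties break towards the smaller class index", {
  # two identical class models: every distance ties
  x <- matrix(rnorm(20 * 5), 20, 5)
  m <- simca_fit(rbind(x, x), factor(rep(c("A", "B"), each = 20)))
  pred <- simca_classify(m, x)$class
  expect_true(all(pred == "A"))
})

test_that("cross-validation keeps plants whole and scores the grid", {
  d <- separable_classes(n_per_class = 20, gap = 6)
  fm <- structure(list(x = d$x, y = d$y, plant = d$plant,
                       wavelengths = seq_len(ncol(d$x))),
                  class = "feature_matrix")
  cv <- cross_validate(fm, "rf", grid = list(list()), folds = 5, seed = 3)
  expect_equal(dim(cv$fold_scores), c(1, 5))
  expect_gte(mean(cv$fold_scores), 0.95)
  # no plant assigned to two folds
  expect_equal(anyDuplicated(names(cv$fold_of_plant)), 0)
  # grid of two points: ties resolve to the first, best is reported
  cv2 <- cross_validate(fm, "rf",
                        grid = list(list(trees = 50), list(trees = 60)),
                        folds = 3, seed = 3)
  expect_true(cv2$best_index %in% 1:2)
  expect_equal(cv2$best,
               list(list(trees = 50), list(trees = 60))[[cv2$best_index]])
})

test_that("cross-validation reduces folds when plants are scarce", {
  d <- separable_classes(n_per_class = 3, gap = 6)
  fm <- structure(list(x = d$x, y = d$y, plant = d$plant,
                       wavelengths = seq_len(ncol(d$x))),
                  class = "feature_matrix")
  expect_warning(cv <- cross_validate(fm, "maxent", folds = 5, seed = 1),
                 "reducing folds")
  expect_equal(ncol(cv$fold_scores), 3)
})

test_that("feature matrices are SNV-preprocessed mean spectra", {
  co <- small_cohort()
  fm <- roi_features(co)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm$x), length(co$rois))
  # every row is SNV-normalised
  expect_equal(unname(rowMeans(fm$x)), rep(0, nrow(fm$x)), tolerance = 1e-10)
  fm2 <- roi_features(co, pca_k = 3)
  expect_equal(ncol(fm2$x), 3)
})

test_that("predictions validate the feature dimension", {
  d <- separable_classes()
  m <- train_classifier(d$x, "rf", y = d$y, seed = 1)
  expect_error(predict(m, d$x[, 1:3]), "features")
})
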