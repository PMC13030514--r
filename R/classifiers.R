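#' Build a classification feature matrix from ROIs
#'
#' The default feature vector of an ROI is its smoothed, SNV-transformed mean
#' spectrum (all bands). Optionally the spectra are further reduced to `k`
#' principal-component scores fitted on the supplied set.
#'
#' @param x A `weed_cohort` or ROI table data.frame.
#' @param smooth_window Moving-average window (odd; default 5).
#' @param snv_enabled Apply SNV after smoothing (default `TRUE`).
#' @param pca_k Optional number of PCA score features; `NULL` keeps all
#'   bands.
#' @return A `feature_matrix` list: `x` (numeric matrix), `y` (factor of
#'   species), `plant` (character plant ids), `wavelengths`.
#' @export
roi_features <- function(x, smooth_window = 5, snv_enabled = TRUE,
                         pca_k = NULL) {
  tab <- if (inherits(x, "weed_cohort")) roi_table(x) else x
  wl <- roi_wavelengths(x)
  bands <- grep("^b[0-9]", names(tab))
  m <- as.matrix(tab[, bands, drop = FALSE])
  m <- preprocess_spectra(m, window = smooth_window,
                          snv_enabled = snv_enabled)
  if (!is.null(pca_k)) {
    fit <- fit_pixel_pca(m, k = pca_k)
    m <- fit$scores
    colnames(m) <- paste0("t", seq_len(pca_k))
  } else {
    colnames(m) <- sprintf("b%g", wl)
  }
  if (anyNA(m)) stop("feature matrix contains missing values", call. = FALSE)
  structure(list(x = m, y = factor(tab$species), plant = tab$plant_id,
                 wavelengths = wl),
            class = "feature_matrix")
}

.algorithms <- function() c("rf", "svm", "nn", "maxent", "simca")

.default_hyperparams <- function(algorithm) {
  switch(algorithm,
    rf = list(trees = 100, features_per_split = 11),
    svm = list(cost = 1.0),
    nn = list(size = NULL, decay = 0, maxit = 100),
    maxent = list(decay = 0.001, maxit = 500),
    simca = list(ncomp = 2, od_quantile = 0.95))
}

#' Train a species classifier
#'
#' Five algorithms under one interface, each at its published default
#' hyperparameters:
#' \describe{
#'   \item{`rf`}{random forest — 100 trees, unrestricted depth, 11 features
#'     per split (all features if fewer are available, with a message).}
#'   \item{`svm`}{linear support vector machine, `C = 1.0`, one-vs-rest;
#'     class probabilities via a softmax over the per-class decision values
#'     (an approximation, documented — needed for log loss).}
#'   \item{`nn`}{single-hidden-layer neural network with logistic hidden
#'     activation; hidden width auto-selected as the geometric mean of input
#'     and output dimension, rounded up.}
#'   \item{`maxent`}{maximum-entropy model, i.e. L2-regularised multinomial
#'     logistic regression with penalty `decay = 0.001`.}
#'   \item{`simca`}{soft independent modelling of class analogy — one
#'     2-component PCA model per class, classification by smallest orthogonal
#'     distance (see [simca_fit()]).}
#' }
#' Training class priors are recorded for log-loss-reduction baselines.
#'
#' @param features A `feature_matrix` (from [roi_features()]), or a numeric
#'   matrix when `y` is given.
#' @param algorithm One of `"rf"`, `"svm"`, `"nn"`, `"maxent"`, `"simca"`.
#' @param y Factor of class labels (ignored when `features` is a
#'   `feature_matrix`).
#' @param hyperparams Named list overriding the defaults above.
#' @param seed Integer seed; identical seeds give identical fits and
#'   predictions.
#' @return A `weed_classifier` object.
#' @export
train_classifier <- function(features, algorithm = .algorithms(), y = NULL,
                             hyperparams = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  if (inherits(features, "feature_matrix")) {
    y <- features$y
    x <- features$x
  } else {
    x <- as.matrix(features)
    y <- factor(y)
  }
  y <- droplevels(y)
  if (nlevels(y) < 2 && algorithm != "simca")
    stop("'", algorithm, "' needs at least 2 classes (SIMCA accepts one)",
         call. = FALSE)
  hp <- utils::modifyList(.default_hyperparams(algorithm), hyperparams)
  set.seed(seed)
  fit <- switch(algorithm,
    rf = {
      mtry <- hp$features_per_split
      if (mtry > ncol(x)) {
        message("features_per_split (", mtry, ") > ", ncol(x),
                " features; using all features")
        mtry <- ncol(x)
      }
      randomForest::randomForest(x, y, ntree = hp$trees, mtry = mtry)
    },
    svm = .svm_ovr_fit(x, y, cost = hp$cost),
    nn = {
      size <- hp$size
      if (is.null(size)) size <- ceiling(sqrt(ncol(x) * nlevels(y)))
      nnet::nnet(x, nnet::class.ind(y), size = size, decay = hp$decay,
                 maxit = hp$maxit, softmax = TRUE, MaxNWts = 100000,
                 trace = FALSE)
    },
    maxent = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, decay = hp$decay, maxit = hp$maxit,
                     MaxNWts = 100000, trace = FALSE)
    },
    simca = simca_fit(x, y, ncomp = hp$ncomp, od_quantile = hp$od_quantile))
  structure(list(algorithm = algorithm, fit = fit, classes = levels(y),
                 priors = as.numeric(table(y)) / length(y),
                 hyperparams = hp, seed = seed,
                 feature_names = colnames(x)),
            class = "weed_classifier")
}

# One-vs-rest linear SVMs; decision values oriented so larger = that class.
.svm_ovr_fit <- function(x, y, cost) {
  models <- lapply(levels(y), function(cl) {
    yy <- factor(ifelse(y == cl, "target", "other"),
                 levels = c("target", "other"))
    m <- e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(m, x, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- mean(dv[yy == "target"]) < mean(dv[yy == "other"])
    list(model = m, flip = flip)
  })
  names(models) <- levels(y)
  models
}

.svm_ovr_decision <- function(fit, newx) {
  dv <- vapply(fit, function(m) {
    d <- attr(stats::predict(m$model, newx, decision.values = TRUE),
              "decision.values")[, 1]
    if (m$flip) -d else d
  }, numeric(nrow(newx)))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
  dv
}

.softmax <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

#' @export
print.weed_classifier <- function(x, ...) {
  cat("<weed_classifier> ", x$algorithm, ", ", length(x$classes),
      " classes, ", length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Predict species for new feature rows
#'
#' @param object A `weed_classifier`.
#' @param newdata Numeric matrix (or `feature_matrix`) with the training
#'   feature dimension.
#' @param type `"prob"` for a row-normalised class-probability matrix (rows
#'   sum to 1; SIMCA emits inverse-distance scores normalised to sum 1) or
#'   `"class"` for hard labels (row-wise argmax, first-class tie-break).
#' @param ... Unused.
#' @return Matrix of probabilities or factor of classes.
#' @export
predict.weed_classifier <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  newx <- if (inherits(newdata, "feature_matrix")) newdata$x else
    as.matrix(newdata)
  if (ncol(newx) != length(object$feature_names))
    stop("newdata has ", ncol(newx), " features; the model was trained on ",
         length(object$feature_names), call. = FALSE)
  prob <- switch(object$algorithm,
    rf = {
      p <- stats::predict(object$fit, newx, type = "prob")
      p[, object$classes, drop = FALSE]
    },
    svm = .softmax(.svm_ovr_decision(object$fit, newx)),
    nn = {
      p <- stats::predict(object$fit, newx)
      if (is.null(dim(p))) p <- matrix(p, nrow = nrow(newx))
      p
    },
    maxent = {
      df <- data.frame(newx, check.names = FALSE)
      p <- stats::predict(object$fit, df, type = "probs")
      if (is.null(dim(p)))
        p <- cbind(1 - p, p)  # two-class multinom returns a vector
      p
    },
    simca = {
      d <- simca_classify(object$fit, newx)$distances
      inv <- 1 / (d + 1e-12)
      inv / rowSums(inv)
    })
  prob <- matrix(as.numeric(prob), nrow = nrow(newx),
                 dimnames = list(NULL, object$classes))
  if (type == "prob") return(prob)
  factor(object$classes[max.col(prob, ties.method = "first")],
         levels = object$classes)
}

# ---- SIMCA ----------------------------------------------------------------

#' Fit a SIMCA model
#'
#' Soft independent modelling of class analogy: a separate principal-component
#' model (class mean + first `ncomp` loadings, default PC1-PC2) is fitted to
#' the training spectra of each class. Each class also records a critical
#' orthogonal-distance threshold (the `od_quantile` quantile of its training
#' residual norms) usable for class-membership tests.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels (a single class is allowed).
#' @param ncomp Components per class model (capped at `n_class - 1` and the
#'   feature dimension).
#' @param od_quantile Quantile for the critical distance (default 0.95).
#' @return A `simca_model`: per class `mean`, `loadings`, `eigenvalues`,
#'   `threshold`.
#' @export
simca_fit <- function(x, y, ncomp = 2, od_quantile = 0.95) {
  x <- as.matrix(x); y <- droplevels(factor(y))
  sub <- lapply(levels(y), function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xs)
    xc <- sweep(xs, 2, mu)
    k <- max(1, min(ncomp, nrow(xs) - 1, ncol(xs)))
    sv <- svd(xc)
    v <- sv$v[, seq_len(k), drop = FALSE]
    od <- sqrt(rowSums((xc - xc %*% v %*% t(v))^2))
    list(mean = mu, loadings = v,
         eigenvalues = (sv$d^2 / max(1, nrow(xs) - 1))[seq_len(k)],
         threshold = max(stats::quantile(od, od_quantile), 1e-8))
  })
  names(sub) <- levels(y)
  structure(list(classes = levels(y), models = sub, ncomp = ncomp),
            class = "simca_model")
}

#' Classify samples with a SIMCA model
#'
#' Computes each sample's orthogonal distance to every class model — the
#' residual norm after projecting the mean-centred sample onto the class's
#' principal-component plane — and assigns the class with the smallest
#' distance (ties broken by the smaller class index).
#'
#' @param model A `simca_model`.
#' @param x Numeric matrix (or single spectrum) with the training feature
#'   dimension.
#' @return `list(class = factor, distances = n x n_classes matrix)`.
#' @export
simca_classify <- function(model, x) {
  stopifnot(inherits(model, "simca_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  p <- length(model$models[[1]]$mean)
  if (ncol(x) != p)
    stop("feature dimension ", ncol(x), " does not match the model (", p,
         ")", call. = FALSE)
  d <- vapply(model$models, function(m) {
    xc <- sweep(x, 2, m$mean)
    proj <- xc %*% m$loadings %*% t(m$loadings)
    sqrt(rowSums((xc - proj)^2))
  }, numeric(nrow(x)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  colnames(d) <- model$classes
  cls <- factor(model$classes[max.col(-d, ties.method = "first")],
                levels = model$classes)
  list(class = cls, distances = d)
}

# ---- cross-validation -----------------------------------------------------

#' Grouped, stratified k-fold cross-validation with grid search
#'
#' Folds are stratified by species and grouped by plant: all ROIs of a plant
#' land in the same fold, so no plant ever straddles folds. Each grid point
#' (a named list of hyperparameter overrides) is scored by mean fold
#' accuracy; the best point is the maximum, ties resolved by grid order. If
#' some species has fewer plants than folds the fold count is reduced with a
#' warning.
#'
#' @param features A `feature_matrix` with plant ids.
#' @param algorithm Algorithm id (see [train_classifier()]).
#' @param grid List of hyperparameter lists (default: one point, the
#'   published defaults).
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment and training.
#' @return list: `best` (the winning grid point), `best_index`,
#'   `fold_scores` (grid x fold accuracy matrix), `fold_of_plant`.
#' @export
cross_validate <- function(features, algorithm, grid = list(list()),
                           folds = 5, seed = 1) {
  stopifnot(inherits(features, "feature_matrix"), folds >= 2)
  plants <- unique(data.frame(plant = features$plant,
                              species = as.character(features$y),
                              stringsAsFactors = FALSE))
  min_plants <- min(table(plants$species))
  if (min_plants < folds) {
    warning("a species has only ", min_plants, " plants; reducing folds to ",
            min_plants, call. = FALSE)
    folds <- min_plants
  }
  set.seed(seed)
  fold_of_plant <- integer(0)
  for (ids in split(plants$plant, plants$species)) {
    fold_of_plant[ids] <- rep_len(sample(folds),
                                  length(ids))[sample(length(ids))]
  }
  fold <- fold_of_plant[features$plant]
  scores <- matrix(NA_real_, length(grid), folds)
  for (gi in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      mdl <- train_classifier(features$x[tr, , drop = FALSE], algorithm,
                              y = features$y[tr], hyperparams = grid[[gi]],
                              seed = seed)
      pred <- stats::predict(mdl, features$x[!tr, , drop = FALSE],
                             type = "class")
      scores[gi, f] <- mean(as.character(pred) ==
                              as.character(features$y[!tr]))
    }
  }
  best <- which.max(rowMeans(scores))
  list(best = grid[[best]], best_index = best, fold_scores = scores,
       fold_of_plant = fold_of_plant)
}
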