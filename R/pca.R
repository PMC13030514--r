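#' Pixel-level principal component analysis
#'
#' PCA of pixel spectra on the mean-centred, unscaled covariance (reflectance
#' % units are homogeneous across bands, so no correlation scaling). The
#' total variance (trace of the covariance over *all* bands) is recorded so
#' explained-variance percentages stay well defined when only `k` components
#' are retained. Loadings follow a fixed sign convention — each column's
#' largest-magnitude element is made positive — so scores are reproducible
#' across runs and libraries.
#'
#' @param pixels Numeric `n x bands` matrix of pixel spectra.
#' @param k Number of components to retain (default 6).
#' @return A `pixel_pca` object: `mean_spectrum`, `loadings` (bands x k,
#'   orthonormal columns), `eigenvalues` (non-increasing), `scores`
#'   (n x k, zero mean per column), `total_variance`, `k`, `n`.
#' @export
fit_pixel_pca <- function(pixels, k = 6) {
  x <- as.matrix(pixels)
  n <- nrow(x); p <- ncol(x)
  if (k > min(n, p))
    stop("k = ", k, " exceeds min(n, bands) = ", min(n, p), call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  eig <- sv$d^2 / (n - 1)
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  scores <- xc %*% v
  structure(list(mean_spectrum = mu, loadings = v,
                 eigenvalues = eig[seq_len(k)], scores = scores,
                 total_variance = sum(eig), k = k, n = n),
            class = "pixel_pca")
}

#' @export
print.pixel_pca <- function(x, ...) {
  cat("<pixel_pca> ", x$n, " pixels, ", nrow(x$loadings), " bands, k = ",
      x$k, "\n  explained %: ",
      paste(sprintf("%.2f", explained_variance(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-component explained variance (%)
#'
#' For a fitted [fit_pixel_pca()] model, each retained eigenvalue as a
#' percentage of the total variance over all bands. A bare numeric vector is
#' treated as eigenvalues, normalised by `total_variance` (default: their
#' sum).
#'
#' @param x A `pixel_pca` model or numeric eigenvalue vector.
#' @param total_variance Total variance used as denominator for numeric input.
#' @return Numeric vector of percentages in \[0, 100\], non-increasing.
#' @examples
#' explained_variance(c(0.817, 0.092), total_variance = 1)  # 81.7 9.2
#' @export
explained_variance <- function(x, total_variance = NULL) {
  if (inherits(x, "pixel_pca")) {
    ev <- x$eigenvalues
    tot <- x$total_variance
  } else {
    ev <- as.numeric(x)
    tot <- if (is.null(total_variance)) sum(ev) else total_variance
  }
  100 * ev / tot
}

#' Cumulative explained variance (%)
#'
#' Sum of per-component explained variance up to component `k`. For a fitted
#' model the percentages come from [explained_variance()]; a bare numeric
#' vector is taken to already hold per-component explained percentages (as
#' printed in variance-accounting tables). `k = 0` returns 0 by convention.
#'
#' @param x A `pixel_pca` model or numeric vector of per-component explained
#'   percentages.
#' @param k Component count.
#' @return Cumulative percentage.
#' @examples
#' cumulative_variance(c(81.71, 9.2), 2)  # 90.91
#' @export
cumulative_variance <- function(x, k) {
  if (k == 0) return(0)
  expl <- if (inherits(x, "pixel_pca")) explained_variance(x) else
    as.numeric(x)
  if (k > length(expl))
    stop("k = ", k, " exceeds the ", length(expl),
         " components with recorded variance", call. = FALSE)
  sum(expl[seq_len(k)])
}

#' Score scatter with point density
#'
#' Returns the (t1, t2) score pair of every pixel together with a point
#' density estimated by a 100 x 100 2-D histogram on the score plane
#' (display-only; feeds density-coloured scatter plots).
#'
#' @param model A `pixel_pca` with `k >= 2`.
#' @param grid Histogram grid size per axis.
#' @return data.frame with columns `t1`, `t2`, `density` (one row per pixel).
#' @export
variance_scatter <- function(model, grid = 100) {
  stopifnot(inherits(model, "pixel_pca"))
  if (model$k < 2)
    stop("variance scatter needs a model with at least 2 components",
         call. = FALSE)
  t1 <- model$scores[, 1]; t2 <- model$scores[, 2]
  bx <- .scatter_bin(t1, grid); by <- .scatter_bin(t2, grid)
  counts <- table(factor(bx, levels = seq_len(grid)),
                  factor(by, levels = seq_len(grid)))
  data.frame(t1 = t1, t2 = t2,
             density = as.numeric(counts[cbind(bx, by)]))
}

.scatter_bin <- function(x, grid) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  pmin(pmax(findInterval(x, seq(rng[1], rng[2], length.out = grid + 1),
                         rightmost.closed = TRUE), 1L), grid)
}

#' Pool cohort pixels for PCA
#'
#' Stacks the pixel spectra of a cohort (optionally restricted to one
#' species) into one matrix, sub-sampling at most `max_pixels` pixels for
#' tractability.
#'
#' @param cohort A `weed_cohort`.
#' @param species Optional species filter.
#' @param max_pixels Cap on pooled pixels.
#' @param seed Seed for the sub-sample draw.
#' @return Numeric pixel-by-band matrix.
#' @export
cohort_pixels <- function(cohort, species = NULL, max_pixels = 20000,
                          seed = 1) {
  rois <- cohort$rois
  if (!is.null(species))
    rois <- Filter(function(r) r$species %in% species, rois)
  mats <- lapply(rois, `[[`, "spectra")
  x <- do.call(rbind, mats)
  if (nrow(x) > max_pixels) {
    set.seed(seed)
    x <- x[sample.int(nrow(x), max_pixels), , drop = FALSE]
  }
  x
}
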