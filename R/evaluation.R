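#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Class set (default: union of observed labels); labels
#'   outside it are an error.
#' @return `length(classes)` square count matrix, rows = true classes.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  table(factor(y_true, levels = classes),
        factor(y_pred, levels = classes))
}

#' Per-class precision, recall and F1 (%)
#'
#' From a confusion matrix: `P = 100 * TP / (TP + FP)`,
#' `R = 100 * TP / (TP + FN)`, `F1 = 2 P R / (P + R)`. A class with no
#' predicted and/or no true samples gets 0 for the undefined quantities and
#' is flagged in the `undefined` column rather than dropped, so macro
#' averages stay well defined.
#'
#' @param confusion Square count matrix (rows = true classes).
#' @return data.frame: `class`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `undefined`.
#' @export
precision_recall_f1 <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- ifelse(p_def, 100 * tp / (tp + fp), 0)
  recall <- ifelse(r_def, 100 * tp / (tp + fn), 0)
  f1 <- f1_score(precision, recall)
  data.frame(class = rownames(cm), tp = as.numeric(tp), fp = as.numeric(fp),
             fn = as.numeric(fn), precision = precision, recall = recall,
             f1 = f1, undefined = !(p_def & r_def),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)` (0 when both are 0); vectorised, same
#' scale (%) as its inputs.
#'
#' @param precision,recall Numeric vectors (%).
#' @return Numeric vector.
#' @examples
#' f1_score(93.5, 95.6)  # 94.5 (to one decimal)
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Multiclass log loss (nats)
#'
#' `-mean(log p(true class))` with probabilities clipped to
#' \[1e-15, 1\]. Rows must sum to 1 within 1e-6.
#'
#' @param probabilities `n x classes` matrix with column names.
#' @param y_true True labels.
#' @param classes Class order (default: probability column names).
#' @return Log loss in nats.
#' @export
log_loss <- function(probabilities, y_true, classes = colnames(probabilities)) {
  p <- as.matrix(probabilities)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("probability rows must sum to 1", call. = FALSE)
  j <- match(as.character(y_true), classes)
  if (anyNA(j)) stop("y_true contains labels outside the class set",
                     call. = FALSE)
  pt <- pmin(pmax(p[cbind(seq_len(nrow(p)), j)], 1e-15), 1)
  -mean(log(pt))
}

#' Log-loss reduction over the class-prior baseline
#'
#' `1 - model_ll / prior_ll`, where `prior_ll` is the log loss of the
#' constant predictor emitting the training class frequencies. 1 means
#' perfect probabilities, 0 matches the baseline, negative values mean
#' worse-than-baseline probabilistic predictions.
#'
#' @param model_ll,prior_ll Log losses (nats).
#' @return Unitless reduction.
#' @export
log_loss_reduction <- function(model_ll, prior_ll) {
  1 - model_ll / prior_ll
}

#' Full evaluation report for one classifier
#'
#' Derives hard predictions from the probability matrix (row argmax),
#' tabulates the confusion matrix and per-class precision/recall/F1, and
#' computes overall accuracy (%), macro accuracy (unweighted mean per-class
#' recall, as a fraction), micro accuracy (trace/total, identical to overall
#' accuracy for single-label data — asserted), log loss and log-loss
#' reduction against the training-prior baseline.
#'
#' @param y_true True labels.
#' @param probabilities `n x classes` probability matrix (column names =
#'   classes).
#' @param priors Training class frequencies for the baseline predictor, in
#'   column order; default: empirical frequencies of `y_true`.
#' @param algorithm Optional algorithm id carried into the report.
#' @return An `evaluation_report` list.
#' @export
evaluation_report <- function(y_true, probabilities, priors = NULL,
                              algorithm = NA_character_) {
  classes <- colnames(probabilities)
  y_pred <- classes[max.col(as.matrix(probabilities), ties.method = "first")]
  cm <- confusion_matrix(y_true, y_pred, classes)
  prf <- precision_recall_f1(cm)
  n <- length(y_true)
  overall <- 100 * sum(diag(cm)) / n
  micro <- sum(diag(cm)) / n
  stopifnot(isTRUE(all.equal(overall / 100, micro)))
  if (is.null(priors)) {
    priors <- as.numeric(table(factor(y_true, levels = classes))) / n
  }
  prior_prob <- matrix(priors, n, length(classes), byrow = TRUE,
                       dimnames = list(NULL, classes))
  ll <- log_loss(probabilities, y_true, classes)
  prior_ll <- log_loss(prior_prob, y_true, classes)
  structure(list(algorithm = algorithm, confusion = cm, per_class = prf,
                 accuracy = overall,
                 macro_accuracy = mean(prf$recall) / 100,
                 micro_accuracy = micro, log_loss = ll,
                 log_loss_reduction = log_loss_reduction(ll, prior_ll),
                 prior_log_loss = prior_ll, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", if (!is.na(x$algorithm))
    paste0(x$algorithm, ", "), x$n, " samples\n",
      sprintf("  accuracy %.1f%%  macro %.2f  micro %.2f  log loss %.3f  ",
              x$accuracy, x$macro_accuracy, x$micro_accuracy, x$log_loss),
      sprintf("log-loss reduction %.3f\n", x$log_loss_reduction), sep = "")
  invisible(x)
}

#' Rank evaluation reports
#'
#' Deterministic comparison table: reports sorted by overall accuracy
#' (descending), ties broken by ascending log loss. Input order does not
#' affect the ranking.
#'
#' @param reports List of `evaluation_report`s (named or carrying
#'   `algorithm`).
#' @return data.frame: `algorithm`, `accuracy`, `macro_accuracy`,
#'   `micro_accuracy`, `log_loss`, `log_loss_reduction`, ranked.
#' @export
compare_report <- function(reports) {
  stopifnot(length(reports) >= 1)
  nm <- names(reports)
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(algorithm = if (!is.null(nm) && nzchar(nm[i])) nm[i] else
      r$algorithm, accuracy = r$accuracy,
      macro_accuracy = r$macro_accuracy, micro_accuracy = r$micro_accuracy,
      log_loss = r$log_loss, log_loss_reduction = r$log_loss_reduction,
      stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$accuracy, tab$log_loss, tab$algorithm), ]
  rownames(tab) <- NULL
  tab
}
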