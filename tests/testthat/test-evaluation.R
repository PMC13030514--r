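test_that("confusion matrices tally hand-built cases", {
  y_true <- c("a", "a", "b", "b", "b", "c")
  y_pred <- c("a", "b", "b", "b", "c", "c")
  cm <- confusion_matrix(y_true, y_pred, classes = c("a", "b", "c"))
  expect_equal(as.numeric(cm), c(1, 0, 0, 1, 2, 0, 0, 1, 1))
  # perfect predictions: diagonal; single predicted class: one column
  perfect <- confusion_matrix(y_true, y_true, c("a", "b", "c"))
  expect_equal(sum(diag(perfect)), 6)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  all_a <- confusion_matrix(y_true, rep("a", 6), c("a", "b", "c"))
  expect_true(all(all_a[, c("b", "c")] == 0))
  expect_error(confusion_matrix(y_true, c(y_pred[-6], "z"), c("a", "b", "c")),
               "unknown label")
  expect_error(confusion_matrix(y_true, y_pred[-1]), "equal length")
})

test_that("precision/recall/F1 match a brute-force tally on random labels", {
  set.seed(40)
  for (rep in 1:5) {
    classes <- c("u", "v", "w")
    y_true <- sample(classes, 60, replace = TRUE)
    y_pred <- sample(classes, 60, replace = TRUE)
    prf <- precision_recall_f1(confusion_matrix(y_true, y_pred, classes))
    for (cl in classes) {
      tp <- sum(y_true == cl & y_pred == cl)
      fp <- sum(y_true != cl & y_pred == cl)
      fn <- sum(y_true == cl & y_pred != cl)
      row <- prf[prf$class == cl, ]
      expect_equal(row$tp, tp)
      p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
      r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
      expect_equal(row$precision, p)
      expect_equal(row$recall, r)
      expect_equal(row$f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
    }
  }
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1_score(93.5, 95.6), 1), 94.5)
  expect_equal(f1_score(100, 100), 100)
  expect_equal(f1_score(0, 80), 0)
})

test_that("degenerate classes are flagged, not dropped", {
  cm <- matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  prf <- precision_recall_f1(cm)
  expect_true(all(prf$undefined[2:3]))
  expect_false(prf$undefined[1])
  expect_equal(nrow(prf), 3)
})

test_that("log loss and its reduction behave at the reference points", {
  classes <- c("a", "b")
  y <- c("a", "b", "a")
  onehot <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE,
                   dimnames = list(NULL, classes))
  expect_equal(log_loss(onehot, y), 0, tolerance = 1e-10)
  expect_equal(log_loss_reduction(0, 0.6), 1)
  prior <- matrix(c(2 / 3, 1 / 3), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, classes))
  pll <- log_loss(prior, y)
  expect_equal(log_loss_reduction(pll, pll), 0)
  # a model worse than the prior goes negative (confidently wrong)
  wrong <- matrix(c(0.1, 0.9, 0.9, 0.1, 0.1, 0.9), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, classes))
  expect_lt(log_loss_reduction(log_loss(wrong, y), pll), 0)
  expect_error(log_loss(matrix(c(0.5, 0.2), 1), "a", classes), "sum to 1")
})

test_that("evaluation reports satisfy the accuracy identities", {
  set.seed(41)
  classes <- letters[1:4]
  y <- sample(classes, 80, replace = TRUE)
  prob <- matrix(runif(80 * 4), 80, 4, dimnames = list(NULL, classes))
  prob <- prob / rowSums(prob)
  rep <- evaluation_report(y, prob)
  expect_equal(rep$micro_accuracy, sum(diag(rep$confusion)) / 80)
  expect_equal(rep$accuracy / 100, rep$micro_accuracy)
  expect_equal(rep$macro_accuracy, mean(rep$per_class$recall) / 100)
  # per-class F1 is the harmonic mean of that class's P and R
  expect_equal(rep$per_class$f1,
               f1_score(rep$per_class$precision, rep$per_class$recall))
  expect_equal(sum(rep$confusion), 80)
})

test_that("report comparison ranks by accuracy then log loss, stably", {
  mk <- function(acc, ll, algo) {
    structure(list(algorithm = algo, accuracy = acc, macro_accuracy = acc / 100,
                   micro_accuracy = acc / 100, log_loss = ll,
                   log_loss_reduction = 0.1), class = "evaluation_report")
  }
  a <- mk(93.5, 0.5, "rf"); b <- mk(63.7, 2.37, "maxent")
  cmp <- compare_report(list(rf = a, maxent = b))
  expect_equal(cmp$algorithm, c("rf", "maxent"))
  cmp2 <- compare_report(list(maxent = b, rf = a))
  expect_equal(cmp2$algorithm, c("rf", "maxent"))
  # tie on accuracy: lower log loss first
  c1 <- mk(80, 1.5, "svm"); c2 <- mk(80, 0.7, "nn")
  expect_equal(compare_report(list(c1, c2))$algorithm, c("nn", "svm"))
  single <- compare_report(list(rf = a))
  expect_equal(nrow(single), 1)
})
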