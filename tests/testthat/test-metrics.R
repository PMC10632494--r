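test_that("confusion matrix counts true/predicted pairs", {
  perfect <- confusionMatrix(rep(c("A", "B", "C"), each = 4),
                             rep(c("A", "B", "C"), each = 4),
                             c("A", "B", "C"))
  expect_equal(unname(perfect), diag(c(4L, 4L, 4L)), ignore_attr = TRUE)

  empty <- confusionMatrix(character(0), character(0), c("A", "B"))
  expect_true(all(empty == 0L))

  m <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(m), matrix(c(1L, 0L, 1L, 1L), 2, 2))

  expect_error(confusionMatrix(c("A"), c("A", "B"), c("A", "B")), "length")
  expect_error(confusionMatrix(c("A"), c("Z"), c("A", "B")), "vocabulary")
})

test_that("binary metrics reproduce hand-substituted values", {
  perfect <- binaryMetrics(confusionCounts(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1, f1 = 1))

  bm <- binaryMetrics(confusionCounts(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(bm$accuracy, 0.85)
  expect_equal(bm$sensitivity, 0.9)
  expect_equal(bm$specificity, 0.8)
  expect_equal(bm$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(bm$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9), tolerance = 1e-12)
  expect_equal(bm$f1, 0.8571, tolerance = 1e-4)
  expect_false(any(bm$degenerate))

  # zero-denominator convention: 0 with a flag
  deg <- binaryMetrics(confusionCounts(tp = 0, fp = 0, fn = 5, tn = 5))
  expect_equal(deg$precision, 0)
  expect_equal(deg$sensitivity, 0)
  expect_true(deg$degenerate[["precision"]])
  expect_false(deg$degenerate[["sensitivity"]])  # 0/5 is defined

  expect_error(binaryMetrics(confusionCounts(0, 0, 0, 0)), "all-zero")
})

test_that("one-vs-rest extraction matches hand counts", {
  m <- confusionMatrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  cc <- oneVsRestCounts(m, 1)
  expect_identical(c(cc@tp, cc@fn, cc@fp, cc@tn), c(1L, 1L, 0L, 1L))
})

test_that("multiclass report macro-averages one-vs-rest metrics", {
  classes <- c("A", "B", "C")
  perfect <- multiclassReport(diag(c(4L, 4L, 4L)), classes)
  expect_equal(unname(macroMetrics(perfect)), rep(1, 5))

  expect_error(multiclassReport(matrix(0L, 2, 3), c("A", "B")), "square")

  # permutation invariance of the macro metrics
  set.seed(31)
  truth <- sample(classes, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(classes, 60, replace = TRUE))
  r1 <- evaluatePredictions(truth, pred, classes)
  perm <- c("C", "A", "B")
  r2 <- evaluatePredictions(truth, pred, perm)
  expect_equal(macroMetrics(r1), macroMetrics(r2))

  # conservation: per-class counts always sum to the sample count
  pc <- perClassMetrics(r1)
  expect_true(all(pc$tp + pc$fp + pc$tn + pc$fn == 60L))
  # F1 identity per class
  withP <- pc$precision + pc$sensitivity
  f1ref <- ifelse(withP == 0, 0, 2 * pc$precision * pc$sensitivity / withP)
  expect_equal(pc$f1, f1ref, tolerance = 1e-12)
})

test_that("report agrees with a brute-force metric loop on random labelings", {
  classes <- c("x", "y", "z")
  set.seed(77)
  for (t in 1:100) {
    n <- sample(5:30, 1)
    truth <- sample(classes, n, replace = TRUE)
    truth[1:3] <- classes            # ensure every class occurs
    pred <- sample(classes, n, replace = TRUE)
    rep <- evaluatePredictions(truth, pred, classes)
    # brute force: loop over classes and samples
    accs <- sens <- specs <- precs <- f1s <- numeric(3)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      tp <- sum(truth == cl & pred == cl); fn <- sum(truth == cl & pred != cl)
      fp <- sum(truth != cl & pred == cl); tn <- sum(truth != cl & pred != cl)
      accs[ci] <- (tp + tn) / n
      sens[ci] <- if (tp + fn > 0) tp / (tp + fn) else 0
      specs[ci] <- if (tn + fp > 0) tn / (tn + fp) else 0
      precs[ci] <- if (tp + fp > 0) tp / (tp + fp) else 0
      f1s[ci] <- if (precs[ci] + sens[ci] > 0)
        2 * precs[ci] * sens[ci] / (precs[ci] + sens[ci]) else 0
    }
    expect_equal(unname(macroMetrics(rep)),
                 c(mean(accs), mean(sens), mean(specs), mean(precs), mean(f1s)),
                 tolerance = 1e-12)
    expect_equal(sum(confusion(rep)), n)
  }
})
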