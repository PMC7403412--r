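test_that("stratified splitting reproduces the 70/30 arithmetic", {
  sp <- split_dataset(c(a = 10L), split_spec(train_fraction = 0.5, seed = 2))
  expect_length(sp$train, 5)
  expect_length(sp$test, 5)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:10)
  # determinism and seed dependence
  sp2 <- split_dataset(c(a = 10L), split_spec(train_fraction = 0.5, seed = 2))
  expect_identical(sp, sp2)
  sp3 <- split_dataset(c(a = 10L), split_spec(train_fraction = 0.5, seed = 3))
  expect_false(identical(sp$test, sp3$test))
  # stratification: per-class counts follow the round rule
  labels <- factor(rep(c("w", "x", "y", "z"), times = c(11, 23, 37, 10)))
  s <- split_dataset(labels, split_spec(seed = 1))
  expect_equal(as.vector(table(labels[s$test])), round(0.3 * c(11, 23, 37, 10)))
  expect_error(split_dataset(c(a = 3L), split_spec(train_fraction = 0.99)),
               "empty partition")
})

test_that("confusion matrices have truth on rows and correct marginals", {
  truth <- factor(rep(CLASS_LEVELS <- c("normal", "ethanol", "h2o2", "cryo"),
                      times = c(3, 2, 2, 1)), levels = CLASS_LEVELS)
  pred <- truth
  pred[1] <- "cryo"
  cm <- confusion_matrix(truth, pred)
  expect_equal(rowSums(cm), c(normal = 3, ethanol = 2, h2o2 = 2, cryo = 1))
  expect_equal(sum(cm), 8)
  expect_equal(cm["normal", "cryo"], 1)
})

test_that("confusion metrics reproduce the one-vs-rest definitions", {
  # a 720-cell class with 525 correct and 13/103/79 mispredictions
  m <- matrix(c(525, 13, 103, 79,
                20, 600, 60, 40,
                30, 25, 640, 25,
                10, 15, 20, 675), 4, 4, byrow = TRUE)
  rownames(m) <- colnames(m) <- c("normal", "ethanol", "h2o2", "cryo")
  met <- confusion_metrics(m)
  expect_equal(met$per_class$sensitivity[1], 525 / 720, tolerance = 1e-12)
  expect_equal(met$per_class$specificity[1],
               (sum(m) - 720 - sum(m[-1, 1])) / (sum(m) - 720))
  expect_equal(met$overall_accuracy, sum(diag(m)) / sum(m))
  # identity matrix: everything perfect
  ident <- diag(720, 4)
  mi <- confusion_metrics(ident)
  expect_true(all(abs(unlist(mi$macro) - 1) < 1e-12))
  expect_equal(mi$overall_accuracy, 1)
  # uniform matrix: chance-level sensitivity
  mu <- confusion_metrics(matrix(10, 4, 4))
  expect_true(all(abs(mu$per_class$sensitivity - 0.25) < 1e-12))
  # zero-row class is flagged and excluded from the macro average
  m0 <- m
  m0[2, ] <- 0
  mz <- confusion_metrics(m0)
  expect_true(is.nan(mz$per_class$sensitivity[2]))
  expect_equal(mz$undefined, "ethanol")
  expect_false(is.nan(mz$macro[["sensitivity"]]))
})

test_that("classical training is deterministic and evaluates on the test split", {
  ft <- feature_table_of(1.0, n_per_class = 50L, seed = 11L)
  labels <- ft$label
  for (model in c("svm", "naive_bayes", "knn")) {
    r1 <- train_classical(ft[, 1:11], labels, model, split_spec(seed = 5))
    r2 <- train_classical(ft[, 1:11], labels, model, split_spec(seed = 5))
    expect_identical(r1$confusion, r2$confusion)
    expect_equal(sum(r1$confusion), length(r1$split$test))
    expect_equal(as.vector(rowSums(r1$confusion)),
                 as.vector(table(labels[r1$split$test])))
  }
  few <- c(1:5, 51:55, 101:105, 151:155)   # 5 per class
  expect_error(train_classical(ft[few, 1:11], labels[few], "svm"),
               ">= 10 samples")
})

test_that("separable classes are learned and accuracy rises with effect size", {
  accs <- vapply(c(0, 1), function(e) {
    ft <- feature_table_of(e, n_per_class = 50L, seed = 13L)
    train_classical(ft[, 1:11], ft$label, "svm",
                    split_spec(seed = 7))$accuracy
  }, numeric(1))
  expect_gt(accs[2], 0.85)
  expect_gt(accs[2], accs[1])
  expect_lt(accs[1], 0.5)
})
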