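#' Specification of the stratified train/test split
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.7, the protocol's 70/30 split).
#' @param stratified draw the split per class (always TRUE here).
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Stratified train/test split
#'
#' Per class, the test count is `round((1 - train_fraction) * n)` and the
#' remainder trains — with 2,400 images per class at 70/30 this reproduces
#' 720 test images per class, 2,880 in total. The split is exhaustive,
#' disjoint, and deterministic given the seed.
#'
#' @param labels factor of class labels, or a (named) integer vector of
#'   per-class counts.
#' @param spec a [split_spec()].
#' @return list with integer index vectors `train` and `test` (indices into
#'   the label vector, classes in their order of appearance).
#' @export
split_dataset <- function(labels, spec = split_spec()) {
  if (is.numeric(labels)) {
    nm <- if (!is.null(names(labels))) names(labels) else
      paste0("class", seq_along(labels))
    labels <- factor(rep(nm, labels), levels = nm)
  }
  labels <- as.factor(labels)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 samples")
  test <- with_seed(spec$seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      n_test <- round((1 - spec$train_fraction) * length(idx))
      if (n_test == 0L || n_test == length(idx)) {
        stop("train_fraction produces an empty partition for class ", cl)
      }
      sort(sample(idx, n_test))
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Confusion matrix with rows as ground truth
#'
#' @param truth,predicted factors over the same class levels.
#' @param levels class order; defaults to (normal, ethanol, h2o2, cryo).
#' @return square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = CLASS_LEVELS) {
  t1 <- factor(truth, levels = levels)
  p1 <- factor(predicted, levels = levels)
  unclass(table(truth = t1, predicted = p1))
}

#' Per-class sensitivity, specificity and accuracy from a confusion matrix
#'
#' One-vs-rest metrics: `sensitivity = TP / (TP + FN)` (row sum),
#' `specificity = TN / (TN + FP)`, `accuracy = (TP + TN) / total`; macro
#' values are unweighted means over classes. A class with zero true
#' instances has undefined sensitivity: it is reported as `NaN`, flagged,
#' and excluded from the macro average.
#'
#' @param matrix square confusion matrix, rows = truth.
#' @return list with `per_class` (data frame), `macro` (named vector),
#'   `overall_accuracy` (trace / total) and `undefined` (classes with no
#'   true instances).
#' @export
confusion_metrics <- function(matrix) {
  stopifnot(nrow(matrix) == ncol(matrix), all(matrix >= 0))
  total <- sum(matrix)
  k <- nrow(matrix)
  tp <- diag(matrix)
  fn <- rowSums(matrix) - tp
  fp <- colSums(matrix) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NaN)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / total
  per_class <- data.frame(class = rownames(matrix) %||% paste0("c", 1:k),
                          sensitivity = sens, specificity = spec,
                          accuracy = acc, row.names = NULL)
  list(per_class = per_class,
       macro = c(sensitivity = mean(sens[is.finite(sens)]),
                 specificity = mean(spec), accuracy = mean(acc)),
       overall_accuracy = sum(tp) / total,
       undefined = per_class$class[!is.finite(sens)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a classical classifier on the 11-feature representation
#'
#' Fits one of the three feature-based baselines — RBF-kernel SVM, Gaussian
#' naive Bayes, or kNN (k = 5) — on the training split of z-scored features
#' and evaluates the confusion matrix on the held-out test split.
#'
#' @param features data frame or matrix of feature columns (rows = images).
#' @param labels factor of class labels.
#' @param model `"svm"`, `"naive_bayes"` or `"knn"`.
#' @param spec a [split_spec()].
#' @param k neighbours for kNN.
#' @return list with the fitted `model`, `confusion` matrix (rows = truth),
#'   `metrics` from [confusion_metrics()], `accuracy`, and the `split`.
#' @export
train_classical <- function(features, labels,
                            model = c("svm", "naive_bayes", "knn"),
                            spec = split_spec(), k = 5L) {
  model <- match.arg(model)
  labels <- droplevels(as.factor(labels))
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(table(labels) < 10L)) stop("need >= 10 samples per class")
  split <- split_dataset(labels, spec)
  if (nlevels(droplevels(labels[split$train])) < nlevels(labels)) {
    stop("training split lost a class")
  }
  mu <- colMeans(x[split$train, , drop = FALSE])
  sig <- apply(x[split$train, , drop = FALSE], 2, sd)
  sig[sig == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sig, "/")
  xtr <- xs[split$train, , drop = FALSE]
  xte <- xs[split$test, , drop = FALSE]
  ytr <- labels[split$train]
  fit_pred <- with_seed(spec$seed, switch(model,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = FALSE)
      list(fit = fit, pred = predict(fit, xte))
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      list(fit = fit, pred = predict(fit, xte))
    },
    knn = {
      pred <- class::knn(xtr, xte, ytr, k = k)
      list(fit = list(k = k, train = xtr, cl = ytr), pred = pred)
    }))
  cm <- confusion_matrix(labels[split$test], fit_pred$pred,
                         levels = levels(labels))
  list(model = fit_pred$fit, confusion = cm, metrics = confusion_metrics(cm),
       accuracy = sum(diag(cm)) / sum(cm), split = split,
       scaling = list(center = mu, scale = sig))
}
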