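#' Restrict a feature table to a binary task
#'
#' The study's questions are pairwise: primed anger vs the neutral baseline,
#' primed happiness vs its baseline, and anger vs happiness. This keeps only
#' the instances of two labels. Records from different cameras are analyzed
#' separately by default, since the two sensors are treated as independent
#' measurement devices.
#'
#' @param table A [feature_table].
#' @param label_a,label_b The two class labels (must differ and both be
#'   present).
#' @param camera_id If non-`NULL`, restrict to this camera first.
#' @return A [feature_table] with exactly two classes.
#' @export
make_binary_task <- function(table, label_a, label_b, camera_id = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (identical(label_a, label_b))
    stop("the two task labels must differ", call. = FALSE)
  keep <- table$labels %in% c(label_a, label_b)
  if (!is.null(camera_id)) keep <- keep & table$ids$camera_id == camera_id
  for (lab in c(label_a, label_b))
    if (!any(table$labels[keep] == lab))
      stop("label not present in table: ", lab, call. = FALSE)
  feature_table(table$values[keep, , drop = FALSE],
                table$ids[keep, , drop = FALSE],
                table$labels[keep])
}

classifier_names <- c("naive_bayes", "random_forest", "svm_rbf", "svm_linear")

fit_classifier <- function(name, x, y) {
  y <- factor(y)
  switch(name,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y),
    random_forest = randomForest::randomForest(x = x, y = y, ntree = 100L),
    svm_rbf = e1071::svm(x = x, y = y, kernel = "radial", cost = 1,
                         gamma = 1 / ncol(x), scale = FALSE),
    svm_linear = e1071::svm(x = x, y = y, kernel = "linear", cost = 1,
                            scale = FALSE),
    stop("unknown classifier: ", name,
         " (expected one of ", paste(classifier_names, collapse = ", "), ")",
         call. = FALSE))
}

predict_classifier <- function(name, model, x) {
  newdata <- if (name == "naive_bayes") as.data.frame(x) else x
  as.character(stats::predict(model, newdata))
}

# deterministic stratified fold assignment. Subjects with instances in both
# classes are dealt whole to folds (their records never straddle train/test,
# preventing subject-identity leakage in within-subject designs); remaining
# instances are shuffled within class and dealt round-robin. Both routes keep
# the folds class-balanced.
stratified_folds <- function(labels, k, subjects = NULL) {
  fold <- integer(length(labels))
  assigned <- rep(FALSE, length(labels))
  if (!is.null(subjects)) {
    multi <- names(which(tapply(labels, subjects,
                                function(l) length(unique(l)) > 1L)))
    if (length(multi)) {
      multi <- multi[sample.int(length(multi))]
      for (i in seq_along(multi)) {
        idx <- which(subjects == multi[i])
        fold[idx] <- (i - 1L) %% k + 1L
        assigned[idx] <- TRUE
      }
    }
  }
  for (lab in unique(labels)) {
    idx <- which(labels == lab & !assigned)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated classifier evaluation
#'
#' Evaluates one classifier on a binary task under seeded stratified k-fold
#' cross-validation. Fold assignment is subject-grouped: in within-subject
#' designs (the same subject walking under both conditions), a subject's
#' records are dealt to one fold together, so a classifier can never exploit
#' subject identity across the train/test boundary; this keeps folds
#' class-balanced because such subjects contribute one record per class.
#' Within each fold, z-score normalization and PCA are fit
#' on the training portion only (leakage-safe default) and applied to the
#' held-out portion before classifier fitting and prediction;
#' `global_fit = TRUE` instead fits normalization and PCA once on the whole
#' table before splitting. Accuracy is the pooled proportion of correctly
#' classified held-out instances over all folds.
#'
#' @param task A two-class [feature_table] (from [make_binary_task()]).
#' @param classifier One of `"naive_bayes"` (Gaussian naive Bayes),
#'   `"random_forest"` (100 trees), `"svm_rbf"` (RBF kernel, C = 1,
#'   gamma = 1/n_features) or `"svm_linear"` (linear kernel, C = 1).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold split and any classifier
#'   randomness; identical inputs and seed give an identical report.
#' @param variance_threshold PCA explained-variance threshold.
#' @param global_fit Fit normalization/PCA on the full table before CV.
#' @return A `cv_report` with the task labels, classifier name, per-fold
#'   accuracies, pooled accuracy, 2 x 2 confusion matrix (rows = truth,
#'   columns = predicted) and the seed.
#' @export
cross_validate <- function(task, classifier = classifier_names, k = 10L,
                           seed = 1L, variance_threshold = 0.95,
                           global_fit = FALSE) {
  stopifnot(inherits(task, "feature_table"))
  classifier <- match.arg(classifier)
  labels <- task$labels
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("task must have exactly 2 classes, got ", length(classes),
         call. = FALSE)
  if (min(table(labels)) < k)
    stop("each class needs at least k = ", k, " instances for stratified ",
         k, "-fold CV", call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(labels, k, subjects = task$ids$subject_id)
  if (global_fit) {
    zs <- zscore_fit(task)
    pm <- pca_fit(zscore_apply(task, zs), variance_threshold)
  }
  pred <- character(length(labels))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    train <- feature_table(task$values[tr_idx, , drop = FALSE],
                           task$ids[tr_idx, , drop = FALSE],
                           labels[tr_idx])
    test <- feature_table(task$values[te_idx, , drop = FALSE],
                          task$ids[te_idx, , drop = FALSE],
                          labels[te_idx])
    if (!global_fit) {
      zs <- zscore_fit(train)
      pm <- pca_fit(zscore_apply(train, zs), variance_threshold)
    }
    tr_x <- pca_apply(zscore_apply(train, zs), pm)$values
    te_x <- pca_apply(zscore_apply(test, zs), pm)$values
    model <- fit_classifier(classifier, tr_x, labels[tr_idx])
    pred[te_idx] <- predict_classifier(classifier, model, te_x)
    fold_acc[f] <- mean(pred[te_idx] == labels[te_idx])
  }
  confusion <- table(truth = factor(labels, classes),
                     predicted = factor(pred, classes))
  structure(list(task = classes, classifier = classifier,
                 fold_accuracies = fold_acc,
                 accuracy = mean(pred == labels),
                 confusion = confusion, seed = seed, k = k,
                 n = length(labels)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s vs %s | %s | %d-fold CV (seed %d)\n",
              x$task[1], x$task[2], x$classifier, x$k, x$seed))
  cat(sprintf("  pooled accuracy: %.4f (n = %d)\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Evaluate all classifier families on one task
#'
#' @param task A two-class [feature_table].
#' @param classifiers Character vector of classifier names.
#' @param ... Passed to [cross_validate()].
#' @return Named list of `cv_report` objects.
#' @export
evaluate_task <- function(task, classifiers = classifier_names, ...) {
  stats::setNames(lapply(classifiers, function(cl)
    cross_validate(task, classifier = cl, ...)), classifiers)
}
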