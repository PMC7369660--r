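#' Confusion-matrix metrics for binary predictions
#'
#' Accuracy, precision, sensitivity (recall of the positive class), and
#' specificity, with the malignant class as positive. If a class is absent
#' from the truth vector the metrics that condition on it are reported as
#' `NA` with an `undefined` attribute naming them, rather than dividing by
#' zero.
#'
#' @param y_true,y_pred Vectors of class labels, equal length.
#' @param positive Name of the positive class; defaults to `"malignant"`
#'   when present, otherwise the second factor level.
#' @return Named numeric vector: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, plus `tp`, `fp`, `tn`, `fn` counts.
#' @export
confusion_metrics <- function(y_true, y_pred, positive = NULL) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  lev <- union(levels(factor(y_true)), levels(factor(y_pred)))
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[length(lev)]
  yt <- y_true == positive; yp <- y_pred == positive
  tp <- sum(yt & yp); fn <- sum(yt & !yp)
  fp <- sum(!yt & yp); tn <- sum(!yt & !yp)
  divide <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(accuracy = (tp + tn) / length(yt),
           precision = divide(tp, tp + fp),
           sensitivity = divide(tp, tp + fn),
           specificity = divide(tn, tn + fp),
           tp = tp, fp = fp, tn = tn, fn = fn)
  und <- names(out)[is.na(out)]
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the unique score values (predicting
#' positive when `score >= threshold`) and records the false/true positive
#' rates; the curve runs from (0, 0) to (1, 1) and is nondecreasing in
#' both coordinates. The AUC is the trapezoidal area under this curve,
#' which equals the Mann-Whitney pair statistic (ties counted 1/2).
#'
#' @param y_true Class labels containing both classes.
#' @param scores Real-valued scores, higher = more positive.
#' @param positive Positive class name (default as in
#'   [confusion_metrics()]).
#' @return Object of class `roc_curve`: list with `fpr`, `tpr`,
#'   `thresholds`, and `auc`.
#' @export
roc_curve <- function(y_true, scores, positive = NULL) {
  stopifnot(length(y_true) == length(scores))
  lev <- levels(factor(y_true))
  if (is.null(positive))
    positive <- if ("malignant" %in% lev) "malignant" else lev[length(lev)]
  pos <- y_true == positive
  if (!any(pos) || all(pos)) stop("undefined AUC: need both classes")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / sum(pos), 0)
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / sum(!pos), 0)
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, thr, -Inf), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @rdname roc_curve
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  roc_curve(y_true, scores, positive)$auc
}

# fit one classifier and return class predictions + positive-class scores
train_predict <- function(train, test, classifier, positive) {
  xcols <- setdiff(names(train), "label")
  xtr <- as.matrix(train[xcols]); xte <- as.matrix(test[xcols])
  ytr <- factor(train$label)
  switch(classifier,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial", scale = FALSE)
      pred <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      sc <- dv[, 1]
      # decision values are oriented first-level vs second-level
      if (!startsWith(colnames(dv)[1], positive)) sc <- -sc
      list(pred = as.character(pred), score = sc)
    },
    dt = {
      fit <- rpart::rpart(label ~ ., data = train, method = "class")
      pr <- stats::predict(fit, test, type = "prob")
      sc <- pr[, positive]
      list(pred = colnames(pr)[max.col(pr, ties.method = "first")],
           score = sc)
    },
    knn = {
      pr <- class::knn(xtr, xte, ytr, k = 5, prob = TRUE, use.all = TRUE)
      p <- attr(pr, "prob")
      sc <- ifelse(as.character(pr) == positive, p, 1 - p)
      list(pred = as.character(pr), score = sc)
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr)
      pr <- stats::predict(fit, xte, type = "raw")
      list(pred = colnames(pr)[max.col(pr, ties.method = "first")],
           score = pr[, positive])
    },
    stop("classifier must be one of svm, dt, knn, nb"))
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(factor(labels))) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validation of a texture classifier
#'
#' Evaluates one of four standard classifiers (RBF-kernel SVM, decision
#' tree, k-nearest neighbours with k = 5, Gaussian naive Bayes) on a
#' labelled feature table with stratified k-fold cross-validation.
#' Feature standardization and (optionally) ANOVA feature selection are
#' fitted on each training fold and applied to its test fold, so no test
#' information leaks into the preprocessing; `paper_mode = TRUE` instead
#' fits both once on the full table before splitting. An optional held-out
#' split mode (`holdout = 0.2` for the classical 80:20 protocol) is
#' available via [holdout_evaluate()].
#'
#' @param table Data frame with feature columns and a binary `label`.
#' @param classifier One of `"svm"`, `"dt"`, `"knn"`, `"nb"`.
#' @param folds Number of folds (default 10); automatically reduced (with
#'   a warning) to the smallest class size if that is smaller.
#' @param seed Integer seed controlling fold assignment and any classifier
#'   randomness.
#' @param select_k If non-`NULL`, number of ANOVA-selected features.
#' @param paper_mode Fit normalization/selection on the full table.
#' @param positive Positive class (default `"malignant"` if present).
#' @return Object of class `nslt_eval`: list with `per_fold` (data frame
#'   of per-fold metrics incl. AUC), `mean`, `sd`, pooled `roc` (over the
#'   concatenated out-of-fold scores), `classifier`, `folds`, `n`.
#' @export
cross_validate <- function(table, classifier = c("svm", "dt", "knn", "nb"),
                           folds = 10L, seed = 1L, select_k = NULL,
                           paper_mode = FALSE, positive = NULL) {
  classifier <- match.arg(classifier)
  stopifnot(is.data.frame(table), "label" %in% names(table))
  labels <- factor(table$label)
  if (nlevels(labels) != 2) stop("protocol error: need exactly two classes")
  if (is.null(positive))
    positive <- if ("malignant" %in% levels(labels)) "malignant"
                else levels(labels)[2]
  table$label <- labels
  minclass <- min(table(labels))
  folds <- as.integer(folds)
  if (minclass < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class size)",
                    folds, minclass))
    folds <- minclass
  }
  if (folds < 2) stop("protocol error: need at least 2 folds")
  if (paper_mode) {
    table <- normalize_features(table)
    if (!is.null(select_k)) table <- select_features(table, k = select_k)
  }
  fold_of <- stratified_folds(labels, folds, seed)
  per <- vector("list", folds)
  oof_scores <- numeric(nrow(table)); oof_true <- as.character(labels)
  for (f in seq_len(folds)) {
    tr <- table[fold_of != f, , drop = FALSE]
    te <- table[fold_of == f, , drop = FALSE]
    if (!paper_mode) {
      tr <- normalize_features(tr)
      te <- normalize_features(te, center = attr(tr, "center"),
                               scale = attr(tr, "scale"))
      if (!is.null(select_k)) {
        tr <- select_features(tr, k = select_k)
        te <- te[names(tr)]
      }
    }
    set.seed(seed + f)   # classifier-level randomness, per fold
    res <- train_predict(tr, te, classifier, positive)
    cm <- confusion_metrics(te$label, res$pred, positive)
    auc_f <- if (length(unique(te$label)) == 2)
      roc_auc(te$label, res$score, positive) else NA_real_
    per[[f]] <- c(fold = f, cm[c("accuracy", "precision", "sensitivity",
                                 "specificity")], auc = auc_f)
    oof_scores[fold_of == f] <- res$score
  }
  per <- as.data.frame(do.call(rbind, per))
  mets <- c("accuracy", "precision", "sensitivity", "specificity", "auc")
  structure(list(
    per_fold = per,
    mean = colMeans(per[mets], na.rm = TRUE),
    sd = apply(per[mets], 2, stats::sd, na.rm = TRUE),
    roc = roc_curve(oof_true, oof_scores, positive),
    classifier = classifier, folds = folds, n = nrow(table),
    positive = positive),
    class = "nslt_eval")
}

#' @export
print.nslt_eval <- function(x, ...) {
  cat(sprintf("%s | %d-fold CV on %d samples (positive = %s)\n",
              toupper(x$classifier), x$folds, x$n, x$positive))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  cat(sprintf("  pooled AUC   %.4f\n", x$roc$auc))
  invisible(x)
}

#' Held-out split evaluation
#'
#' Stratified single split (default 80:20), preprocessing fitted on the
#' training part only; complements [cross_validate()].
#'
#' @inheritParams cross_validate
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @return List with `metrics` (confusion metrics), `auc`, `roc`, and the
#'   test indices.
#' @export
holdout_evaluate <- function(table, classifier = c("svm", "dt", "knn", "nb"),
                             test_fraction = 0.2, seed = 1L, select_k = NULL,
                             positive = NULL) {
  classifier <- match.arg(classifier)
  labels <- factor(table$label)
  if (is.null(positive))
    positive <- if ("malignant" %in% levels(labels)) "malignant"
                else levels(labels)[2]
  set.seed(seed)
  te_idx <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(test_fraction * length(idx))))
  }))
  tr <- table[-te_idx, , drop = FALSE]
  te <- table[te_idx, , drop = FALSE]
  tr <- normalize_features(tr)
  te <- normalize_features(te, center = attr(tr, "center"),
                           scale = attr(tr, "scale"))
  if (!is.null(select_k)) {
    tr <- select_features(tr, k = select_k)
    te <- te[names(tr)]
  }
  set.seed(seed + 1L)
  res <- train_predict(tr, te, classifier, positive)
  roc <- roc_curve(te$label, res$score, positive)
  list(metrics = confusion_metrics(te$label, res$pred, positive),
       auc = roc$auc, roc = roc, test_idx = sort(te_idx))
}
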