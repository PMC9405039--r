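#' Confusion counts for +/-1 labels
#'
#' Positive = +1 = disease class. TP/FN count correctly/wrongly classified
#' positives, TN/FP correctly/wrongly classified negatives.
#'
#' @param y_true,y_pred Equal-length vectors with values in \{+1, -1\}.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) {
    stop("labels must be +1 or -1")
  }
  structure(list(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == -1 & y_pred == 1),
    tn = sum(y_true == -1 & y_pred == -1),
    fn = sum(y_true == 1 & y_pred == -1)
  ), class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' acc = (TP+TN)/(TP+TN+FP+FN); sen = TP/(TP+FN), the fraction of disease
#' cases detected; spe = TN/(TN+FP), the fraction of healthy cases cleared.
#' A metric whose denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param cc A [confusion()] result.
#' @return Named numeric vector `c(acc, sen, spe)`.
#' @export
classification_metrics <- function(cc) {
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("no predictions to evaluate")
  c(acc = (cc$tp + cc$tn) / total,
    sen = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    spe = if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_)
}

#' ROC curve and AUC from continuous scores
#'
#' The ROC curve is built by sweeping every distinct score value as a
#' threshold (ties grouped, one vertex per distinct score), giving a
#' deterministic staircase from (0,0) to (1,1); the AUC is its trapezoidal
#' integral, which equals the probability that a random positive outscores a
#' random negative, ties counted one half.
#'
#' @param y_true Labels in \{+1, -1\}; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return List with `roc` (data frame of `fpr`, `tpr`, ordered) and `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("labels and scores differ in length")
  if (!all(y_true %in% c(-1, 1))) stop("labels must be +1 or -1")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == -1)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC is undefined with a single-class truth vector")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  # group tied scores: cumulative counts at the end of each tie group
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(y == 1)[last_of_group]
  cfp <- cumsum(y == -1)[last_of_group]
  tpr <- c(0, ctp / n_pos)
  fpr <- c(0, cfp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Cross-validation plan
#'
#' @param k Fold count (default 10).
#' @param stratified Preserve class proportions per fold (default TRUE)?
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(k = 10, stratified = TRUE, seed = 1) {
  stopifnot(k >= 2)
  structure(list(k = k, stratified = stratified, seed = seed),
            class = "cv_plan")
}

# Fold assignment: a length-n integer vector in 1..k. Stratified assignment
# shuffles within each class and deals round-robin, keeping fold class
# proportions within one instance of the global ones.
assign_folds <- function(y, plan) {
  n <- length(y)
  if (n < plan$k) stop("fewer instances than folds")
  set.seed(plan$seed)
  folds <- integer(n)
  if (plan$stratified) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(plan$k), length(idx))
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(plan$k), n)
  }
  folds
}

#' Stratified k-fold cross-validation of a scoring classifier
#'
#' For each fold, `fit_fn` is trained on the remaining k-1 folds and its
#' predictions and scores on the held-out fold are collected. Confusion
#' counts are pooled over all folds (micro-average) and the headline
#' metrics computed from the pooled counts; per-fold metrics are retained
#' as the macro view. The ROC/AUC is computed once from the pooled
#' out-of-fold scores.
#'
#' @param fit_fn Function taking a training [design_matrix()] and returning
#'   a fitted model for which `predict(model, X, type = "class")` and
#'   `predict(model, X, type = "score")` work (e.g. a partially applied
#'   [fit_adaboost()]).
#' @param dm A [design_matrix()].
#' @param plan A [cv_plan()].
#' @return An object of class `metric_report`: pooled `counts`, `metrics`
#'   (acc/sen/spe), `auc`, `roc` points, `per_fold` data frame, `oof`
#'   (out-of-fold scores/predictions in input order) and the `plan`.
#' @export
cross_validate <- function(fit_fn, dm, plan = cv_plan()) {
  folds <- assign_folds(dm$y, plan)
  n <- length(dm$y)
  oof_score <- numeric(n); oof_pred <- numeric(n)
  per_fold <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test <- folds == f
    train <- design_matrix(dm$X[!test, , drop = FALSE], dm$y[!test])
    if (length(unique(train$y)) < 2) {
      stop("fold ", f, " leaves a single-class training set; ",
           "use a stratified plan")
    }
    model <- fit_fn(train)
    Xte <- dm$X[test, , drop = FALSE]
    oof_pred[test] <- predict(model, Xte, type = "class")
    oof_score[test] <- predict(model, Xte, type = "score")
    m <- classification_metrics(confusion(dm$y[test], oof_pred[test]))
    per_fold[[f]] <- data.frame(fold = f, n = sum(test),
                                acc = m["acc"], sen = m["sen"], spe = m["spe"],
                                row.names = NULL)
  }
  counts <- confusion(dm$y, oof_pred)
  ra <- roc_auc(dm$y, oof_score)
  structure(list(
    counts = counts,
    metrics = classification_metrics(counts),
    auc = ra$auc,
    roc = ra$roc,
    per_fold = do.call(rbind, per_fold),
    oof = data.frame(y = dm$y, pred = oof_pred, score = oof_score,
                     fold = folds),
    plan = plan
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("pooled %d-fold CV: ACC %.3f  SEN %.3f  SPE %.3f  AUC %.3f\n",
              x$plan$k, m["acc"], m["sen"], m["spe"], x$auc))
  invisible(x)
}

#' Export a metric report
#'
#' `format = "json"` writes the pooled counts, metrics, AUC and per-fold
#' table; `format = "tsv"` writes one summary row (ACC, SEN, SPE, AUC to 3
#' decimals); `format = "roc"` writes the ROC points as CSV.
#'
#' @param report A `metric_report`.
#' @param path Output path.
#' @param format One of `"json"`, `"tsv"`, `"roc"`.
#' @param label Optional classifier label for the TSV row.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path,
                                format = c("json", "tsv", "roc"),
                                label = "classifier") {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(
      counts = unclass(report$counts),
      metrics = as.list(report$metrics),
      auc = report$auc,
      per_fold = report$per_fold
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (format == "tsv") {
    row <- data.frame(classifier = label,
                      ACC = round(report$metrics["acc"], 3),
                      SEN = round(report$metrics["sen"], 3),
                      SPE = round(report$metrics["spe"], 3),
                      AUC = round(report$auc, 3))
    utils::write.table(row, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write.csv(report$roc, path, row.names = FALSE)
  }
  invisible(path)
}
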