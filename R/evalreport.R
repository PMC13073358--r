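# Metric suite, risk-score behavior, ablation harness ------------------------

#' Support-weighted classification metrics
#'
#' Computes the confusion matrix (rows = true class, columns = predicted),
#' overall accuracy, and per-class precision/recall/F1 averaged with
#' class-support weights. With support weighting, weighted recall equals
#' accuracy by identity. Zero-division cells (a class never predicted, or
#' precision + recall = 0) yield 0 and set the `zero_division` flag.
#'
#' @param pred,truth Integer label vectors in 0..`n_classes - 1`.
#' @param n_classes Number of classes.
#' @return List with `accuracy`, `precision_w`, `recall_w`, `f1_w`,
#'   `per_class` (data frame), `confusion`, `zero_division`.
#' @export
classification_metrics <- function(pred, truth, n_classes = 4L) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    stopf("pred and truth must be equal-length, non-empty")
  }
  lv <- seq_len(n_classes) - 1L
  cm <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = lv, pred = lv))
  support <- rowSums(cm)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  zero_div <- FALSE
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  if (any(pred_n == 0 & support > 0)) zero_div <- TRUE
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  if (any(prec + rec == 0 & support > 0)) zero_div <- TRUE
  wts <- support / sum(support)
  list(
    accuracy = sum(tp) / sum(cm),
    precision_w = sum(wts * prec),
    recall_w = sum(wts * rec),
    f1_w = sum(wts * f1),
    per_class = data.frame(class = lv, precision = prec, recall = rec,
                           f1 = f1, support = support),
    confusion = cm,
    zero_division = zero_div
  )
}

# Midrank (trapezoidal) AUC of scores against a binary indicator.
auc_midrank <- function(scores, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest ROC AUC per class and micro-averaged AUC
#'
#' Per-class AUC treats each class as positive against all others, using
#' that class's predicted probability as the score, with the midrank
#' (trapezoidal) tie convention. The micro AUC pools all `n_classes * n`
#' one-vs-rest (score, indicator) pairs into a single binary problem. A
#' class absent from the truth yields `NA` for its AUC; the micro AUC is
#' still computed.
#'
#' @param probs n x `n_classes` matrix of class probabilities (rows sum to 1).
#' @param truth Integer labels in 0..`n_classes - 1`.
#' @return List with `per_class_auc` (length `n_classes`) and `micro_auc`.
#' @export
ovr_roc_auc <- function(probs, truth) {
  n_classes <- ncol(probs)
  if (nrow(probs) != length(truth)) stopf("probs and truth lengths differ")
  per <- vapply(seq_len(n_classes), function(k) {
    auc_midrank(probs[, k], truth == k - 1L)
  }, numeric(1))
  onehot <- outer(truth, seq_len(n_classes) - 1L, `==`)
  micro <- auc_midrank(as.vector(probs), as.vector(onehot))
  list(per_class_auc = per, micro_auc = micro)
}

#' Risk-score class means and strict monotonicity
#'
#' Mean continuous risk score per ordinal class and a flag that is `TRUE`
#' iff the means increase strictly from class 0 to class 3 (the intended
#' progression-aware behavior). An empty class gives `NA` and a `FALSE`
#' flag.
#'
#' @param risk Numeric risk scores in \[0,1\].
#' @param labels Integer labels in 0..3.
#' @return List with `means` (length 4) and `monotone`.
#' @export
risk_monotonicity <- function(risk, labels) {
  means <- vapply(0:3, function(k) {
    if (any(labels == k)) mean(risk[labels == k]) else NA_real_
  }, numeric(1))
  monotone <- !anyNA(means) && all(diff(means) > 0)
  list(means = means, monotone = monotone)
}

#' Fraction of misclassifications between adjacent ordinal classes
#'
#' Among misclassified samples, the proportion whose predicted and true
#' classes differ by exactly one ordinal step. With no errors the fraction
#' is 0 and `no_errors` is set.
#'
#' @param pred,truth Integer label vectors in 0..3.
#' @return List with `fraction`, `n_errors`, `no_errors`.
#' @export
adjacency_confusion <- function(pred, truth) {
  err <- pred != truth
  if (!any(err)) return(list(fraction = 0, n_errors = 0L, no_errors = TRUE))
  list(fraction = mean(abs(pred[err] - truth[err]) == 1),
       n_errors = sum(err), no_errors = FALSE)
}

#' Full evaluation report for a model on a record set
#'
#' Runs eval-mode predictions over the records and assembles the metric
#' suite: accuracy and support-weighted precision/recall/F1, per-class and
#' micro-averaged one-vs-rest AUC, the confusion matrix, the adjacent-error
#' fraction, risk-score class means with the strict-monotonicity flag, and
#' (optionally, when `concordance` is supplied from [concordance_eval()])
#' the heatmap-mask concordance rate.
#'
#' @param model A `stagevit_model`.
#' @param records List of `image_record`s.
#' @param concordance Optional result of [concordance_eval()].
#' @return A `metrics_report` list.
#' @export
evaluate_model <- function(model, records, concordance = NULL) {
  pr <- predict_records(model, records)
  cm <- classification_metrics(pr$pred, pr$labels, model$config$n_classes)
  roc <- ovr_roc_auc(pr$probs, pr$labels)
  rm <- risk_monotonicity(pr$risk, pr$labels)
  adj <- adjacency_confusion(pr$pred, pr$labels)
  structure(
    list(accuracy = cm$accuracy, precision_w = cm$precision_w,
         recall_w = cm$recall_w, f1_w = cm$f1_w, per_class = cm$per_class,
         confusion = cm$confusion, zero_division = cm$zero_division,
         per_class_auc = roc$per_class_auc, micro_auc = roc$micro_auc,
         adjacent_error_fraction = adj$fraction, n_errors = adj$n_errors,
         risk_means = rm$means, risk_monotone = rm$monotone,
         concordance_rate = if (is.null(concordance)) NA_real_ else concordance$rate,
         predictions = data.frame(
           image_id = vapply(records, function(r) r$image_id, character(1)),
           true = pr$labels, pred = pr$pred, risk_score = pr$risk)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision_w %.4f  recall_w %.4f  f1_w %.4f\n",
              x$accuracy, x$precision_w, x$recall_w, x$f1_w))
  cat(sprintf("micro AUC %.4f  per-class AUC %s\n", x$micro_auc,
              paste(sprintf("%.3f", x$per_class_auc), collapse = " ")))
  cat(sprintf("risk means %s  monotone %s\n",
              paste(sprintf("%.3f", x$risk_means), collapse = " "),
              x$risk_monotone))
  cat(sprintf("adjacent-error fraction %.3f (%d errors)\n",
              x$adjacent_error_fraction, x$n_errors))
  if (!is.na(x$concordance_rate)) {
    cat(sprintf("heatmap-mask concordance %.3f\n", x$concordance_rate))
  }
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @param predictions_csv Optional path for a per-image prediction CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, predictions_csv = NULL) {
  out <- report
  out$confusion <- unclass(out$confusion)
  preds <- out$predictions
  out$predictions <- NULL
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(predictions_csv)) utils::write.csv(preds, predictions_csv, row.names = FALSE)
  invisible(path)
}

#' Ablation harness: train and evaluate architecture variants
#'
#' Trains every requested variant under identical data, seeds, augmentation
#' and budgets, evaluates each run on the test records, and reports
#' per-run metrics, per-variant means, and full-minus-variant deltas
#' (accuracy, weighted F1, micro AUC, and class-2 "High-Risk" recall).
#'
#' @param model_cfg,train_cfg,train_records,val_records,aug As in
#'   [train_model()].
#' @param test_records Held-out records.
#' @param variants Subset of `c("full", "no_progression", "no_self_attention")`.
#' @param seeds Integer seeds applied identically to every variant.
#' @return List with `per_run`, `summary` (per-variant means), and `deltas`
#'   (full minus variant).
#' @export
ablation_suite <- function(model_cfg, train_cfg, train_records, val_records,
                           test_records,
                           variants = c("full", "no_progression", "no_self_attention"),
                           seeds = train_cfg$seeds, aug = aug_config()) {
  bad <- setdiff(variants, c("full", "no_progression", "no_self_attention"))
  if (length(bad)) stopf("unknown variant(s): %s", paste(bad, collapse = ", "))
  rows <- list()
  for (v in variants) {
    for (s in seeds) {
      fit <- train_model(model_cfg, train_cfg, train_records, val_records,
                         seed = s, variant = v, aug = aug)
      rep <- evaluate_model(fit$model, test_records)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = s, accuracy = rep$accuracy, f1_w = rep$f1_w,
        micro_auc = rep$micro_auc,
        recall_class2 = rep$per_class$recall[3],
        recall_class3 = rep$per_class$recall[4],
        risk_monotone = as.numeric(rep$risk_monotone),
        stringsAsFactors = FALSE)
    }
  }
  per_run <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "f1_w", "micro_auc", "recall_class2",
                   "recall_class3", "risk_monotone")
  summary <- do.call(rbind, lapply(split(per_run, per_run$variant), function(d) {
    cbind(data.frame(variant = d$variant[1]), as.data.frame(t(colMeans(d[metric_cols]))))
  }))
  rownames(summary) <- NULL
  summary <- summary[match(variants, summary$variant), , drop = FALSE]
  deltas <- NULL
  if ("full" %in% variants) {
    full_row <- summary[summary$variant == "full", metric_cols]
    deltas <- do.call(rbind, lapply(variants, function(v) {
      cbind(data.frame(variant = v),
            full_row - summary[summary$variant == v, metric_cols])
    }))
    rownames(deltas) <- NULL
  }
  list(per_run = per_run, summary = summary, deltas = deltas)
}
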