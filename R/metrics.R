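#' Multi-label evaluation metrics
#'
#' Accuracy is sample-wise label (Hamming) accuracy averaged over samples:
#' for each sample the fraction of its labels predicted correctly, then the
#' mean over samples. Precision and recall pool true/false positive counts
#' per label over all samples and macro-average the per-label values over
#' the labels whose denominator is defined; undefined labels are excluded
#' and reported. ROC-AUC uses the Mann-Whitney convention (tied pairs count
#' one half); PR-AUC is average precision (step integration of the
#' precision-recall curve at distinct score thresholds). AUC/AUPR are
#' macro-averaged over labels that contain both classes; single-class
#' labels are excluded and reported.
#'
#' @name metrics
#' @keywords internal
NULL

.check_shapes <- function(truth, pred) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!all(dim(truth) == dim(pred))) {
    stop_config(sprintf("shape mismatch: truth %dx%d vs pred %dx%d",
                        nrow(truth), ncol(truth), nrow(pred), ncol(pred)),
                field = "pred")
  }
  list(truth = truth, pred = pred)
}

#' Sample-wise multi-label accuracy
#'
#' @param truth binary matrix (samples x labels).
#' @param pred binary matrix of the same shape.
#' @return fraction in \[0, 1\].
#' @export
ml_accuracy <- function(truth, pred) {
  s <- .check_shapes(truth, pred)
  mean(rowMeans(s$truth == s$pred))
}

.label_counts <- function(truth, pred) {
  tp <- colSums(truth == 1 & pred == 1)
  fp <- colSums(truth == 0 & pred == 1)
  fn <- colSums(truth == 1 & pred == 0)
  tn <- colSums(truth == 0 & pred == 0)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Macro-averaged precision over labels
#'
#' @inheritParams ml_accuracy
#' @return fraction, with attribute `per_label` (per-label values, `NA`
#'   where undefined) and `excluded` (indices of undefined labels).
#' @export
macro_precision <- function(truth, pred) {
  s <- .check_shapes(truth, pred)
  ct <- .label_counts(s$truth, s$pred)
  per <- ifelse(ct$tp + ct$fp > 0, ct$tp / (ct$tp + ct$fp), NA_real_)
  structure(mean(per, na.rm = TRUE), per_label = per,
            excluded = which(is.na(per)))
}

#' Macro-averaged recall over labels
#'
#' @inheritParams ml_accuracy
#' @return fraction, with attributes as in [macro_precision()].
#' @export
macro_recall <- function(truth, pred) {
  s <- .check_shapes(truth, pred)
  ct <- .label_counts(s$truth, s$pred)
  per <- ifelse(ct$tp + ct$fn > 0, ct$tp / (ct$tp + ct$fn), NA_real_)
  structure(mean(per, na.rm = TRUE), per_label = per,
            excluded = which(is.na(per)))
}

# ROC-AUC of one label via the rank (Mann-Whitney) formula; ties share rank.
.auc_one <- function(y, s) {
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
}

# PR-AUC of one label: average precision over distinct-threshold steps.
.aupr_one <- function(y, s) {
  np <- sum(y == 1)
  if (np == 0 || np == length(y)) return(NA_real_)
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Macro-averaged ROC-AUC over labels
#'
#' @param truth binary matrix (samples x labels).
#' @param scores numeric score/probability matrix of the same shape.
#' @return fraction, with attributes `per_label` and `excluded`
#'   (single-class labels, left out of the mean).
#' @export
macro_auc <- function(truth, scores) {
  s <- .check_shapes(truth, scores)
  per <- vapply(seq_len(ncol(s$truth)),
                function(j) .auc_one(s$truth[, j], s$pred[, j]), numeric(1))
  structure(mean(per, na.rm = TRUE), per_label = per,
            excluded = which(is.na(per)))
}

#' Macro-averaged PR-AUC (average precision) over labels
#'
#' @inheritParams macro_auc
#' @return fraction, with attributes `per_label` and `excluded`.
#' @export
macro_aupr <- function(truth, scores) {
  s <- .check_shapes(truth, scores)
  per <- vapply(seq_len(ncol(s$truth)),
                function(j) .aupr_one(s$truth[, j], s$pred[, j]), numeric(1))
  structure(mean(per, na.rm = TRUE), per_label = per,
            excluded = which(is.na(per)))
}

#' Full multi-label evaluation report
#'
#' Binarizes scores at `threshold` (tie rule `>=`) for accuracy, precision
#' and recall; uses the raw scores for ROC-AUC and PR-AUC.
#'
#' @param truth binary matrix (samples x labels).
#' @param scores score/probability matrix of the same shape.
#' @param threshold binarization threshold (default 0.5).
#' @return an object of class `metrics_report`: the five macro metrics, a
#'   per-label breakdown table, and the labels excluded from each macro
#'   mean.
#' @export
evaluate_predictions <- function(truth, scores, threshold = 0.5) {
  s <- .check_shapes(truth, scores)
  pred <- (s$pred >= threshold) * 1L
  acc <- ml_accuracy(s$truth, pred)
  pr <- macro_precision(s$truth, pred)
  rc <- macro_recall(s$truth, pred)
  auc <- macro_auc(s$truth, s$pred)
  aupr <- macro_aupr(s$truth, s$pred)
  lab <- colnames(s$truth)
  if (is.null(lab)) lab <- paste0("label_", seq_len(ncol(s$truth)))
  per_label <- data.frame(
    label = lab,
    prevalence = colMeans(s$truth),
    precision = as.numeric(attr(pr, "per_label")),
    recall = as.numeric(attr(rc, "per_label")),
    auc = as.numeric(attr(auc, "per_label")),
    aupr = as.numeric(attr(aupr, "per_label")),
    stringsAsFactors = FALSE
  )
  structure(list(
    accuracy = as.numeric(acc),
    precision = as.numeric(pr),
    recall = as.numeric(rc),
    auc = as.numeric(auc),
    aupr = as.numeric(aupr),
    threshold = threshold,
    per_label = per_label,
    excluded = list(precision = attr(pr, "excluded"),
                    recall = attr(rc, "excluded"),
                    auc = attr(auc, "excluded"),
                    aupr = attr(aupr, "excluded"))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> acc %.4f | macro P %.4f R %.4f | AUC %.4f AUPR %.4f (tau=%g)\n",
    x$accuracy, x$precision, x$recall, x$auc, x$aupr, x$threshold))
  nex <- sum(lengths(x$excluded) > 0)
  if (nex > 0) {
    for (m in names(x$excluded)) {
      if (length(x$excluded[[m]]) > 0) {
        cat(sprintf("  excluded from macro %s: %s\n", m,
                    paste(x$per_label$label[x$excluded[[m]]], collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes a flat per-label CSV and a JSON summary next to it.
#'
#' @param report a `metrics_report`.
#' @param path output path stem; `<path>.csv` and `<path>.json` are
#'   written.
#' @return invisibly, the two paths.
#' @export
write_metrics_report <- function(report, path) {
  if (!inherits(report, "metrics_report")) stop_config("expected metrics_report")
  csv <- paste0(path, ".csv")
  js <- paste0(path, ".json")
  utils::write.csv(report$per_label, csv, row.names = FALSE)
  jsonlite::write_json(list(
    accuracy = report$accuracy, precision = report$precision,
    recall = report$recall, auc = report$auc, aupr = report$aupr,
    threshold = report$threshold,
    excluded = report$excluded
  ), js, digits = NA, auto_unbox = TRUE)
  invisible(c(csv, js))
}
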