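# Validation metrics with the pathogenic (MR) class as positive.

#' Confusion matrix with MR as the positive class
#'
#' @param predictions,truths Aligned label vectors over `{mr, benign}`.
#' @return An object of class `cnv_confusion`: list with integer `tp`,
#'   `fn`, `fp`, `tn`.
#' @export
confusion <- function(predictions, truths) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length")
  bad <- setdiff(unique(c(predictions, truths)), c("mr", "benign"))
  if (length(bad))
    stop("labels must be 'mr' or 'benign'; found: ",
         paste(bad, collapse = ", "))
  structure(list(
    tp = sum(predictions == "mr" & truths == "mr"),
    fn = sum(predictions == "benign" & truths == "mr"),
    fp = sum(predictions == "mr" & truths == "benign"),
    tn = sum(predictions == "benign" & truths == "benign")
  ), class = "cnv_confusion")
}

#' @rdname confusion
#' @param tp,fn,fp,tn Non-negative cell counts (direct construction).
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  structure(as.list(counts), class = "cnv_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/total`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, and the false
#' positive/negative rates `1 - specificity` / `1 - sensitivity`.
#' A metric whose denominator is zero is reported as `NA` (missing),
#' never as 0.
#'
#' @param cm A `cnv_confusion`.
#' @return A list of class `cnv_metrics` with the proportions above.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "cnv_confusion"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  structure(list(
    sensitivity = sens,
    specificity = spec,
    accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$fn + cm$fp + cm$tn),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    fnr = if (is.na(sens)) NA_real_ else 1 - sens
  ), class = "cnv_metrics")
}

#' @export
print.cnv_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%d%%", round(100 * v))
  prop <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat("CNV classification metrics (positive class: MR)\n")
  cat("  sensitivity:", pct(x$sensitivity),
      " specificity:", pct(x$specificity),
      " accuracy:", pct(x$accuracy), "\n")
  cat("  PPV:", prop(x$ppv), " NPV:", prop(x$npv),
      " FPR:", prop(x$fpr), " FNR:", prop(x$fnr), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals
#' trapezoidal integration over all thresholds and handles tied scores
#' as half-concordant pairs.
#'
#' @param mr_distances Numeric scores (higher = more MR-like).
#' @param truths Truth labels over `{mr, benign}`; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(mr_distances, truths) {
  truths <- as.character(truths)
  pos <- truths == "mr"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc requires both classes among truths")
  r <- rank(mr_distances, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ranked MR-distance table
#'
#' Orders classification results by MR distance, descending, ties keeping
#' input order, as plotted in ranked-distance validation curves.
#'
#' @param results `data.frame` from [classify()] (`predicted_class`,
#'   `mr_distance`).
#' @param truths Optional truth labels aligned with rows.
#' @return A `data.frame` with `rank`, `mr_distance`, `predicted` and
#'   (when supplied) `truth`.
#' @export
ranked_distance_table <- function(results, truths = NULL) {
  ord <- order(-results$mr_distance)  # stable: ties keep input order
  out <- data.frame(
    rank = seq_along(ord),
    mr_distance = results$mr_distance[ord],
    predicted = results$predicted_class[ord]
  )
  if (!is.null(truths)) out$truth <- as.character(truths)[ord]
  rownames(out) <- NULL
  out
}

#' Write a metric report
#'
#' Emits both a human-readable summary and machine-readable tab-separated
#' key/value pairs. Percent-style metrics are printed as whole
#' percentages and predictive values as two-decimal proportions, matching
#' conventional clinical reporting granularity.
#'
#' @param m A `cnv_metrics`.
#' @param path Output path for the key/value table.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(m, path) {
  stopifnot(inherits(m, "cnv_metrics"))
  kv <- data.frame(metric = names(m),
                   value = vapply(m, function(v) unname(v), numeric(1)))
  utils::write.table(kv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
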