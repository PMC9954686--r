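# Slice- and subject-level evaluation.
#
# Subject-level predictions aggregate a subject's slice predictions by
# vote for majority: the per-class vote fraction is the share of the
# subject's slices predicted as that class, and the subject label is the
# argmax (ties broken by lexicographic class order).  Reports follow the
# standard classification-report conventions; repetition summaries use
# the population standard deviation over runs.

#' Vote-for-majority aggregation of slice predictions to subjects
#'
#' @param slice_preds data.frame from [predict_slices()] (needs
#'   subject_id, true_label, predicted_label; `prob_*` columns for the
#'   soft variant).
#' @param method `"hard"` counts predicted labels (default, the published
#'   procedure); `"soft"` averages class probabilities instead.
#' @return data.frame, one row per subject: subject_id, true_label,
#'   predicted_label, n_slices and one `vote_<class>` fraction per class
#'   (fractions sum to 1).
#' @export
vote_majority <- function(slice_preds, method = c("hard", "soft")) {
  method <- match.arg(method)
  if (nrow(slice_preds) == 0) stopf("vote_majority: empty predictions")
  prob_cols <- grep("^prob_", names(slice_preds), value = TRUE)
  classes <- if (method == "soft" || length(prob_cols) > 0) {
    sub("^prob_", "", prob_cols)
  } else sort(unique(c(slice_preds$predicted_label, slice_preds$true_label)))
  classes <- sort(classes)
  subjects <- unique(slice_preds$subject_id)
  rows <- lapply(subjects, function(sid) {
    sp <- slice_preds[slice_preds$subject_id == sid, , drop = FALSE]
    frac <- if (method == "hard") {
      tab <- table(factor(sp$predicted_label, levels = classes))
      as.numeric(tab) / nrow(sp)
    } else {
      colMeans(sp[, paste0("prob_", classes), drop = FALSE])
    }
    pred <- classes[which.max(frac)]  # which.max: first (lexicographic) tie winner
    out <- data.frame(subject_id = sid, true_label = sp$true_label[1],
                      predicted_label = pred, n_slices = nrow(sp),
                      stringsAsFactors = FALSE)
    votes <- as.data.frame(as.list(stats::setNames(frac, paste0("vote_", classes))))
    cbind(out, votes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard classification report
#'
#' Per-class precision, recall and F1 with macro (unweighted class mean)
#' and weighted (true-class support) averages, plus accuracy.  A class
#' never predicted gets precision 0; an absent true class gets recall 0
#' (the common report default).
#'
#' @param pred_labels,true_labels aligned label vectors.
#' @param level `"slice"` or `"subject"` (metadata only).
#' @return object of class `eval_report`.
#' @export
classification_report <- function(pred_labels, true_labels, level = "slice") {
  if (length(pred_labels) != length(true_labels)) {
    stopf("classification_report: length mismatch (%d vs %d)",
          length(pred_labels), length(true_labels))
  }
  if (length(true_labels) == 0) stopf("classification_report: empty input")
  classes <- sort(unique(c(pred_labels, true_labels)))
  pred <- factor(pred_labels, levels = classes)
  true <- factor(true_labels, levels = classes)
  cm <- table(true, pred)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  per_class <- data.frame(class = classes, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.numeric(support), stringsAsFactors = FALSE)
  structure(list(
    level = level, classes = classes, per_class = per_class,
    accuracy = sum(tp) / sum(cm),
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                 f1 = sum(w * f1)),
    support = sum(support), confusion = cm), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Classification report (%s level, n = %d)\n", x$level, x$support))
  pc <- x$per_class
  pc[, 2:4] <- round(pc[, 2:4], digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy     %.*f\n", digits, x$accuracy))
  cat(sprintf("macro avg    P %.*f  R %.*f  F1 %.*f\n", digits, x$macro[1],
              digits, x$macro[2], digits, x$macro[3]))
  cat(sprintf("weighted avg P %.*f  R %.*f  F1 %.*f\n", digits, x$weighted[1],
              digits, x$weighted[2], digits, x$weighted[3]))
  invisible(x)
}

report_metrics <- function(report) {
  c(accuracy = report$accuracy,
    macro_precision = unname(report$macro["precision"]),
    macro_recall = unname(report$macro["recall"]),
    macro_f1 = unname(report$macro["f1"]),
    weighted_precision = unname(report$weighted["precision"]),
    weighted_recall = unname(report$weighted["recall"]),
    weighted_f1 = unname(report$weighted["f1"]))
}

#' Aggregate repeated runs as mean and standard deviation
#'
#' @param reports list of `eval_report`s from repeated runs (same level
#'   and experiment).
#' @param sd_type `"population"` (default, matches the published
#'   "mean ± sd over three repetitions" convention) or `"sample"`.
#' @return object of class `repetition_summary`: data.frame with metric,
#'   mean, sd and a `pretty` "m ± s" rendering (two decimals).
#' @export
aggregate_repetitions <- function(reports, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(reports) < 1) stopf("aggregate_repetitions: need at least one report")
  levels <- unique(vapply(reports, `[[`, character(1), "level"))
  if (length(levels) != 1) stopf("aggregate_repetitions: mixed report levels")
  M <- t(vapply(reports, report_metrics, numeric(7)))
  mu <- colMeans(M)
  sdv <- apply(M, 2, function(x) {
    if (sd_type == "population" || length(x) == 1) sqrt(mean((x - mean(x))^2))
    else stats::sd(x)
  })
  out <- data.frame(metric = colnames(M), mean = unname(mu), sd = unname(sdv),
                    pretty = sprintf("%.2f ± %.2f", mu, sdv),
                    stringsAsFactors = FALSE)
  structure(out, level = levels, n_repetitions = length(reports),
            class = c("repetition_summary", "data.frame"))
}

#' Confusion matrix normalized per true class
#'
#' Entry (r, c) is the fraction of true-class-r items predicted as class
#' c; rows of nonempty true classes sum to 1, an empty true class yields
#' an all-zero row.
#'
#' @param pred_labels,true_labels aligned label vectors.
#' @param classes optional fixed class order (default: sorted union).
#' @return numeric matrix with classes on both axes.
#' @export
normalized_confusion <- function(pred_labels, true_labels, classes = NULL) {
  if (length(pred_labels) != length(true_labels)) {
    stopf("normalized_confusion: length mismatch")
  }
  classes <- classes %||% sort(unique(c(pred_labels, true_labels)))
  cm <- table(factor(true_labels, levels = classes),
              factor(pred_labels, levels = classes))
  n <- rowSums(cm)
  out <- sweep(unclass(cm), 1, ifelse(n > 0, n, 1), `/`)
  dimnames(out) <- list(true = classes, predicted = classes)
  out
}
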