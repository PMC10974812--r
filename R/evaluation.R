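#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, in the order of
#' `class_set`. The total count equals the number of evaluated items.
#'
#' @param true,predicted Label vectors (character or factor over
#'   `class_set`).
#' @param class_set Ordered class labels.
#' @return Integer `nbclass x nbclass` matrix with dimnames.
#' @export
confusion_matrix <- function(true, predicted, class_set) {
  true <- as_emotion(as.character(true), class_set)
  predicted <- as_emotion(as.character(predicted), class_set)
  stopifnot(length(true) == length(predicted))
  m <- table(true = true, predicted = predicted)
  out <- matrix(as.integer(m), length(class_set), length(class_set),
                dimnames = list(true = class_set, predicted = class_set))
  out
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || length(cm) == 0L) {
    stop("confusion matrix must be a non-empty square matrix")
  }
  if (sum(cm) == 0) stop("empty confusion matrix (no evaluated items)")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  invisible(cm)
}

#' Overall accuracy of a confusion matrix
#'
#' The rate of correct predictions. For the multiclass case the
#' one-vs-rest TP/TN formulation collapses to `trace / total` — correct
#' predictions over all predictions — which is what is computed here.
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Average recall per class (macro recall)
#'
#' The unweighted mean over classes of `TP / (TP + FN)` — the model's
#' sensitivity averaged with every class counting equally.
#'
#' @param cm Confusion matrix.
#' @param zero_support `"error"` (default) to reject classes with no true
#'   items, or `"mask"` to average over supported classes with a warning.
#' @return Fraction in `[0, 1]`.
#' @export
average_recall_per_class <- function(cm, zero_support = c("error", "mask")) {
  zero_support <- match.arg(zero_support)
  check_cm(cm)
  support <- rowSums(cm)
  if (any(support == 0)) {
    if (zero_support == "error") {
      stop("class(es) with zero support: ",
           paste(rownames(cm)[support == 0], collapse = ", "))
    }
    warning("zero-support class(es) masked from the recall average")
  }
  rec <- diag(cm)[support > 0] / support[support > 0]
  mean(rec)
}

#' Support-weighted and per-class metrics
#'
#' Support-weighted recall `sum_c (n_c / N) recall_c` (algebraically equal
#' to the overall accuracy), support-weighted precision-based accuracy, and
#' per-class recall, precision and F1. A class never predicted has
#' precision 0 and hence F1 0 (zero-denominator convention); likewise a
#' class with no true items has recall 0.
#'
#' @param cm Confusion matrix.
#' @return List with `weighted_recall`, `weighted_accuracy` (alias of the
#'   support-weighted recall), and a `per_class` data frame (`class`,
#'   `support`, `recall`, `precision`, `f1`).
#' @export
weighted_metrics <- function(cm) {
  check_cm(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  recall <- ifelse(support > 0, tp / support, 0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  f1 <- ifelse(recall + precision > 0,
               2 * recall * precision / (recall + precision), 0)
  weighted_recall <- sum(support / sum(cm) * recall)
  list(weighted_recall = weighted_recall,
       weighted_accuracy = weighted_recall,
       per_class = data.frame(class = rownames(cm) %||%
                                as.character(seq_len(nrow(cm))),
                              support = support,
                              recall = recall, precision = precision,
                              f1 = f1, row.names = NULL))
}

#' Row-normalize a confusion matrix
#'
#' Divides each row by its sum so rows sum to 1; the diagonal of the result
#' is the per-class recall vector. Zero rows are emitted as zeros with a
#' warning.
#'
#' @param cm Confusion matrix.
#' @return Real matrix of the same shape.
#' @export
row_normalize <- function(cm) {
  check_cm(cm)
  s <- rowSums(cm)
  if (any(s == 0)) warning("zero row(s) left as zeros")
  out <- cm / ifelse(s == 0, 1, s)
  out
}

#' Aggregate a confusion matrix by valence-arousal quadrant
#'
#' Groups true and predicted labels by their quadrant (see
#' [quadrant_map()]) and splits the classification errors into
#' intra-quadrant (both labels in the same quadrant) and inter-quadrant
#' ones.
#'
#' @param cm Confusion matrix over emotions.
#' @param qmap Named map emotion -> quadrant; default [quadrant_map()].
#' @return List with `quadrant_matrix` (counts), `intra_quadrant_error_rate`
#'   and `inter_quadrant_error_rate` (fractions of all errors; `NaN` when
#'   there are no errors).
#' @export
quadrant_confusion <- function(cm, qmap = quadrant_map()) {
  check_cm(cm)
  classes <- rownames(cm)
  missing <- setdiff(classes, names(qmap))
  if (length(missing) > 0L) {
    stop("label(s) missing from the quadrant map: ",
         paste(missing, collapse = ", "))
  }
  quads <- unique(qmap[classes])
  qm <- matrix(0L, length(quads), length(quads),
               dimnames = list(true = quads, predicted = quads))
  for (i in classes) {
    for (j in classes) {
      qm[qmap[i], qmap[j]] <- qm[qmap[i], qmap[j]] + cm[i, j]
    }
  }
  err <- cm
  diag(err) <- 0L
  total_err <- sum(err)
  same_quad <- outer(qmap[classes], qmap[classes], "==")
  intra <- sum(err[same_quad])
  list(quadrant_matrix = qm,
       intra_quadrant_error_rate = if (total_err == 0) NaN else intra / total_err,
       inter_quadrant_error_rate = if (total_err == 0) NaN else (total_err - intra) / total_err)
}

#' Full evaluation report for a confusion matrix
#'
#' @param cm Confusion matrix.
#' @param qmap Quadrant map for the valence-arousal aggregation.
#' @param zero_support Passed to [average_recall_per_class()].
#' @return An `eval_report` list: `confusion`, `overall_accuracy`,
#'   `average_recall`, `weighted_accuracy`, `weighted_recall`, `per_class`,
#'   `quadrant`.
#' @export
eval_report <- function(cm, qmap = quadrant_map(),
                        zero_support = "error") {
  wm <- weighted_metrics(cm)
  structure(list(confusion = cm,
                 overall_accuracy = overall_accuracy(cm),
                 average_recall = average_recall_per_class(cm, zero_support),
                 weighted_accuracy = wm$weighted_accuracy,
                 weighted_recall = wm$weighted_recall,
                 per_class = wm$per_class,
                 quadrant = quadrant_confusion(cm, qmap)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.3f, avg recall %.3f, weighted %.3f>\n",
              x$overall_accuracy, x$average_recall, x$weighted_accuracy))
  invisible(x)
}
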