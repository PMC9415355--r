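# Classification metrics: confusion matrices, per-taxon precision and
# recall, macro means with confidence intervals across taxa.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of units (images or specimens) with true
#' class `i` predicted as class `j`.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param class_labels Ordered class labels fixing row/column order.
#' @return Object of class `confusion_matrix`: integer `C x C` matrix with
#'   dimnames `true` x `predicted`.
#' @export
confusion <- function(true_labels, predicted_labels, class_labels) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("label vectors must have equal length")
  if (!all(true_labels %in% class_labels) ||
      !all(predicted_labels %in% class_labels))
    stop_invalid("labels outside class_labels")
  tt <- factor(true_labels, levels = class_labels)
  pp <- factor(predicted_labels, levels = class_labels)
  m <- unclass(table(true = tt, predicted = pp))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Precision, recall, and accuracy from a confusion matrix
#'
#' Precision for class x is the proportion of correct predictions among all
#' units classified as x, `TPx / (TPx + FPx)`; recall is the proportion of
#' true class-x units classified as x, `TPx / (TPx + FNx)`; accuracy is the
#' proportion of correct classifications over all units. A class that was
#' never predicted has undefined precision; it is reported as 0 with its
#' `undefined_precision` flag raised so macro means stay conservative and
#' auditable (likewise for recall of a class absent from the test set).
#' Macro means are unweighted over classes; 95% confidence intervals are
#' t-intervals across the per-class values.
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `metrics_report`: list with `accuracy`,
#'   `per_class_precision`, `per_class_recall`, `macro_precision`,
#'   `macro_recall`, `ci95_precision`, `ci95_recall`,
#'   `undefined_precision_flags`, `undefined_recall_flags`, `total`.
#' @export
precision_recall <- function(cm) {
  m <- unclass(cm)
  total <- sum(m)
  if (!is.matrix(m) || total == 0) stop_invalid("empty confusion matrix")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  undef_p <- (tp + fp) == 0
  undef_r <- (tp + fn) == 0
  precision <- ifelse(undef_p, 0, tp / (tp + fp))
  recall <- ifelse(undef_r, 0, tp / (tp + fn))
  ci <- function(v) {
    k <- length(v)
    if (k < 2) return(c(lo = v, hi = v))
    half <- stats::qt(0.975, k - 1) * stats::sd(v) / sqrt(k)
    c(lo = max(0, mean(v) - half), hi = min(1, mean(v) + half))
  }
  structure(list(accuracy = sum(tp) / total,
                 per_class_precision = precision,
                 per_class_recall = recall,
                 macro_precision = mean(precision),
                 macro_recall = mean(recall),
                 ci95_precision = ci(precision),
                 ci95_recall = ci(recall),
                 undefined_precision_flags = undef_p,
                 undefined_recall_flags = undef_r,
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n = %d: accuracy %.3f, macro precision %.3f (95%% CI %.3f-%.3f), macro recall %.3f\n",
    x$total, x$accuracy, x$macro_precision, x$ci95_precision["lo"],
    x$ci95_precision["hi"], x$macro_recall))
  if (any(x$undefined_precision_flags))
    cat("  undefined precision for:",
        paste(names(which(x$undefined_precision_flags)), collapse = ", "), "\n")
  invisible(x)
}

#' Join per-taxon precision with mean body size
#'
#' Builds the table behind size-vs-precision analyses: one row per taxon
#' with its mean silhouette area in mm^2 and classification precision.
#'
#' @param per_taxon_precision Named or plain numeric vector, one per taxon.
#' @param per_taxon_mean_size_mm2 Numeric vector aligned with the precision
#'   vector.
#' @param taxa Taxon labels (defaults to the precision names).
#' @param order Optional higher-rank group of each taxon.
#' @param training_size Optional training size annotation.
#' @return `data.frame` with columns `taxon, order, mean_size_mm2,
#'   precision, training_size`.
#' @export
size_precision_table <- function(per_taxon_precision, per_taxon_mean_size_mm2,
                                 taxa = names(per_taxon_precision),
                                 order = NA_character_,
                                 training_size = NA_integer_) {
  if (length(per_taxon_precision) != length(per_taxon_mean_size_mm2))
    stop_invalid("precision and size vectors are misaligned")
  if (is.null(taxa)) taxa <- paste0("taxon_", seq_along(per_taxon_precision))
  if (length(taxa) != length(per_taxon_precision))
    stop_invalid("taxa labels are misaligned")
  data.frame(taxon = taxa, order = order,
             mean_size_mm2 = as.numeric(per_taxon_mean_size_mm2),
             precision = as.numeric(per_taxon_precision),
             training_size = training_size,
             stringsAsFactors = FALSE)
}
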