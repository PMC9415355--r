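# Specimen-level aggregation of per-image decisions. A specimen is imaged
# many times from two orthogonal views as it sinks; individual frames may be
# misclassified, which aggregation compensates for when most frames (or the
# bulk of the score mass) point to the right taxon.

#' Majority vote over a specimen's frames
#'
#' Each image carries equal weight; the specimen is assigned to the class
#' with the most votes. Vote ties are broken by the larger summed score among
#' the tied classes (when scores are supplied), remaining ties by the lowest
#' class index.
#'
#' @param per_image_classes Integer vector of 1-based per-frame class
#'   indices.
#' @param per_image_scores Optional score matrix (rows = frames, columns =
#'   classes) used only for tie-breaking.
#' @param n_classes Number of classes; defaults to what the inputs imply.
#' @return 1-based index of the winning class.
#' @export
majority_vote <- function(per_image_classes, per_image_scores = NULL,
                          n_classes = NULL) {
  if (length(per_image_classes) == 0L)
    stop_invalid("at least one per-image vote is required")
  if (is.null(n_classes))
    n_classes <- if (!is.null(per_image_scores)) ncol(per_image_scores)
                 else max(per_image_classes)
  votes <- tabulate(per_image_classes, nbins = n_classes)
  top <- which(votes == max(votes))
  if (length(top) > 1L && !is.null(per_image_scores)) {
    sums <- colSums(per_image_scores[, top, drop = FALSE])
    top <- top[sums == max(sums)]
  }
  top[1]
}

#' Max-scoring-sum vote over a specimen's frames
#'
#' The unbounded per-class score vectors of all frames are summed
#' element-wise and the class with the highest total is assigned. Summing
#' raw scores weights each frame by the classifier's confidence: frames the
#' model finds hard contribute little to any class.
#'
#' @param per_image_scores Score matrix (rows = frames, columns = classes)
#'   or list of equal-length score vectors.
#' @return 1-based index of the winning class (ties to the lowest index).
#' @export
score_sum_vote <- function(per_image_scores) {
  if (is.list(per_image_scores)) {
    lens <- lengths(per_image_scores)
    if (length(lens) == 0L) stop_invalid("at least one score vector is required")
    if (length(unique(lens)) != 1L)
      stop_invalid("score vectors have inconsistent lengths")
    per_image_scores <- do.call(rbind, per_image_scores)
  }
  if (!is.matrix(per_image_scores) || nrow(per_image_scores) == 0L)
    stop_invalid("at least one score vector is required")
  which.max(colSums(per_image_scores))
}

#' Classify one specimen from its frames
#'
#' Scores every valid frame with the fitted model and aggregates: per-image
#' modal class, majority vote, and max scoring sum.
#'
#' @param model A fitted `taxon_scorer`.
#' @param x Feature matrix of the specimen's frames (or a `specimen_record`,
#'   whose features are then extracted).
#' @return Object of class `specimen_prediction`: list with
#'   `per_image_classes`, `scores`, `voted_majority`, `voted_scoresum`
#'   (labels), and the corresponding indices.
#' @export
predict_specimen <- function(model, x) {
  if (inherits(x, "specimen_record"))
    x <- features_from_record(x, pool = sqrt(model$n_features - 6))$x
  s <- predict(model, x, type = "score")
  cls <- apply(s, 1, predict_image)
  mj <- majority_vote(cls, s, n_classes = ncol(s))
  ss <- score_sum_vote(s)
  structure(list(per_image_classes = cls, scores = s,
                 majority_index = mj, scoresum_index = ss,
                 voted_majority = model$class_labels[mj],
                 voted_scoresum = model$class_labels[ss]),
            class = "specimen_prediction")
}

#' @export
print.specimen_prediction <- function(x, ...) {
  cat(sprintf("<specimen_prediction> %d frames: majority -> %s, score-sum -> %s\n",
              length(x$per_image_classes), x$voted_majority, x$voted_scoresum))
  invisible(x)
}
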