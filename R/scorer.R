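# Reference per-image scoring model: a regularized multinomial linear scorer
# over a fixed feature map (area-pooled pixels of the standard crop
# concatenated with blob geometric features), trained by full-batch gradient
# descent with validation-based early stopping. The scorer emits unbounded
# per-class scores (pre-softmax logits); probability squashing is never
# applied to the reported scores. The interface is classifier-agnostic: any
# model that maps a frame to a score vector can stand behind it.

#' Feature vector of one frame
#'
#' Detects the blob, applies the standard 496-px crop, area-pools the crop to
#' a `pool x pool` intensity grid, and appends geometric descriptors
#' (log area, log perimeter, log max diameter, bounding-box aspect ratio,
#' bounding-box fill fraction, mean silhouette intensity).
#'
#' @param frame Numeric matrix in `[0, 1]`, width 496 px.
#' @param threshold Passed to [detect_blob()].
#' @param crop_height Passed to [crop_to_standard()].
#' @param pool Side of the pooled pixel grid.
#' @return Numeric feature vector of length `pool^2 + 6`, with the frame's
#'   [blob_features()] attached as attribute `geometry`. Signals
#'   `specvote_no_blob` if the frame contains no detectable silhouette.
#' @export
frame_features <- function(frame, threshold = "otsu", crop_height = 496L,
                           pool = 16L) {
  blob <- detect_blob(frame, threshold)
  feats <- blob_features(blob)
  cropped <- crop_to_standard(frame, feats, crop_height = crop_height)
  px <- as.vector(pool_image(cropped, pool))
  bb <- feats$bbox
  bh <- bb["row_max"] - bb["row_min"] + 1
  bw <- bb["col_max"] - bb["col_min"] + 1
  geom <- c(log_area = log(feats$area),
            log_perimeter = log(feats$perimeter + 1),
            log_max_diameter = log(feats$max_diameter + 1),
            aspect = max(bh, bw) / min(bh, bw),
            fill = feats$area / (bh * bw),
            blob_mean = mean(frame[blob$mask]))
  out <- c(px, unname(geom))
  attr(out, "geometry") <- feats
  out
}

#' Build a feature dataset from taxon specs
#'
#' Generates specimens one at a time, extracts per-frame features, and
#' discards the pixel data, so arbitrarily large synthetic datasets fit in
#' memory. Frames without a detectable blob are dropped (counted); a
#' specimen with zero valid frames is excluded and reported.
#'
#' @param specs List of [taxon_spec] objects.
#' @param n_specimens_per_taxon Specimens per taxon.
#' @param frames_base,seed,... Passed to [generate_specimen()].
#' @param pool,threshold,crop_height Passed to [frame_features()].
#' @return Object of class `feature_dataset`: list with `x` (feature matrix,
#'   one row per frame), `meta` (`data.frame`: specimen_id, taxon, frame,
#'   view, area_px), `manifest`, `n_dropped_frames`, `excluded_specimens`.
#' @export
build_feature_dataset <- function(specs, n_specimens_per_taxon,
                                  frames_base = 65, seed = 1L, pool = 16L,
                                  threshold = "otsu", crop_height = 496L,
                                  ...) {
  xs <- list(); metas <- list(); excluded <- character(); dropped <- 0L
  for (spec in specs) {
    for (j in seq_len(n_specimens_per_taxon)) {
      sid <- sprintf("%s_s%03d", spec$name, j)
      rec <- generate_specimen(spec, sid, frames_base = frames_base,
                               seed = seed, ...)
      fd <- features_from_record(rec, pool = pool, threshold = threshold,
                                 crop_height = crop_height)
      dropped <- dropped + fd$n_dropped
      if (nrow(fd$meta) == 0L) { excluded <- c(excluded, sid); next }
      xs[[sid]] <- fd$x
      metas[[sid]] <- fd$meta
    }
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  manifest <- unique(meta[, c("specimen_id", "taxon")])
  rownames(manifest) <- NULL
  structure(list(x = do.call(rbind, xs), meta = meta, manifest = manifest,
                 n_dropped_frames = dropped, excluded_specimens = excluded,
                 pool = pool),
            class = "feature_dataset")
}

#' Extract the feature rows of one specimen record
#'
#' @param record A `specimen_record`.
#' @inheritParams build_feature_dataset
#' @return List with `x`, `meta`, `n_dropped` for this specimen.
#' @export
features_from_record <- function(record, pool = 16L, threshold = "otsu",
                                 crop_height = 496L) {
  rows <- list(); metas <- list(); dropped <- 0L
  for (i in seq_along(record$frames)) {
    f <- tryCatch(frame_features(record$frames[[i]], threshold = threshold,
                                 crop_height = crop_height, pool = pool),
                  specvote_no_blob = function(e) NULL)
    if (is.null(f)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- f
    metas[[length(metas) + 1L]] <- data.frame(
      specimen_id = record$specimen_id, taxon = record$taxon,
      frame = i, view = record$views[i],
      area_px = attr(f, "geometry")$area, stringsAsFactors = FALSE)
  }
  list(x = if (length(rows)) do.call(rbind, rows) else
         matrix(numeric(), 0, pool^2 + 6),
       meta = if (length(metas)) do.call(rbind, metas) else
         data.frame(specimen_id = character(), taxon = character(),
                    frame = integer(), view = character(),
                    area_px = integer()),
       n_dropped = dropped)
}

#' Combine in-memory specimen records into a feature dataset
#'
#' @param records List of `specimen_record` objects (e.g. from
#'   [generate_records()]).
#' @inheritParams build_feature_dataset
#' @return A `feature_dataset`, see [build_feature_dataset()].
#' @export
features_from_records <- function(records, pool = 16L, threshold = "otsu",
                                  crop_height = 496L) {
  parts <- lapply(records, features_from_record, pool = pool,
                  threshold = threshold, crop_height = crop_height)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  rownames(meta) <- NULL
  manifest <- unique(meta[, c("specimen_id", "taxon")])
  rownames(manifest) <- NULL
  structure(list(x = do.call(rbind, lapply(parts, `[[`, "x")), meta = meta,
                 manifest = manifest,
                 n_dropped_frames = sum(vapply(parts, `[[`, 0L, "n_dropped")),
                 excluded_specimens = names(records)[
                   vapply(parts, function(p) nrow(p$meta) == 0L, NA)],
                 pool = pool),
            class = "feature_dataset")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(p, y_idx, w = NULL) {
  nll <- -log(pmax(p[cbind(seq_along(y_idx), y_idx)], 1e-12))
  if (is.null(w)) mean(nll) else sum(w * nll) / sum(w)
}

#' Fit the multinomial image scorer
#'
#' Minimizes L2-regularized cross-entropy over training frames by full-batch
#' gradient descent with momentum, logging training loss, validation loss,
#' and validation accuracy after every epoch. The returned parameters are
#' those of the epoch with minimum validation loss. Training stops when
#' neither the validation loss nor the validation accuracy has improved for
#' `patience` epochs, or at `max_epochs`. Deterministic: parameters start at
#' zero and the objective is convex, so identical data yield identical fits.
#'
#' @param x Training feature matrix (rows = frames), e.g. from
#'   [build_feature_dataset()].
#' @param y Training labels (character/factor), one per row of `x`.
#' @param x_val,y_val Validation features and labels (non-empty).
#' @param class_labels Ordered class labels; defaults to the sorted unique
#'   training labels. Fixed at fit time and stored with the model.
#' @param lr Learning rate.
#' @param l2 L2 penalty on the weights.
#' @param max_epochs,patience Early-stopping control.
#' @param weights,val_weights Optional non-negative per-frame observation
#'   weights. Specimens yield very different frame counts (frame number is
#'   inversely related to sinking speed), so weighting each frame by
#'   `1 / n_frames(specimen)` makes every specimen — and hence every taxon of
#'   a specimen-balanced design — contribute equally to the loss.
#' @return Object of class `taxon_scorer`.
#' @export
fit_taxon_scorer <- function(x, y, x_val, y_val, class_labels = NULL,
                             lr = 0.3, l2 = 1e-3, max_epochs = 200L,
                             patience = 10L, weights = NULL,
                             val_weights = NULL) {
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.character(y); y_val <- as.character(y_val)
  if (length(unique(y)) < 2L)
    stop_invalid("training labels contain a single class; need >= 2")
  if (nrow(x_val) == 0L) stop_invalid("validation set is empty")
  if (is.null(class_labels)) class_labels <- sort(unique(y))
  if (!all(y %in% class_labels) || !all(y_val %in% class_labels))
    stop_invalid("labels outside class_labels")
  C <- length(class_labels)
  n <- nrow(x); d <- ncol(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-9] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  xvs <- sweep(sweep(x_val, 2, center), 2, scale, "/")
  y_idx <- match(y, class_labels)
  yv_idx <- match(y_val, class_labels)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), y_idx)] <- 1
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0)) stop_invalid("invalid training weights")
  wn <- w / sum(w)

  W <- matrix(0, d, C); b <- rep(0, C)
  vW <- matrix(0, d, C); vb <- rep(0, C)
  mom <- 0.9
  log_rows <- vector("list", max_epochs)
  best <- list(loss = Inf, epoch = 0L, W = W, b = b)
  best_acc <- -Inf; best_acc_epoch <- 0L
  for (epoch in seq_len(max_epochs)) {
    P <- softmax_rows(sweep(xs %*% W, 2, b, "+"))
    G <- (P - Y) * wn
    gW <- crossprod(xs, G) + l2 * W
    gb <- colSums(G)
    vW <- mom * vW - lr * gW; vb <- mom * vb - lr * gb
    W <- W + vW; b <- b + vb
    train_loss <- cross_entropy(P, y_idx, w)
    Pv <- softmax_rows(sweep(xvs %*% W, 2, b, "+"))
    val_loss <- cross_entropy(Pv, yv_idx, val_weights)
    ok_v <- max.col(Pv, ties.method = "first") == yv_idx
    val_acc <- if (is.null(val_weights)) mean(ok_v)
               else sum(val_weights * ok_v) / sum(val_weights)
    log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                    val_loss = val_loss, val_acc = val_acc)
    if (val_loss < best$loss)
      best <- list(loss = val_loss, epoch = epoch, W = W, b = b)
    if (val_acc > best_acc) { best_acc <- val_acc; best_acc_epoch <- epoch }
    if (epoch - best$epoch >= patience && epoch - best_acc_epoch >= patience)
      break
  }
  structure(list(class_labels = class_labels, W = best$W, b = best$b,
                 center = center, scale = scale,
                 best_epoch = best$epoch,
                 training_log = do.call(rbind, log_rows[!vapply(
                   log_rows, is.null, NA)]),
                 config = list(lr = lr, l2 = l2, max_epochs = max_epochs,
                               patience = patience),
                 n_train = n, n_val = nrow(x_val), n_features = d),
            class = "taxon_scorer")
}

#' @export
print.taxon_scorer <- function(x, ...) {
  cat(sprintf(
    "<taxon_scorer> %d classes, %d features; trained on %d frames (%d validation)\n",
    length(x$class_labels), x$n_features, x$n_train, x$n_val))
  cat(sprintf("  best epoch %d / %d logged; validation loss %.4f, accuracy %.3f\n",
              x$best_epoch, nrow(x$training_log),
              x$training_log$val_loss[x$best_epoch],
              x$training_log$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.taxon_scorer <- function(object, ...) {
  print(object)
  cat("  classes:", paste(object$class_labels, collapse = ", "), "\n")
  tl <- object$training_log
  cat(sprintf("  final epoch %d: train loss %.4f, val loss %.4f, val acc %.3f\n",
              nrow(tl), tl$train_loss[nrow(tl)], tl$val_loss[nrow(tl)],
              tl$val_acc[nrow(tl)]))
  invisible(object)
}

#' @export
coef.taxon_scorer <- function(object, ...) {
  rbind(`(intercept)` = object$b, object$W)
}

#' Plot the training log of a fitted scorer
#'
#' @param x A `taxon_scorer`.
#' @param ... Unused.
#' @export
plot.taxon_scorer <- function(x, ...) {
  tl <- x$training_log
  graphics::plot(tl$epoch, tl$val_loss, type = "l", col = "firebrick",
                 xlab = "epoch", ylab = "loss",
                 ylim = range(c(tl$val_loss, tl$train_loss)))
  graphics::lines(tl$epoch, tl$train_loss, col = "steelblue")
  graphics::abline(v = x$best_epoch, lty = 2)
  graphics::legend("topright", c("validation", "training"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Score frames with a fitted scorer
#'
#' @param object A `taxon_scorer`.
#' @param newdata Feature matrix (rows = frames), a single feature vector, a
#'   `feature_dataset`, or a frame matrix in `[0, 1]` (features are then
#'   extracted with [frame_features()]).
#' @param type `"score"` for the unbounded per-class score matrix (logits,
#'   no probability squashing), `"class"` for predicted labels, `"prob"` for
#'   softmax probabilities.
#' @param ... Unused.
#' @return Matrix `n x C` (`score`/`prob`) or character vector (`class`).
#' @export
predict.taxon_scorer <- function(object, newdata,
                                 type = c("score", "class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_dataset")) newdata$x
       else if (is.matrix(newdata) && ncol(newdata) == object$n_features)
         newdata
       else if (is.matrix(newdata))   # a raw frame: extract its features
         matrix(frame_features(newdata), nrow = 1)
       else matrix(newdata, nrow = 1)
  if (ncol(x) != object$n_features)
    stop_invalid(sprintf("newdata has %d features; model expects %d",
                         ncol(x), object$n_features))
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  s <- sweep(xs %*% object$W, 2, object$b, "+")
  colnames(s) <- object$class_labels
  switch(type,
         score = s,
         prob = softmax_rows(s),
         class = object$class_labels[apply(s, 1, predict_image)])
}

#' Score a single frame
#'
#' @param model A fitted `taxon_scorer`.
#' @param frame Image matrix in `[0, 1]` (width 496) or a precomputed
#'   feature vector.
#' @return Named numeric score vector, one unbounded score per class.
#' @export
score_image <- function(model, frame) {
  if (!inherits(model, "taxon_scorer"))
    stop_invalid("model must be a fitted taxon_scorer")
  x <- if (is.matrix(frame)) matrix(frame_features(frame), nrow = 1)
       else matrix(frame, nrow = 1)
  drop(predict(model, x, type = "score"))
}

#' Per-image class decision
#'
#' Argmax of an unbounded score vector; exact ties go to the lowest class
#' index, so the decision is deterministic.
#'
#' @param scores Numeric score vector.
#' @return 1-based index of the predicted class.
#' @export
predict_image <- function(scores) {
  if (any(is.na(scores))) stop_invalid("scores contain NA/NaN")
  which.max(scores)
}

#' Save or load a fitted scorer
#'
#' Serializes a `taxon_scorer` to a single JSON file: class labels,
#' parameters (full double precision), feature standardization, training
#' log, and configuration, so fits can be archived and reloaded without
#' binary formats.
#'
#' @param model A fitted `taxon_scorer`.
#' @param path JSON file path.
#' @return `read_scorer` returns the restored `taxon_scorer`.
#' @export
write_scorer <- function(model, path) {
  if (!inherits(model, "taxon_scorer"))
    stop_invalid("model must be a fitted taxon_scorer")
  payload <- list(class_labels = model$class_labels, W = model$W,
                  b = model$b, center = model$center, scale = model$scale,
                  best_epoch = model$best_epoch,
                  training_log = model$training_log, config = model$config,
                  n_train = model$n_train, n_val = model$n_val,
                  n_features = model$n_features)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$W <- matrix(unlist(p$W), nrow = p$n_features)
  structure(list(class_labels = p$class_labels, W = p$W, b = p$b,
                 center = p$center, scale = p$scale,
                 best_epoch = p$best_epoch,
                 training_log = as.data.frame(p$training_log),
                 config = p$config, n_train = p$n_train, n_val = p$n_val,
                 n_features = p$n_features),
            class = "taxon_scorer")
}
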