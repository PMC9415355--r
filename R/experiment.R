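# Orchestration of the two experiments: the balanced sample-size sweep
# (learning curve over training specimens per taxon, fixed test set) and
# stratified grouped k-fold cross-validation. Both operate on a
# `feature_dataset`, so image pixels are touched once, during feature
# extraction; after that, refitting at each training size is cheap.

#' Sweep configuration
#'
#' @param sizes Strictly increasing training sizes (specimens per taxon).
#' @param n_test_per_taxon Fixed test specimens per taxon.
#' @param validation_fraction Fraction of training specimens carved out for
#'   validation (stratified per taxon, floor 1).
#' @param seed Master seed for all splits.
#' @param voting_schemes Subset of `per_image`, `majority`, `score_sum`.
#' @param scorer Named list of arguments passed to [fit_taxon_scorer()].
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(sizes = seq(5L, 50L, 5L), n_test_per_taxon = 10L,
                         validation_fraction = 0.10, seed = 1L,
                         voting_schemes = c("per_image", "majority",
                                            "score_sum"),
                         scorer = list()) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop_invalid("sizes must be strictly increasing")
  voting_schemes <- match.arg(voting_schemes,
                              c("per_image", "majority", "score_sum"),
                              several.ok = TRUE)
  structure(list(sizes = as.integer(sizes),
                 n_test_per_taxon = as.integer(n_test_per_taxon),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), voting_schemes = voting_schemes,
                 scorer = scorer),
            class = "sweep_config")
}

# fit on (train, val) specimen ids, score the held-out specimens, and return
# per-scheme predictions; everything indexed against the cached features
fit_and_score <- function(data, train_ids, val_ids, test_ids, class_labels,
                          scorer_args) {
  meta <- data$meta
  tr <- meta$specimen_id %in% train_ids
  va <- meta$specimen_id %in% val_ids
  stopifnot(!any(meta$specimen_id[tr | va] %in% test_ids))
  # one specimen, one unit of loss: frames are weighted by 1/n_frames
  per_spec_w <- function(idx) {
    nf <- table(meta$specimen_id[idx])
    as.numeric(1 / nf[meta$specimen_id[idx]])
  }
  model <- do.call(fit_taxon_scorer, c(
    list(x = data$x[tr, , drop = FALSE], y = meta$taxon[tr],
         x_val = data$x[va, , drop = FALSE], y_val = meta$taxon[va],
         class_labels = class_labels, weights = per_spec_w(tr),
         val_weights = per_spec_w(va)), scorer_args))
  te <- meta$specimen_id %in% test_ids
  s <- predict(model, data$x[te, , drop = FALSE], type = "score")
  cls_idx <- apply(s, 1, predict_image)
  frame_meta <- meta[te, , drop = FALSE]
  per_spec <- lapply(split(seq_len(nrow(frame_meta)),
                           frame_meta$specimen_id), function(idx) {
    list(true = frame_meta$taxon[idx[1]],
         majority = class_labels[majority_vote(cls_idx[idx],
                                               s[idx, , drop = FALSE],
                                               length(class_labels))],
         score_sum = class_labels[score_sum_vote(s[idx, , drop = FALSE])])
  })
  list(model = model,
       image_true = frame_meta$taxon,
       image_pred = class_labels[cls_idx],
       spec_true = vapply(per_spec, `[[`, "", "true"),
       spec_majority = vapply(per_spec, `[[`, "", "majority"),
       spec_scoresum = vapply(per_spec, `[[`, "", "score_sum"))
}

scheme_confusion <- function(scored, scheme, class_labels) {
  switch(scheme,
         per_image = confusion(scored$image_true, scored$image_pred,
                               class_labels),
         majority = confusion(scored$spec_true, scored$spec_majority,
                              class_labels),
         score_sum = confusion(scored$spec_true, scored$spec_scoresum,
                               class_labels))
}

#' Run the balanced sample-size sweep
#'
#' Draws a fixed test set, then for each training size: takes a balanced
#' nested subsample of the pool, carves out a stratified validation set,
#' fits one scorer, scores every test frame, and evaluates per-image,
#' majority-vote, and score-sum classification. The test specimen set is
#' asserted identical across sizes.
#'
#' @param data A `feature_dataset`.
#' @param cfg A [sweep_config()].
#' @return Object of class `sweep_result`: list with `curve` (long
#'   `data.frame`: size, scheme, accuracy, macro precision/recall, CI),
#'   `metrics[[size]][[scheme]]`, `confusions[[size]][[scheme]]`,
#'   `training[[size]]` (log summary), `test_ids`, `splits`, `class_labels`,
#'   `cfg`.
#' @export
run_sweep <- function(data, cfg = sweep_config()) {
  manifest <- data$manifest
  class_labels <- sort(unique(manifest$taxon))
  split0 <- assign_test_split(manifest, cfg$n_test_per_taxon, cfg$seed)
  pool <- manifest[manifest$specimen_id %in% split0$pool, , drop = FALSE]
  pool_min <- min(table(pool$taxon))
  if (max(cfg$sizes) > pool_min)
    stop_insufficient(sprintf(
      "largest sweep size %d exceeds the smallest per-taxon pool (%d)",
      max(cfg$sizes), pool_min))
  metrics <- list(); confusions <- list(); training <- list(); splits <- list()
  curve <- list()
  test_ref <- sort(split0$test)
  for (size in cfg$sizes) {
    ids <- subsample_balanced(pool, size, cfg$seed)
    tv <- split_validation(manifest[manifest$specimen_id %in% ids, ,
                                    drop = FALSE],
                           cfg$validation_fraction, cfg$seed)
    stopifnot(identical(sort(split0$test), test_ref))
    scored <- fit_and_score(data, tv$train, tv$validation, split0$test,
                            class_labels, cfg$scorer)
    key <- as.character(size)
    splits[[key]] <- list(train = tv$train, val = tv$validation)
    tl <- scored$model$training_log
    training[[key]] <- data.frame(size = size, epochs = nrow(tl),
                                  best_epoch = scored$model$best_epoch,
                                  best_val_loss = min(tl$val_loss),
                                  best_val_acc = max(tl$val_acc))
    metrics[[key]] <- list(); confusions[[key]] <- list()
    for (scheme in cfg$voting_schemes) {
      cm <- scheme_confusion(scored, scheme, class_labels)
      rep <- precision_recall(cm)
      metrics[[key]][[scheme]] <- rep
      confusions[[key]][[scheme]] <- cm
      curve[[length(curve) + 1L]] <- data.frame(
        size = size, scheme = scheme, accuracy = rep$accuracy,
        macro_precision = rep$macro_precision,
        macro_recall = rep$macro_recall,
        ci_precision_lo = rep$ci95_precision["lo"],
        ci_precision_hi = rep$ci95_precision["hi"],
        ci_recall_lo = rep$ci95_recall["lo"],
        ci_recall_hi = rep$ci95_recall["hi"], row.names = NULL)
    }
  }
  structure(list(curve = do.call(rbind, curve), metrics = metrics,
                 confusions = confusions, training = do.call(rbind, training),
                 test_ids = test_ref,
                 splits = list(test = test_ref, sweeps = splits),
                 class_labels = class_labels, cfg = cfg),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d sizes x %d schemes, %d test specimens\n",
              length(unique(x$curve$size)), length(x$cfg$voting_schemes),
              length(x$test_ids)))
  print(x$curve[, c("size", "scheme", "accuracy", "macro_precision",
                    "macro_recall")], row.names = FALSE)
  invisible(x)
}

#' Plot the learning curve of a sweep
#'
#' Accuracy versus training specimens per taxon, one line per voting scheme.
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @export
plot.sweep_result <- function(x, ...) {
  cv <- x$curve
  schemes <- unique(cv$scheme)
  cols <- c(per_image = "gray40", majority = "firebrick",
            score_sum = "steelblue")[schemes]
  graphics::plot(range(cv$size), range(cv$accuracy), type = "n",
                 xlab = "training specimens per taxon", ylab = "accuracy")
  for (sc in schemes) {
    sub <- cv[cv$scheme == sc, ]
    graphics::lines(sub$size, sub$accuracy, type = "b", col = cols[[sc]],
                    pch = 16)
  }
  graphics::legend("bottomright", schemes, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Grouped k-fold cross-validation of the full dataset
#'
#' Each fold is held out in turn as the test set; the remaining specimens
#' are split into training and validation exactly as in the sweep, one model
#' is fitted per fold, and specimen-level majority-vote accuracy is
#' reported per fold with its mean and range.
#'
#' @param data A `feature_dataset`.
#' @param k Number of folds.
#' @param cfg A [sweep_config()] (supplies validation fraction, seed, scorer
#'   arguments).
#' @return Object of class `cv_result`: list with `fold_accuracy` (length
#'   `k`), `mean`, `min`, `max`, `per_image_accuracy`, `fold_of`, `k`.
#' @export
run_cv <- function(data, k = 10L, cfg = sweep_config()) {
  manifest <- data$manifest
  class_labels <- sort(unique(manifest$taxon))
  fold_of <- grouped_kfold(manifest, k, cfg$seed)
  acc <- numeric(k); img_acc <- numeric(k)
  for (fold in 0:(k - 1L)) {
    test_ids <- names(fold_of)[fold_of == fold]
    rest <- manifest[!(manifest$specimen_id %in% test_ids), , drop = FALSE]
    tv <- split_validation(rest, cfg$validation_fraction, cfg$seed + fold)
    scored <- fit_and_score(data, tv$train, tv$validation, test_ids,
                            class_labels, cfg$scorer)
    acc[fold + 1L] <- mean(scored$spec_true == scored$spec_majority)
    img_acc[fold + 1L] <- mean(scored$image_true == scored$image_pred)
  }
  structure(list(fold_accuracy = acc, mean = mean(acc), min = min(acc),
                 max = max(acc), per_image_accuracy = img_acc,
                 fold_of = fold_of, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds: mean majority-vote accuracy %.3f (range %.3f-%.3f)\n",
    x$k, x$mean, x$min, x$max))
  invisible(x)
}

#' Write experiment reports to disk
#'
#' Emits the tables behind the standard figures: `learning_curve.csv`,
#' per-(size, scheme) confusion matrices as CSV with taxon name headers,
#' `metrics.json` keyed by training size and voting scheme,
#' `size_precision.csv` (when per-taxon body sizes are supplied),
#' `cv_accuracy.csv` (when a `cv_result` is supplied), `splits.json`, and a
#' `run_manifest.json` with the configuration and seed for exact re-runs.
#'
#' @param sweep A `sweep_result`.
#' @param out_dir Output directory (created if missing).
#' @param cv Optional `cv_result`.
#' @param taxon_sizes_mm2 Optional named vector of per-taxon mean body sizes.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(sweep, out_dir, cv = NULL, taxon_sizes_mm2 = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  files <- character()
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(sweep$curve, p("learning_curve.csv"), row.names = FALSE)
  files <- c(files, p("learning_curve.csv"))
  for (key in names(sweep$confusions)) {
    for (scheme in names(sweep$confusions[[key]])) {
      f <- p(sprintf("confusion_size%s_%s.csv", key, scheme))
      utils::write.csv(as.data.frame(unclass(
        sweep$confusions[[key]][[scheme]])), f)
      files <- c(files, f)
    }
  }
  metrics <- lapply(sweep$metrics, function(by_scheme)
    lapply(by_scheme, function(m)
      list(accuracy = m$accuracy, macro_precision = m$macro_precision,
           macro_recall = m$macro_recall,
           per_class_precision = as.list(m$per_class_precision),
           per_class_recall = as.list(m$per_class_recall),
           total = m$total)))
  jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p("metrics.json"))
  if (!is.null(taxon_sizes_mm2)) {
    last <- names(sweep$metrics)[length(sweep$metrics)]
    scheme <- if ("majority" %in% names(sweep$metrics[[last]])) "majority"
              else names(sweep$metrics[[last]])[1]
    prec <- sweep$metrics[[last]][[scheme]]$per_class_precision
    tab <- size_precision_table(prec,
                                taxon_sizes_mm2[sweep$class_labels],
                                taxa = sweep$class_labels,
                                training_size = as.integer(last))
    utils::write.csv(tab, p("size_precision.csv"), row.names = FALSE)
    files <- c(files, p("size_precision.csv"))
  }
  if (!is.null(cv)) {
    utils::write.csv(data.frame(fold = seq_len(cv$k) - 1L,
                                majority_accuracy = cv$fold_accuracy,
                                per_image_accuracy = cv$per_image_accuracy),
                     p("cv_accuracy.csv"), row.names = FALSE)
    files <- c(files, p("cv_accuracy.csv"))
  }
  write_splits(sweep$splits, p("splits.json"))
  files <- c(files, p("splits.json"))
  jsonlite::write_json(list(seed = sweep$cfg$seed, sizes = sweep$cfg$sizes,
                            n_test_per_taxon = sweep$cfg$n_test_per_taxon,
                            validation_fraction = sweep$cfg$validation_fraction,
                            voting_schemes = sweep$cfg$voting_schemes,
                            class_labels = sweep$class_labels),
                       p("run_manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p("run_manifest.json"))
  invisible(files)
}

#' Desk-scale reference experiment
#'
#' The package's standard small experiment: an 8-taxon community with
#' moderate sinking-speed spread (about 14-27 frames per specimen), 30
#' specimens per taxon, a fixed test set of 10 specimens per taxon, and a
#' learning-curve sweep over 2, 5, 10, and 20 training specimens per taxon
#' with the reference scorer. Completes in a few minutes on one CPU.
#'
#' @param seed Master seed for generation and splitting.
#' @param sizes Training sizes for the sweep.
#' @param n_taxa,n_specimens_per_taxon,frames_base,n_test_per_taxon
#'   Community and split dimensions.
#' @param scorer Arguments passed on to [fit_taxon_scorer()].
#' @return List with `specs`, `data` (the `feature_dataset`), `cfg`, and
#'   `sweep` (the `sweep_result`).
#' @export
desk_experiment <- function(seed = 1L, sizes = c(2L, 5L, 10L, 20L),
                            n_taxa = 8L, n_specimens_per_taxon = 30L,
                            frames_base = 55, n_test_per_taxon = 10L,
                            scorer = list()) {
  specs <- make_taxon_specs(n_taxa, seed = seed, speed_range = c(2, 4))
  fd <- build_feature_dataset(specs, n_specimens_per_taxon,
                              frames_base = frames_base, seed = seed,
                              height = 496L)
  cfg <- sweep_config(sizes = sizes, n_test_per_taxon = n_test_per_taxon,
                      seed = seed, scorer = scorer)
  list(specs = specs, data = fd, cfg = cfg, sweep = run_sweep(fd, cfg))
}
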