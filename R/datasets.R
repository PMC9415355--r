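# Specimen-grouped, leakage-free dataset splitting. All assignment happens at
# the specimen level; every image inherits its specimen's assignment, so no
# image can appear on both sides of a split.

check_manifest <- function(manifest) {
  if (!is.data.frame(manifest) ||
      !all(c("specimen_id", "taxon") %in% names(manifest)))
    stop_invalid("manifest must be a data.frame with specimen_id and taxon columns")
  if (anyDuplicated(manifest$specimen_id))
    stop_invalid("manifest has duplicated specimen_id values")
  invisible(manifest)
}

#' Draw the fixed test split
#'
#' Selects exactly `n_test_per_taxon` specimens per taxon uniformly without
#' replacement as the test set; the remainder is the training pool. The test
#' set is fixed once per experiment so every model is evaluated on the same
#' specimens.
#'
#' @param manifest `data.frame` with `specimen_id` and `taxon` columns.
#' @param n_test_per_taxon Test specimens per taxon (default 10).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List with `test` and `pool` character vectors of specimen ids.
#' @export
assign_test_split <- function(manifest, n_test_per_taxon = 10L, seed = 1L) {
  check_manifest(manifest)
  taxa <- sort(unique(manifest$taxon))
  counts <- table(manifest$taxon)
  short <- taxa[counts[taxa] <= n_test_per_taxon]
  if (n_test_per_taxon > 0L && length(short) > 0L)
    stop_insufficient(sprintf(
      "taxa with too few specimens for %d test + >=1 training: %s",
      n_test_per_taxon, paste(short, collapse = ", ")))
  test <- character()
  with_seed(seed, {
    for (tx in taxa) {
      ids <- sort(manifest$specimen_id[manifest$taxon == tx])
      if (n_test_per_taxon > 0L)
        test <- c(test, sample(ids, n_test_per_taxon))
    }
  })
  list(test = test, pool = setdiff(manifest$specimen_id, test))
}

#' Balanced nested subsample of the training pool
#'
#' Draws exactly `n_per_taxon` specimens per taxon. Subsamples are nested
#' under a fixed seed: the subsample for `n` is a subset of the subsample for
#' any `n' > n`, so points on a learning curve differ only by added data.
#'
#' @param manifest Pool manifest (`specimen_id`, `taxon`).
#' @param n_per_taxon Specimens to draw per taxon.
#' @param seed Integer seed.
#' @return Character vector of selected specimen ids.
#' @export
subsample_balanced <- function(manifest, n_per_taxon, seed = 1L) {
  check_manifest(manifest)
  taxa <- sort(unique(manifest$taxon))
  out <- character()
  for (tx in taxa) {
    ids <- sort(manifest$specimen_id[manifest$taxon == tx])
    if (length(ids) < n_per_taxon)
      stop_insufficient(sprintf("taxon %s has %d pool specimens, need %d",
                                tx, length(ids), n_per_taxon))
    # one permutation per (seed, taxon); taking prefixes nests the subsamples
    perm <- with_seed(derive_seed(seed, tx), sample(ids))
    out <- c(out, perm[seq_len(n_per_taxon)])
  }
  out
}

#' Carve a validation set out of the training specimens
#'
#' Stratified per taxon: each taxon contributes
#' `max(1, round(fraction * n_taxon))` validation specimens (round half up),
#' so no taxon is absent from validation even at small training sizes.
#'
#' @param manifest Manifest restricted to the training specimens.
#' @param fraction Validation fraction (default 0.10).
#' @param seed Integer seed.
#' @return List with disjoint, exhaustive `train` and `validation` id vectors.
#' @export
split_validation <- function(manifest, fraction = 0.10, seed = 1L) {
  check_manifest(manifest)
  if (fraction <= 0 || fraction >= 1)
    stop_invalid("fraction must lie in (0, 1)")
  taxa <- sort(unique(manifest$taxon))
  counts <- table(manifest$taxon)
  if (any(counts[taxa] < 2))
    stop_insufficient(sprintf(
      "taxa with a single training specimen cannot be split: %s",
      paste(taxa[counts[taxa] < 2], collapse = ", ")))
  val <- character()
  with_seed(seed, {
    for (tx in taxa) {
      ids <- sort(manifest$specimen_id[manifest$taxon == tx])
      n_val <- max(1L, as.integer(round_half_up(fraction * length(ids))))
      val <- c(val, sample(ids, n_val))
    }
  })
  list(train = setdiff(manifest$specimen_id, val), validation = val)
}

#' Stratified grouped k-fold assignment
#'
#' Partitions specimens into `k` folds, stratified by taxon: within each
#' taxon, specimen counts across folds differ by at most one, and no specimen
#' (hence no image) appears in two folds.
#'
#' @param manifest Manifest (`specimen_id`, `taxon`).
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed.
#' @return Named integer vector mapping specimen_id to fold index in
#'   `0:(k-1)`.
#' @export
grouped_kfold <- function(manifest, k = 10L, seed = 1L) {
  check_manifest(manifest)
  if (k < 2) stop_invalid("k must be >= 2 (k = 1 leaves no held-out data)")
  counts <- table(manifest$taxon)
  if (any(counts < k))
    stop_invalid(sprintf("k = %d exceeds the specimen count of taxa: %s", k,
                         paste(names(counts)[counts < k], collapse = ", ")))
  taxa <- sort(unique(manifest$taxon))
  fold_of <- integer()
  with_seed(seed, {
    for (ti in seq_along(taxa)) {
      ids <- sample(sort(manifest$specimen_id[manifest$taxon == taxa[ti]]))
      # rotate the fold sequence per taxon so remainders spread across folds
      folds <- (seq_along(ids) - 1L + ti - 1L) %% k
      names(folds) <- ids
      fold_of <- c(fold_of, folds)
    }
  })
  fold_of[manifest$specimen_id]
}

#' Write or read dataset splits as JSON
#'
#' Serializes splits as
#' `{"test": [...], "sweeps": {"<size>": {"train": [...], "val": [...]}}}`.
#'
#' @param splits List with `test` and `sweeps` entries as above.
#' @param path JSON file path.
#' @return `read_splits` returns the splits list.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(splits, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
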