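# Brute-force oracles, independent of the package's implementation paths.

# Connected components by queue-based flood fill in plain R. Returns a list
# of sorted column-major pixel index vectors, one per component.
bf_components <- function(fg, connectivity = 8) {
  h <- nrow(fg); w <- ncol(fg)
  dirs <- expand.grid(dr = -1:1, dc = -1:1)
  dirs <- dirs[!(dirs$dr == 0 & dirs$dc == 0), ]
  if (connectivity == 4) dirs <- dirs[abs(dirs$dr) + abs(dirs$dc) == 1, ]
  lab <- matrix(0L, h, w)
  comps <- list()
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!fg[i, j] || lab[i, j]) next
    id <- length(comps) + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- id
    px <- integer()
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      px <- c(px, (p[2] - 1L) * h + p[1])
      for (k in seq_len(nrow(dirs))) {
        ni <- p[1] + dirs$dr[k]; nj <- p[2] + dirs$dc[k]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w && fg[ni, nj] &&
            !lab[ni, nj]) {
          lab[ni, nj] <- id
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
    comps[[id]] <- sort(px)
  }
  comps
}

# Maximum pairwise Euclidean distance over ALL foreground pixel centers.
bf_max_diameter <- function(mask) {
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) < 2) return(0)
  max(as.vector(stats::dist(fg)))
}

# Shoelace polygon area.
bf_polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

# Metrics by direct label counting.
bf_metrics <- function(true, pred, classes) {
  acc <- mean(true == pred)
  prec <- vapply(classes, function(cl) {
    n_pred <- sum(pred == cl)
    if (n_pred == 0) 0 else sum(pred == cl & true == cl) / n_pred
  }, 0)
  rec <- vapply(classes, function(cl) {
    n_true <- sum(true == cl)
    if (n_true == 0) 0 else sum(pred == cl & true == cl) / n_true
  }, 0)
  list(accuracy = acc, precision = unname(prec), recall = unname(rec))
}

# A bright frame with dark axis-aligned rectangles. `rects` is a list of
# c(r0, c0, r1, c1) in 1-based inclusive coordinates.
block_frame <- function(h, w, rects, dark = 0.1, bright = 0.95) {
  f <- matrix(bright, h, w)
  for (r in rects) f[r[1]:r[3], r[2]:r[4]] <- dark
  f
}

# A connected random-walk blob frame (8-connected by construction).
random_blob_frame <- function(seed, h = 40, w = 40, n_steps = 80) {
  set.seed(seed)
  f <- matrix(0.95, h, w)
  i <- h %/% 2L; j <- w %/% 2L
  for (s in seq_len(n_steps)) {
    f[i, j] <- 0.1
    i <- min(max(i + sample(-1:1, 1), 2L), h - 1L)
    j <- min(max(j + sample(-1:1, 1), 2L), w - 1L)
  }
  f
}

# Manifest of n_taxa x n_per_taxon specimens.
make_manifest <- function(n_taxa, n_per_taxon, prefix = "t") {
  taxa <- sprintf("%s%02d", prefix, seq_len(n_taxa))
  data.frame(
    specimen_id = as.vector(vapply(taxa, function(tx)
      sprintf("%s_s%03d", tx, seq_len(n_per_taxon)),
      character(n_per_taxon))),
    taxon = rep(taxa, each = n_per_taxon),
    stringsAsFactors = FALSE)
}

# Small shared rendered dataset, built once per test run.
.tiny_cache <- new.env(parent = emptyenv())
tiny_feature_dataset <- function() {
  if (is.null(.tiny_cache$fd)) {
    specs <- make_taxon_specs(3, seed = 42)
    .tiny_cache$fd <- build_feature_dataset(
      specs, n_specimens_per_taxon = 8, frames_base = 12, seed = 42,
      height = 496L)
  }
  .tiny_cache$fd
}
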