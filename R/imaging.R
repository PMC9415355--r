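# Silhouette segmentation and geometric measurement.
#
# Conventions fixed for bit-exact reproducibility: 8-connected components for
# the blob; perimeter = count of foreground pixels with at least one
# 4-neighbour outside the blob; coordinates 0-based could be ambiguous, so all
# coordinates here are 1-based (row, col), origin top-left, and bounding boxes
# are inclusive.

# Otsu's automatic threshold on a 256-bin histogram of intensities in [0,1].
# Returns a value t such that `pixel < t` is the foreground test.
otsu_threshold <- function(v) {
  counts <- .hist256(v)
  n <- length(v)
  p <- counts / n
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t <- which.max(sigma_b[1:255])   # split: bins <= t-1 vs > t-1
  t / 256
}

# Fill holes: complement components (4-connected) that do not touch the
# matrix border are interior holes.
fill_holes <- function(mask) {
  comp <- .label_mask(!mask, 4L)
  if (!any(comp > 0L)) return(mask)
  outside <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1],
                      comp[, ncol(comp)]))
  hole <- comp > 0L & !(comp %in% outside)
  mask[hole] <- TRUE
  mask
}

#' Detect the specimen silhouette in a frame
#'
#' Thresholds the frame (pixels strictly darker than the threshold are
#' foreground), keeps the largest 8-connected component, and fills interior
#' holes so translucent body parts do not fragment the area measurement.
#'
#' @param frame Numeric matrix of intensities in `[0, 1]`.
#' @param threshold `"otsu"` for Otsu's automatic threshold, or a fixed
#'   numeric cutoff.
#' @return Object of class `blob_mask`: list with `mask` (logical matrix
#'   congruent with the frame), `n_foreground`, and `threshold`.
#'   Signals a condition of class `specvote_no_blob` if no pixel falls below
#'   the threshold (empty cuvette frame); callers typically drop such frames
#'   with a logged count.
#' @export
detect_blob <- function(frame, threshold = "otsu") {
  check_frame(frame)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(as.vector(frame))
         else as.numeric(threshold)
  fg <- frame < thr
  if (!any(fg)) stop_no_blob("no pixel below threshold: empty frame")
  # label within the foreground bounding box only, then map back
  w <- which(fg) - 1L
  rr <- range(w %% nrow(fg)) + 1L; cc <- range(w %/% nrow(fg)) + 1L
  sub <- fg[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  lab <- .label_mask(sub, 8L)
  sizes <- tabulate(lab[lab > 0L])
  submask <- fill_holes(lab == which.max(sizes))
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  mask[rr[1]:rr[2], cc[1]:cc[2]] <- submask
  structure(list(mask = mask, n_foreground = sum(submask), threshold = thr),
            class = "blob_mask")
}

#' @export
print.blob_mask <- function(x, ...) {
  cat(sprintf("<blob_mask> %d foreground px in %dx%d frame (threshold %.4f)\n",
              x$n_foreground, nrow(x$mask), ncol(x$mask), x$threshold))
  invisible(x)
}

#' Geometric features of a silhouette
#'
#' Computes the blob measurements stored per frame by the imaging system:
#' area (foreground pixel count), perimeter (number of foreground pixels on
#' the 4-connected outer boundary), maximum diameter (max Feret: largest
#' Euclidean distance between any two silhouette pixel centers, attained on
#' the convex hull), centroid, and the inclusive bounding box.
#'
#' @param blob A `blob_mask` (or bare logical matrix).
#' @return Object of class `geometric_features`: list with `area`,
#'   `perimeter`, `max_diameter`, `centroid` (row, col), and `bbox`
#'   (row_min, col_min, row_max, col_max).
#' @export
blob_features <- function(blob) {
  full <- if (inherits(blob, "blob_mask")) blob$mask else blob
  if (!is.logical(full) || !any(full)) stop_invalid("empty blob mask")
  fg <- which(full, arr.ind = TRUE)
  area <- nrow(fg)
  # perimeter is computed on the bounding-box submask for speed
  rr <- range(fg[, 1]); cc <- range(fg[, 2])
  mask <- full[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core & pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  perimeter <- sum(core & !interior)
  if (area == 1L) {
    maxd <- 0
  } else {
    hull <- grDevices::chull(fg[, 2], fg[, 1])
    pts <- fg[hull, , drop = FALSE]
    maxd <- sqrt(max(as.vector(stats::dist(pts))^2))
  }
  structure(list(area = area, perimeter = perimeter, max_diameter = maxd,
                 centroid = c(row = mean(fg[, 1]), col = mean(fg[, 2])),
                 bbox = c(row_min = min(fg[, 1]), col_min = min(fg[, 2]),
                          row_max = max(fg[, 1]), col_max = max(fg[, 2]))),
            class = "geometric_features")
}

#' @export
print.geometric_features <- function(x, ...) {
  cat(sprintf(
    "<geometric_features> area %d px, perimeter %d px, max diameter %.2f px\n",
    x$area, x$perimeter, x$max_diameter))
  invisible(x)
}

#' Crop a frame to the standard cuvette geometry
#'
#' Output width is always the 496-px cuvette width; output height is
#' `max(crop_height, blob bounding-box height)` (tall specimens are cropped
#' with a greater height). The vertical window is centered on the blob's
#' vertical center, clamped to the frame, and padded with background
#' intensity where it extends beyond the sensor.
#'
#' @param frame Input frame, width must be 496 px.
#' @param blob The frame's `blob_mask` (or its `geometric_features`).
#' @param crop_height Standard crop height in px.
#' @param background Padding intensity.
#' @return Cropped frame, `496` columns and `max(crop_height, blob height)`
#'   rows.
#' @export
crop_to_standard <- function(frame, blob, crop_height = 496L,
                             background = 0.95) {
  check_frame(frame)
  if (ncol(frame) != 496L)
    stop_invalid("frame width must be 496 px (cuvette-standard geometry)")
  feats <- if (inherits(blob, "geometric_features")) blob else blob_features(blob)
  bb <- feats$bbox
  blob_h <- bb["row_max"] - bb["row_min"] + 1L
  out_h <- max(as.integer(crop_height), as.integer(blob_h))
  center <- (bb["row_min"] + bb["row_max"]) / 2
  h <- nrow(frame)
  s <- round_half_up(center - (out_h - 1) / 2)
  if (out_h <= h) {
    s <- min(max(s, 1L), h - out_h + 1L)
    frame[s:(s + out_h - 1L), , drop = FALSE]
  } else {
    out <- matrix(background, nrow = out_h, ncol = ncol(frame))
    top <- floor((out_h - h) / 2)
    out[(top + 1L):(top + h), ] <- frame
    out
  }
}

#' Estimate specimen body size in mm^2
#'
#' The mean silhouette area across all frames of a specimen characterizes its
#' body size. Pixel areas are converted to mm^2 using the cuvette field of
#' view: `field_width_mm` of real width maps onto `field_width_px` image
#' columns, giving a pixel area of `(field_width_mm / field_width_px)^2`
#' (about 4.06e-4 mm^2 at the 10 mm / 496 px default).
#'
#' @param areas Numeric vector of per-frame blob areas in pixels.
#' @param field_width_mm,field_width_px Field-of-view calibration.
#' @return Object of class `body_size`: list with `mean_area_px`,
#'   `mean_area_mm2`, `px_to_mm2`.
#' @export
estimate_body_size <- function(areas, field_width_mm = 10,
                               field_width_px = 496L) {
  if (length(areas) == 0L) stop_invalid("at least one area is required")
  if (any(areas < 1)) stop_invalid("areas must be >= 1 px")
  px_to_mm2 <- (field_width_mm / field_width_px)^2
  mean_px <- mean(areas)
  structure(list(mean_area_px = mean_px,
                 mean_area_mm2 = mean_px * px_to_mm2,
                 px_to_mm2 = px_to_mm2),
            class = "body_size")
}

#' @export
print.body_size <- function(x, ...) {
  cat(sprintf("<body_size> mean area %.1f px = %.4g mm^2 (%.4g mm^2/px)\n",
              x$mean_area_px, x$mean_area_mm2, x$px_to_mm2))
  invisible(x)
}

#' Per-frame geometric features of a specimen record
#'
#' Runs blob detection on every frame and tabulates the stored geometric
#' features, mirroring the per-image text file the imaging system writes.
#' Frames where no blob is found are dropped with a warning.
#'
#' @param record A `specimen_record`.
#' @param threshold Passed to [detect_blob()].
#' @return `data.frame` with columns `specimen_id, frame, view, area_px,
#'   perimeter_px, max_diameter_px`; the number of dropped frames is attached
#'   as attribute `n_dropped`.
#' @export
frame_geometry <- function(record, threshold = "otsu") {
  rows <- list()
  dropped <- 0L
  for (i in seq_along(record$frames)) {
    feats <- tryCatch(blob_features(detect_blob(record$frames[[i]], threshold)),
                      specvote_no_blob = function(e) NULL)
    if (is.null(feats)) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = record$specimen_id, frame = i, view = record$views[i],
      area_px = feats$area, perimeter_px = feats$perimeter,
      max_diameter_px = feats$max_diameter, stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    warning(sprintf("%s: dropped %d frame(s) with no detectable blob",
                    record$specimen_id, dropped))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen_id = character(), frame = integer(),
               view = character(), area_px = integer(),
               perimeter_px = integer(), max_diameter_px = numeric())
  attr(out, "n_dropped") <- dropped
  out
}
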