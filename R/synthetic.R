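#' Construct a synthetic taxon specification
#'
#' A taxon spec parameterizes the silhouette generator: body size and its
#' between-specimen spread, body shape (superellipse elongation plus thin
#' appendages), silhouette darkness, sinking speed (which controls how many
#' frames a specimen yields at a fixed camera frame rate), and texture noise.
#'
#' @param taxon_id Integer index of the taxon (0-based class index).
#' @param name Taxon label.
#' @param base_area_mm2 Mean silhouette area across specimens, in mm^2.
#' @param area_cv Coefficient of variation of specimen area (log-normal draw).
#' @param elongation Major/minor axis ratio of the body, `>= 1`.
#' @param n_appendages Number of thin radial appendages (legs, cerci, gills).
#' @param appendage_length_frac Appendage length as a fraction of the body
#'   major semi-axis, in `[0, 1]`.
#' @param gray_level Silhouette intensity in `[0, 1)`; the backlit background
#'   is bright (0.95).
#' @param sinking_speed Relative sinking speed; frames per specimen scale as
#'   `frames_base / sinking_speed`.
#' @param texture_noise Additive pixel-noise level in `[0, 1]`.
#' @return An object of class `taxon_spec`.
#' @export
taxon_spec <- function(taxon_id, name, base_area_mm2, area_cv = 0.25,
                       elongation = 2, n_appendages = 0L,
                       appendage_length_frac = 0.4, gray_level = 0.25,
                       sinking_speed = 1, texture_noise = 0.5) {
  if (!is.numeric(base_area_mm2) || base_area_mm2 <= 0)
    stop_invalid("base_area_mm2 must be positive")
  if (elongation < 1) stop_invalid("elongation must be >= 1")
  if (gray_level < 0 || gray_level >= 0.95)
    stop_invalid("gray_level must lie in [0, background)")
  if (sinking_speed <= 0) stop_invalid("sinking_speed must be positive")
  if (area_cv < 0) stop_invalid("area_cv must be non-negative")
  if (appendage_length_frac < 0 || appendage_length_frac > 1)
    stop_invalid("appendage_length_frac must lie in [0, 1]")
  structure(list(
    taxon_id = as.integer(taxon_id), name = as.character(name),
    base_area_mm2 = base_area_mm2, area_cv = area_cv,
    elongation = elongation, n_appendages = as.integer(n_appendages),
    appendage_length_frac = appendage_length_frac, gray_level = gray_level,
    sinking_speed = sinking_speed, texture_noise = texture_noise
  ), class = "taxon_spec")
}

#' @export
print.taxon_spec <- function(x, ...) {
  cat(sprintf(
    "<taxon_spec> %s (id %d): area %.3g mm^2 (cv %.2f), elong %.2f, %d appendages, sink %.3g\n",
    x$name, x$taxon_id, x$base_area_mm2, x$area_cv, x$elongation,
    x$n_appendages, x$sinking_speed))
  invisible(x)
}

# Mean images per specimen observed for a 16-taxon freshwater
# macroinvertebrate community imaged at 50 fps; spans 16 (fast-sinking
# bivalves) to 360 (slow-sinking stonefly larvae).
.mean_frames_16 <- c(162, 67, 132, 61, 67, 43, 360, 166, 161, 202, 257, 16,
                     102, 40, 200, 89)

#' Generate a community of synthetic taxon specifications
#'
#' Produces `n_taxa` pairwise-distinct specs whose body sizes span at least an
#' order of magnitude and whose sinking speeds yield frame counts from roughly
#' 16 to 360 images per specimen at the default `frames_base = 360`. For
#' `n_taxa = 16` the per-taxon frame-count means reproduce the empirical
#' distribution of a real freshwater community; for other community sizes
#' speeds are log-spaced over the same range.
#'
#' @param n_taxa Number of taxa, `>= 2`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param speed_range Range of sinking speeds (log-spaced across taxa).
#'   The default spans the full empirical frame-count spread (16-360 images
#'   per specimen at `frames_base = 360`); desk-scale experiments that want
#'   roughly equal frame counts per specimen can pass a narrow range such as
#'   `c(2, 4)`. Ignored for `n_taxa = 16`, where the empirical per-taxon
#'   means are used.
#' @return List of [taxon_spec] objects.
#' @export
make_taxon_specs <- function(n_taxa, seed = 1L, speed_range = c(1, 22.5)) {
  if (!is.numeric(n_taxa) || n_taxa < 2)
    stop_invalid("n_taxa must be >= 2 (classification needs at least two classes)")
  n_taxa <- as.integer(n_taxa)
  with_seed(seed, {
    areas <- exp(seq(log(0.5), log(25), length.out = n_taxa))
    areas <- areas * exp(stats::rnorm(n_taxa, 0, 0.05))
    elong <- rep(c(1.4, 2.2, 3.0, 1.8, 2.6, 1.2, 3.4, 2.0), length.out = n_taxa)
    napp <- rep(c(0L, 2L, 4L, 6L, 3L, 1L, 5L, 2L), length.out = n_taxa)
    alen <- rep(c(0.3, 0.5, 0.4, 0.6, 0.35, 0.45, 0.55, 0.25), length.out = n_taxa)
    gray <- rep(seq(0.1, 0.45, length.out = 8), length.out = n_taxa)
    tex <- rep(c(0.5, 0.4, 0.6, 0.45, 0.55, 0.5, 0.35, 0.6), length.out = n_taxa)
    if (n_taxa == 16L) {
      speeds <- 360 / .mean_frames_16
    } else {
      speeds <- exp(seq(log(speed_range[1]), log(speed_range[2]),
                        length.out = n_taxa))
      speeds <- sample(speeds)
    }
    lapply(seq_len(n_taxa), function(i) {
      taxon_spec(taxon_id = i - 1L,
                 name = sprintf("taxon_%02d", i),
                 base_area_mm2 = areas[i], area_cv = 0.2,
                 elongation = elong[i], n_appendages = napp[i],
                 appendage_length_frac = alen[i], gray_level = gray[i],
                 sinking_speed = speeds[i], texture_noise = tex[i])
    })
  })
}

# superellipse |u/a|^p + |v/b|^p <= 1 area constant: A = c_p * a * b
.se_p <- 2.5
.se_cp <- 4 * gamma(1 + 1 / .se_p)^2 / gamma(1 + 2 / .se_p)

# Body thickness as a fraction of the minor axis: a specimen seen edge-on
# shows this fraction of its broadside width. Viewing angle is then a major
# source of single-frame ambiguity, which specimen-level voting compensates.
.view_b_thickness <- 0.6

#' Render one synthetic silhouette frame
#'
#' Draws a dark superellipse body with thin radial appendages on a bright
#' backlit background, at a given in-plane rotation and position, then adds
#' Gaussian texture noise. The second camera view (`view_B`) shows the body
#' rotated 90 degrees about the vertical axis, i.e. with its minor axis
#' foreshortened to the body thickness.
#'
#' @param spec A [taxon_spec].
#' @param area_px Silhouette area of this specimen in pixels (view A).
#' @param angle In-plane rotation, radians.
#' @param center `(row, col)` of the body centroid.
#' @param view `"view_A"` or `"view_B"`.
#' @param height,width Sensor frame size in pixels.
#' @param background Background intensity.
#' @param noise_sd Gaussian noise standard deviation (0 disables noise; noise
#'   consumes the current RNG stream).
#' @param oop_phase Out-of-plane tumbling phase in radians, or `NULL`. The
#'   apparent body width varies between the full minor axis and the body
#'   thickness as the specimen rotates about its sinking axis; the second
#'   camera sees the same rotation a quarter turn out of phase. With
#'   `NULL`, view A shows the full width and view B the thickness.
#' @return Numeric matrix in `[0, 1]` of size `height x width`.
#' @export
render_frame <- function(spec, area_px, angle = 0, center = NULL,
                         view = "view_A", height = 700L, width = 496L,
                         background = 0.95, noise_sd = NULL,
                         oop_phase = NULL) {
  if (is.null(center)) center <- c(height / 2, width / 2)
  if (is.null(noise_sd)) noise_sd <- 0.04 * spec$texture_noise
  k <- area_px / .se_cp
  a <- sqrt(k * spec$elongation)
  b <- sqrt(k / spec$elongation)
  if (is.null(oop_phase)) {
    if (view == "view_B") b <- b * .view_b_thickness
  } else {
    ph <- oop_phase + if (view == "view_B") pi / 2 else 0
    b <- b * (.view_b_thickness + (1 - .view_b_thickness) * abs(cos(ph)))
  }
  frame <- matrix(background, nrow = height, ncol = width)

  # render only a local window around the body
  alen <- spec$appendage_length_frac * a
  r <- ceiling(a + alen) + 3
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(height, ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(width, ceiling(center[2] + r))
  if (r1 >= r0 && c1 >= c0) {
    rows <- r0:r1; cols <- c0:c1
    app_theta <- if (spec$n_appendages > 0L && alen > 1)
      seq(0, 2 * pi, length.out = spec$n_appendages + 1L)[-1] + 0.4
    else numeric()
    inside <- .silhouette_window_mask(rows - center[1], cols - center[2],
                                      angle, a, b, .se_p, app_theta, alen,
                                      max(1, 0.035 * a))
    sub <- frame[rows, cols, drop = FALSE]
    sub[inside] <- spec$gray_level
    frame[rows, cols] <- sub
  }
  if (noise_sd > 0) {
    frame <- .clamp01(frame + stats::rnorm(height * width, 0, noise_sd))
    dim(frame) <- c(height, width)
  }
  frame
}

#' Generate the image sequence of one specimen
#'
#' Simulates a specimen sinking through the cuvette: the frame count is
#' `clamp(round(frames_base / sinking_speed), 1, frame_cap)` (slow sinkers are
#' photographed more often at a fixed frame rate), the specimen area is drawn
#' once per specimen from a log-normal with mean `base_area_mm2` and CV
#' `area_cv`, and each frame renders the silhouette with a tumbling in-plane
#' rotation (random walk, step sd 10 degrees) and downward vertical drift.
#' Frames alternate between the two orthogonal camera views.
#'
#' @param spec A [taxon_spec].
#' @param specimen_id Identifier string; combined with `seed` to derive the
#'   specimen's private RNG stream, so output is independent of generation
#'   order.
#' @param frames_base Frame-count scale (frames at sinking speed 1).
#' @param seed Master integer seed.
#' @param frame_cap Maximum frames per specimen.
#' @param height,width Sensor frame size (pre-crop); width is fixed by the
#'   cuvette at 496 px.
#' @param background Background intensity.
#' @return An object of class `specimen_record`: list with `specimen_id`,
#'   `taxon_id`, `taxon`, `area_mm2`, `frames` (list of matrices), and
#'   `views` (per-frame `"view_A"`/`"view_B"` tags).
#' @export
generate_specimen <- function(spec, specimen_id, frames_base = 360, seed = 1L,
                              frame_cap = 400L, height = 700L, width = 496L,
                              background = 0.95) {
  if (!is.numeric(frames_base) || frames_base <= 0)
    stop_invalid("frames_base must be positive")
  n_frames <- min(max(1L, as.integer(round(frames_base / spec$sinking_speed))),
                  frame_cap)
  px_to_mm2 <- (10 / 496)^2
  # Kinderman-Ramage normal sampler: same quality, much cheaper per draw for
  # the per-pixel texture noise
  with_seed(derive_seed(seed, specimen_id), normal_kind = "Kinderman-Ramage", {
    sdlog <- sqrt(log(1 + spec$area_cv^2))
    meanlog <- log(spec$base_area_mm2) - sdlog^2 / 2
    area_mm2 <- stats::rlnorm(1, meanlog, sdlog)
    area_px <- area_mm2 / px_to_mm2
    angle0 <- stats::runif(1, 0, 2 * pi)
    steps <- stats::rnorm(n_frames, 0, 10 * pi / 180)
    angles <- angle0 + cumsum(steps)
    # out-of-plane tumbling about the sinking axis modulates apparent width
    phases <- stats::runif(1, 0, 2 * pi) +
      cumsum(stats::rnorm(n_frames, 0, 20 * pi / 180))
    rows <- height * seq(0.2, 0.8, length.out = n_frames) +
      stats::rnorm(n_frames, 0, 4)
    cols <- width / 2 + stats::rnorm(n_frames, 0, 8)
    views <- rep(c("view_A", "view_B"), length.out = n_frames)
    frames <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      frames[[i]] <- render_frame(spec, area_px, angle = angles[i],
                                  center = c(rows[i], cols[i]),
                                  view = views[i], height = height,
                                  width = width, background = background,
                                  oop_phase = phases[i])
    }
    structure(list(specimen_id = as.character(specimen_id),
                   taxon_id = spec$taxon_id, taxon = spec$name,
                   area_mm2 = area_mm2, frames = frames, views = views),
              class = "specimen_record")
  })
}

#' @export
print.specimen_record <- function(x, ...) {
  cat(sprintf("<specimen_record> %s (%s): %d frames, %.3g mm^2\n",
              x$specimen_id, x$taxon, length(x$frames), x$area_mm2))
  invisible(x)
}

#' Generate a labeled silhouette-sequence dataset on disk
#'
#' Writes one folder per specimen (`<out>/<taxon>/<specimen_id>/`) containing
#' its frames as 8-bit grayscale PNGs named `frame_<k>_<view>.png`, plus a
#' manifest CSV `manifest.csv` with columns
#' `specimen_id,taxon,n_frames,views`.
#'
#' @param specs List of [taxon_spec] objects.
#' @param n_specimens_per_taxon Specimens generated per taxon.
#' @param frames_base Frame-count scale, see [generate_specimen()].
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param ... Passed to [generate_specimen()].
#' @return The manifest `data.frame`, invisibly also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(specs, n_specimens_per_taxon, frames_base = 360,
                             seed = 1L, out_dir, ...) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  rows <- list()
  for (spec in specs) {
    for (j in seq_len(n_specimens_per_taxon)) {
      sid <- sprintf("%s_s%03d", spec$name, j)
      rec <- generate_specimen(spec, sid, frames_base = frames_base,
                               seed = seed, ...)
      dir <- file.path(out_dir, spec$name, sid)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (k in seq_along(rec$frames)) {
        png::writePNG(rec$frames[[k]],
                      file.path(dir, sprintf("frame_%03d_%s.png", k,
                                             rec$views[k])))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = sid, taxon = spec$name,
        n_frames = length(rec$frames),
        views = paste(rec$views, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate specimen records in memory
#'
#' Like [generate_dataset()] but returns the specimen records themselves (no
#' PNG output). Convenient for experiments that extract features on the fly.
#'
#' @inheritParams generate_dataset
#' @return List of `specimen_record` objects with a `manifest` attribute.
#' @export
generate_records <- function(specs, n_specimens_per_taxon, frames_base = 360,
                             seed = 1L, ...) {
  recs <- list()
  for (spec in specs) {
    for (j in seq_len(n_specimens_per_taxon)) {
      sid <- sprintf("%s_s%03d", spec$name, j)
      recs[[sid]] <- generate_specimen(spec, sid, frames_base = frames_base,
                                       seed = seed, ...)
    }
  }
  manifest <- data.frame(
    specimen_id = vapply(recs, `[[`, "", "specimen_id"),
    taxon = vapply(recs, `[[`, "", "taxon"),
    n_frames = vapply(recs, function(r) length(r$frames), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(recs, "manifest") <- manifest
  recs
}

#' Read a specimen's frames back from disk
#'
#' Loads the PNG frames of one specimen folder written by
#' [generate_dataset()] (or any folder of `frame_<k>_<view>.png` files,
#' 8-bit grayscale) into a `specimen_record`.
#'
#' @param dir Specimen directory.
#' @param taxon Taxon label (defaults to the parent directory name).
#' @param taxon_id Integer class index, if known.
#' @return A `specimen_record` (with `area_mm2 = NA`: body size is estimated
#'   from the frames, not stored).
#' @export
read_specimen <- function(dir, taxon = basename(dirname(dir)),
                          taxon_id = NA_integer_) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop_invalid(paste("no PNG frames in", dir))
  frames <- lapply(files, function(f) {
    px <- png::readPNG(f)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    px
  })
  views <- ifelse(grepl("view_B", basename(files)), "view_B", "view_A")
  structure(list(specimen_id = basename(dir), taxon_id = taxon_id,
                 taxon = taxon, area_mm2 = NA_real_, frames = frames,
                 views = views),
            class = "specimen_record")
}
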