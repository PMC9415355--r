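# Image resampling and augmentation. All geometric transforms use the
# convention x = column, y = row, origin at the image center, bilinear
# interpolation, constant background padding.

# Row/column resampling weights. `bilinear` maps output pixel centers to
# input coordinates ((o+0.5)*n_in/n_out - 0.5, so same-size resampling is the
# identity); `area` averages the input cells overlapped by each output cell
# (a box filter, appropriate for strong downsampling).
resample_weights <- function(n_in, n_out, method = c("bilinear", "area")) {
  method <- match.arg(method)
  w <- matrix(0, n_out, n_in)
  if (method == "bilinear") {
    for (o in seq_len(n_out)) {
      xi <- (o - 0.5) * n_in / n_out - 0.5
      xi <- min(max(xi, 0), n_in - 1)
      x0 <- floor(xi); t <- xi - x0
      w[o, x0 + 1] <- w[o, x0 + 1] + (1 - t)
      if (t > 0) w[o, min(x0 + 2, n_in)] <- w[o, min(x0 + 2, n_in)] + t
    }
  } else {
    r <- n_in / n_out
    for (o in seq_len(n_out)) {
      lo <- (o - 1) * r; hi <- o * r
      cells <- floor(lo):min(ceiling(hi) - 1, n_in - 1)
      cover <- pmin(hi, cells + 1) - pmax(lo, cells)
      w[o, cells + 1] <- cover / r
    }
  }
  w
}

#' Resize an image
#'
#' Separable bilinear resampling to a square `side x side` image (the
#' standard 224 px input size of image classifiers). Same-size input is
#' returned unchanged; intensities stay within the input range.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param side Output side length in px.
#' @return `side x side` numeric matrix.
#' @export
resize_image <- function(frame, side = 224L) {
  check_frame(frame)
  if (side < 1) stop_invalid("side must be >= 1")
  wr <- resample_weights(nrow(frame), side, "bilinear")
  wc <- resample_weights(ncol(frame), side, "bilinear")
  wr %*% frame %*% t(wc)
}

# area-averaged downsampling used by the reference scorer's pixel features
pool_image <- function(frame, side = 16L) {
  wr <- resample_weights(nrow(frame), side, "area")
  wc <- resample_weights(ncol(frame), side, "area")
  wr %*% frame %*% t(wc)
}

#' Shear transform parameters
#'
#' @param lambda_x Vertical displacement factor (shifts x by `lambda_x * y`).
#' @param lambda_y Horizontal displacement factor (shifts y by `lambda_y * x`).
#' @return Object of class `shear_params`.
#' @export
shear_params <- function(lambda_x = 0, lambda_y = 0) {
  if (abs(1 - lambda_x * lambda_y) < .Machine$double.eps)
    stop_invalid("lambda_x * lambda_y = 1: shear is not invertible")
  structure(list(lambda_x = lambda_x, lambda_y = lambda_y),
            class = "shear_params")
}

#' Apply the shear map to coordinates
#'
#' Shear preserves straight lines while changing angles:
#' `x' = x + lambda_x * y`, `y' = lambda_y * x + y`, i.e. multiplication by
#' the matrix `(1 lambda_x; lambda_y 1)`. Areas scale by the determinant
#' `|1 - lambda_x * lambda_y|`.
#'
#' @param x,y Coordinate vectors (x = column axis, y = row axis).
#' @param p A [shear_params].
#' @return Two-column matrix of mapped `(x', y')` coordinates.
#' @export
shear_coords <- function(x, y, p) {
  cbind(x = x + p$lambda_x * y, y = p$lambda_y * x + y)
}

# Inverse-mapped affine warp about the image center with bilinear sampling.
# `A` is the forward 2x2 map on (x, y) = (col, row) offsets from the center.
warp_affine <- function(frame, A, background = 0.95) {
  h <- nrow(frame); w <- ncol(frame)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  inv <- solve(A)
  xo <- rep(seq_len(w) - cx, each = h)
  yo <- rep(seq_len(h) - cy, times = w)
  xi <- inv[1, 1] * xo + inv[1, 2] * yo + cx
  yi <- inv[2, 1] * xo + inv[2, 2] * yo + cy
  x0 <- floor(xi); y0 <- floor(yi)
  tx <- xi - x0; ty <- yi - y0
  val <- rep(background, h * w)
  # gather the four neighbours, treating out-of-frame samples as background
  sample_at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- rep(background, length(yy))
    v[ok] <- frame[cbind(yy[ok], xx[ok])]
    v
  }
  v00 <- sample_at(y0, x0);     v01 <- sample_at(y0, x0 + 1)
  v10 <- sample_at(y0 + 1, x0); v11 <- sample_at(y0 + 1, x0 + 1)
  val <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  matrix(val, nrow = h)
}

#' Augmentation configuration
#'
#' @param rotation_range Maximum absolute in-plane rotation, degrees, in
#'   `[0, 180]`.
#' @param allow_horizontal_flip,allow_vertical_flip Enable the respective
#'   axis flip, each applied with probability 1/2 when enabled.
#' @param shear_range Length-2 interval from which `lambda_x` and `lambda_y`
#'   are drawn independently.
#' @param background Padding intensity for pixels mapped from outside the
#'   frame.
#' @return Object of class `augment_config`.
#' @export
augment_config <- function(rotation_range = 180, allow_horizontal_flip = TRUE,
                           allow_vertical_flip = TRUE,
                           shear_range = c(-0.2, 0.2), background = 0.95) {
  if (rotation_range < 0 || rotation_range > 180)
    stop_invalid("rotation_range must lie in [0, 180] degrees")
  if (length(shear_range) != 2L || shear_range[1] > shear_range[2])
    stop_invalid("shear_range must be an interval c(lo, hi)")
  structure(list(rotation_range = rotation_range,
                 allow_horizontal_flip = allow_horizontal_flip,
                 allow_vertical_flip = allow_vertical_flip,
                 shear_range = shear_range, background = background),
            class = "augment_config")
}

#' Randomly augment an image
#'
#' Applies, in order: rotation drawn uniformly within
#' `[-rotation_range, rotation_range]`, independent horizontal/vertical flips
#' with probability 1/2 each (where enabled), and a shear with `lambda_x`,
#' `lambda_y` drawn from `shear_range`. Output has the input's dimensions,
#' padded with background intensity; deterministic given `draw_seed`.
#' Augmentation changes pixels only — it never changes an image's label or
#' specimen assignment.
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param cfg An [augment_config].
#' @param draw_seed Integer seed for this draw.
#' @return Augmented frame, same dimensions.
#' @export
augment_image <- function(frame, cfg, draw_seed = 1L) {
  check_frame(frame)
  with_seed(draw_seed, {
    angle <- if (cfg$rotation_range > 0)
      stats::runif(1, -cfg$rotation_range, cfg$rotation_range) * pi / 180
    else 0
    flip_h <- cfg$allow_horizontal_flip && stats::runif(1) < 0.5
    flip_v <- cfg$allow_vertical_flip && stats::runif(1) < 0.5
    lam <- if (any(cfg$shear_range != 0))
      stats::runif(2, cfg$shear_range[1], cfg$shear_range[2])
    else c(0, 0)
    out <- frame
    if (angle != 0) {
      rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
      out <- warp_affine(out, rot, cfg$background)
    }
    if (flip_h) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
    if (flip_v) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    if (any(lam != 0)) {
      sh <- matrix(c(1, lam[2], lam[1], 1), 2)   # (1 lx; ly 1) column-major
      out <- warp_affine(out, sh, cfg$background)
    }
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
  })
}
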