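test_that("blob detection finds the largest dark component", {
  expect_error(detect_blob(matrix(0.95, 20, 20)), class = "specvote_no_blob")

  f <- block_frame(30, 30, list(c(11, 11, 20, 20)))
  b <- detect_blob(f)
  expect_equal(b$n_foreground, 100)
  expect_true(all(which(b$mask, arr.ind = TRUE)[, 1] %in% 11:20))

  f2 <- block_frame(30, 40, list(c(3, 3, 12, 12), c(20, 30, 22, 32)))
  b2 <- detect_blob(f2)
  expect_equal(b2$n_foreground, 100)
  expect_false(any(b2$mask[20:22, 30:32]))
})

test_that("interior holes are filled", {
  f <- matrix(0.95, 30, 30)
  f[10:20, 10:20] <- 0.1
  f[13:17, 13:17] <- 0.95   # translucent interior
  b <- detect_blob(f)
  expect_equal(b$n_foreground, 121)
})

test_that("geometric features match hand-derived values", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  ft <- blob_features(m)
  expect_equal(ft$area, 1)
  expect_equal(ft$max_diameter, 0)
  expect_equal(unname(ft$centroid), c(3, 3))

  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  ft <- blob_features(sq)
  expect_equal(ft$area, 100)
  expect_equal(ft$max_diameter, sqrt(9^2 + 9^2))
  expect_equal(ft$perimeter, 36)
  expect_equal(unname(ft$bbox), c(6, 6, 15, 15))

  expect_error(blob_features(matrix(FALSE, 3, 3)),
               class = "specvote_invalid_argument")
})

test_that("area matches a brute-force component count on random block frames", {
  for (seed in 1:20) {
    set.seed(seed)
    n_blocks <- sample(2:4, 1)
    rects <- lapply(seq_len(n_blocks), function(i) {
      r0 <- sample(1:30, 1); c0 <- sample(1:30, 1)
      c(r0, c0, min(40, r0 + sample(2:9, 1)), min(40, c0 + sample(2:9, 1)))
    })
    f <- block_frame(40, 40, rects)
    b <- detect_blob(f, threshold = 0.5)
    comps <- bf_components(f < 0.5, connectivity = 8)
    expect_equal(b$n_foreground, max(lengths(comps)))
  }
})

test_that("max diameter equals the brute-force maximum over all pixel pairs", {
  for (seed in 1:15) {
    f <- random_blob_frame(seed)
    b <- detect_blob(f, threshold = 0.5)
    expect_equal(blob_features(b)$max_diameter, bf_max_diameter(b$mask))
  }
})

test_that("standard crop centers the blob and keeps the cuvette width", {
  f <- matrix(0.95, 700, 496)
  f[301:400, 200:260] <- 0.1   # blob height 100 centered at row 350.5
  b <- detect_blob(f)
  out <- crop_to_standard(f, b)
  expect_equal(dim(out), c(496L, 496L))
  blob_rows <- range(which(out < 0.5, arr.ind = TRUE)[, 1])
  expect_lte(abs(mean(blob_rows) - 248), 1.5)

  # taller specimens are cropped with a greater height
  f2 <- matrix(0.95, 700, 496); f2[51:650, 240:260] <- 0.1
  out2 <- crop_to_standard(f2, detect_blob(f2))
  expect_equal(dim(out2), c(600L, 496L))

  # blob near the top edge: clamp then pad still yields 496 rows
  f3 <- matrix(0.95, 700, 496); f3[30:70, 240:260] <- 0.1
  out3 <- crop_to_standard(f3, detect_blob(f3))
  expect_equal(dim(out3), c(496L, 496L))
  expect_true(any(out3 < 0.5))

  # frames shorter than the crop window are padded with background
  f4 <- matrix(0.95, 300, 496); f4[100:140, 240:260] <- 0.1
  out4 <- crop_to_standard(f4, detect_blob(f4))
  expect_equal(dim(out4), c(496L, 496L))

  expect_error(crop_to_standard(matrix(0.5, 100, 300), b),
               class = "specvote_invalid_argument")
})

test_that("body size conversion reproduces the cuvette calibration", {
  bs <- estimate_body_size(c(100, 200, 300))
  expect_equal(signif(bs$px_to_mm2, 3), 4.06e-4)
  expect_equal(bs$mean_area_px, 200)
  expect_equal(bs$mean_area_mm2, 200 * (10 / 496)^2)
  expect_equal(estimate_body_size(1)$mean_area_px, 1)
  expect_error(estimate_body_size(numeric()),
               class = "specvote_invalid_argument")
  expect_error(estimate_body_size(c(10, 0.5)),
               class = "specvote_invalid_argument")
})

test_that("detected area scales as the square of linear size", {
  sp <- taxon_spec(0, "x", 1, elongation = 2, n_appendages = 0,
                   texture_noise = 0)
  base_px <- 2000
  a1 <- detect_blob(render_frame(sp, base_px, height = 400L,
                                 noise_sd = 0))$n_foreground
  for (s in c(1.5, 2, 3)) {
    as_ <- detect_blob(render_frame(sp, base_px * s^2, height = 400L,
                                    noise_sd = 0))$n_foreground
    expect_lt(abs(as_ / a1 - s^2) / s^2, 0.05)
  }
})

test_that("frame geometry tabulates per-frame features and drops empty frames", {
  sp <- taxon_spec(0, "x", 2, sinking_speed = 10)
  rec <- generate_specimen(sp, "s1", frames_base = 40, seed = 2,
                           height = 300L)
  geo <- frame_geometry(rec)
  expect_equal(nrow(geo), 4)
  expect_named(geo, c("specimen_id", "frame", "view", "area_px",
                      "perimeter_px", "max_diameter_px"))
  expect_true(all(geo$area_px > 0))

  rec$frames[[2]] <- matrix(0.95, 300, 496)   # empty cuvette frame
  expect_warning(geo2 <- frame_geometry(rec), "dropped 1 frame")
  expect_equal(nrow(geo2), 3)
  expect_equal(attr(geo2, "n_dropped"), 1L)
})
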