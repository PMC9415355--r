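test_that("taxon spec communities are distinct, deterministic, and validated", {
  specs <- make_taxon_specs(16, seed = 1)
  expect_length(specs, 16)
  sig <- vapply(specs, function(s)
    paste(signif(s$base_area_mm2, 6), s$elongation, s$n_appendages), "")
  expect_equal(anyDuplicated(sig), 0L)

  expect_equal(make_taxon_specs(2, seed = 7), make_taxon_specs(2, seed = 7))
  expect_error(make_taxon_specs(1, seed = 1),
               class = "specvote_invalid_argument")
  expect_error(taxon_spec(0, "x", base_area_mm2 = -1),
               class = "specvote_invalid_argument")
  expect_error(taxon_spec(0, "x", 1, elongation = 0.5),
               class = "specvote_invalid_argument")
})

test_that("frame counts scale inversely with sinking speed", {
  sp1 <- taxon_spec(0, "slow", 2, sinking_speed = 1)
  sp2 <- taxon_spec(1, "fast", 2, sinking_speed = 2)
  r40 <- generate_specimen(sp1, "a", frames_base = 40, seed = 1,
                           height = 200L)
  r20 <- generate_specimen(sp2, "a", frames_base = 40, seed = 1,
                           height = 200L)
  expect_length(r40$frames, 40)
  expect_length(r20$frames, 20)

  # sinking speed equal to frames_base leaves a single frame
  sp <- taxon_spec(0, "x", 2, sinking_speed = 40)
  expect_length(generate_specimen(sp, "a", frames_base = 40, seed = 1,
                                  height = 200L)$frames, 1)
  # cap applies
  spc <- taxon_spec(0, "x", 2, sinking_speed = 0.001)
  expect_length(generate_specimen(spc, "a", frames_base = 40, seed = 1,
                                  frame_cap = 50L, height = 200L)$frames, 50)
  expect_error(generate_specimen(sp1, "a", frames_base = 0, seed = 1),
               class = "specvote_invalid_argument")
})

test_that("specimen generation is deterministic and tagged with views", {
  sp <- taxon_spec(0, "x", 3, sinking_speed = 10, n_appendages = 3)
  r1 <- generate_specimen(sp, "s1", frames_base = 40, seed = 9)
  r2 <- generate_specimen(sp, "s1", frames_base = 40, seed = 9)
  expect_identical(r1$frames, r2$frames)
  expect_equal(r1$views, rep(c("view_A", "view_B"), length.out = 4))
  expect_true(all(vapply(r1$frames, function(f)
    all(f >= 0 & f <= 1), NA)))
  # a different specimen id gives a different draw
  r3 <- generate_specimen(sp, "s2", frames_base = 40, seed = 9)
  expect_false(identical(r1$frames[[1]], r3$frames[[1]]))
})

test_that("default 16-taxon community mirrors the observed frame-count and size spread", {
  specs <- make_taxon_specs(16, seed = 1)
  mean_frames <- vapply(specs, function(s) round(360 / s$sinking_speed), 0)
  expect_lte(min(mean_frames), 20)
  expect_gte(max(mean_frames), 300)
  areas <- vapply(specs, `[[`, 0, "base_area_mm2")
  expect_gte(max(areas) / min(areas), 10)
})

test_that("the two camera views foreshorten the body width", {
  sp <- taxon_spec(0, "x", 5, elongation = 2.5, sinking_speed = 1,
                   texture_noise = 0)
  fa <- render_frame(sp, 6000, angle = 0, view = "view_A", height = 300L,
                     noise_sd = 0)
  fb <- render_frame(sp, 6000, angle = 0, view = "view_B", height = 300L,
                     noise_sd = 0)
  expect_gt(sum(fa < 0.5), sum(fb < 0.5))
})

test_that("datasets on disk match their manifest exactly", {
  out <- withr::local_tempdir()
  specs <- list(taxon_spec(0, "tax_a", 1.5, sinking_speed = 5,
                           n_appendages = 2),
                taxon_spec(1, "tax_b", 4, elongation = 3, sinking_speed = 10))
  man <- generate_dataset(specs, n_specimens_per_taxon = 2, frames_base = 20,
                          seed = 3, out_dir = out, height = 300L)
  expect_equal(nrow(man), 4)
  expect_setequal(man$specimen_id,
                  basename(list.dirs(out, recursive = TRUE)[
                    grepl("_s[0-9]+$", list.dirs(out, recursive = TRUE))]))
  pngs <- list.files(out, pattern = "\\.png$", recursive = TRUE)
  expect_equal(length(pngs), sum(man$n_frames))
  expect_true(file.exists(file.path(out, "manifest.csv")))

  # identical seed reproduces byte-identical PNGs
  out2 <- withr::local_tempdir()
  generate_dataset(specs, n_specimens_per_taxon = 2, frames_base = 20,
                   seed = 3, out_dir = out2, height = 300L)
  f1 <- file.path(out, sort(pngs))
  f2 <- file.path(out2, sort(pngs))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("specimen folders round-trip through PNG within 8-bit precision", {
  out <- withr::local_tempdir()
  specs <- list(taxon_spec(0, "tax_rt", 2, sinking_speed = 10,
                           n_appendages = 2))
  generate_dataset(specs, 1, frames_base = 30, seed = 6, out_dir = out,
                   height = 300L)
  rec <- read_specimen(file.path(out, "tax_rt", "tax_rt_s001"))
  orig <- generate_specimen(specs[[1]], "tax_rt_s001", frames_base = 30,
                            seed = 6, height = 300L)
  expect_length(rec$frames, length(orig$frames))
  expect_equal(rec$views, orig$views)
  expect_lt(max(abs(rec$frames[[1]] - orig$frames[[1]])), 1 / 255)
  # measurements agree on the quantized frames
  a1 <- detect_blob(rec$frames[[2]])$n_foreground
  a2 <- detect_blob(orig$frames[[2]])$n_foreground
  expect_lt(abs(a1 - a2) / a2, 0.02)
  expect_error(read_specimen(file.path(out, "nope")),
               class = "specvote_invalid_argument")
})
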