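# Separable two-class fixture in feature space: class means 8 SD apart.
separable_fixture <- function(n = 40, d = 6, gap = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * d), n, d)
  x[y == "b", 1] <- x[y == "b", 1] + gap
  list(x = x, y = y)
}

test_that("the scorer separates well-separated classes and logs its stopping", {
  tr <- separable_fixture(seed = 1)
  va <- separable_fixture(n = 20, seed = 2)
  m <- fit_taxon_scorer(tr$x, tr$y, va$x, va$y)
  tl <- m$training_log
  # validation accuracy reaches 1.0 within 50 epochs on separable classes
  expect_lte(which(tl$val_acc == 1)[1], 50)
  # returned parameters always correspond to the validation-loss minimum
  expect_equal(m$best_epoch, which.min(tl$val_loss))
  expect_equal(predict(m, va$x, type = "class"), va$y)

  # determinism: same data in, identical parameters out
  m2 <- fit_taxon_scorer(tr$x, tr$y, va$x, va$y)
  expect_identical(m$W, m2$W)
  expect_identical(m$b, m2$b)
})

test_that("degenerate training inputs are rejected", {
  tr <- separable_fixture()
  expect_error(fit_taxon_scorer(tr$x, rep("a", nrow(tr$x)), tr$x, rep("a", nrow(tr$x))),
               class = "specvote_invalid_argument")
  expect_error(fit_taxon_scorer(tr$x, tr$y, tr$x[0, , drop = FALSE],
                                character()),
               class = "specvote_invalid_argument")
  expect_error(fit_taxon_scorer(tr$x, tr$y, tr$x, tr$y,
                                weights = rep(-1, nrow(tr$x))),
               class = "specvote_invalid_argument")
})

test_that("scores are pure, unbounded linear functions of the features", {
  tr <- separable_fixture(seed = 3)
  va <- separable_fixture(n = 20, seed = 4)
  m <- fit_taxon_scorer(tr$x, tr$y, va$x, va$y)
  s1 <- predict(m, va$x, type = "score")
  s2 <- predict(m, va$x, type = "score")
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(20L, 2L))
  expect_equal(colnames(s1), c("a", "b"))

  # shifting feature j by delta moves scores by delta/scale_j * W[j, ]
  delta <- 0.7; j <- 1
  xs <- va$x; xs[, j] <- xs[, j] + delta
  shift <- delta / m$scale[j] * m$W[j, ]
  expect_equal(predict(m, xs, type = "score"),
               sweep(s1, 2, shift, "+"), tolerance = 1e-10)

  pr <- predict(m, va$x, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, 20))
})

test_that("per-image decisions follow the argmax with deterministic ties", {
  expect_equal(predict_image(c(0.1, 3.2, -1)), 2)
  expect_equal(predict_image(c(2, 2)), 1)
  s <- c(-1.4, 0.3, 0.2)
  expect_equal(predict_image(s + 100), predict_image(s))
  expect_error(predict_image(c(1, NaN)), class = "specvote_invalid_argument")
})

test_that("scorer methods print, summarise, and expose coefficients", {
  tr <- separable_fixture(seed = 5)
  va <- separable_fixture(n = 20, seed = 6)
  m <- fit_taxon_scorer(tr$x, tr$y, va$x, va$y)
  expect_output(print(m), "taxon_scorer")
  expect_output(summary(m), "classes: a, b")
  cf <- coef(m)
  expect_equal(dim(cf), c(ncol(tr$x) + 1L, 2L))
  expect_equal(rownames(cf)[1], "(intercept)")
})

test_that("frame features carry pooled pixels plus geometry", {
  sp <- taxon_spec(0, "x", 3, sinking_speed = 20, n_appendages = 2)
  rec <- generate_specimen(sp, "s1", frames_base = 20, seed = 3,
                           height = 496L)
  v <- frame_features(rec$frames[[1]], pool = 16)
  expect_length(v, 16^2 + 6)
  expect_s3_class(attr(v, "geometry"), "geometric_features")
  expect_error(frame_features(matrix(0.95, 496, 496)),
               class = "specvote_no_blob")
})

test_that("end-to-end scoring on separable synthetic taxa is near-perfect per image", {
  specs <- list(
    taxon_spec(0, "small", 0.8, area_cv = 0.05, elongation = 1.3,
               sinking_speed = 6),
    taxon_spec(1, "large", 12, area_cv = 0.05, elongation = 3,
               n_appendages = 4, sinking_speed = 6))
  fd <- build_feature_dataset(specs, n_specimens_per_taxon = 10,
                              frames_base = 30, seed = 8, height = 496L)
  man <- fd$manifest
  sp <- assign_test_split(man, 3, seed = 8)
  tv <- split_validation(man[man$specimen_id %in% sp$pool, ], 0.2, seed = 8)
  tr <- fd$meta$specimen_id %in% tv$train
  va <- fd$meta$specimen_id %in% tv$validation
  te <- fd$meta$specimen_id %in% sp$test
  m <- fit_taxon_scorer(fd$x[tr, ], fd$meta$taxon[tr], fd$x[va, ],
                        fd$meta$taxon[va])
  pred <- predict(m, fd$x[te, ], type = "class")
  expect_gte(mean(pred == fd$meta$taxon[te]), 0.99)
})

test_that("fitted scorers survive a JSON round trip", {
  tr <- separable_fixture(seed = 9)
  va <- separable_fixture(n = 20, seed = 10)
  m <- fit_taxon_scorer(tr$x, tr$y, va$x, va$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_scorer(m, path)
  m2 <- read_scorer(path)
  expect_equal(m2$class_labels, m$class_labels)
  expect_equal(m2$W, m$W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(predict(m2, va$x, type = "class"),
               predict(m, va$x, type = "class"))
  expect_error(write_scorer(list(), path),
               class = "specvote_invalid_argument")
})
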