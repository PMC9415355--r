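test_that("confusion matrices tally true-by-predicted counts", {
  cm <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  perfect <- confusion(c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(sum(diag(perfect)), 3)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)

  expect_error(confusion("a", c("a", "b"), c("a", "b")),
               class = "specvote_invalid_argument")
  expect_error(confusion("z", "a", c("a", "b")),
               class = "specvote_invalid_argument")

  # row sums equal per-class true counts on random label pairs
  set.seed(7)
  for (i in 1:100) {
    classes <- letters[1:sample(2:6, 1)]
    n <- sample(5:200, 1)
    true <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion(true, pred, classes)
    expect_equal(as.vector(rowSums(cm)),
                 as.vector(table(factor(true, classes))))
    expect_equal(sum(cm), n)
  }
})

test_that("precision and recall follow their defining formulas", {
  cm <- confusion(rep(c("x", "y"), c(10, 10)),
                  c(rep("x", 8), rep("y", 2), "x", rep("y", 9)),
                  c("x", "y"))
  r <- precision_recall(cm)
  expect_equal(r$per_class_precision[["x"]], 8 / 9)
  expect_equal(r$per_class_recall[["x"]], 8 / 10)
  expect_equal(r$accuracy, 17 / 20)

  d <- confusion(c("a", "b"), c("a", "b"), c("a", "b"))
  rd <- precision_recall(d)
  expect_equal(rd$accuracy, 1)
  expect_equal(unname(rd$per_class_precision), c(1, 1))
  expect_equal(unname(rd$per_class_recall), c(1, 1))
  expect_equal(rd$macro_precision, 1)

  expect_error(precision_recall(matrix(0L, 2, 2)),
               class = "specvote_invalid_argument")
})

test_that("a never-predicted class gets zero precision and a raised flag", {
  cm <- confusion(c("a", "a", "b"), c("a", "a", "a"), c("a", "b"))
  r <- precision_recall(cm)
  expect_equal(unname(r$undefined_precision_flags), c(FALSE, TRUE))
  expect_equal(r$per_class_precision[["b"]], 0)
  expect_equal(r$per_class_recall[["b"]], 0)
})

test_that("matrix-derived metrics equal brute-force label counting", {
  set.seed(11)
  for (i in 1:200) {
    classes <- letters[1:sample(2:6, 1)]
    n <- sample(5:150, 1)
    true <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    r <- precision_recall(confusion(true, pred, classes))
    bf <- bf_metrics(true, pred, classes)
    expect_equal(r$accuracy, bf$accuracy)
    expect_equal(unname(r$per_class_precision), bf$precision)
    expect_equal(unname(r$per_class_recall), bf$recall)
  }
})

test_that("on a balanced test set accuracy equals macro recall", {
  set.seed(13)
  for (i in 1:20) {
    classes <- letters[1:sample(2:5, 1)]
    per <- sample(5:20, 1)
    true <- rep(classes, each = per)
    pred <- sample(classes, length(true), replace = TRUE)
    r <- precision_recall(confusion(true, pred, classes))
    expect_equal(r$accuracy, r$macro_recall)
  }
})

test_that("confidence intervals across taxa bracket the macro mean", {
  set.seed(17)
  true <- rep(letters[1:6], each = 30)
  pred <- ifelse(runif(180) < 0.8, true, sample(letters[1:6], 180, TRUE))
  r <- precision_recall(confusion(true, pred, letters[1:6]))
  expect_lte(r$ci95_precision[["lo"]], r$macro_precision)
  expect_gte(r$ci95_precision[["hi"]], r$macro_precision)
  expect_gte(r$ci95_precision[["lo"]], 0)
  expect_lte(r$ci95_precision[["hi"]], 1)
})

test_that("size-precision tables join taxa, sizes, and precision", {
  prec <- c(t1 = 0.9, t2 = 0.6, t3 = 1, t4 = 0.3, t5 = 0.75)
  sizes <- c(0.4, 2.2, 9.1, 0.9, 30)
  tab <- size_precision_table(prec, sizes, training_size = 25L)
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$precision >= 0 & tab$precision <= 1))
  expect_equal(tab$taxon, names(prec))

  # rank correlation on the table matches the hand-computed rank statistic
  rho <- cor(tab$mean_size_mm2, tab$precision, method = "spearman")
  rk_s <- rank(sizes); rk_p <- rank(prec)
  rho_hand <- 1 - 6 * sum((rk_s - rk_p)^2) / (5 * (5^2 - 1))
  expect_equal(rho, rho_hand)

  expect_error(size_precision_table(prec, sizes[1:3]),
               class = "specvote_invalid_argument")
})
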