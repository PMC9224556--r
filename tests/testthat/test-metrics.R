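test_that("confusion matrices tally true/predicted pairs", {
  perfect <- confusion(rep(1:3, each = 3), rep(1:3, each = 3))
  expect_equal(unname(diag(perfect)), c(3, 3, 3))
  expect_equal(sum(perfect), 9)

  all2 <- confusion(rep(1:3, each = 3), rep(2, 9))
  expect_equal(unname(all2[, 2]), c(3, 3, 3))
  expect_equal(sum(all2[, c(1, 3)]), 0)

  withr::with_seed(10, {
    truth <- sample(1:3, 50, replace = TRUE)
    pred <- sample(1:3, 50, replace = TRUE)
  })
  expect_equal(unname(unclass(confusion(truth, pred))),
               unname(confusion_oracle(truth, pred)))
  expect_error(confusion(c(1, 4), c(1, 2)), "\\{1, 2, 3\\}")
  expect_error(confusion(1:3, 1:2), "length")
})

test_that("one-vs-all indexes match hand tallies", {
  perfect <- confusion(rep(1:3, each = 3), rep(1:3, each = 3))
  m <- one_vs_all_metrics(perfect)
  expect_equal(unname(m$macro), rep(1, 5))
  expect_equal(m$overall_accuracy, 1)

  cm <- matrix(c(2, 0, 0, 1, 3, 1, 0, 0, 2), nrow = 3)  # by column
  dimnames(cm) <- list(true = 1:3, predicted = 1:3)
  class(cm) <- c("confusion_matrix", class(cm))
  m2 <- one_vs_all_metrics(cm)
  # class 1: TP 2, FN 1 -> sensitivity 2/3; no false positives -> precision 1
  expect_equal(m2$per_class$sensitivity[1], 2 / 3)
  expect_equal(m2$per_class$precision[1], 1)
  # class 2: 3 of 5 predicted-2 are correct
  expect_equal(m2$per_class$precision[2], 3 / 5)
  expect_equal(m2$overall_accuracy, 7 / 9)
})

test_that("per-class indexes satisfy the defining identities on random matrices", {
  withr::with_seed(77, {
    for (rep in 1:100) {
      truth <- sample(1:3, 40, replace = TRUE)
      pred <- sample(1:3, 40, replace = TRUE)
      cm <- confusion(truth, pred)
      m <- suppressWarnings(one_vs_all_metrics(cm))
      n <- sum(cm)
      for (k in 1:3) {
        tp <- sum(truth == k & pred == k)
        fn <- sum(truth == k & pred != k)
        fp <- sum(truth != k & pred == k)
        tn <- sum(truth != k & pred != k)
        row <- m$per_class[k, ]
        expect_equal(unname(unlist(row[c("TP", "TN", "FP", "FN")])),
                     c(tp, tn, fp, tn * 0 + fn))
        expect_equal(row$TP + row$TN + row$FP + row$FN, n)
        expect_equal(row$accuracy, (tp + tn) / n)
        if (tp + fn > 0) expect_equal(row$sensitivity, tp / (tp + fn))
        if (tp + fp > 0) expect_equal(row$precision, tp / (tp + fp))
        if (!is.na(row$f_score)) {
          expect_equal(row$f_score,
                       2 * row$precision * row$sensitivity /
                         (row$precision + row$sensitivity))
        }
      }
      # macro averages lie within the per-class range
      for (nm in c("sensitivity", "specificity", "precision", "accuracy")) {
        v <- m$per_class[[nm]]
        expect_gte(m$macro[[nm]], min(v, na.rm = TRUE))
        expect_lte(m$macro[[nm]], max(v, na.rm = TRUE))
      }
      expect_equal(sum(m$per_class$TP), sum(diag(cm)))
    }
  })
})

test_that("undefined per-class indexes are excluded from macro means with a warning", {
  cm <- confusion(c(1, 1, 2, 3), c(1, 1, 1, 3))  # class 2 never predicted
  expect_warning(m <- one_vs_all_metrics(cm), "undefined")
  expect_true(is.na(m$per_class$precision[2]))
  expect_false(is.na(m$macro[["precision"]]))
})

test_that("Fisher ratio follows its closed form and scale invariance", {
  expect_equal(fisher_ratio(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(-1, 0, 1, 0)
  b <- a + 2
  expect_equal(fisher_ratio(a, b), 4 / (var(a) + var(b)))
  withr::with_seed(2, {
    x <- rnorm(30); y <- rnorm(30, 1)
  })
  expect_equal(fisher_ratio(3.7 * x, 3.7 * y), fisher_ratio(x, y),
               tolerance = 1e-12)
  expect_error(fisher_ratio(c(1, 1), c(1, 1)), "zero variance")
  # pairwise average over the three classes
  vals <- c(x, y, y + 2)
  cls <- rep(1:3, each = 30)
  expect_equal(avg_fisher_ratio(vals, cls),
               mean(c(fisher_ratio(x, y), fisher_ratio(x, y + 2),
                      fisher_ratio(y, y + 2))), tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits match their definitions", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  ba2 <- bland_altman(x, x - 1)
  expect_equal(ba2$bias, 1)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(1, 1))
  # Monte-Carlo against the closed form: d ~ N(0.5, 1)
  withr::with_seed(123, {
    y <- rnorm(1e4)
    ba3 <- bland_altman(y + rnorm(1e4, 0.5, 1), y)
  })
  expect_equal(ba3$bias, 0.5, tolerance = 0.03 / 0.5)
  expect_equal(ba3$loa_upper, 0.5 + 1.96, tolerance = 0.05 / 2.46)
  expect_true(ba3$loa_lower <= ba3$bias && ba3$bias <= ba3$loa_upper)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("mean absolute error averages absolute deviations", {
  expect_equal(mean_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_absolute_error(c(1, 2, 3), c(2, 1, 7)), 2)
  withr::with_seed(5, {
    a <- rnorm(40); b <- rnorm(40)
  })
  acc <- 0
  for (i in seq_along(a)) acc <- acc + abs(a[i] - b[i])
  expect_equal(mean_absolute_error(a, b), acc / 40, tolerance = 1e-12)
  expect_error(mean_absolute_error(1:3, 1:2), "length")
})
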