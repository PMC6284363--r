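test_that("confusion matrix counts actual x predicted", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2))
  expect_equal(unclass(cm), diag(1L, 3), ignore_attr = TRUE)
  cm2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), classes = 0:2)
  expect_equal(unname(unclass(cm2)),
               matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), 3, byrow = TRUE))
  cm0 <- confusion_matrix(character(0), character(0))
  expect_true(all(cm0 == 0L))
  expect_error(confusion_matrix("a", "z", classes = c("a", "b")), "outside")
  expect_error(confusion_matrix(1:3, 1:2), "length")
})

test_that("one-vs-rest reduction matches the reference matrix arithmetic", {
  t7 <- published_tables()$multi_3d$matrix
  ct <- one_vs_rest_counts(t7, 1)
  expect_equal(ct, list(TP = 861, FP = 139, FN = 139, TN = 1861))
  expect_equal(ct$TP + ct$FP + ct$FN + ct$TN, sum(t7))
  id <- confusion_matrix(c(0, 1, 2), c(0, 1, 2))
  expect_equal(one_vs_rest_counts(id, 2)[c("FP", "FN")], list(FP = 0, FN = 0))
  zero <- confusion_matrix(character(0), character(0))
  expect_equal(unlist(one_vs_rest_counts(zero, 1)), c(TP = 0, FP = 0, FN = 0, TN = 0))
  # row/column conservation per class
  for (i in 1:3) {
    ct <- one_vs_rest_counts(t7, i)
    expect_equal(ct$TP + ct$FN, sum(t7[i, ]))
    expect_equal(ct$TP + ct$FP, sum(t7[, i]))
  }
})

test_that("metric report reproduces the reference 3D results", {
  rep <- metrics(published_tables()$multi_3d$matrix)
  pc <- rep$per_class
  expect_equal(pc$sensitivity[3], 90.20, tolerance = 1e-4)  # ictal
  expect_equal(pc$specificity[1], 93.05, tolerance = 1e-4)  # inter-ictal
  expect_equal(pc$accuracy[1], 90.73, tolerance = 1e-3)
  expect_equal(rep$macro$accuracy, 92.3767, tolerance = 1e-4)
  expect_equal(rep$macro$fnr, 11.4333, tolerance = 1e-4)
  # identity predictions: perfect metrics
  perfect <- metrics(confusion_matrix(rep(stage_levels(), 5), rep(stage_levels(), 5)))
  expect_equal(perfect$per_class$sensitivity, rep(100, 3))
  expect_equal(perfect$per_class$specificity, rep(100, 3))
  expect_equal(perfect$macro$fnr, 0)
  expect_equal(perfect$macro$fpr, 0)
  # macro complements are exact before rounding
  set.seed(17)
  y1 <- sample(stage_levels(), 60, replace = TRUE)
  y2 <- sample(stage_levels(), 60, replace = TRUE)
  r <- metrics(confusion_matrix(y1, y2))
  expect_equal(r$macro$fnr + r$macro$sensitivity, 100)
  expect_equal(r$macro$fpr + r$macro$specificity, 100)
})

test_that("metrics agree with brute-force label counting", {
  set.seed(23)
  for (trial in 1:10) {
    y1 <- sample(stage_levels(), 40, replace = TRUE)
    y2 <- sample(stage_levels(), 40, replace = TRUE)
    r <- metrics(confusion_matrix(y1, y2))
    b <- brute_metrics(y1, y2, stage_levels())
    expect_equal(r$per_class$accuracy, unname(b[, "accuracy"]))
    expect_equal(r$per_class$specificity, unname(b[, "specificity"]))
    expect_equal(r$per_class$sensitivity, unname(b[, "sensitivity"]))
  }
  # an absent class yields NA cells and a warning, excluded from the macro
  expect_warning(r0 <- metrics(confusion_matrix(rep("ictal", 4), rep("ictal", 4),
                                                classes = stage_levels())))
  expect_true(is.na(r0$per_class$sensitivity[1]))
  expect_false(is.na(r0$macro$sensitivity))
})

test_that("published tables reproduce except the one internally inconsistent cell", {
  rep <- reproduce_tables()
  bad <- rep[!rep$match, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$table, "multi_3d")
  expect_equal(bad$row, "ictal")
  expect_equal(bad$metric, "specificity")
  expect_equal(bad$computed, 95.65, tolerance = 1e-4)
  # macro summaries and comparison-table means all reproduce
  macro <- rep[rep$row %in% c("macro", "comparison"), ]
  expect_true(all(macro$match))
  expect_equal(rep$computed[rep$table == "multi_3d" & rep$metric == "mean_accuracy"],
               92.37, tolerance = 0.01)
  expect_equal(rep$computed[rep$table == "multi_2d" & rep$metric == "mean_accuracy"],
               89.91, tolerance = 0.01)
  # perturbing one fixture count flags at least one additional cell
  tabs <- published_tables()
  tabs$single_2d$matrix[1, 1] <- tabs$single_2d$matrix[1, 1] + 1
  rep2 <- reproduce_tables(tabs)
  expect_gt(sum(!rep2$match), 1)
})
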