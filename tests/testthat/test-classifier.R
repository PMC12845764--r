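test_that("the LDA stage projects 20 MFCCs onto C-1 = 2 components", {
  m <- tiny_ref()
  expect_equal(ncol(m$lda$scaling), 2L)
  expect_length(m$center, 20L)
  proj <- lda_project(m, tiny_segs()[1:5])
  expect_equal(dim(proj), c(5L, 2L))
  expect_error(lda_svm(tiny_segs()[tiny_segs()$labels == "NoBee"]),
               "two classes")
})

test_that("fitting is deterministic and separates the fixture classes", {
  segs <- tiny_segs()
  m <- tiny_ref()
  pred <- predict(m, segs)
  expect_gte(mean(pred == segs$labels), 0.9)
  m2 <- lda_svm(segs, tiny_fc())
  expect_identical(predict(m2, segs), pred)
  expect_identical(pred[1], predict(m, segs[c(1, 1)])[2])   # duplicated clip
  expect_identical(predict(m, segs[integer(0)]), character(0))
})

test_that("class distributions count and percentage over a fixed alphabet", {
  d <- class_distribution(c("A", "A", "B"), c("A", "B", "C"))
  expect_equal(d$count, c(2L, 1L, 0L))
  expect_equal(sum(d$count), 3L)
  expect_equal(sum(d$percent), 100)
  # the published rounding convention: 11,963 of 20,000 prints as 59.8%
  d2 <- class_distribution(rep(c("QueenPresent", "NoBee"), c(11963, 8037)))
  expect_equal(round(d2$percent[d2$class == "QueenPresent"], 1), 59.8)
})

test_that("metrics reports follow the standard definitions and conventions", {
  perfect <- classification_metrics(c("a", "b", "a"), c("a", "b", "a"), "a")
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # TP=8 FP=2 FN=2 TN=8
  truths <- rep(c("pos", "neg"), each = 10)
  preds <- c(rep("pos", 8), rep("neg", 2), rep("pos", 2), rep("neg", 8))
  met <- classification_metrics(preds, truths, "pos")
  expect_equal(met$precision, 0.8)
  expect_equal(met$recall, 0.8)
  expect_equal(met$f1, 0.8)
  expect_equal(met$accuracy, 0.8)
  expect_equal(met$accuracy,
               sum(diag(met$confusion)) / sum(met$confusion))

  # no positive predictions and no positive truths: 0 by convention
  met0 <- classification_metrics(rep("neg", 4), rep("neg", 4), "pos")
  expect_equal(met0$precision, 0)
  expect_equal(met0$recall, 0)
  expect_equal(met0$accuracy, 1)
  expect_error(classification_metrics("a", c("a", "b")), "equal length")
})

test_that("the augmentation experiment freezes its test split and steps ratios", {
  real <- tiny_segs(3, seed = 6)
  synthetic <- tiny_segs(2, seed = 60)
  synthetic <- synthetic[synthetic$labels == "QueenPresent"]
  res <- run_augmentation_experiment(real, synthetic, "QueenPresent",
                                     steps = c(20, 26, 30, 33.3),
                                     feature_cfg = tiny_fc(), seed = 2)
  expect_equal(nrow(res$table), 4L)
  expect_true(all(diff(res$table$n_QueenPresent) > 0))
  expect_equal(res$table$n_QueenAbsent, rep(res$table$n_QueenAbsent[1], 4))
  # final step is balanced to within rounding
  last <- res$table[4, ]
  expect_equal(last$n_QueenPresent / (last$n_QueenPresent +
                                        last$n_QueenAbsent + last$n_NoBee),
               1 / 3, tolerance = 0.01)
  # frozen test split: rerunning reproduces the identical held-out set
  res2 <- run_augmentation_experiment(real, synthetic, "QueenPresent",
                                      steps = c(20, 26, 30, 33.3),
                                      feature_cfg = tiny_fc(), seed = 2)
  expect_identical(res$test$segments, res2$test$segments)
  expect_true(all(res$table$accuracy >= 0 & res$table$accuracy <= 1))

  expect_error(
    run_augmentation_experiment(real, synthetic[1:2], "QueenPresent",
                                steps = c(20, 33.3),
                                feature_cfg = tiny_fc(), seed = 2),
    "synthetic")
})
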