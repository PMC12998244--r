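test_that("confusion counts tally pairs, weights and reject unknown labels", {
  cm <- confusionCounts(c("a", "a", "b"), c("a", "b", "b"))
  m <- counts(cm)
  expect_equal(unname(m["a", "a"]), 1)
  expect_equal(unname(m["a", "b"]), 1)
  expect_equal(unname(m["b", "b"]), 1)
  expect_equal(unname(m["b", "a"]), 0)

  perfect <- confusionCounts(letters[1:4], letters[1:4])
  expect_true(all(counts(perfect) == diag(4)))

  # weight 1/R over R repeats: each call's true row sums to 1
  truth <- rep(c("a", "b"), each = 3)
  preds <- c("a", "a", "b", "b", "b", "a")
  cmW <- confusionCounts(rep(truth, 4), rep(preds, 4),
                         weights = rep(1 / 4, 24))
  expect_equal(unname(rowSums(counts(cmW))), c(3, 3))

  expect_error(confusionCounts("a", "z", labels = c("a", "b")), "outside")
})

test_that("report reproduces hand-computed two-class metrics exactly", {
  # TP 40, FN 10, FP 5, TN 45
  cm <- new("ConfusionMatrix", labels = c("pos", "neg"),
            counts = matrix(c(40, 10, 5, 45), 2, byrow = TRUE))
  rep <- classificationReport(cm)
  pos <- perClassMetrics(rep)[perClassMetrics(rep)$label == "pos", ]
  expect_equal(pos$accuracy, 0.85)
  expect_equal(pos$recall, 0.80)
  expect_equal(pos$precision, 40 / 45)
  expect_equal(pos$f1, 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
})

test_that("perfect and uniform-random confusions hit their closed forms", {
  perfect <- classificationReport(confusionCounts(letters[1:3], letters[1:3]))
  expect_true(all(microMetrics(perfect) == 1))
  expect_true(all(macroMetrics(perfect) == 1))

  # balanced 4-class uniform-random: every cell N/16
  cm <- new("ConfusionMatrix", labels = letters[1:4],
            counts = matrix(4, 4, 4))
  rep <- classificationReport(cm)
  # one-vs-rest TN inflation: micro accuracy (2a + k - 2) / k with a = 1/4
  expect_equal(unname(microMetrics(rep)["accuracy"]), 0.625)
  expect_equal(unname(microMetrics(rep)["traceAccuracy"]), 0.25)
  expect_true(all(perClassMetrics(rep)$recall == 0.25))
})

test_that("micro identities and metric bounds hold", {
  set.seed(13)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    n <- 60
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    rep <- classificationReport(confusionCounts(truth, pred,
                                                labels = letters[1:k]))
    mi <- microMetrics(rep)
    # single-label multiclass: micro precision = micro recall = trace/total
    expect_equal(unname(mi["precision"]), unname(mi["traceAccuracy"]))
    expect_equal(unname(mi["recall"]), unname(mi["traceAccuracy"]))
    pc <- perClassMetrics(rep)
    expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
    expect_true(all(unlist(pc[, 6:9]) >= 0 & unlist(pc[, 6:9]) <= 1))
  }
})

test_that("class order permutation permutes per-class and fixes micro", {
  truth <- c("a", "a", "b", "c", "c", "c")
  pred <- c("a", "b", "b", "c", "a", "c")
  r1 <- classificationReport(confusionCounts(truth, pred,
                                             labels = c("a", "b", "c")))
  r2 <- classificationReport(confusionCounts(truth, pred,
                                             labels = c("c", "a", "b")))
  expect_equal(microMetrics(r1), microMetrics(r2))
  p1 <- perClassMetrics(r1); p2 <- perClassMetrics(r2)
  expect_equal(p1[order(p1$label), -1], p2[order(p2$label), -1],
               ignore_attr = TRUE)
})

test_that("empty matrices and zero-prediction classes are handled", {
  expect_error(classificationReport(
    new("ConfusionMatrix", labels = c("a", "b"), counts = matrix(0, 2, 2))),
    "all-zero")
  # class b never predicted -> precision 0, logged
  roarboutLog(clear = TRUE)
  cm <- confusionCounts(c("a", "b", "b"), c("a", "a", "a"))
  rep <- classificationReport(cm)
  expect_equal(perClassMetrics(rep)$precision[2], 0)
  expect_true(any(grepl("no positive predictions", roarboutLog())))
})
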