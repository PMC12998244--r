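plantedBlobs <- function(nPer = 30, seed = 3) {
  # three well-separated (duration, max freq) blobs in grunt/IR/FTR layout
  set.seed(seed)
  mk <- function(dm, fm, lab) {
    d <- rnorm(nPer, dm, 0.03)
    callAnnotations(bout_id = paste0(lab, seq_len(nPer)), call_type = lab,
                    begin_s = 0, end_s = d, max_freq_hz = rnorm(nPer, fm, 8),
                    duration_s = d)
  }
  rbind(mk(0.15, 120, "grunt"), mk(0.5, 210, "intermediary_roar"),
        mk(1.0, 320, "full_throated_roar"))
}

test_that("planted blobs are recovered nearly perfectly", {
  ann <- plantedBlobs()
  ft <- standardizeFeatures(buildFeatures(ann))
  res <- kmeansCalls(ft, k = 3, seed = 1)
  expect_gte(adjustedRand(assignments(res), ann$call_type), 0.99)
  # assignments are a Lloyd fixed point: every row at its nearest centroid
  x <- as.matrix(ft[c("duration_s", "max_freq_hz")])
  d2 <- vapply(seq_len(3), function(j)
    colSums((t(x) - centroids(res)[j, ])^2), numeric(nrow(x)))
  expect_true(all(assignments(res) == max.col(-d2)))
})

test_that("k equal to the number of rows gives zero inertia", {
  ann <- syntheticAnnotations(6)
  ft <- standardizeFeatures(buildFeatures(ann))
  res <- kmeansCalls(ft, k = 6, seed = 2)
  expect_lt(inertia(res), 1e-12)
})

test_that("duplicating every row leaves the centroids unchanged", {
  ann <- plantedBlobs(nPer = 15)
  ann2 <- rbind(ann, transform(ann, bout_id = paste0(bout_id, "_copy")))
  ft1 <- standardizeFeatures(buildFeatures(ann))
  ft2 <- standardizeFeatures(buildFeatures(ann2))
  r1 <- kmeansCalls(ft1, k = 3, seed = 5)
  r2 <- kmeansCalls(ft2, k = 3, seed = 5)
  # compare in the original units: each table has its own (n-1) scaling
  unstd <- function(r) {
    m <- sweep(centroids(r), 2, unname(r@standardization$scale), "*")
    m <- sweep(m, 2, unname(r@standardization$center), "+")
    m[order(m[, 1]), ]
  }
  expect_equal(unstd(r1), unstd(r2), tolerance = 1e-9)
})

test_that("clustering is deterministic given the seed and validates input", {
  ann <- plantedBlobs(nPer = 10)
  ft <- standardizeFeatures(buildFeatures(ann))
  expect_identical(assignments(kmeansCalls(ft, 3, seed = 7)),
                   assignments(kmeansCalls(ft, 3, seed = 7)))
  expect_error(kmeansCalls(buildFeatures(ann), 3), "standardized")
  expect_error(kmeansCalls(ft, k = 50), "fewer rows")
})

test_that("label mapping recovers planted labels and ranks by duration", {
  ann <- plantedBlobs()
  ft <- standardizeFeatures(buildFeatures(ann))
  res <- mapClusters(kmeansCalls(ft, 3, seed = 1), ann$call_type)
  expect_gte(mean(predictedLabels(res) == ann$call_type), 0.99)

  # unsupervised k = 3 heuristic: longest = FTR, middle = IR, shortest = grunt
  res2 <- mapClusters(kmeansCalls(ft, 3, seed = 1))
  durs <- res2@centroids[, 1] * res2@standardization$scale["duration_s"] +
    res2@standardization$center["duration_s"]
  expect_identical(labelMap(res2)[order(durs, decreasing = TRUE)],
                   c("full_throated_roar", "intermediary_roar", "grunt"))
  expect_error(mapClusters(kmeansCalls(ft, 3, seed = 1), ann$call_type[1:5]),
               "match")
})

test_that("predictFtr returns the planted full-throated roars", {
  ann <- plantedBlobs()
  ftr <- predictFtr(ann, seed = 2)
  expect_setequal(ftr$bout_id,
                  ann$bout_id[ann$call_type == "full_throated_roar"])
  expect_identical(predictFtr(ann, seed = 2)$bout_id, ftr$bout_id)
  # moans must be removed upstream
  moany <- plantedBlobs(nPer = 5)
  moany$call_type[1] <- "moan"
  expect_error(predictFtr(moany), "moans")
})
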