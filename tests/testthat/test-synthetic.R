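test_that("zero noise reproduces the deterministic template", {
  spec <- callTypeSpecs()$full_throated_roar
  ctr <- genContour("full_throated_roar", spec, seed = 3, durationS = 1,
                    maxFreqHz = 320, noiseSdHz = 0)
  tmpl <- contourTemplate("full_throated_roar", 1, spec$f0Scale * 320)
  expect_equal(f0Values(ctr), unname(tmpl[, "f0_hz"]))
  expect_equal(frameTimes(ctr), unname(tmpl[, "time_s"]))
  # arch peaks at the asymmetry point
  expect_equal(which.max(tmpl[, "f0_hz"]) / nrow(tmpl), 0.25, tolerance = 0.05)
})

test_that("contour generation is seed-deterministic", {
  a <- genContour("moan", seed = 9)
  b <- genContour("moan", seed = 9)
  expect_identical(f0Values(a), f0Values(b))
  expect_false(identical(f0Values(a), f0Values(genContour("moan", seed = 10))))
})

test_that("individual peak scaling shifts mean peak F0 proportionally", {
  spec <- callTypeSpecs()$full_throated_roar
  i1 <- individualSpec("a", peakScale = 1.0)
  i2 <- individualSpec("b", peakScale = 1.3)
  peaks <- function(ind) vapply(1:100, function(s)
    max(f0Values(genContour("full_throated_roar", spec, ind, seed = s))),
    numeric(1))
  ratio <- mean(peaks(i2)) / mean(peaks(i1))
  expect_lt(abs(ratio - 1.3), 0.065)  # 5% of the planted ratio
})

test_that("bouts follow the stage grammar with the requested counts", {
  bout <- genBout("b1", counts = c(moan = 2, full_throated_roar = 3,
                                   intermediary_roar = 2, grunt = 8),
                  seed = 2)
  expect_equal(nrow(bout$annotations), 15)
  expect_identical(bout$annotations$call_type,
                   rep(callTypes(), c(2, 3, 2, 8)))
  expect_equal(length(bout$contours), 15)

  only <- genBout("b2", counts = c(grunt = 4), seed = 3)
  expect_true(all(only$annotations$call_type == "grunt"))
  expect_error(genBout("b3", counts = c(grunt = -1)), "non-negative")
})

test_that("intermediary roars always sit after FTRs and before grunts", {
  for (s in 1:50) {
    ann <- genBout(paste0("b", s), seed = s)$annotations
    stage <- match(ann$call_type, callTypes())
    expect_true(all(diff(stage) >= 0))  # stages never go backwards
    expect_true(all(diff(ann$begin_s) > 0))
  }
})

test_that("datasets are reproducible and carry per-bout truth", {
  ds <- genDataset(5, 10, seed = 4)
  expect_equal(length(unique(ds$annotations$bout_id)), 50)
  expect_equal(length(ds$contours), nrow(ds$annotations))
  expect_equal(nrow(ds$individuals), 5)
  ds2 <- genDataset(5, 10, seed = 4)
  expect_identical(ds$annotations, ds2$annotations)
  expect_identical(f0Values(ds$contours[[300]]), f0Values(ds2$contours[[300]]))
})

test_that("zero separation makes call types indistinguishable to K-means", {
  ds0 <- genDataset(3, 8, separation = 0, seed = 6)
  rep0 <- runCalltypeKmeans(ds0$annotations, k = 4)
  # near chance: no better than the largest class share plus slack
  share <- max(table(ds0$annotations$call_type)) /
    nrow(ds0$annotations)
  expect_lt(unname(microMetrics(rep0)["traceAccuracy"]), share + 0.15)
})

test_that("rendered audio round-trips through the pitch tracker", {
  flat <- f0Contour(rep(150, 250), seq(0.002, by = 0.004, length.out = 250))
  aud <- renderAudio(flat, 16000, harmonics = 3, snrDb = 30, seed = 5)
  expect_equal(sampleRate(aud), 16000)
  est <- extractF0(bandpass(aud))
  expect_lte(abs(median(f0Values(est)) - 150), lagStep(150))

  # same seed, same waveform
  aud2 <- renderAudio(flat, 16000, harmonics = 3, snrDb = 30, seed = 5)
  expect_identical(samples(aud), samples(aud2))

  # noise only: voicing gate leaves (almost) nothing
  noise <- renderAudio(flat, 16000, harmonics = 1, snrDb = -Inf, seed = 6)
  expect_lte(length(extractF0(noise)), 25)

  expect_error(renderAudio(flat, rate = 800, harmonics = 3), "Nyquist")
})
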