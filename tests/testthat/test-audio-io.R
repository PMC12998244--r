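test_that("WAV round trip preserves samples, rate and channels", {
  path <- withr::local_tempfile(fileext = ".wav")

  zeros <- audioClip(numeric(16000), 16000)
  writeWav(zeros, path)
  back <- readWav(path)
  expect_equal(nSamples(back), 16000)
  expect_equal(sampleRate(back), 16000)
  expect_true(all(samples(back) == 0))

  set.seed(1)
  quad <- audioClip(matrix(runif(4000, -1, 1), ncol = 4), 16000)
  writeWav(quad, path)
  back <- readWav(path)
  expect_equal(nChannels(back), 4)
  # float32 storage: agreement to single precision
  expect_equal(samples(back), samples(quad), tolerance = 1e-7)

  writeWav(quad, path, format = "pcm16")
  expect_equal(samples(readWav(path)), samples(quad), tolerance = 1e-4)
})

test_that("readWav rejects missing and non-WAV files", {
  expect_error(readWav(file.path(tempdir(), "nope.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeLines("definitely not audio data at all", bad)
  expect_error(readWav(bad), "RIFF")
})

test_that("selection tables round trip and resolve default columns", {
  ann <- callAnnotations(
    bout_id = c("b1", "b1", "b2"), source_id = c("s1", "s1", "s2"),
    call_type = c("moan", "grunt", NA),
    begin_s = c(0.5, 2.25, 1.0), end_s = c(1.75, 2.5, 2.2337),
    max_freq_hz = c(110.5, 120, 333.25))
  path <- withr::local_tempfile(fileext = ".txt")
  writeSelectionTable(ann, path)
  back <- readSelectionTable(path)
  expect_equal(nrow(back), 3)
  expect_identical(back$begin_s, ann$begin_s)
  expect_identical(back$duration_s, ann$duration_s)
  expect_identical(back$call_type, ann$call_type)
  expect_identical(back$bout_id, ann$bout_id)
})

test_that("duration falls back to end - begin without a Delta Time column", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Begin Time (s)\tEnd Time (s)\tMax Freq (Hz)",
               "2.0\t3.5\t200"), path)
  ann <- readSelectionTable(path)
  expect_equal(ann$duration_s, 1.5)
})

test_that("schema and parse errors name the offending column and row", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Begin Time (s)\tEnd Time (s)", "0\t1"), path)
  expect_error(readSelectionTable(path), "max_freq")

  writeLines(c("Begin Time (s)\tEnd Time (s)\tMax Freq (Hz)",
               "0\t1\t100", "oops\t2\t100"), path)
  expect_error(readSelectionTable(path), "row 2")

  # a column map absorbs dialect drift
  writeLines(c("Start\tStop\tPeak Hz", "0.25\t1.5\t140"), path)
  ann <- readSelectionTable(path, columnMap = list(
    begin = "Start", end = "Stop", max_freq = "Peak Hz"))
  expect_equal(ann$max_freq_hz, 140)
})

test_that("annotation invariants are enforced", {
  expect_error(callAnnotations("b", begin_s = 1, end_s = 1,
                               max_freq_hz = 100), "end_s")
  expect_error(callAnnotations("b", begin_s = 0, end_s = 1,
                               max_freq_hz = -5), "max_freq")
  expect_error(callAnnotations("b", begin_s = 0, end_s = 1,
                               max_freq_hz = 100, duration_s = 2),
               "inconsistent")
  # overlapping calls within one bout
  expect_error(callAnnotations("b", begin_s = c(0, 0.5), end_s = c(1, 1.5),
                               max_freq_hz = 100), "overlap")
})

test_that("sliceCall extracts the annotated interval of one channel", {
  rate <- 16000
  x <- matrix(seq_len(3 * rate * 2), ncol = 2) / (6 * rate)
  clip <- audioClip(x, rate)
  ann <- callAnnotations("b", begin_s = 1, end_s = 2, max_freq_hz = 100)

  cut <- sliceCall(clip, ann, channel = 1)
  expect_equal(nSamples(cut), rate)
  # start sample = floor(begin * rate), 0-based -> row 16001
  expect_equal(samples(cut)[1, 1], x[rate + 1, 1])
  expect_equal(nChannels(cut), 1)

  whole <- sliceCall(clip, callAnnotations("b", begin_s = 0, end_s = 3,
                                           max_freq_hz = 100), 2)
  expect_equal(as.numeric(samples(whole)), x[, 2])

  expect_error(sliceCall(clip, callAnnotations("b", begin_s = 3.5, end_s = 4,
                                               max_freq_hz = 100)),
               "outside")
  # slice length error <= 1 sample vs duration * rate
  for (d in c(0.333, 0.5011, 1.25)) {
    a <- callAnnotations("b", begin_s = 0.1, end_s = 0.1 + d,
                         max_freq_hz = 100)
    expect_lte(abs(nSamples(sliceCall(clip, a)) - d * rate), 1)
  }
})
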