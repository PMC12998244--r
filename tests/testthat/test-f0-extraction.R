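test_that("bandpass passes the band and attenuates beyond it", {
  for (mode in c("butterworth", "fft_hann")) {
    cfg <- f0Config(filterMode = mode)
    inBand <- bandpass(toneClip(200, 2), cfg)
    expect_identical(attr(inBand, "filter_mode"), mode)
    expect_equal(nSamples(inBand), 32000)
    mid <- 8001:24000  # steady-state region away from filter edges
    rms <- function(clip) sqrt(mean(samples(clip)[mid]^2))
    expect_gte(rms(inBand) / sqrt(0.5), 0.9)

    expect_lte(rms(bandpass(toneClip(2000, 2), cfg)) / sqrt(0.5), 0.05)
    # >= 40 dB one octave beyond each band edge
    expect_lte(rms(bandpass(toneClip(750, 2), cfg)) / sqrt(0.5), 0.01)
    expect_lte(rms(bandpass(toneClip(15, 2), cfg)) / sqrt(0.5), 0.01)
  }
})

test_that("bandpass of silence is silence and bad bands are refused", {
  out <- bandpass(audioClip(numeric(4000), 16000))
  expect_true(all(abs(samples(out)) < 1e-12))
  expect_error(bandpass(toneClip(100), f0Config(bandHighHz = 9000)),
               "Nyquist")
})

test_that("a pure tone is tracked at its frequency", {
  f0 <- extractF0(toneClip(200))
  expect_gt(length(f0), 100)
  expect_lte(abs(median(f0Values(f0)) - 200), lagStep(200))
  # frame grid is deterministic: hop = acWindow / 2
  expect_equal(unique(round(diff(frameTimes(f0)) * 16000)), 64)
})

test_that("a harmonic stack resolves to its fundamental, not a harmonic", {
  t <- seq_len(16000) / 16000
  stack <- audioClip(sin(2 * pi * 150 * t) + 0.5 * sin(2 * pi * 300 * t) +
                     0.33 * sin(2 * pi * 450 * t), 16000)
  est <- median(f0Values(extractF0(stack)))
  expect_lte(abs(est - 150), lagStep(150))
})

test_that("extractF0 agrees with the brute-force autocorrelation oracle", {
  set.seed(7)
  cfg <- f0Config(smoothFrames = 1)  # frame-by-frame comparison
  for (f in c(90, 180, 310)) {
    t <- seq_len(4096) / 16000
    x <- sin(2 * pi * f * t) + rnorm(4096, 0, 0.05)
    clip <- audioClip(x, 16000)
    est <- f0Values(extractF0(clip, cfg))
    hop <- 64L
    for (frame in seq_along(est)) {
      oracle <- bruteForceF0(x, 16000, start = (frame - 1L) * hop + 1L)
      expect_equal(est[frame], oracle)
    }
  }
})

test_that("silence and noise yield empty contours; short clips error", {
  expect_equal(length(extractF0(audioClip(numeric(4000), 16000))), 0)
  set.seed(3)
  noise <- audioClip(rnorm(16000, 0, 0.1), 16000)
  expect_lte(length(extractF0(noise)), 12)  # voicing gate rejects noise
  expect_error(extractF0(audioClip(numeric(64), 16000)), "shorter")
})

test_that("retained frames stay within one lag step across the band", {
  # periodic signals at 20 dB SNR; >= 90% of frames within one lag step
  set.seed(11)
  for (f in c(45, 120, 260, 340)) {
    t <- seq_len(16000) / 16000
    sig <- sin(2 * pi * f * t) + 0.5 * sin(2 * pi * 2 * f * t)
    x <- sig + rnorm(16000, 0, sqrt(mean(sig^2)) / 10)
    f0 <- extractF0(bandpass(audioClip(x, 16000)))
    expect_gt(length(f0), 20)
    ok <- abs(f0Values(f0) - f) <= lagStep(f) + 1e-9
    expect_gte(mean(ok), 0.9)
  }
})

test_that("contour frame count depends only on clip length and config", {
  set.seed(5)
  n1 <- length(extractF0(audioClip(sin(2 * pi * 100 * seq_len(8000) / 16000),
                                   16000)))
  n2 <- length(extractF0(audioClip(0.3 * sin(2 * pi * 250 *
                                             seq_len(8000) / 16000 + 1),
                                   16000)))
  expect_equal(n1, n2)
})
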