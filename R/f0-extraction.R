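#' F0 extraction configuration
#'
#' Parameters of the band-limited autocorrelation pitch tracker. Defaults
#' follow the roaring-bout workflow: calls are bandpass-filtered to the
#' 30-375 Hz band in which lion F0 lives, and F0 is measured per 128-sample
#' window by normalized autocorrelation over the lags spanning that band.
#'
#' @param bandLowHz lower band edge (Hz); default 30.
#' @param bandHighHz upper band edge (Hz); default 375.
#' @param filterWindow Hann window length in samples for the `fft_hann`
#'   filter mode; default 2048.
#' @param filterOverlap window overlap fraction for `fft_hann`; default 0.68.
#' @param acWindow autocorrelation window in samples; default 128.
#' @param amplitudeTopFraction amplitude gate as a fraction of the clip's
#'   maximum absolute amplitude: frames whose peak falls below
#'   `amplitudeTopFraction * max(|x|)` are marked missing; default 0.01 (1%).
#' @param minAc voicing gate: frames whose best normalized autocorrelation
#'   falls below this are marked missing (unvoiced/noise); default 0.4.
#' @param peakTolerance relative tolerance band under the global
#'   autocorrelation maximum within which the shortest local-maximum lag is
#'   preferred; guards against octave (period-doubling) errors. Default 0.02.
#' @param smoothFrames odd width of the running-median filter applied to the
#'   retained contour values; suppresses isolated lag-jitter frames, which
#'   matter most at low F0 where the lag grid is dense. 1 disables. Default 5.
#' @param filterMode `"butterworth"` (zero-phase 4th-order Butterworth
#'   cascade, applied forward-backward) or `"fft_hann"` (windowed FFT
#'   band masking with overlap-add).
#' @return A list of class `F0Config`.
#' @seealso [bandpass()], [extractF0()]
#' @export
f0Config <- function(bandLowHz = 30, bandHighHz = 375, filterWindow = 2048,
                     filterOverlap = 0.68, acWindow = 128,
                     amplitudeTopFraction = 0.01, minAc = 0.4,
                     peakTolerance = 0.02, smoothFrames = 5L,
                     filterMode = c("butterworth", "fft_hann")) {
  filterMode <- match.arg(filterMode)
  if (smoothFrames < 1 || smoothFrames %% 2 == 0)
    stopValidation("smoothFrames must be a positive odd integer")
  if (bandLowHz <= 0 || bandHighHz <= bandLowHz)
    stopValidation("require 0 < bandLowHz < bandHighHz")
  if (filterOverlap <= 0 || filterOverlap >= 1)
    stopValidation("filterOverlap must be in (0, 1)")
  if (acWindow < 8)
    stopValidation("acWindow must be at least 8 samples")
  structure(list(bandLowHz = bandLowHz, bandHighHz = bandHighHz,
                 filterWindow = as.integer(filterWindow),
                 filterOverlap = filterOverlap,
                 acWindow = as.integer(acWindow),
                 amplitudeTopFraction = amplitudeTopFraction,
                 minAc = minAc, peakTolerance = peakTolerance,
                 smoothFrames = as.integer(smoothFrames),
                 filterMode = filterMode),
            class = "F0Config")
}

#' Bandpass-filter a call
#'
#' Restricts a mono clip to the configured frequency band. The default mode
#' applies a 4th-order Butterworth high-pass/low-pass cascade forward and
#' backward (zero phase); `fft_hann` mode masks FFT bins outside the band
#' under a moving Hann window with overlap-add. Both attenuate energy one
#' octave beyond each band edge by over 40 dB. The mode used is attached as
#' attribute `filter_mode` on the result.
#'
#' @param clip a mono [AudioClip-class].
#' @param cfg an [f0Config()].
#' @return A filtered [AudioClip-class] of the same length and rate.
#' @export
bandpass <- function(clip, cfg = f0Config()) {
  stopifnot(is(clip, "AudioClip"))
  if (nChannels(clip) != 1L)
    stopValidation("bandpass expects a mono clip; use sliceCall() first")
  rate <- sampleRate(clip)
  if (cfg$bandHighHz >= rate / 2)
    stopValidation("bandHighHz (%g) must be below Nyquist (%g)",
                   cfg$bandHighHz, rate / 2)
  x <- as.numeric(samples(clip))
  y <- if (cfg$filterMode == "butterworth") {
    hp <- signal::butter(4, cfg$bandLowHz / (rate / 2), type = "high")
    lp <- signal::butter(4, cfg$bandHighHz / (rate / 2), type = "low")
    as.numeric(signal::filtfilt(lp, signal::filtfilt(hp, x)))
  } else {
    .fftHannBandpass(x, rate, cfg)
  }
  out <- audioClip(y, rate)
  attr(out, "filter_mode") <- cfg$filterMode
  out
}

## Windowed FFT band masking with overlap-add; analysis Hann window, output
## normalised by the accumulated window profile.
.fftHannBandpass <- function(x, rate, cfg) {
  w <- cfg$filterWindow
  hop <- max(1L, as.integer(round(w * (1 - cfg$filterOverlap))))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1))
  n <- length(x)
  xp <- c(numeric(w), x, numeric(2L * w))
  acc <- numeric(length(xp))
  norm <- numeric(length(xp))
  freqs <- (seq_len(w) - 1) * rate / w
  freqsFolded <- pmin(freqs, rate - freqs)
  keep <- freqsFolded >= cfg$bandLowHz & freqsFolded <= cfg$bandHighHz
  starts <- seq(1L, length(xp) - w + 1L, by = hop)
  for (s in starts) {
    seg <- xp[s:(s + w - 1L)] * win
    sp <- stats::fft(seg)
    sp[!keep] <- 0
    back <- Re(stats::fft(sp, inverse = TRUE)) / w
    acc[s:(s + w - 1L)] <- acc[s:(s + w - 1L)] + back * win
    norm[s:(s + w - 1L)] <- norm[s:(s + w - 1L)] + win^2
  }
  y <- acc / pmax(norm, 1e-12)
  y[(w + 1L):(w + n)]
}

#' Extract a fundamental-frequency contour
#'
#' Windowed normalized-autocorrelation pitch tracking. The clip is scanned in
#' `acWindow`-sample frames hopping by half a window. Per frame, the
#' normalized cross-correlation between the frame and its lagged copy is
#' evaluated at every integer lag corresponding to the configured band; F0 is
#' `rate / lag*`. Frames failing the amplitude gate (peak below
#' `amplitudeTopFraction` of the clip maximum), the voicing gate (best
#' correlation below `minAc`), or with zero energy are dropped.
#'
#' Octave disambiguation: the correlation of a periodic signal is equally
#' high at its period and at multiples of it, so among local maxima within
#' `peakTolerance` of the global maximum the shortest lag (the true period,
#' hence the lowest frequency that explains all periodicity) is taken.
#' A running median of `smoothFrames` retained values then suppresses
#' isolated lag-jitter frames.
#'
#' @param clip a mono, ideally bandpass-filtered [AudioClip-class].
#' @param cfg an [f0Config()].
#' @param callRef optional call identifier stored on the contour.
#' @return An [F0Contour-class]; retained frames only.
#' @examples
#' clip <- audioClip(sin(2 * pi * 200 * seq_len(16000) / 16000), 16000)
#' f0 <- extractF0(clip)
#' median(f0Values(f0))  # 200 Hz
#' @export
extractF0 <- function(clip, cfg = f0Config(), callRef = NA_character_) {
  stopifnot(is(clip, "AudioClip"))
  if (nChannels(clip) != 1L)
    stopValidation("extractF0 expects a mono clip")
  x <- as.numeric(samples(clip))
  n <- length(x)
  w <- cfg$acWindow
  if (n <= w)
    stopValidation("clip of %d samples shorter than one %d-sample window: empty contour",
                   n, w)
  rate <- sampleRate(clip)
  lagMin <- max(1L, as.integer(round(rate / cfg$bandHighHz)))
  lagMax <- as.integer(round(rate / cfg$bandLowHz))
  lagMax <- min(lagMax, n - w)
  if (lagMax < lagMin)
    stopValidation("clip too short to search lags for the configured band")
  lags <- lagMin:lagMax
  hop <- max(1L, w %/% 2L)
  starts <- seq(1L, n - w + 1L - lagMax, by = hop)
  if (!length(starts))
    stopValidation("clip too short for one full correlation frame")

  thr <- cfg$amplitudeTopFraction * max(abs(x))
  lagIdx <- outer(lags, 0:(w - 1L), "+")  # lag x window sample offsets
  vals <- numeric(0)
  times <- numeric(0)
  for (s in starts) {
    frame <- x[s:(s + w - 1L)]
    if (max(abs(frame)) < thr) next
    e0 <- sum(frame^2)
    if (e0 <= 0) next
    seg <- x[s:(s + w - 1L + lagMax)]
    c2 <- cumsum(seg^2)
    eLag <- c2[lags + w] - c2[lags]
    cross <- as.numeric(matrix(seg[lagIdx + 1L], nrow = length(lags)) %*% frame)
    r <- cross / sqrt(e0 * pmax(eLag, 1e-300))
    m <- max(r)
    if (m < cfg$minAc) next
    lag <- .pickLag(r, lags, m, cfg$peakTolerance)
    vals <- c(vals, rate / lag)
    times <- c(times, (s - 1L + w / 2) / rate)
  }
  if (cfg$smoothFrames > 1L && length(vals) >= 3L) {
    k <- min(cfg$smoothFrames, length(vals) - (1 - length(vals) %% 2))
    vals <- as.numeric(stats::runmed(vals, k))
  }
  f0Contour(vals, times, callRef)
}

## Shortest local-maximum lag within the tolerance band below the global
## maximum: the true period is the shortest lag at which a periodic signal
## correlates fully with itself, and its multiples (subharmonics) tie with it
## only spuriously.
.pickLag <- function(r, lags, m, tol) {
  nl <- length(r)
  isLocalMax <- rep(TRUE, nl)
  if (nl > 1L) {
    isLocalMax[-1L] <- r[-1L] >= r[-nl]
    isLocalMax[-nl] <- isLocalMax[-nl] & (r[-nl] >= r[-1L])
  }
  cand <- which(isLocalMax & r >= m * (1 - tol))
  if (!length(cand)) cand <- which.max(r)
  lags[cand[1L]]
}
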