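## Synthetic roaring bouts. A complete bout follows the fixed stage grammar
## moans -> full-throated roars -> intermediary roars -> grunts; every call
## gets a (duration, max frequency) feature draw and an F0 contour from a
## parametric template (arched rise-fall for roars, quasi-flat for moans, a
## brief pulse for grunts). Per-individual multiplicative signatures (peak
## scale, arch asymmetry, duration scale) make lions separable, emulating the
## individually identifiable full-throated roar. Templates are parametric
## stand-ins shaped like field contours, not estimates of any real dataset.

#' Call-type specifications for the synthetic generator
#'
#' Defaults place the four call types in the qualitative layout of real
#' roaring bouts: grunts shortest and lowest, intermediary roars in the
#' middle, full-throated roars longest and highest, and moans long, low in
#' maximum frequency and highly variable, overlapping the roars in duration.
#' `separation` rescales the spread of the type means around their grand
#' mean in units of one third (so `separation = 3` is the default geometry
#' and `separation = 0` collapses all type means).
#'
#' @param separation spread of type feature means, in the generator's
#'   default-geometry units (3 = default layout; 0 = indistinguishable).
#' @return Named list of call-type specs (duration and max-frequency mean/sd,
#'   F0 peak as a fraction of max frequency, contour shape, per-bout count
#'   range).
#' @export
callTypeSpecs <- function(separation = 3) {
  ## freqSd is the spread of the bounding-box maximum frequency (the
  ## clustering feature); f0Sd is the spread of the contour F0 level. For
  ## moans and grunts the two are decoupled: their bounding-box maximum moves
  ## with harmonic content while the emitted F0 stays stereotyped, which is
  ## exactly why moans cluster poorly on features yet remain recognisable by
  ## contour. Roar contours instead follow the drawn maximum frequency (the
  ## arch peak carries the individual signature), so f0Sd is unused there.
  base <- list(
    moan = list(durMean = 1.2, durSd = 0.45, freqMean = 110, freqSd = 35,
                f0Scale = 0.95, f0Sd = 8, shape = "flat",
                countRange = c(1L, 3L)),
    full_throated_roar = list(durMean = 1.0, durSd = 0.15, freqMean = 320,
                              freqSd = 10, f0Scale = 0.75, f0Sd = NA,
                              shape = "arch", countRange = c(2L, 4L)),
    intermediary_roar = list(durMean = 0.5, durSd = 0.09, freqMean = 210,
                             freqSd = 10, f0Scale = 0.75, f0Sd = NA,
                             shape = "arch", countRange = c(1L, 3L)),
    grunt = list(durMean = 0.15, durSd = 0.04, freqMean = 120, freqSd = 12,
                 f0Scale = 0.60, f0Sd = 6, shape = "pulse",
                 countRange = c(4L, 10L)))
  if (separation < 0) stopValidation("separation must be non-negative")
  durGm <- mean(vapply(base, `[[`, numeric(1), "durMean"))
  freqGm <- mean(vapply(base, `[[`, numeric(1), "freqMean"))
  s <- separation / 3
  for (ct in names(base)) {
    base[[ct]]$durMean <- durGm + (base[[ct]]$durMean - durGm) * s
    base[[ct]]$freqMean <- freqGm + (base[[ct]]$freqMean - freqGm) * s
  }
  base
}

#' Per-individual contour signature
#'
#' @param lionId individual identifier.
#' @param peakScale multiplicative scale on roar peak frequency.
#' @param asymmetry fraction of the roar duration at which the arch peaks.
#' @param durationScale multiplicative scale on roar durations.
#' @return A list of class `IndividualSpec`.
#' @export
individualSpec <- function(lionId, peakScale = 1, asymmetry = 0.25,
                           durationScale = 1) {
  if (peakScale <= 0 || durationScale <= 0)
    stopValidation("signature scales must be positive")
  structure(list(lionId = as.character(lionId), peakScale = peakScale,
                 asymmetry = asymmetry, durationScale = durationScale),
            class = "IndividualSpec")
}

#' Deterministic F0 contour template
#'
#' The noise-free contour a call type follows. Roars are an asymmetric arch
#' in log-F0 (half-cosine rise from 60% of peak to the peak at
#' `asymmetry * duration`, half-cosine fall to 45%); moans are quasi-flat
#' with a slow drift; grunts a brief symmetric pulse.
#'
#' @param callType one of [callTypes()].
#' @param durationS call duration (s).
#' @param peakHz contour peak F0 (Hz).
#' @param asymmetry arch peak position as a fraction of duration.
#' @param hopS frame spacing (s); default 0.004 matches the extraction hop
#'   of 64 samples at 16 kHz.
#' @return Numeric matrix with columns `time_s` and `f0_hz`.
#' @export
contourTemplate <- function(callType, durationS, peakHz, asymmetry = 0.25,
                            hopS = 0.004) {
  times <- seq(hopS / 2, durationS, by = hopS)
  if (!length(times)) times <- durationS / 2
  u <- times / durationS
  f0 <- switch(callType,
    moan = peakHz * (1 + 0.03 * sin(2 * pi * u)),
    grunt = {
      lf <- ifelse(u <= 0.5,
        log(0.7 * peakHz) + (log(peakHz) - log(0.7 * peakHz)) *
          (1 - cos(pi * u / 0.5)) / 2,
        log(peakHz) + (log(0.6 * peakHz) - log(peakHz)) *
          (1 - cos(pi * (u - 0.5) / 0.5)) / 2)
      exp(lf)
    },
    {
      ## arch (full-throated and intermediary roars)
      a <- asymmetry
      lf <- ifelse(u <= a,
        log(0.6 * peakHz) + (log(peakHz) - log(0.6 * peakHz)) *
          (1 - cos(pi * u / a)) / 2,
        log(peakHz) + (log(0.45 * peakHz) - log(peakHz)) *
          (1 - cos(pi * (u - a) / (1 - a))) / 2)
      exp(lf)
    })
  cbind(time_s = times, f0_hz = f0)
}

#' Generate one synthetic F0 contour
#'
#' Samples a contour from the call type's template: duration and maximum
#' frequency are drawn from the type spec (unless supplied), the individual
#' signature scales roar peak frequency, arch asymmetry and duration, and
#' i.i.d. Gaussian frame noise is added.
#'
#' @param callType one of [callTypes()].
#' @param spec the call type's spec from [callTypeSpecs()].
#' @param individual optional [individualSpec()].
#' @param seed integer seed; the same seed reproduces the contour exactly.
#' @param durationS,maxFreqHz optional fixed feature values (otherwise drawn).
#' @param noiseSdHz per-frame F0 noise (Hz); 0 gives the deterministic
#'   template.
#' @param hopS frame spacing (s).
#' @param callRef identifier stored on the contour.
#' @return An [F0Contour-class].
#' @export
genContour <- function(callType, spec = callTypeSpecs()[[callType]],
                       individual = NULL, seed = 1L, durationS = NULL,
                       maxFreqHz = NULL, noiseSdHz = 4, hopS = 0.004,
                       callRef = NA_character_) {
  isRoar <- callType %in% c("full_throated_roar", "intermediary_roar")
  set.seed(childSeed(seed, 601L))
  if (is.null(durationS)) {
    durationS <- rnorm(1, spec$durMean, spec$durSd)
    if (isRoar && !is.null(individual))
      durationS <- durationS * individual$durationScale
    durationS <- max(durationS, 0.05)
  }
  if (is.null(maxFreqHz)) {
    maxFreqHz <- rnorm(1, spec$freqMean, spec$freqSd)
    if (isRoar && !is.null(individual))
      maxFreqHz <- maxFreqHz * individual$peakScale
    maxFreqHz <- max(maxFreqHz, 45)
  }
  asym <- if (!is.null(individual) && isRoar) individual$asymmetry else 0.25
  peakHz <- if (isRoar || is.null(spec$f0Sd) || is.na(spec$f0Sd)) {
    spec$f0Scale * maxFreqHz
  } else {
    ## moan/grunt F0 level: stereotyped around the type mean, independent of
    ## the call's (harmonics-driven) bounding-box maximum
    max(spec$f0Scale * spec$freqMean + rnorm(1, 0, spec$f0Sd), 40)
  }
  tmpl <- contourTemplate(callType, durationS, peakHz,
                          asymmetry = asym, hopS = hopS)
  f0 <- tmpl[, "f0_hz"]
  if (noiseSdHz > 0) f0 <- f0 + rnorm(length(f0), 0, noiseSdHz)
  f0 <- pmin(pmax(f0, 32), 372)
  out <- f0Contour(f0, tmpl[, "time_s"], callRef)
  ## the drawn call features travel with the contour so annotation tables
  ## carry the true draw, not the noisy frame extrema
  attr(out, "durationS") <- durationS
  attr(out, "maxFreqHz") <- maxFreqHz
  out
}

#' Generate one synthetic roaring bout
#'
#' Draws per-stage call counts (or uses `counts`), lays the calls out in the
#' fixed grammar order moans, full-throated roars, intermediary roars, grunts
#' with random inter-call gaps, and generates one contour per call. The
#' intermediary roars therefore always fall after the full-throated roars and
#' before the grunts.
#'
#' @param boutId bout identifier.
#' @param typeSpecs call-type specs from [callTypeSpecs()].
#' @param individual optional [individualSpec()]; also used as the source id.
#' @param seed integer seed.
#' @param counts optional named integer vector of per-type call counts
#'   overriding the spec's count ranges (names from [callTypes()]).
#' @param gapRangeS inter-call silent gap range (s).
#' @param noiseSdHz per-frame contour noise (Hz).
#' @return List with `annotations` (a call-annotation data.frame) and
#'   `contours` (parallel list of [F0Contour-class]).
#' @export
genBout <- function(boutId, typeSpecs = callTypeSpecs(), individual = NULL,
                    seed = 1L, counts = NULL, gapRangeS = c(0.5, 2),
                    noiseSdHz = 4) {
  if (!is.null(counts)) {
    if (any(counts < 0)) stopValidation("call counts must be non-negative")
    counts <- counts[CALL_TYPES]
    counts[is.na(counts)] <- 0L
    names(counts) <- CALL_TYPES
  } else {
    set.seed(childSeed(seed, 602L))
    counts <- vapply(CALL_TYPES, function(ct) {
      rg <- typeSpecs[[ct]]$countRange
      sample(rg[1]:rg[2], 1L)
    }, integer(1))
  }
  sourceId <- if (is.null(individual)) boutId else individual$lionId

  rows <- list(); contours <- list()
  t0 <- 0; idx <- 0L
  for (ct in CALL_TYPES) {
    for (j in seq_len(counts[[ct]])) {
      idx <- idx + 1L
      ref <- sprintf("%s_c%03d", boutId, idx)
      ctr <- genContour(ct, typeSpecs[[ct]], individual,
                        seed = childSeed(seed, 603L, idx),
                        noiseSdHz = noiseSdHz, callRef = ref)
      dur <- attr(ctr, "durationS")
      maxFreq <- attr(ctr, "maxFreqHz")
      set.seed(childSeed(seed, 604L, idx))
      gap <- runif(1, gapRangeS[1], gapRangeS[2])
      begin <- t0 + gap
      rows[[idx]] <- data.frame(bout_id = boutId, source_id = sourceId,
                                call_type = ct, begin_s = begin,
                                end_s = begin + dur, max_freq_hz = maxFreq,
                                duration_s = dur, stringsAsFactors = FALSE)
      contours[[idx]] <- ctr
      t0 <- begin + dur
    }
  }
  if (!idx) stopValidation("bout with zero calls")
  list(annotations = validateAnnotations(do.call(rbind, rows)),
       contours = contours)
}

#' Generate a labeled synthetic corpus of roaring bouts
#'
#' Builds `nIndividuals` lions with evenly spaced contour signatures (peak
#' scale spanning `1 +/- signatureSpread`, with asymmetry and duration-scale
#' signatures interleaved so no two lions share a profile) and
#' `boutsPerIndividual` bouts each. Per-call features follow
#' [callTypeSpecs()] at the requested `separation`.
#'
#' @param nIndividuals number of lions.
#' @param boutsPerIndividual bouts per lion.
#' @param separation call-type mean separation (see [callTypeSpecs()]).
#' @param signatureSpread half-range of the per-lion peak-frequency scale;
#'   0.15 spreads lion peaks over +/- 15%.
#' @param seed integer seed; fixed seed gives a byte-identical corpus.
#' @param noiseSdHz per-frame contour noise (Hz).
#' @return List with `annotations`, `contours` (parallel list),
#'   `individuals` (signature table) and `typeSpecs`.
#' @export
genDataset <- function(nIndividuals = 5L, boutsPerIndividual = 10L,
                       separation = 3, signatureSpread = 0.15, seed = 1L,
                       noiseSdHz = 4) {
  if (nIndividuals < 1L) stopValidation("need at least one individual")
  specs <- callTypeSpecs(separation)
  peak <- if (nIndividuals == 1L) 1 else
    seq(1 - signatureSpread, 1 + signatureSpread, length.out = nIndividuals)
  asym <- seq(0.18, 0.32, length.out = max(nIndividuals, 2L))[
    ((seq_len(nIndividuals) * 2L - 1L) %% max(nIndividuals, 2L)) + 1L]
  durS <- seq(0.9, 1.1, length.out = max(nIndividuals, 2L))[
    ((seq_len(nIndividuals) * 3L - 2L) %% max(nIndividuals, 2L)) + 1L]
  individuals <- lapply(seq_len(nIndividuals), function(i)
    individualSpec(sprintf("L%02d", i), peakScale = peak[i],
                   asymmetry = asym[i], durationScale = durS[i]))

  annList <- list(); contours <- list()
  for (i in seq_len(nIndividuals)) {
    for (b in seq_len(boutsPerIndividual)) {
      bout <- genBout(sprintf("%s_b%02d", individuals[[i]]$lionId, b),
                      specs, individuals[[i]],
                      seed = childSeed(seed, 605L, i, b),
                      noiseSdHz = noiseSdHz)
      annList[[length(annList) + 1L]] <- bout$annotations
      contours <- c(contours, bout$contours)
    }
  }
  indDf <- data.frame(
    lion_id = vapply(individuals, `[[`, character(1), "lionId"),
    peak_scale = peak, asymmetry = asym, duration_scale = durS)
  list(annotations = do.call(rbind, annList), contours = contours,
       individuals = indDf, typeSpecs = specs)
}

#' Render a contour as audio
#'
#' Synthesises a harmonic stack that follows the contour's instantaneous F0,
#' with 1/k amplitude on the k-th harmonic, a short fade at both ends, and
#' white noise at the requested SNR. Together with [extractF0()] this closes
#' the loop for end-to-end testing of the pitch tracker.
#'
#' @param contour an [F0Contour-class].
#' @param rate sampling rate (Hz); must exceed twice the highest harmonic.
#' @param harmonics number of harmonics (1 = pure tone).
#' @param snrDb signal-to-noise ratio in dB; `-Inf` gives noise only.
#' @param seed integer seed for the noise.
#' @return An [AudioClip-class] spanning the contour.
#' @export
renderAudio <- function(contour, rate = 16000, harmonics = 3L, snrDb = 20,
                        seed = 1L) {
  stopifnot(is(contour, "F0Contour"))
  if (!length(contour)) stopValidation("cannot render an empty contour")
  fmax <- max(f0Values(contour)) * harmonics
  if (rate < 2 * fmax)
    stopValidation("rate %g Hz below Nyquist for harmonic %d at %g Hz",
                   rate, harmonics, fmax)
  dur <- max(frameTimes(contour)) + min(frameTimes(contour))
  n <- max(2L, round(dur * rate))
  tt <- (seq_len(n) - 0.5) / rate
  f0 <- approx(frameTimes(contour), f0Values(contour), xout = tt,
               rule = 2)$y
  phase <- 2 * pi * cumsum(f0) / rate
  sig <- numeric(n)
  for (k in seq_len(harmonics)) sig <- sig + sin(k * phase) / k
  fade <- pmin(1, tt / 0.005, (dur - tt) / 0.005)
  sig <- sig * pmax(fade, 0)
  set.seed(childSeed(seed, 606L))
  if (is.finite(snrDb)) {
    rms <- sqrt(mean(sig^2))
    noiseSd <- rms / 10^(snrDb / 20)
    out <- sig + rnorm(n, 0, noiseSd)
  } else {
    out <- rnorm(n, 0, 0.1)
  }
  audioClip(out, rate)
}
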