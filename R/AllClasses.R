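#' AudioClip: a sampled waveform
#'
#' Container for a (possibly multi-channel) audio waveform. Samples are stored
#' column-wise, one column per channel, with the sampling rate in Hz. Lion
#' roaring bouts in this workflow arrive as 16 kHz recordings from autonomous
#' recording units; any rate is accepted.
#'
#' @slot samples numeric matrix, one column per channel, one row per frame.
#' @slot rate sampling rate in samples per second (Hz).
#'
#' @seealso [readWav()], [sliceCall()], [audioClip()]
#' @exportClass AudioClip
setClass("AudioClip",
  representation(samples = "matrix", rate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
      msg <- c(msg, "'rate' must be a single positive finite number")
    if (nrow(object@samples) < 1L)
      msg <- c(msg, "clip must contain at least one sample")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AudioClip
#'
#' @param samples numeric vector (mono) or matrix with one column per channel.
#' @param rate sampling rate in Hz.
#' @return An [AudioClip-class] object.
#' @examples
#' clip <- audioClip(sin(2 * pi * 200 * seq_len(16000) / 16000), 16000)
#' nSamples(clip)
#' @export
audioClip <- function(samples, rate) {
  if (!is.matrix(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  new("AudioClip", samples = samples, rate = as.numeric(rate))
}

#' F0Contour: a fundamental-frequency contour
#'
#' An ordered sequence of fundamental-frequency (F0) estimates in Hz with the
#' frame centre times they were measured at. Frames rejected by the amplitude
#' or voicing gates are dropped, so times need not be uniformly spaced. This is
#' the observation sequence for the Gaussian HMM classifiers.
#'
#' @slot valuesHz F0 estimates in Hz.
#' @slot frameTimesS frame centre times in seconds, strictly increasing.
#' @slot callRef identifier of the call the contour was extracted from.
#'
#' @seealso [extractF0()], [genContour()]
#' @exportClass F0Contour
setClass("F0Contour",
  representation(valuesHz = "numeric", frameTimesS = "numeric",
                 callRef = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@valuesHz) != length(object@frameTimesS))
      msg <- c(msg, "'valuesHz' and 'frameTimesS' must have equal length")
    if (length(object@frameTimesS) > 1L && any(diff(object@frameTimesS) <= 0))
      msg <- c(msg, "'frameTimesS' must be strictly increasing")
    if (any(!is.finite(object@valuesHz)) || any(object@valuesHz <= 0))
      msg <- c(msg, "'valuesHz' must be positive and finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an F0Contour
#'
#' @param valuesHz F0 values in Hz.
#' @param frameTimesS strictly increasing frame times in seconds.
#' @param callRef optional call identifier.
#' @return An [F0Contour-class] object.
#' @export
f0Contour <- function(valuesHz, frameTimesS, callRef = NA_character_) {
  new("F0Contour", valuesHz = as.numeric(valuesHz),
      frameTimesS = as.numeric(frameTimesS),
      callRef = as.character(callRef))
}

#' GaussianHMM: hidden Markov model with Gaussian emissions
#'
#' A discrete-time hidden Markov model whose states emit one-dimensional
#' Gaussian observations (F0 values in Hz). Two states are used throughout the
#' roaring-bout analysis: they partition each contour into a rising/peak part
#' and a falling/terminal part, so the pair of emission means together with the
#' transition matrix summarises a call type's (or an individual's) contour
#' shape.
#'
#' @slot initialProbs initial state distribution (sums to 1).
#' @slot transitions row-stochastic state-by-state transition matrix.
#' @slot emissionMeans per-state emission mean (Hz).
#' @slot emissionVars per-state emission variance (Hz^2), bounded below by the
#'   fitting variance floor.
#'
#' @seealso [fitHmm()], [hmmLogLik()]
#' @exportClass GaussianHMM
setClass("GaussianHMM",
  representation(initialProbs = "numeric", transitions = "matrix",
                 emissionMeans = "numeric", emissionVars = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- length(object@initialProbs)
    if (abs(sum(object@initialProbs) - 1) > 1e-9 || any(object@initialProbs < 0))
      msg <- c(msg, "'initialProbs' must be a probability simplex")
    if (!all(dim(object@transitions) == c(k, k)))
      msg <- c(msg, "'transitions' must be a square state-by-state matrix")
    else if (any(abs(rowSums(object@transitions) - 1) > 1e-9) ||
             any(object@transitions < 0))
      msg <- c(msg, "each transition row must sum to 1")
    if (length(object@emissionMeans) != k || length(object@emissionVars) != k)
      msg <- c(msg, "emission parameter length must match number of states")
    if (any(object@emissionVars <= 0))
      msg <- c(msg, "'emissionVars' must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GaussianHMM
#'
#' @param initialProbs initial state probabilities.
#' @param transitions row-stochastic transition matrix.
#' @param emissionMeans per-state Gaussian means (Hz).
#' @param emissionVars per-state Gaussian variances (Hz^2).
#' @return A [GaussianHMM-class] object.
#' @examples
#' m <- gaussianHmm(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
#'                  c(120, 300), c(100, 100))
#' hmmLogLik(m, f0Contour(c(118, 125, 290), c(0, 0.004, 0.008)))
#' @export
gaussianHmm <- function(initialProbs, transitions, emissionMeans, emissionVars) {
  new("GaussianHMM", initialProbs = as.numeric(initialProbs),
      transitions = as.matrix(transitions),
      emissionMeans = as.numeric(emissionMeans),
      emissionVars = as.numeric(emissionVars))
}

#' ConfusionMatrix: true-by-predicted counts
#'
#' Counts of classification decisions, rows indexed by the true label and
#' columns by the predicted label. Counts may be fractional when decisions
#' from repeated randomized runs are averaged.
#'
#' @slot labels ordered class labels.
#' @slot counts label-by-label non-negative matrix (true x predicted).
#'
#' @seealso [confusionCounts()], [classificationReport()]
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(labels = "character", counts = "matrix"),
  validity = function(object) {
    k <- length(object@labels)
    msg <- character()
    if (!all(dim(object@counts) == c(k, k)))
      msg <- c(msg, "'counts' must be labels x labels")
    if (any(object@counts < 0) || any(!is.finite(object@counts)))
      msg <- c(msg, "'counts' must be finite and non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' ClassificationReport: per-class, micro and macro metrics
#'
#' Performance metrics derived from a [ConfusionMatrix-class] by one-vs-rest
#' reduction. For each class, true/false positives and negatives are counted
#' and four metrics computed: accuracy (TP + TN) / (TP + TN + FP + FN), recall
#' TP / (TP + FN), precision TP / (TP + FP), and F1 = 2PR / (P + R). Micro
#' metrics apply the formulas to TP/FP/TN/FN pooled over classes; macro
#' metrics are unweighted means of per-class values. Note the accuracy formula
#' includes one-vs-rest true negatives and therefore exceeds the plain
#' fraction-correct for more than two classes; the latter is reported
#' separately as \code{traceAccuracy}.
#'
#' @slot confusion the underlying [ConfusionMatrix-class].
#' @slot perClass data.frame of per-class counts and metrics.
#' @slot micro named numeric vector (accuracy, traceAccuracy, precision,
#'   recall, f1) on pooled counts.
#' @slot macro named numeric vector of unweighted per-class means.
#'
#' @seealso [classificationReport()]
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(confusion = "ConfusionMatrix", perClass = "data.frame",
                 micro = "numeric", macro = "numeric"))

#' ClusterResult: a fitted K-means partition
#'
#' Result of Lloyd's K-means on the standardized (duration, maximum frequency)
#' feature plane, with an optional mapping from cluster index to call-type
#' label.
#'
#' @slot assignments cluster index (1..k) per row of the feature table.
#' @slot centroids k x 2 matrix of centroids in standardized feature space.
#' @slot labelMap character vector naming a call type per cluster (may be NA
#'   before [mapClusters()] is applied); injective over non-NA entries.
#' @slot inertia total within-cluster sum of squared distances.
#' @slot standardization list with per-feature center and scale used by the
#'   table the clustering was fitted on.
#'
#' @seealso [kmeansCalls()], [mapClusters()]
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(assignments = "integer", centroids = "matrix",
                 labelMap = "character", inertia = "numeric",
                 standardization = "list"),
  validity = function(object) {
    k <- nrow(object@centroids)
    msg <- character()
    if (length(object@labelMap) != k)
      msg <- c(msg, "'labelMap' must have one entry per cluster")
    lm <- object@labelMap[!is.na(object@labelMap)]
    if (anyDuplicated(lm))
      msg <- c(msg, "'labelMap' must be injective")
    if (any(object@assignments < 1L | object@assignments > k))
      msg <- c(msg, "'assignments' out of cluster range")
    if (length(msg)) msg else TRUE
  }
)

## Canonical call-type labels, in bout-stage order.
CALL_TYPES <- c("moan", "full_throated_roar", "intermediary_roar", "grunt")

#' Canonical roaring-bout call types
#'
#' The four call types of a complete roaring bout in their stage order:
#' moans open the bout, then full-throated roars, then intermediary roars,
#' then grunts.
#'
#' @return Character vector of the four call-type labels.
#' @export
callTypes <- function() CALL_TYPES
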