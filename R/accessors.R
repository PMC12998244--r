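#' @name accessors
#' @title Accessors for roarbout S4 objects
#' @description Small accessor generics for the package's core classes.
#' @param x an object.
#' @return The requested slot content.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioClip", function(x) x@rate)

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "AudioClip", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "AudioClip", function(x) ncol(x@samples))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "AudioClip", function(x) nrow(x@samples))

#' @rdname accessors
#' @export
setGeneric("f0Values", function(x) standardGeneric("f0Values"))
#' @rdname accessors
#' @export
setMethod("f0Values", "F0Contour", function(x) x@valuesHz)

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "F0Contour", function(x) x@frameTimesS)

#' @rdname accessors
#' @export
setGeneric("callRef", function(x) standardGeneric("callRef"))
#' @rdname accessors
#' @export
setMethod("callRef", "F0Contour", function(x) x@callRef)

#' @rdname accessors
#' @export
setMethod("length", "F0Contour", function(x) length(x@valuesHz))

#' @rdname accessors
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))
#' @rdname accessors
#' @export
setMethod("initialProbs", "GaussianHMM", function(x) x@initialProbs)

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "GaussianHMM", function(x) x@transitions)

#' @rdname accessors
#' @export
setGeneric("emissionMeans", function(x) standardGeneric("emissionMeans"))
#' @rdname accessors
#' @export
setMethod("emissionMeans", "GaussianHMM", function(x) x@emissionMeans)

#' @rdname accessors
#' @export
setGeneric("emissionVars", function(x) standardGeneric("emissionVars"))
#' @rdname accessors
#' @export
setMethod("emissionVars", "GaussianHMM", function(x) x@emissionVars)

#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setMethod("nStates", "GaussianHMM", function(x) length(x@initialProbs))

#' @rdname accessors
#' @export
setGeneric("confusionLabels", function(x) standardGeneric("confusionLabels"))
#' @rdname accessors
#' @export
setMethod("confusionLabels", "ConfusionMatrix", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "ConfusionMatrix", function(x) {
  m <- x@counts
  dimnames(m) <- list(true = x@labels, predicted = x@labels)
  m
})

#' @rdname accessors
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
#' @rdname accessors
#' @export
setMethod("perClassMetrics", "ClassificationReport", function(x) x@perClass)

#' @rdname accessors
#' @export
setGeneric("microMetrics", function(x) standardGeneric("microMetrics"))
#' @rdname accessors
#' @export
setMethod("microMetrics", "ClassificationReport", function(x) x@micro)

#' @rdname accessors
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))
#' @rdname accessors
#' @export
setMethod("macroMetrics", "ClassificationReport", function(x) x@macro)

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setMethod("assignments", "ClusterResult", function(x) x@assignments)

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "ClusterResult", function(x) x@centroids)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "ClusterResult", function(x) x@labelMap)

#' @rdname accessors
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))
#' @rdname accessors
#' @export
setMethod("inertia", "ClusterResult", function(x) x@inertia)

setMethod("show", "AudioClip", function(object) {
  cat(sprintf("AudioClip: %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              nrow(object@samples) / object@rate))
})

setMethod("show", "F0Contour", function(object) {
  n <- length(object@valuesHz)
  cat(sprintf("F0Contour '%s': %d frames", object@callRef, n))
  if (n > 0)
    cat(sprintf(", %.1f-%.1f Hz over %.3f-%.3f s",
                min(object@valuesHz), max(object@valuesHz),
                object@frameTimesS[1], object@frameTimesS[n]))
  cat("\n")
})

setMethod("show", "GaussianHMM", function(object) {
  k <- length(object@initialProbs)
  cat(sprintf("GaussianHMM with %d states\n", k))
  cat("  means (Hz):", paste(sprintf("%.2f", object@emissionMeans),
                             collapse = ", "), "\n")
  cat("  vars (Hz^2):", paste(sprintf("%.2f", object@emissionVars),
                              collapse = ", "), "\n")
  cat("  initial:", paste(sprintf("%.3f", object@initialProbs),
                          collapse = ", "), "\n")
  cat("  transitions:\n")
  print(round(object@transitions, 3))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (true x predicted)\n")
  print(round(counts(object), 3))
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport\n")
  cat(sprintf("  micro: accuracy %.3f (trace %.3f) precision %.3f recall %.3f f1 %.3f\n",
              object@micro["accuracy"], object@micro["traceAccuracy"],
              object@micro["precision"], object@micro["recall"],
              object@micro["f1"]))
  cat(sprintf("  macro: accuracy %.3f precision %.3f recall %.3f f1 %.3f\n",
              object@macro["accuracy"], object@macro["precision"],
              object@macro["recall"], object@macro["f1"]))
  cat("  per class:\n")
  print(object@perClass, digits = 3, row.names = FALSE)
})

setMethod("show", "ClusterResult", function(object) {
  k <- nrow(object@centroids)
  cat(sprintf("ClusterResult: k = %d, inertia = %.4f\n", k, object@inertia))
  tab <- table(factor(object@assignments, levels = seq_len(k)))
  for (i in seq_len(k)) {
    lab <- if (is.na(object@labelMap[i])) "(unmapped)" else object@labelMap[i]
    cat(sprintf("  cluster %d [%s]: n = %d, centroid = (%.3f, %.3f)\n",
                i, lab, tab[i], object@centroids[i, 1], object@centroids[i, 2]))
  }
})
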