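## Leave-one-out classification protocols. Call-type classification holds out
## one call at a time; individual identification holds out one whole bout to
## avoid temporal autocorrelation between roars of the same bout leaking into
## training.

#' Call-type classification by leave-one-out HMM comparison
#'
#' For every call, one two-state Gaussian HMM per call type is trained on all
#' remaining calls of that type and the held-out call is assigned to the HMM
#' with the highest forward log-likelihood. The whole protocol is repeated
#' `nRepeats` times with fresh randomized initialisations, and decisions are
#' pooled into one confusion matrix with weight 1/nRepeats per decision, so
#' each call contributes one unit. Argmax ties break by alphabetical class
#' order and are logged.
#'
#' @param contours list of [F0Contour-class] objects (or numeric vectors).
#' @param labels call-type label per contour.
#' @param cfg a [fitConfig()].
#' @param nRepeats randomized repeats of the full protocol.
#' @return A [ClassificationReport-class] with attribute `predictions`, a
#'   data.frame of per-repeat decisions.
#' @export
classifyCallsLoo <- function(contours, labels, cfg = fitConfig(),
                             nRepeats = 10L) {
  labels <- as.character(labels)
  if (length(contours) != length(labels))
    stopValidation("one label per contour required")
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stopValidation("need at least 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stopValidation("class '%s' has fewer than 2 calls; cannot leave one out",
                   names(sizes)[sizes < 2L][1])
  n <- length(contours)
  seqsByClass <- lapply(classes, function(cl) which(labels == cl))
  names(seqsByClass) <- classes

  trueAll <- character(0); predAll <- character(0); repAll <- integer(0)
  for (r in seq_len(nRepeats)) {
    ## class HMMs on full data; exact for test calls of *other* classes
    fullModels <- lapply(seq_along(classes), function(ci) {
      cfgR <- cfg
      cfgR$seed <- childSeed(cfg$seed, 301L, r, ci)
      fitHmm(contours[seqsByClass[[ci]]], cfgR)
    })
    for (i in seq_len(n)) {
      ci <- match(labels[i], classes)
      cfgR <- cfg
      cfgR$seed <- childSeed(cfg$seed, 301L, r, ci, i)
      ownModel <- fitHmm(contours[setdiff(seqsByClass[[ci]], i)], cfgR)
      lls <- vapply(seq_along(classes), function(cj) {
        model <- if (cj == ci) ownModel else fullModels[[cj]]
        hmmLogLik(model, contours[[i]])
      }, numeric(1))
      pred <- classes[argmaxFixedOrder(lls, classes, "classifyCallsLoo")]
      trueAll <- c(trueAll, labels[i])
      predAll <- c(predAll, pred)
      repAll <- c(repAll, r)
    }
  }
  cm <- confusionCounts(trueAll, predAll, labels = classes,
                        weights = rep(1 / nRepeats, length(trueAll)))
  report <- classificationReport(cm)
  attr(report, "predictions") <- data.frame(repeat_ = repAll, true = trueAll,
                                            predicted = predAll)
  report
}

#' Assemble bouts for individual identification
#'
#' Groups contours by (lion, bout) into the structure
#' [classifyIndividualsLoo()] consumes.
#'
#' @param lionIds,boutIds character vectors, one entry per contour.
#' @param contours list of contours, parallel to the id vectors.
#' @return List of bouts, each `list(lion_id, bout_id, contours)`.
#' @export
groupBouts <- function(lionIds, boutIds, contours) {
  stopifnot(length(lionIds) == length(boutIds),
            length(boutIds) == length(contours))
  key <- paste(lionIds, boutIds, sep = "\r")
  lapply(unique(key), function(k) {
    idx <- which(key == k)
    list(lion_id = lionIds[idx[1]], bout_id = boutIds[idx[1]],
         contours = contours[idx])
  })
}

#' Individual identification by leave-one-bout-out HMM comparison
#'
#' One two-state Gaussian HMM is trained per lion on the full-throated-roar
#' contours of that lion's bouts; each bout in turn is held out of its own
#' lion's training data and scored against every lion's HMM. A bout's score
#' under a lion is the sum of its contours' forward log-likelihoods
#' (independence across calls; `mode = "concat"` instead concatenates the
#' bout's contours into one observation sequence). The bout is assigned to
#' the highest-scoring lion; decisions over `nRepeats` randomized repeats are
#' pooled with weight 1/nRepeats.
#'
#' @param bouts list of bouts from [groupBouts()]: every lion needs at least
#'   2 bouts.
#' @param cfg a [fitConfig()].
#' @param nRepeats randomized repeats.
#' @param mode bout scoring: `"sum"` (default) or `"concat"`.
#' @return A [ClassificationReport-class] over bouts, with attribute
#'   `predictions`.
#' @export
classifyIndividualsLoo <- function(bouts, cfg = fitConfig(), nRepeats = 10L,
                                   mode = c("sum", "concat")) {
  mode <- match.arg(mode)
  lions <- sort(unique(vapply(bouts, `[[`, character(1), "lion_id")))
  if (length(lions) < 2L)
    stopValidation("need at least 2 lions")
  boutLion <- vapply(bouts, `[[`, character(1), "lion_id")
  sizes <- table(boutLion)
  if (any(sizes < 2L))
    stopValidation("lion '%s' has fewer than 2 bouts; cannot leave one out",
                   names(sizes)[sizes < 2L][1])

  boutContours <- function(b) {
    if (mode == "concat")
      list(unlist(lapply(b$contours, .contourValues), use.names = FALSE))
    else b$contours
  }
  lionBouts <- lapply(lions, function(l) which(boutLion == l))
  names(lionBouts) <- lions
  scoreBout <- function(model, b) {
    sum(vapply(boutContours(b), function(ct) hmmLogLik(model, ct), numeric(1)))
  }

  trueAll <- character(0); predAll <- character(0); repAll <- integer(0)
  for (r in seq_len(nRepeats)) {
    fullModels <- lapply(seq_along(lions), function(li) {
      cfgR <- cfg
      cfgR$seed <- childSeed(cfg$seed, 401L, r, li)
      cts <- unlist(lapply(bouts[lionBouts[[li]]], boutContours),
                    recursive = FALSE)
      fitHmm(cts, cfgR)
    })
    for (bi in seq_along(bouts)) {
      li <- match(boutLion[bi], lions)
      cfgR <- cfg
      cfgR$seed <- childSeed(cfg$seed, 401L, r, li, bi)
      trainIdx <- setdiff(lionBouts[[li]], bi)
      ownModel <- fitHmm(unlist(lapply(bouts[trainIdx], boutContours),
                                recursive = FALSE), cfgR)
      scores <- vapply(seq_along(lions), function(lj) {
        model <- if (lj == li) ownModel else fullModels[[lj]]
        scoreBout(model, bouts[[bi]])
      }, numeric(1))
      pred <- lions[argmaxFixedOrder(scores, lions, "classifyIndividualsLoo")]
      trueAll <- c(trueAll, boutLion[bi])
      predAll <- c(predAll, pred)
      repAll <- c(repAll, r)
    }
  }
  cm <- confusionCounts(trueAll, predAll, labels = lions,
                        weights = rep(1 / nRepeats, length(trueAll)))
  report <- classificationReport(cm)
  attr(report, "predictions") <- data.frame(repeat_ = repAll, true = trueAll,
                                            predicted = predAll)
  report
}
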