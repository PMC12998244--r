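## K-means call-type clustering on the standardized (duration, max frequency)
## plane. Two variants mirror the analysis: k = 4 with all call types, and
## k = 3 after moans (whose features overlap the roars) are removed.

#' K-means clustering of the standardized feature table
#'
#' Lloyd's algorithm from `nInit` seeded starts (initial centroids sampled
#' from the data rows); the start with the lowest inertia wins. If a start
#' collapses a cluster to empty, the offending centroid is re-seeded at the
#' point farthest from its nearest centroid (logged) and the start is rerun.
#' Deterministic given `seed`.
#'
#' @param features a standardized feature table from [standardizeFeatures()].
#' @param k number of clusters (4 with moans, 3 without).
#' @param seed integer seed.
#' @param nInit number of seeded starts.
#' @return A [ClusterResult-class]; the label map is unset until
#'   [mapClusters()].
#' @export
kmeansCalls <- function(features, k, seed = 1L, nInit = 10L) {
  std <- attr(features, "standardization")
  if (is.null(std))
    stopValidation("kmeansCalls expects a standardized table; call standardizeFeatures() first")
  if (k < 2L) stopValidation("k must be at least 2")
  x <- as.matrix(features[.featureCols])
  if (nrow(x) < k)
    stopValidation("fewer rows (%d) than clusters (%d)", nrow(x), k)

  runStart <- function(centers, attempt = 1L) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L,
                                     algorithm = "Lloyd")),
      error = function(e) e)
    if (inherits(fit, "condition")) {
      if (attempt > 5L) return(NULL)
      ## empty cluster: re-seed one centroid at the farthest point
      d2 <- vapply(seq_len(nrow(x)), function(i)
        min(colSums((t(centers) - x[i, ])^2)), numeric(1))
      centers[((attempt - 1L) %% k) + 1L, ] <- x[which.max(d2), ]
      logEvent("kmeansCalls: empty cluster; re-seeded centroid at farthest point (attempt %d)",
               attempt)
      return(runStart(centers, attempt + 1L))
    }
    fit
  }

  best <- NULL
  for (s in seq_len(nInit)) {
    set.seed(childSeed(seed, 501L, s))
    centers <- x[sample.int(nrow(x), k), , drop = FALSE]
    ## nudge duplicated initial centers apart deterministically
    while (anyDuplicated(centers)) {
      dup <- which(duplicated(centers))[1]
      centers[dup, ] <- centers[dup, ] + 1e-6 * dup
    }
    fit <- runStart(centers)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stopValidation("k-means failed to produce a partition")
  new("ClusterResult", assignments = as.integer(best$cluster),
      centroids = unname(best$centers),
      labelMap = rep(NA_character_, k),
      inertia = best$tot.withinss, standardization = std)
}

## Exact optimal one-to-one cluster -> label assignment by exhaustive
## permutation search (k <= 4 here, so at most 24 candidates).
.bestPermutation <- function(agreement) {
  k <- nrow(agreement)
  perms <- .allPermutations(k)
  scores <- vapply(seq_len(nrow(perms)), function(i)
    sum(agreement[cbind(seq_len(k), perms[i, ])]), numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1L)
    logEvent("mapClusters: %d tied label assignments; chose first in centroid-index order",
             length(best))
  perms[best[1L], ]
}

.allPermutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .allPermutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Map clusters to call-type labels
#'
#' With reference labels, finds the one-to-one cluster-to-label assignment
#' maximizing agreement (exact optimum; evaluation use). Without labels, the
#' application heuristic for k = 3 codifies the graphical selection of the
#' roar cluster: centroids are ranked by unstandardized duration - longest is
#' the full-throated roar, middle the intermediary roar, shortest the grunt.
#'
#' @param result a [ClusterResult-class].
#' @param referenceLabels optional true labels, one per clustered row; must
#'   contain exactly k distinct labels.
#' @return The [ClusterResult-class] with `labelMap` filled in.
#' @export
mapClusters <- function(result, referenceLabels = NULL) {
  stopifnot(is(result, "ClusterResult"))
  k <- nrow(result@centroids)
  if (!is.null(referenceLabels)) {
    referenceLabels <- as.character(referenceLabels)
    if (length(referenceLabels) != length(result@assignments))
      stopValidation("referenceLabels must match the number of clustered rows")
    labs <- sort(unique(referenceLabels))
    if (length(labs) != k)
      stopValidation("k = %d but %d distinct reference labels", k,
                     length(labs))
    agreement <- matrix(0, k, k, dimnames = list(NULL, labs))
    for (i in seq_len(k))
      for (j in seq_len(k))
        agreement[i, j] <- sum(result@assignments == i &
                               referenceLabels == labs[j])
    perm <- .bestPermutation(agreement)
    result@labelMap <- labs[perm]
  } else {
    if (k != 3L)
      stopValidation("the duration-rank heuristic is defined for k = 3 (moans removed)")
    durCenter <- result@standardization$center["duration_s"]
    durScale <- result@standardization$scale["duration_s"]
    dur <- result@centroids[, 1] * durScale + durCenter
    ord <- order(dur, decreasing = TRUE)  # longest first
    map <- character(3)
    map[ord] <- c("full_throated_roar", "intermediary_roar", "grunt")
    result@labelMap <- map
  }
  validObject(result)
  result
}

#' Predicted call-type label per row
#'
#' @param result a mapped [ClusterResult-class].
#' @return Character vector of predicted labels, one per clustered row.
#' @export
predictedLabels <- function(result) {
  stopifnot(is(result, "ClusterResult"))
  if (anyNA(result@labelMap))
    stopValidation("cluster result has no label map; call mapClusters() first")
  result@labelMap[result@assignments]
}

#' Predict full-throated roars by K-means
#'
#' The data-driven full-throated-roar selector: on annotations with moans
#' already removed, clusters the standardized two-feature table into k = 3,
#' names the longest-duration cluster the full-throated-roar cluster via the
#' duration-rank heuristic, and returns the annotations assigned to it.
#'
#' @param annotations call annotations with moans removed upstream.
#' @param seed integer seed for the clustering.
#' @param nInit number of K-means starts.
#' @return The subset of `annotations` predicted to be full-throated roars,
#'   with a `predicted_label` column describing every input row attached as
#'   attribute `predictions`.
#' @export
predictFtr <- function(annotations, seed = 1L, nInit = 10L) {
  annotations <- validateAnnotations(annotations)
  if (any(!is.na(annotations$call_type) & annotations$call_type == "moan"))
    stopValidation("moans must be removed before predictFtr (k = 3 clustering)")
  if (nrow(annotations) < 3L)
    stopValidation("need at least 3 annotations for k = 3 clustering")
  feats <- standardizeFeatures(buildFeatures(annotations))
  res <- mapClusters(kmeansCalls(feats, k = 3L, seed = seed, nInit = nInit))
  pred <- predictedLabels(res)
  if (!any(pred == "full_throated_roar"))
    logEvent("predictFtr: no rows fell in the full-throated-roar cluster")
  out <- annotations[pred == "full_throated_roar", , drop = FALSE]
  attr(out, "predictions") <- pred
  out
}
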