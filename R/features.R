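## The two-feature table: each vocalization is summarised by its duration (s)
## and the maximum frequency (Hz) of its spectrogram bounding box. These two
## features alone separate the roaring-bout call types.

#' Build the duration/maximum-frequency feature table
#'
#' @param annotations a call-annotation data.frame (see [callAnnotations()]).
#' @return A data.frame with one row per annotation (order preserved):
#'   `id`, `bout_id`, `source_id`, `call_type`, `duration_s`, `max_freq_hz`.
#' @export
buildFeatures <- function(annotations) {
  annotations <- validateAnnotations(annotations)
  data.frame(id = seq_len(nrow(annotations)),
             bout_id = annotations$bout_id,
             source_id = annotations$source_id,
             call_type = annotations$call_type,
             duration_s = annotations$duration_s,
             max_freq_hz = annotations$max_freq_hz,
             stringsAsFactors = FALSE)
}

.featureCols <- c("duration_s", "max_freq_hz")

#' Standardize the feature columns
#'
#' Centres each feature on its mean and divides by its sample standard
#' deviation (n - 1 denominator), fitted on the table itself. The fitted
#' centre/scale pair is stored in attribute `standardization` for the inverse
#' transform, so standardization is always per dataset (per study site),
#' never pooled across sites.
#'
#' @param features a feature table from [buildFeatures()].
#' @return The table with `duration_s` and `max_freq_hz` standardized and a
#'   `standardization` attribute (list with `center` and `scale`).
#' @seealso [unstandardizeFeatures()]
#' @export
standardizeFeatures <- function(features) {
  if (nrow(features) < 2L)
    stopValidation("standardization needs at least 2 rows")
  ctr <- vapply(features[.featureCols], mean, numeric(1))
  scl <- vapply(features[.featureCols], sd, numeric(1))
  degenerate <- names(scl)[scl <= 0 | !is.finite(scl)]
  if (length(degenerate))
    stopValidation("degenerate feature with zero variance: %s",
                   paste(degenerate, collapse = ", "))
  for (col in .featureCols)
    features[[col]] <- (features[[col]] - ctr[col]) / scl[col]
  attr(features, "standardization") <- list(center = ctr, scale = scl)
  features
}

#' Invert a standardization
#'
#' @param features a table produced by [standardizeFeatures()].
#' @return The table on its original scale, standardization attribute removed.
#' @export
unstandardizeFeatures <- function(features) {
  std <- attr(features, "standardization")
  if (is.null(std))
    stopValidation("table carries no standardization to invert")
  for (col in .featureCols)
    features[[col]] <- features[[col]] * std$scale[col] + std$center[col]
  attr(features, "standardization") <- NULL
  features
}

#' Balance call-type classes by downsampling
#'
#' Randomly downsamples every labeled class, without replacement, to the size
#' of the smallest class, reproducibly from `seed`. Mirrors the balancing
#' applied before HMM call-type experiments, where e.g. class sizes
#' 197/211/195/813 reduce to 195 per class.
#'
#' @param annotations a labeled call-annotation data.frame.
#' @param seed integer seed controlling the subsample.
#' @return The balanced annotation subset (row order: grouped by class in
#'   label-sorted order).
#' @export
balanceClasses <- function(annotations, seed = 1L) {
  annotations <- validateAnnotations(annotations)
  lab <- annotations$call_type
  if (any(is.na(lab)))
    stopValidation("balanceClasses requires every annotation to be labeled")
  sizes <- table(lab)
  if (length(sizes) < 2L)
    stopValidation("balanceClasses needs at least 2 labeled classes")
  if (any(sizes == 0L))
    stopValidation("empty class: %s", names(sizes)[sizes == 0L][1])
  target <- min(sizes)
  keep <- integer(0)
  classes <- sort(names(sizes))
  for (i in seq_along(classes)) {
    idx <- which(lab == classes[i])
    if (length(idx) > target) {
      set.seed(childSeed(seed, i))
      idx <- sort(sample(idx, target))
    }
    keep <- c(keep, idx)
  }
  annotations[keep, , drop = FALSE]
}
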