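## End-to-end experiment runners. Each writes its confusion matrix, report
## tables and a YAML manifest (all parameters, seed, package version) into an
## output directory so a run can be reproduced exactly.

.writeManifest <- function(outDir, experiment, params) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- c(list(experiment = experiment,
                     package_version = as.character(packageVersion("roarbout")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                params)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

#' Run the HMM call-type classification experiment
#'
#' Balances the labeled calls across call types, runs leave-one-out two-state
#' Gaussian HMM classification, and writes the confusion matrix, metric
#' tables and a manifest to `outDir`.
#'
#' @param annotations labeled call annotations.
#' @param contours list of contours parallel to `annotations`.
#' @param cfg a [fitConfig()].
#' @param nRepeats randomized repeats of the LOO protocol.
#' @param seed seed for class balancing.
#' @param outDir output directory; `NULL` skips writing artifacts.
#' @return The [ClassificationReport-class].
#' @export
runCalltypeHmm <- function(annotations, contours, cfg = fitConfig(),
                           nRepeats = 10L, seed = 1L, outDir = NULL) {
  if (is.null(annotations$call_type) || any(is.na(annotations$call_type)))
    stopValidation("calltype_hmm stage: annotations must carry call_type labels")
  if (nrow(annotations) != length(contours))
    stopValidation("calltype_hmm stage: one contour per annotation required")
  annotations$.row <- seq_len(nrow(annotations))
  balanced <- balanceClasses(annotations, seed = seed)
  report <- classifyCallsLoo(contours[balanced$.row], balanced$call_type,
                             cfg = cfg, nRepeats = nRepeats)
  if (!is.null(outDir)) {
    writeReport(report, outDir, "calltype_hmm")
    .writeManifest(outDir, "calltype_hmm",
                   list(seed = seed, n_repeats = nRepeats,
                        n_restarts = cfg$nRestarts, n_states = cfg$nStates,
                        max_em_iters = cfg$maxEmIters,
                        variance_floor = cfg$varianceFloor,
                        fit_seed = cfg$seed,
                        n_calls = nrow(balanced),
                        class_size = min(table(balanced$call_type))))
  }
  report
}

#' Run the K-means call-type clustering experiment
#'
#' Builds and standardizes the (duration, max frequency) feature table,
#' optionally drops moans, clusters with K-means, maps clusters to labels by
#' the optimal assignment against the true labels, and reports the metrics.
#' `k = 3` is refused while labeled moans are present.
#'
#' @param annotations labeled call annotations.
#' @param k number of clusters (4 with moans, 3 without).
#' @param dropMoans drop moan-labeled rows before clustering.
#' @param seed clustering seed.
#' @param nInit K-means starts.
#' @param outDir output directory; `NULL` skips writing artifacts.
#' @return The [ClassificationReport-class], with the mapped
#'   [ClusterResult-class] attached as attribute `clusters`.
#' @export
runCalltypeKmeans <- function(annotations, k = 4L, dropMoans = FALSE,
                              seed = 1L, nInit = 10L, outDir = NULL) {
  if (is.null(annotations$call_type) || any(is.na(annotations$call_type)))
    stopValidation("calltype_kmeans stage: annotations must carry call_type labels")
  if (dropMoans)
    annotations <- annotations[annotations$call_type != "moan", , drop = FALSE]
  if (!nrow(annotations))
    stopValidation("calltype_kmeans stage: no annotations left to cluster")
  if (k == 3L && any(annotations$call_type == "moan"))
    stopValidation("k = 3 clustering requires moans to be removed (set dropMoans = TRUE)")
  feats <- standardizeFeatures(buildFeatures(annotations))
  res <- kmeansCalls(feats, k = k, seed = seed, nInit = nInit)
  res <- mapClusters(res, referenceLabels = annotations$call_type)
  pred <- predictedLabels(res)
  cm <- confusionCounts(annotations$call_type, pred,
                        labels = sort(unique(annotations$call_type)))
  report <- classificationReport(cm)
  attr(report, "clusters") <- res
  if (!is.null(outDir)) {
    writeReport(report, outDir, sprintf("calltype_kmeans_k%d", k))
    assign_df <- cbind(buildFeatures(annotations),
                       cluster = assignments(res), predicted = pred)
    write.table(assign_df,
                file.path(outDir, sprintf("assignments_k%d.tsv", k)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(outDir, "calltype_kmeans",
                   list(seed = seed, k = k, drop_moans = dropMoans,
                        n_init = nInit, n_calls = nrow(annotations),
                        inertia = inertia(res)))
  }
  report
}

#' Run the individual-identification experiment
#'
#' Selects full-throated roars either from the manual labels or by the
#' K-means predictor, groups their contours into per-lion bouts, and runs
#' leave-one-bout-out per-lion HMM classification. Lions left with fewer than
#' two bouts after roar selection cannot be cross-validated and are dropped
#' with a logged warning.
#'
#' @param annotations labeled call annotations (source_id = lion).
#' @param contours list of contours parallel to `annotations`.
#' @param ftrSource `"manual"` (use the call-type labels) or `"kmeans"`
#'   (predict full-throated roars with [predictFtr()] after dropping moans).
#' @param cfg a [fitConfig()].
#' @param nRepeats randomized repeats.
#' @param seed seed for the K-means roar selection.
#' @param outDir output directory; `NULL` skips writing artifacts.
#' @return The [ClassificationReport-class] over bouts, with attribute
#'   `perLion`, a data.frame of per-lion bout and roar counts.
#' @export
runIndividualId <- function(annotations, contours,
                            ftrSource = c("manual", "kmeans"),
                            cfg = fitConfig(), nRepeats = 10L, seed = 1L,
                            outDir = NULL) {
  ftrSource <- match.arg(ftrSource)
  if (nrow(annotations) != length(contours))
    stopValidation("individual_id stage: one contour per annotation required")
  annotations$.row <- seq_len(nrow(annotations))
  ftr <- if (ftrSource == "manual") {
    annotations[!is.na(annotations$call_type) &
                annotations$call_type == "full_throated_roar", , drop = FALSE]
  } else {
    noMoans <- annotations[is.na(annotations$call_type) |
                           annotations$call_type != "moan", , drop = FALSE]
    predictFtr(noMoans, seed = seed)
  }
  if (!nrow(ftr))
    stopValidation("individual_id stage: no full-throated roars selected")

  ## drop lions that cannot be cross-validated
  boutsPerLion <- tapply(ftr$bout_id, ftr$source_id,
                         function(b) length(unique(b)))
  bad <- names(boutsPerLion)[boutsPerLion < 2L]
  if (length(bad)) {
    logEvent("individual_id: dropped lion(s) with < 2 bouts after roar selection: %s",
             paste(bad, collapse = ", "))
    warning("dropped lion(s) with fewer than 2 bouts: ",
            paste(bad, collapse = ", "), call. = FALSE)
    ftr <- ftr[!(ftr$source_id %in% bad), , drop = FALSE]
  }
  if (length(unique(ftr$source_id)) < 2L)
    stopValidation("individual_id stage: fewer than 2 lions with >= 2 bouts")

  bouts <- groupBouts(ftr$source_id, ftr$bout_id, contours[ftr$.row])
  report <- classifyIndividualsLoo(bouts, cfg = cfg, nRepeats = nRepeats)
  perLion <- data.frame(
    lion_id = names(boutsPerLion),
    n_bouts = as.integer(boutsPerLion),
    n_roars = as.integer(table(ftr$source_id)[names(boutsPerLion)]),
    row.names = NULL)
  perLion$n_roars[is.na(perLion$n_roars)] <- 0L
  attr(report, "perLion") <- perLion
  if (!is.null(outDir)) {
    writeReport(report, outDir, sprintf("individual_id_%s", ftrSource))
    write.table(perLion, file.path(outDir, "per_lion_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(outDir, "individual_id",
                   list(seed = seed, ftr_source = ftrSource,
                        n_repeats = nRepeats, n_restarts = cfg$nRestarts,
                        fit_seed = cfg$seed, n_roars = nrow(ftr),
                        n_lions = length(unique(ftr$source_id))))
  }
  report
}
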