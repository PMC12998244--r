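#' Per-lion full-throated-roar counts from the Bubye Valley case study
#'
#' The numbers of roaring bouts and of full-throated roars available per
#' collared lion in the Bubye Valley Conservancy case study, under both roar
#' selection methods (manual labeling vs. K-means prediction). Shipped as a
#' plain-text table in `inst/extdata`.
#'
#' @return data.frame with columns `lion_id`, `n_bouts_manual`,
#'   `n_bouts_automatic`, `n_roars_manual`, `n_roars_automatic`.
#' @export
bvcRoarCounts <- function() {
  path <- system.file("extdata", "bvc_roar_counts.tsv", package = "roarbout")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Mean and standard error of per-lion roar counts
#'
#' Summarises how many full-throated roars each selection method yields per
#' lion: the mean count across lions and its standard error
#' (sd / sqrt(n lions)).
#'
#' @param counts a data.frame as returned by [bvcRoarCounts()].
#' @return data.frame with one row per method (`manual`, `automatic`) and
#'   columns `total`, `mean`, `se`.
#' @export
roarCountSummary <- function(counts = bvcRoarCounts()) {
  summarise <- function(x) c(total = sum(x), mean = mean(x),
                             se = sd(x) / sqrt(length(x)))
  out <- rbind(manual = summarise(counts$n_roars_manual),
               automatic = summarise(counts$n_roars_automatic))
  data.frame(method = rownames(out), out, row.names = NULL)
}
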