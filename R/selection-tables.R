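## Raven-style selection tables: UTF-8, tab-separated, header row, one
## selection per line. Default headers follow the Raven 1.6 export dialect;
## a column map absorbs drift between Raven versions and manual edits.

.defaultColumns <- list(
  begin      = c("Begin Time (s)", "begin_s"),
  end        = c("End Time (s)", "end_s"),
  max_freq   = c("Max Freq (Hz)", "High Freq (Hz)", "max_freq_hz"),
  delta_time = c("Delta Time (s)", "duration_s"),
  label      = c("Call Type", "Annotation", "call_type"),
  bout_id    = c("Bout ID", "bout_id", "Begin File"),
  source_id  = c("Source ID", "source_id")
)

.resolveColumn <- function(header, candidates, what, required = FALSE) {
  hit <- candidates[candidates %in% header]
  if (length(hit)) return(hit[1])
  if (required)
    stopValidation(
      "selection table: cannot resolve required column '%s' (tried: %s)",
      what, paste(candidates, collapse = "; "))
  NA_character_
}

.parseNumericColumn <- function(x, colName) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stopValidation("selection table: non-numeric value '%s' in column '%s', row %d",
                   x[bad[1]], colName, bad[1])
  v
}

#' Read a Raven-style selection table
#'
#' Parses a tab-separated selection table with a header row into a validated
#' call-annotation data.frame (see [callAnnotations()]). Begin/end times and
#' maximum frequency are required (resolved from the Raven 1.6 default
#' headers or `columnMap`); duration is taken from the Delta Time column when
#' present and computed as end - begin otherwise. Label and bout/source
#' identifier columns are optional.
#'
#' @param path path to a tab-separated selection table.
#' @param columnMap optional named list overriding column names; recognised
#'   names: `begin`, `end`, `max_freq`, `delta_time`, `label`, `bout_id`,
#'   `source_id`.
#' @return A call-annotation data.frame, rows in file order.
#' @seealso [writeSelectionTable()]
#' @export
readSelectionTable <- function(path, columnMap = list()) {
  if (!file.exists(path))
    stop(sprintf("selection table not found: '%s'", path), call. = FALSE)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  header <- names(raw)
  cols <- .defaultColumns
  for (nm in names(columnMap)) cols[[nm]] <- columnMap[[nm]]

  beginCol <- .resolveColumn(header, cols$begin, "begin", required = TRUE)
  endCol <- .resolveColumn(header, cols$end, "end", required = TRUE)
  freqCol <- .resolveColumn(header, cols$max_freq, "max_freq", required = TRUE)
  deltaCol <- .resolveColumn(header, cols$delta_time, "delta_time")
  labelCol <- .resolveColumn(header, cols$label, "label")
  boutCol <- .resolveColumn(header, cols$bout_id, "bout_id")
  sourceCol <- .resolveColumn(header, cols$source_id, "source_id")

  begin <- .parseNumericColumn(raw[[beginCol]], beginCol)
  end <- .parseNumericColumn(raw[[endCol]], endCol)
  maxFreq <- .parseNumericColumn(raw[[freqCol]], freqCol)
  duration <- if (!is.na(deltaCol)) .parseNumericColumn(raw[[deltaCol]], deltaCol)
              else end - begin
  duration[is.na(duration)] <- (end - begin)[is.na(duration)]

  boutId <- if (!is.na(boutCol)) raw[[boutCol]] else rep("bout1", nrow(raw))
  sourceId <- if (!is.na(sourceCol)) raw[[sourceCol]] else boutId
  label <- if (!is.na(labelCol)) raw[[labelCol]] else rep(NA_character_, nrow(raw))
  label[!is.na(label) & !nzchar(trimws(label))] <- NA_character_

  callAnnotations(bout_id = boutId, source_id = sourceId, call_type = label,
                  begin_s = begin, end_s = end, max_freq_hz = maxFreq,
                  duration_s = duration)
}

#' Write a Raven-style selection table
#'
#' Writes annotations as a tab-separated table with Raven 1.6 default headers
#' plus `Bout ID`/`Source ID` columns. Numeric columns are written with 17
#' significant digits so a write/read round trip is exact.
#'
#' @param annotations a call-annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSelectionTable <- function(annotations, path) {
  annotations <- validateAnnotations(annotations)
  num <- function(x) sprintf("%.17g", x)
  out <- data.frame(
    "Selection" = seq_len(nrow(annotations)),
    "View" = "Spectrogram 1",
    "Channel" = 1L,
    "Begin Time (s)" = num(annotations$begin_s),
    "End Time (s)" = num(annotations$end_s),
    "Max Freq (Hz)" = num(annotations$max_freq_hz),
    "Delta Time (s)" = num(annotations$duration_s),
    "Call Type" = ifelse(is.na(annotations$call_type), "",
                         annotations$call_type),
    "Bout ID" = annotations$bout_id,
    "Source ID" = annotations$source_id,
    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an F0 contour as a tab-separated file
#'
#' @param contour an [F0Contour-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeContour <- function(contour, path) {
  stopifnot(is(contour, "F0Contour"))
  out <- data.frame(frame_time_s = sprintf("%.17g", frameTimes(contour)),
                    f0_hz = sprintf("%.17g", f0Values(contour)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an F0 contour written by [writeContour()]
#'
#' @param path path to a two-column tab-separated contour file.
#' @param callRef optional call identifier to attach.
#' @return An [F0Contour-class].
#' @export
readContour <- function(path, callRef = NA_character_) {
  df <- read.delim(path)
  f0Contour(df$f0_hz, df$frame_time_s, callRef)
}
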