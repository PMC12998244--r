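## WAV (RIFF) reading and writing. Minimal by design: PCM16, PCM32 and IEEE
## float32, the encodings autonomous recording units and Raven exports use.
## Samples are normalised to [-1, 1] doubles in memory.

#' Read a WAV file
#'
#' Reads a RIFF WAV file (PCM 16/32-bit integer or IEEE float32) into an
#' [AudioClip-class]. All channels are kept: quadraphonic recorders such as
#' the CARACAL store four microphones (M1..M4) as four channels.
#'
#' @param path path to a WAV file.
#' @return An [AudioClip-class] with one column per channel.
#' @seealso [writeWav()], [sliceCall()]
#' @export
readWav <- function(path) {
  if (!file.exists(path))
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("'%s' is not a RIFF/WAV file (no RIFF header)", path),
         call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("'%s' is not a WAV file (no WAVE tag)", path), call. = FALSE)

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1L, size = 2L,
                         endian = "little", signed = FALSE),
        channels = readBin(body[3:4], "integer", 1L, size = 2L,
                           endian = "little", signed = FALSE),
        rate = readBin(body[5:8], "integer", 1L, size = 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, size = 2L,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + (size %% 2L)))
      next
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw))
    stop(sprintf("'%s': missing fmt or data chunk", path), call. = FALSE)

  n <- length(dataRaw)
  x <- switch(as.character(fmt$format),
    "1" = switch(as.character(fmt$bits),
      "16" = readBin(dataRaw, "integer", n %/% 2L, size = 2L,
                     endian = "little") / 32768,
      "32" = readBin(dataRaw, "integer", n %/% 4L, size = 4L,
                     endian = "little") / 2147483648,
      stop(sprintf("unsupported PCM bit depth: %d", fmt$bits), call. = FALSE)),
    "3" = readBin(dataRaw, "numeric", n %/% 4L, size = 4L, endian = "little"),
    stop(sprintf("unsupported WAV format code: %d", fmt$format),
         call. = FALSE))
  audioClip(matrix(x, ncol = fmt$channels, byrow = TRUE), fmt$rate)
}

#' Write a WAV file
#'
#' @param clip an [AudioClip-class].
#' @param path output path.
#' @param format `"float32"` (IEEE float, lossless for doubles truncated to
#'   single precision) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(clip, path, format = c("float32", "pcm16")) {
  stopifnot(is(clip, "AudioClip"))
  format <- match.arg(format)
  x <- t(samples(clip))  # interleave channels
  nch <- nChannels(clip)
  bits <- if (format == "float32") 32L else 16L
  fmtCode <- if (format == "float32") 3L else 1L
  bytesPerSample <- bits %/% 8L
  dataSize <- length(x) * bytesPerSample

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmtCode, con, size = 2L, endian = "little")
  writeBin(as.integer(nch), con, size = 2L, endian = "little")
  writeBin(as.integer(sampleRate(clip)), con, size = 4L, endian = "little")
  writeBin(as.integer(sampleRate(clip) * nch * bytesPerSample), con,
           size = 4L, endian = "little")
  writeBin(as.integer(nch * bytesPerSample), con, size = 2L, endian = "little")
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4L, endian = "little")
  if (format == "float32") {
    writeBin(as.vector(x), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Slice one annotated call out of a recording
#'
#' Cuts the `[begin_s, end_s)` interval of one channel out of a long clip.
#' The start sample is `floor(begin_s * rate)` (0-based) and the slice holds
#' `round((end_s - begin_s) * rate)` samples, so slice length matches the
#' annotated duration to within one sample.
#'
#' @param clip an [AudioClip-class].
#' @param ann a single-row annotation data.frame (see [callAnnotations()]).
#' @param channel channel to extract, 1-based; default 1 (microphone M1).
#' @return A mono [AudioClip-class].
#' @export
sliceCall <- function(clip, ann, channel = 1L) {
  stopifnot(is(clip, "AudioClip"), nrow(ann) == 1L)
  if (channel < 1L || channel > nChannels(clip))
    stopValidation("channel %d outside 1..%d", channel, nChannels(clip))
  rate <- sampleRate(clip)
  start0 <- floor(ann$begin_s * rate)           # 0-based
  len <- round((ann$end_s - ann$begin_s) * rate)
  if (ann$begin_s < 0 || start0 + len > nSamples(clip))
    stopValidation("annotation [%g, %g] s outside clip of %.3f s",
                   ann$begin_s, ann$end_s, nSamples(clip) / rate)
  audioClip(samples(clip)[(start0 + 1L):(start0 + len), channel], rate)
}

#' Construct and validate a call-annotation table
#'
#' One row per annotated vocalization: bout and source identifiers, optional
#' call-type label, time bounds in seconds, maximum frequency (Hz) and
#' duration (s). Invariants enforced: `end_s > begin_s`, `duration_s` agrees
#' with `end_s - begin_s` to 1e-6 s, `max_freq_hz > 0`, and annotations
#' within a bout do not overlap in time.
#'
#' @param bout_id,source_id character identifiers (source = station or lion).
#' @param call_type one of [callTypes()] or NA for unlabeled.
#' @param begin_s,end_s call bounds in seconds (half-open interval).
#' @param max_freq_hz maximum frequency of the call's bounding box (Hz).
#' @param duration_s call duration (s); defaults to `end_s - begin_s`.
#' @return A validated data.frame of class annotations.
#' @export
callAnnotations <- function(bout_id, source_id = bout_id, call_type = NA,
                            begin_s, end_s, max_freq_hz,
                            duration_s = end_s - begin_s) {
  df <- data.frame(bout_id = as.character(bout_id),
                   source_id = as.character(source_id),
                   call_type = as.character(call_type),
                   begin_s = as.numeric(begin_s),
                   end_s = as.numeric(end_s),
                   max_freq_hz = as.numeric(max_freq_hz),
                   duration_s = as.numeric(duration_s),
                   stringsAsFactors = FALSE)
  validateAnnotations(df)
}

#' @rdname callAnnotations
#' @param df a data.frame with the columns above.
#' @export
validateAnnotations <- function(df) {
  need <- c("bout_id", "begin_s", "end_s", "max_freq_hz", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopValidation("annotation table missing column(s): %s",
                   paste(miss, collapse = ", "))
  if (!nrow(df)) stopValidation("annotation table is empty")
  bad <- which(!(df$end_s > df$begin_s))
  if (length(bad))
    stopValidation("annotation %d: end_s must exceed begin_s", bad[1])
  bad <- which(df$duration_s <= 0)
  if (length(bad))
    stopValidation("annotation %d: duration_s must be positive", bad[1])
  bad <- which(abs(df$duration_s - (df$end_s - df$begin_s)) > 1e-6)
  if (length(bad))
    stopValidation("annotation %d: duration_s inconsistent with end_s - begin_s",
                   bad[1])
  bad <- which(!(df$max_freq_hz > 0))
  if (length(bad))
    stopValidation("annotation %d: max_freq_hz must be positive", bad[1])
  known <- !is.na(df$call_type)
  if (any(known & !(df$call_type %in% CALL_TYPES)))
    stopValidation("unknown call_type: %s",
                   df$call_type[known & !(df$call_type %in% CALL_TYPES)][1])
  for (b in unique(df$bout_id)) {
    sub <- df[df$bout_id == b, ]
    sub <- sub[order(sub$begin_s), ]
    if (nrow(sub) > 1L &&
        any(sub$begin_s[-1] < sub$end_s[-nrow(sub)] - 1e-9))
      stopValidation("bout '%s': annotations overlap in time", b)
  }
  df
}
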