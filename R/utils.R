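## Internal helpers shared across modules.

## Counter-based child-seed derivation: one user-facing integer seed fans out
## to independent per-task seeds so partial regeneration (one bout, one
## restart) is reproducible without replaying the whole RNG stream. Constants
## are an LCG multiplier and a Mersenne prime modulus; arithmetic stays in
## doubles well below 2^53.
childSeed <- function(seed, ...) {
  idx <- c(...)
  k <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) {
    k <- (k * 69069 + as.double(i) + 1) %% 2147483647
  }
  as.integer(k)
}

## Event log used for tie-breaks, empty-cluster reseeds and dropped lions.
## Kept in a session-local environment; retrieved by roarboutLog().
.log_env <- new.env(parent = emptyenv())
.log_env$events <- character()

logEvent <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  .log_env$events <- c(.log_env$events, msg)
  invisible(msg)
}

#' Retrieve or clear the session event log
#'
#' Ties broken during classification, empty-cluster reseeds during K-means and
#' individuals dropped for lack of cross-validatable bouts are recorded in a
#' session log rather than spammed as warnings.
#'
#' @param clear if TRUE, empty the log after returning it.
#' @return Character vector of logged events.
#' @export
roarboutLog <- function(clear = FALSE) {
  ev <- .log_env$events
  if (clear) .log_env$events <- character()
  ev
}

## argmax with deterministic tie-breaking by the fixed order of `values`;
## ties (exact equality) are logged with `context`.
argmaxFixedOrder <- function(values, names, context = "argmax") {
  best <- which(values == max(values))
  if (length(best) > 1L)
    logEvent("%s: tie between {%s}; broke by fixed order", context,
             paste(names[best], collapse = ", "))
  best[1L]
}

stopValidation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
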