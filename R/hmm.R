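#' HMM fitting configuration
#'
#' Controls Baum-Welch fitting of the two-state Gaussian contour HMMs.
#' Desk-scale defaults keep leave-one-out experiments fast; the field-scale
#' protocol of 1000 randomized repeats is reached by raising `nRestarts` /
#' the classifier's `nRepeats`.
#'
#' @param nStates number of hidden states; 2 throughout this workflow.
#' @param nRestarts independent EM restarts with randomized initialisations;
#'   the restart with the highest final log-likelihood is kept.
#' @param maxEmIters maximum EM iterations per restart.
#' @param logLikTol relative log-likelihood improvement below which EM stops.
#' @param varianceFloor lower bound on emission variances (Hz^2); prevents
#'   collapse on repeated values.
#' @param seed integer seed from which all restart initialisations derive.
#' @return A list of class `FitConfig`.
#' @export
fitConfig <- function(nStates = 2L, nRestarts = 5L, maxEmIters = 100L,
                      logLikTol = 1e-6, varianceFloor = 1, seed = 1L) {
  if (nRestarts < 1L) stopValidation("nRestarts must be >= 1")
  if (logLikTol <= 0) stopValidation("logLikTol must be positive")
  if (varianceFloor <= 0) stopValidation("varianceFloor must be positive")
  structure(list(nStates = as.integer(nStates),
                 nRestarts = as.integer(nRestarts),
                 maxEmIters = as.integer(maxEmIters),
                 logLikTol = logLikTol, varianceFloor = varianceFloor,
                 seed = as.integer(seed)),
            class = "FitConfig")
}

.contourValues <- function(x) {
  if (is(x, "F0Contour")) f0Values(x) else as.numeric(x)
}

#' Forward-algorithm log-likelihood of a contour under a Gaussian HMM
#'
#' Exact marginal log p(observations | model) by the forward algorithm,
#' computed in log space (no underflow for contours up to 1e5 frames).
#'
#' @param model a [GaussianHMM-class].
#' @param contour an [F0Contour-class] or numeric vector of F0 values (Hz).
#' @return Log-likelihood in nats.
#' @export
hmmLogLik <- function(model, contour) {
  stopifnot(is(model, "GaussianHMM"))
  x <- .contourValues(contour)
  if (!length(x)) stopValidation("cannot score an empty contour")
  cpp_forward_loglik(x, model@initialProbs, model@transitions,
                     model@emissionMeans, model@emissionVars)
}

#' Fit a Gaussian HMM to F0 contours by EM with random restarts
#'
#' Baum-Welch over multiple independent sequences. Each restart initialises
#' emission means uniformly between the pooled 5th and 95th data percentiles,
#' emission variances at the pooled variance, and transition rows from a
#' Dirichlet(5, 5); the restart with the highest final log-likelihood wins.
#' Within each restart the log-likelihood is non-decreasing across EM
#' iterations (up to numerical slack); the trace of the winning restart is
#' attached as attribute `logLikTrace` and its final training log-likelihood
#' as attribute `logLik`.
#'
#' @param contours list of [F0Contour-class] objects (or numeric vectors).
#' @param cfg a [fitConfig()].
#' @return A fitted [GaussianHMM-class].
#' @export
fitHmm <- function(contours, cfg = fitConfig()) {
  if (is(contours, "F0Contour") || is.numeric(contours))
    contours <- list(contours)
  seqs <- lapply(contours, .contourValues)
  seqs <- seqs[lengths(seqs) > 0L]
  if (!length(seqs)) stopValidation("all contours are empty")
  pooled <- unlist(seqs, use.names = FALSE)
  if (length(pooled) < 2L * cfg$nStates)
    stopValidation("need at least %d total frames to fit %d states",
                   2L * cfg$nStates, cfg$nStates)
  K <- cfg$nStates
  q <- quantile(pooled, c(0.05, 0.95), names = FALSE)
  v0 <- max(var(pooled), cfg$varianceFloor)
  if (!is.finite(v0)) v0 <- cfg$varianceFloor

  best <- NULL
  bestLL <- -Inf
  for (r in seq_len(cfg$nRestarts)) {
    set.seed(childSeed(cfg$seed, 101L, r))
    mu0 <- if (diff(q) > 0) runif(K, q[1], q[2]) else rep(q[1], K)
    A0 <- matrix(rgamma(K * K, shape = 5), K, K)
    A0 <- A0 / rowSums(A0)
    fit <- cpp_baum_welch(seqs, rep(1 / K, K), A0, mu0, rep(v0, K),
                          cfg$maxEmIters, cfg$logLikTol, cfg$varianceFloor)
    model <- gaussianHmm(fit$initialProbs, fit$transitions,
                         fit$emissionMeans, fit$emissionVars)
    finalLL <- sum(vapply(seqs, function(x)
      cpp_forward_loglik(x, model@initialProbs, model@transitions,
                         model@emissionMeans, model@emissionVars),
      numeric(1)))
    if (finalLL > bestLL) {
      bestLL <- finalLL
      best <- model
      attr(best, "logLikTrace") <- fit$logLikTrace
    }
  }
  attr(best, "logLik") <- bestLL
  best
}

#' Simulate observation sequences from a Gaussian HMM
#'
#' Draws hidden state paths from the Markov chain and Gaussian emissions per
#' state. Used for parameter-recovery checks.
#'
#' @param model a [GaussianHMM-class].
#' @param lengths integer vector: one sequence per element, of that length.
#' @param seed integer seed.
#' @return List of numeric observation vectors.
#' @export
simulateHmm <- function(model, lengths, seed = 1L) {
  stopifnot(is(model, "GaussianHMM"))
  K <- nStates(model)
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    set.seed(childSeed(seed, 202L, i))
    T <- lengths[i]
    st <- integer(T)
    st[1] <- sample.int(K, 1L, prob = model@initialProbs)
    if (T > 1L)
      for (t in 2:T)
        st[t] <- sample.int(K, 1L, prob = model@transitions[st[t - 1L], ])
    out[[i]] <- rnorm(T, model@emissionMeans[st],
                      sqrt(model@emissionVars[st]))
  }
  out
}
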