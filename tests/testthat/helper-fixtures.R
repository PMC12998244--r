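# Fixtures are built in code: tone clips, random HMMs, and small independent
# oracles the implementation is checked against.

toneClip <- function(freq, durS = 1, rate = 16000, amp = 1) {
  t <- seq_len(round(durS * rate)) / rate
  audioClip(amp * sin(2 * pi * freq * t), rate)
}

randomHmm2 <- function() {
  A <- matrix(rgamma(4, 1) + 0.05, 2)
  A <- A / rowSums(A)
  p <- rgamma(2, 1) + 0.05
  gaussianHmm(p / sum(p), A, runif(2, 50, 350), runif(2, 50, 500))
}

# Independent oracle: marginal log-likelihood by exhaustive enumeration of
# all K^T hidden state paths.
enumLogLik <- function(model, x) {
  K <- length(initialProbs(model))
  T <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(p) {
    ll <- log(initialProbs(model)[p[1]]) +
      dnorm(x[1], emissionMeans(model)[p[1]],
            sqrt(emissionVars(model)[p[1]]), log = TRUE)
    if (T > 1)
      for (t in 2:T)
        ll <- ll + log(transitionMatrix(model)[p[t - 1], p[t]]) +
          dnorm(x[t], emissionMeans(model)[p[t]],
                sqrt(emissionVars(model)[p[t]]), log = TRUE)
    ll
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# Independent oracle: direct O(n^2) normalized autocorrelation over all
# candidate lags for a single frame starting at `start` (1-based), with the
# documented peak rule (shortest local maximum within `tol` of the global
# maximum) written out plainly.
bruteForceF0 <- function(x, rate, start, w = 128L, lo = 30, hi = 375,
                         tol = 0.02) {
  lagMin <- max(1L, round(rate / hi))
  lagMax <- min(round(rate / lo), length(x) - w - start + 1L)
  lags <- lagMin:lagMax
  frame <- x[start:(start + w - 1L)]
  r <- vapply(lags, function(L) {
    lagged <- x[(start + L):(start + L + w - 1L)]
    sum(frame * lagged) / sqrt(sum(frame^2) * sum(lagged^2))
  }, numeric(1))
  m <- max(r)
  for (i in seq_along(lags)) {
    leftOk <- i == 1L || r[i] >= r[i - 1L]
    rightOk <- i == length(lags) || r[i] >= r[i + 1L]
    if (leftOk && rightOk && r[i] >= m * (1 - tol)) return(rate / lags[i])
  }
  rate / lags[which.max(r)]
}

# Quantization step of the integer-lag pitch grid at frequency f.
lagStep <- function(f, rate = 16000) {
  lag <- round(rate / f)
  rate / (lag - 1) - rate / lag
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

syntheticAnnotations <- function(n = 12, labels = NULL, seed = 99) {
  set.seed(seed)
  k <- n
  dur <- runif(k, 0.2, 1.5)
  begin <- cumsum(runif(k, 0.2, 0.8) + c(0, dur[-k]))
  callAnnotations(bout_id = "b1", source_id = "s1",
                  call_type = if (is.null(labels)) NA else labels,
                  begin_s = begin, end_s = begin + dur,
                  max_freq_hz = runif(k, 80, 350))
}
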