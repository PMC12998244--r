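test_that("forward log-likelihood matches closed forms", {
  m <- gaussianHmm(c(0.3, 0.7), matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                       byrow = TRUE), c(100, 250), c(50, 80))
  # one frame: log sum_s pi_s N(x; mu_s, var_s)
  x <- 180
  expect_equal(hmmLogLik(m, x),
               log(0.3 * dnorm(x, 100, sqrt(50)) +
                   0.7 * dnorm(x, 250, sqrt(80))))
  # identical states collapse to i.i.d. Gaussian likelihood
  d <- gaussianHmm(c(0.5, 0.5), matrix(0.5, 2, 2), c(150, 150), c(60, 60))
  xs <- c(140, 155, 160, 149)
  expect_equal(hmmLogLik(d, xs),
               sum(dnorm(xs, 150, sqrt(60), log = TRUE)))
})

test_that("forward algorithm equals path enumeration on random models", {
  set.seed(21)
  for (i in 1:40) {
    m <- randomHmm2()
    x <- runif(sample(1:8, 1), 40, 400)
    expect_lt(abs(hmmLogLik(m, x) - enumLogLik(m, x)), 1e-10)
  }
})

test_that("EM recovers planted parameters and is monotone", {
  truth <- gaussianHmm(c(0.5, 0.5), matrix(c(0.9, 0.1, 0.2, 0.8), 2,
                                           byrow = TRUE),
                       c(120, 300), c(100, 100))
  xs <- simulateHmm(truth, rep(50, 200), seed = 7)
  fit <- fitHmm(xs, fitConfig(nRestarts = 3, seed = 3))
  mu <- sort(emissionMeans(fit))
  expect_lt(abs(mu[1] - 120), 10)
  expect_lt(abs(mu[2] - 300), 10)
  trace <- attr(fit, "logLikTrace")
  expect_true(all(diff(trace) >= -1e-8 * pmax(abs(trace[-1]), 1)))
})

test_that("degenerate and deterministic fitting behaviour", {
  # constant contour: both means at the value, variances at the floor
  fit <- fitHmm(list(rep(200, 30)), fitConfig(nRestarts = 2, seed = 1))
  expect_equal(emissionMeans(fit), c(200, 200), tolerance = 1e-6)
  expect_equal(emissionVars(fit), c(1, 1))
  # same seed, same model
  xs <- simulateHmm(randomHmm2(), rep(20, 5), seed = 2)
  f1 <- fitHmm(xs, fitConfig(nRestarts = 3, seed = 9))
  f2 <- fitHmm(xs, fitConfig(nRestarts = 3, seed = 9))
  expect_identical(emissionMeans(f1), emissionMeans(f2))
  expect_identical(transitionMatrix(f1), transitionMatrix(f2))
  expect_error(fitHmm(list(numeric(0))), "empty")
})

test_that("restart selection never loses to a single restart", {
  xs <- simulateHmm(gaussianHmm(c(0.5, 0.5),
                                matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE),
                                c(90, 280), c(200, 200)),
                    rep(30, 20), seed = 5)
  multi <- fitHmm(xs, fitConfig(nRestarts = 5, seed = 11))
  single <- fitHmm(xs, fitConfig(nRestarts = 1, seed = 11))
  expect_gte(attr(multi, "logLik") + 1e-8, attr(single, "logLik"))
})

test_that("separable call types classify perfectly under LOO", {
  set.seed(31)
  lowC <- lapply(1:6, function(i) runif(30, 80, 120))
  highC <- lapply(1:6, function(i) runif(30, 250, 350))
  rep1 <- classifyCallsLoo(c(lowC, highC), rep(c("low", "high"), each = 6),
                           fitConfig(nRestarts = 2, seed = 3), nRepeats = 1)
  expect_equal(unname(microMetrics(rep1)["accuracy"]), 1)
  # on separable data repeated runs agree decision-for-decision
  rep3 <- classifyCallsLoo(c(lowC, highC), rep(c("low", "high"), each = 6),
                           fitConfig(nRestarts = 2, seed = 3), nRepeats = 3)
  p3 <- attr(rep3, "predictions")
  expect_true(all(tapply(p3$predicted, p3$repeat_, paste, collapse = "") ==
                  paste(attr(rep1, "predictions")$predicted, collapse = "")))
})

test_that("shuffled labels drive accuracy to chance", {
  set.seed(41)
  contours <- lapply(1:40, function(i) rnorm(25, 150, 30))
  labels <- rep(c("a", "b"), 20)
  rep1 <- classifyCallsLoo(contours, sample(labels),
                           fitConfig(nRestarts = 1, seed = 2), nRepeats = 1)
  acc <- microMetrics(rep1)["traceAccuracy"]
  # binomial null: p = 1/2, n = 40 -> 3 sigma ~ 0.24
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 40) + 1e-9)
})

test_that("LOO validation rejects degenerate class structure", {
  expect_error(classifyCallsLoo(list(1:5, 1:5), c("a", "a")), "2 classes")
  expect_error(classifyCallsLoo(list(1:5, 1:5, 1:5), c("a", "a", "b")),
               "fewer than 2 calls")
})

test_that("individual identification separates distinct contour signatures", {
  ds <- genDataset(nIndividuals = 3, boutsPerIndividual = 6,
                   signatureSpread = 0.3, seed = 17)
  ftr <- ds$annotations$call_type == "full_throated_roar"
  bouts <- groupBouts(ds$annotations$source_id[ftr],
                      ds$annotations$bout_id[ftr], ds$contours[ftr])
  rep1 <- classifyIndividualsLoo(bouts, fitConfig(nRestarts = 2, seed = 5),
                                 nRepeats = 1)
  expect_equal(unname(macroMetrics(rep1)["f1"]), 1)
})

test_that("indistinguishable individuals are confused near symmetry", {
  set.seed(51)
  mk <- function(lion) lapply(1:8, function(b)
    list(lion_id = lion, bout_id = paste0(lion, "_", b),
         contours = lapply(1:3, function(i) rnorm(40, 180, 20))))
  bouts <- c(mk("X"), mk("Y"))
  rep1 <- classifyIndividualsLoo(bouts, fitConfig(nRestarts = 1, seed = 8),
                                 nRepeats = 1)
  acc <- microMetrics(rep1)["traceAccuracy"]
  expect_lt(acc, 0.95)  # same generator: cannot be reliably separated
})

test_that("a single-contour bout scores as that contour's log-likelihood", {
  m <- randomHmm2()
  ctr <- rnorm(20, 150, 20)
  b <- list(list(lion_id = "X", bout_id = "b1", contours = list(ctr)))
  # the bout score under 'sum' is the sum over its one contour
  expect_equal(hmmLogLik(m, ctr),
               sum(vapply(b[[1]]$contours, function(ct) hmmLogLik(m, ct),
                          numeric(1))))
})
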