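test_that("negative-binomial pmf matches hand-computed values", {
  expect_equal(nbPmf(0, K = 1, r = 0.5), 0.5)          # (1 - r)^K
  expect_equal(nbPmf(1, K = 2, r = 0.5), 0.25)          # C(2,1) 0.25 0.5
  expect_equal(sum(nbPmf(0:5000, K = 3, r = 0.7)), 1, tolerance = 1e-9)
  expect_error(nbPmf(1, K = -1, r = 0.5), "positive")
  expect_error(nbPmf(1, K = 1, r = 1.2), "strictly in")
})

test_that("logistic prior follows the closed form", {
  p0 <- accessTFParams(0, 0, 0, 0, K0 = 1, r0 = 0.5, K1 = 5, r1 = 0.8)
  expect_equal(logisticPrior(p0, runif(5), runif(5), runif(5)),
               rep(0.5, 5))
  p1 <- accessTFParams(0, 1, 0, 0, K0 = 1, r0 = 0.5, K1 = 5, r1 = 0.8)
  expect_equal(logisticPrior(p1, 1, 0, 0), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  ## monotone in f when beta1 > 0, over random feature grids
  set.seed(1)
  for (i in 1:5) {
    d <- runif(1); c_ <- runif(1)
    f <- sort(runif(20))
    expect_true(all(diff(logisticPrior(p1, f, d, c_)) > 0))
  }
})

test_that("top-count initialization picks the right fraction with ties", {
  expect_equal(sum(initializePriorStates(sample(1:100))), 5)
  expect_equal(sum(initializePriorStates(sample(1:10000))), 500)
  ## ties at the cutoff are all included
  n <- c(rep(10L, 8), rep(0L, 92))
  expect_equal(sum(initializePriorStates(n)), 8)
  expect_error(initializePriorStates(rep(3L, 100)), "identical")
  expect_error(initializePriorStates(1:10), "at least 20")
})

test_that("E step reproduces Bayes arithmetic exactly", {
  p <- accessTFParams(0, 0, 0, 0, K0 = 1, r0 = 0.4, K1 = 6, r1 = 0.85)
  feats <- data.frame(f = runif(50), d = runif(50), c = runif(50),
                      n = rpois(50, 5))
  ## independent computation of the posterior odds
  y <- 0.5
  num <- y * dnbinom(feats$n, size = 6, prob = 0.15)
  den <- num + (1 - y) * dnbinom(feats$n, size = 1, prob = 0.6)
  expect_equal(eStep(p, feats), num / den, tolerance = 1e-12)
})

test_that("E step with equal emission components returns the prior", {
  p <- accessTFParams(-1, 2, 1, 0.5, K0 = 2, r0 = 0.6, K1 = 2, r1 = 0.6)
  feats <- data.frame(f = runif(100), d = runif(100), c = runif(100),
                      n = rpois(100, 3))
  expect_equal(eStep(p, feats),
               logisticPrior(p, feats$f, feats$d, feats$c),
               tolerance = 1e-12)
})

test_that("posterior is monotone in the count when the bound component
           dominates", {
  p <- accessTFParams(0, 1, 1, 1, K0 = 1, r0 = 0.5, K1 = 5, r1 = 0.8)
  n <- 0:60
  feats <- data.frame(f = 0.4, d = 0.4, c = 0.4, n = n)
  g <- eStep(p, feats)
  expect_true(all(diff(g) > 0))
  ## cross-check against the brute-force likelihood ratio
  lr <- dnbinom(n, size = 5, prob = 0.2) / dnbinom(n, size = 1, prob = 0.5)
  expect_true(all(diff(lr) > 0))
})

test_that("M step recovers components from perfectly separated labels", {
  scen <- simulationScenario(nMotifs = 10000, seed = 5)
  d <- simulateMotifDataset(scen)
  params <- mStep(d, gamma = as.numeric(d$b))
  m <- nbMeans(params)
  expect_lt(abs(m[["bound"]] - 20) / 20, 0.05)
  expect_lt(abs(m[["unbound"]] - 1) / 1, 0.05)
})

test_that("with equal emissions the beta fit equals a plain logistic fit", {
  set.seed(9)
  feats <- data.frame(f = runif(500), d = runif(500), c = runif(500),
                      n = rpois(500, 4))
  gamma <- plogis(-1 + 2 * feats$f + feats$d - 0.5 * feats$c)
  params <- mStep(feats, gamma)
  ref <- suppressWarnings(glm(gamma ~ f + d + c, data = feats,
                              family = quasibinomial()))
  expect_equal(unname(params@beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("M step never decreases the expected complete-data objective", {
  Q <- function(params, feats, gamma) {
    y <- logisticPrior(params, feats$f, feats$d, feats$c)
    sum(gamma * (log(pmax(y, 1e-300)) +
                   nbPmf(feats$n, params@K1, params@r1, log = TRUE)) +
        (1 - gamma) * (log(pmax(1 - y, 1e-300)) +
                   nbPmf(feats$n, params@K0, params@r0, log = TRUE)))
  }
  set.seed(21)
  scen <- simulationScenario(nMotifs = 600, seed = 21)
  feats <- simulateMotifDataset(scen)
  for (i in 1:20) {
    start <- accessTFParams(rnorm(1), rnorm(1), rnorm(1), rnorm(1),
                            K0 = runif(1, 0.2, 3), r0 = runif(1, 0.2, 0.8),
                            K1 = runif(1, 0.2, 8), r1 = runif(1, 0.2, 0.9))
    gamma <- eStep(start, feats)
    if (max(gamma) - min(gamma) < 1e-12) next
    updated <- mStep(feats, gamma, previous = start)
    expect_gte(Q(updated, feats, gamma), Q(start, feats, gamma) - 1e-6)
  }
})

test_that("EM fit recovers the generative posteriors", {
  scen <- simulationScenario(nMotifs = 10000, seed = 2)
  d <- simulateMotifDataset(scen)
  fit <- fitAccessTF(d, seed = 2)
  expect_true(isConverged(fit))
  trueGamma <- eStep(scen@trueParams, d)
  expect_gt(cor(trueGamma, posteriors(fit)$gamma), 0.95)
  ## log-likelihood trajectory is non-decreasing
  traj <- logLikTrajectory(fit)
  expect_true(all(diff(traj) >= -1e-6 * pmax(1, abs(traj[-length(traj)]))))
})

test_that("refitting from the converged state reconverges immediately", {
  scen <- simulationScenario(nMotifs = 3000, seed = 4)
  d <- simulateMotifDataset(scen)
  fit <- fitAccessTF(d, seed = 4)
  refit <- fitAccessTF(d, init = as.numeric(posteriors(fit)$gamma))
  expect_lte(refit@iterations, 2L)
})

test_that("different admissible initializations reach the same posteriors", {
  scen <- simulationScenario(nMotifs = 4000, seed = 6)
  d <- simulateMotifDataset(scen)
  fitA <- fitAccessTF(d, topFraction = 0.05)
  fitB <- fitAccessTF(d, topFraction = 0.10)
  mad <- mean(abs(posteriors(fitA)$gamma - posteriors(fitB)$gamma))
  expect_lt(mad, 0.02)
})

test_that("prediction is a pure E-step pass", {
  scen <- simulationScenario(nMotifs = 2000, seed = 8)
  d <- simulateMotifDataset(scen)
  fit <- fitAccessTF(d)
  pred <- predictPosterior(fit, d)
  expect_equal(as.numeric(pred$gamma), as.numeric(posteriors(fit)$gamma),
               tolerance = 1e-12)
  ## batch equals per-motif
  one <- vapply(1:20, function(i)
    predictPosterior(fit, d[i, ])$gamma, numeric(1))
  expect_equal(one, as.numeric(pred$gamma[1:20]), tolerance = 1e-12)
  ## a zero-count motif with a weak prior is pulled below its prior
  z <- data.frame(f = 0.2, d = 0.2, c = 0.2, n = 0L)
  pz <- predictPosterior(fit, z)
  expect_lt(pz$gamma, pz$y)
})

test_that("train/test splits are disjoint, sized and reproducible", {
  s1 <- splitTrainTest(20000, seed = 99)
  s2 <- splitTrainTest(20000, seed = 99)
  expect_identical(s1, s2)
  expect_length(s1$train, 10000L)
  expect_length(s1$test, 10000L)
  expect_length(intersect(s1$train, s1$test), 0L)
  expect_warning(s3 <- splitTrainTest(100, 10000, 10000, seed = 1),
                 "scaled")
  expect_equal(length(s3$train) + length(s3$test), 100L)
})
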