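#' @importFrom stats dnbinom glm.fit quasibinomial optim plogis qlogis
#'   quantile weighted.mean
NULL

## The model: each motif i carries features (f_i, d_i, c_i) and a tag
## count n_i. Binding b_i is hidden. Prior:
##   logit P(b_i = 1) = beta0 + beta1 f_i + beta2 d_i + beta3 c_i
## Emission: n_i | b_i = k  ~  NegBin(K_k, r_k), pmf
##   C(n + K - 1, n) (1 - r)^K r^n    (gamma form for non-integer K),
## mean K r / (1 - r). EM alternates posterior responsibilities with
## weighted logistic / weighted NB maximum likelihood.

#' Negative-binomial probability mass
#'
#' The emission distribution for flanking tag counts, parameterized by
#' size `K > 0` and success probability `r` in (0, 1):
#' `P(n) = C(n + K - 1, n) (1 - r)^K r^n`, mean `K r / (1 - r)`.
#' Computed in log space; non-integer `K` uses the gamma-function form.
#'
#' @param n Non-negative integer counts.
#' @param K Size parameter (> 0).
#' @param r Success probability in (0, 1).
#' @param log Return log-probabilities?
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' nbPmf(0, K = 1, r = 0.5)   # (1 - r)^K = 0.5
#' @export
nbPmf <- function(n, K, r, log = FALSE) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be positive")
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1))
    stop("r must lie strictly in (0, 1)")
  if (any(n < 0)) stop("counts must be non-negative")
  dnbinom(n, size = K, prob = 1 - r, log = log)
}

#' Prior binding probability from motif features
#'
#' @param params An [AccessTFParams-class].
#' @param f,d,c Feature vectors (normalized PWM score, TSS proximity,
#'   conservation).
#' @return Numeric vector `y` of prior binding probabilities.
#' @export
logisticPrior <- function(params, f, d, c) {
  b <- params@beta
  plogis(b[["beta0"]] + b[["beta1"]] * f + b[["beta2"]] * d +
         b[["beta3"]] * c)
}

#' Initial hard binding states from tag counts
#'
#' Motifs in the top `topFraction` of the tag-count distribution start as
#' bound (responsibility 1), the rest as unbound. Ties at the cutoff
#' count are all included, so slightly more than the nominal fraction can
#' be initialized bound.
#'
#' @param n Integer tag counts (>= 20 motifs).
#' @param topFraction Fraction initialized as bound (default 0.05).
#' @return Numeric vector of 0/1 initial responsibilities.
#' @export
initializePriorStates <- function(n, topFraction = 0.05) {
  if (length(n) < 20L) stop("need at least 20 motifs to initialize")
  if (all(n == n[1]))
    stop("all tag counts identical; the top-count initialization is ",
         "degenerate - simulate or supply a larger, more varied motif set")
  k <- ceiling(topFraction * length(n))
  cutoff <- sort(n, decreasing = TRUE)[k]
  as.numeric(n >= cutoff)
}

#' Posterior responsibilities (E step)
#'
#' `gamma_i = y_i NB(n_i | K1, r1) / [y_i NB(n_i | K1, r1) +
#' (1 - y_i) NB(n_i | K0, r0)]`, evaluated in log space. If both
#' component likelihoods underflow to zero the prior `y_i` is returned
#' for that motif.
#'
#' @param params An [AccessTFParams-class].
#' @param features `data.frame`-like with columns `f`, `d`, `c`, `n`.
#' @return Numeric vector of posterior binding probabilities.
#' @export
eStep <- function(params, features) {
  y <- logisticPrior(params, features$f, features$d, features$c)
  l1 <- nbPmf(features$n, params@K1, params@r1, log = TRUE)
  l0 <- nbPmf(features$n, params@K0, params@r0, log = TRUE)
  ## floor component likelihoods at 1e-300 before normalization
  l1 <- pmax(l1, log(1e-300)); l0 <- pmax(l0, log(1e-300))
  a <- log(pmax(y, 1e-300)) + l1
  b <- log(pmax(1 - y, 1e-300)) + l0
  gamma <- 1 / (1 + exp(b - a))
  dead <- !is.finite(a) & !is.finite(b)
  if (any(dead)) gamma[dead] <- y[dead]
  gamma
}

## weighted NB maximum likelihood over (log K, logit r); method-of-moments
## start; returns c(K, r)
.fitWeightedNB <- function(n, w, init = NULL) {
  w <- pmax(w, 0)
  sw <- sum(w)
  if (sw < 1e-8) stop("negligible total responsibility for one component; ",
                      "the mixture has collapsed")
  m <- sum(w * n) / sw
  v <- sum(w * (n - m)^2) / sw
  if (is.null(init)) {
    r0 <- if (v > m && m > 0) 1 - m / v else 0.5
    r0 <- min(max(r0, 1e-3), 1 - 1e-3)
    K0 <- max(m * (1 - r0) / r0, 1e-3)
    init <- c(K0, r0)
  }
  nll <- function(theta) {
    K <- exp(theta[1]); r <- plogis(theta[2])
    -sum(w * dnbinom(n, size = K, prob = 1 - r, log = TRUE))
  }
  theta0 <- c(log(init[1]), qlogis(init[2]))
  fit <- suppressWarnings(
    optim(theta0, nll, method = "L-BFGS-B",
          lower = c(-12, -12), upper = c(12, 12)))
  if (fit$convergence != 0) {
    ## L-BFGS-B line searches can abort near the optimum on flat
    ## likelihoods; polish with Nelder-Mead from the best point so far
    alt <- optim(fit$par, nll, method = "Nelder-Mead")
    if (alt$value <= fit$value) fit <- alt
    if (fit$convergence != 0 && fit$convergence != 1)
      stop("negative-binomial inner optimization failed: code ",
           fit$convergence, " (", fit$message, ")")
  }
  ## never return a point worse than the start (M-step contract)
  if (nll(theta0) < fit$value) fit$par <- theta0
  c(K = exp(fit$par[1]), r = plogis(fit$par[2]))
}

#' Maximization step
#'
#' Given responsibilities, re-estimates the logistic-prior coefficients
#' by a responsibility-response logistic fit of `gamma` on (f, d, c), the
#' bound NB parameters by `gamma`-weighted maximum likelihood on the
#' counts, and the unbound NB parameters by `(1 - gamma)`-weighted
#' maximum likelihood. Each sub-fit maximizes its term of the expected
#' complete-data log-likelihood, so the EM objective cannot decrease.
#'
#' @param features `data.frame`-like with columns `f`, `d`, `c`, `n`.
#' @param gamma Responsibilities in \[0, 1\].
#' @param previous Optional [AccessTFParams-class] used to warm-start the
#'   NB optimizers.
#' @return An [AccessTFParams-class].
#' @export
mStep <- function(features, gamma, previous = NULL) {
  if (any(gamma < 0 | gamma > 1)) stop("responsibilities must lie in [0, 1]")
  if (max(gamma) - min(gamma) < 1e-12)
    stop("responsibilities are all identical; logistic fit is undefined")
  x <- cbind(1, features$f, features$d, features$c)
  lfit <- glm.fit(x, gamma, family = quasibinomial())
  beta <- unname(lfit$coefficients)
  if (anyNA(beta))
    stop("logistic coefficients not estimable (collinear features)")
  nb1 <- .fitWeightedNB(features$n, gamma,
                        init = if (!is.null(previous))
                          c(previous@K1, previous@r1))
  nb0 <- .fitWeightedNB(features$n, 1 - gamma,
                        init = if (!is.null(previous))
                          c(previous@K0, previous@r0))
  accessTFParams(beta[1], beta[2], beta[3], beta[4],
                 K0 = nb0[["K"]], r0 = nb0[["r"]],
                 K1 = nb1[["K"]], r1 = nb1[["r"]])
}

## observed-data log-likelihood under the mixture
.observedLogLik <- function(params, features) {
  y <- logisticPrior(params, features$f, features$d, features$c)
  l1 <- nbPmf(features$n, params@K1, params@r1, log = TRUE)
  l0 <- nbPmf(features$n, params@K0, params@r0, log = TRUE)
  a <- log(pmax(y, 1e-300)) + l1
  b <- log(pmax(1 - y, 1e-300)) + l0
  m <- pmax(a, b)
  sum(m + log(exp(a - m) + exp(b - m)))
}

#' Fit the binding model by expectation-maximization
#'
#' Starting from the hard top-tag-count initialization
#' ([initializePriorStates()]), alternates [eStep()] and [mStep()] until
#' the relative change in observed-data log-likelihood falls below `tol`
#' or `maxIter` is reached. The log-likelihood trajectory is checked to
#' be non-decreasing (within numerical tolerance) at every iteration.
#'
#' The bound/unbound component labels are fixed by the initialization
#' (high-count motifs start bound); after fitting, the components are
#' reordered if necessary so that the bound component has the larger
#' mean.
#'
#' @param features `data.frame`-like with columns `f`, `d`, `c`, `n`
#'   (>= 1000 motifs recommended).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxIter Maximum EM iterations.
#' @param topFraction Initialization fraction, see
#'   [initializePriorStates()].
#' @param threshold Posterior cutoff for hard bound calls.
#' @param seed Optional integer recorded in the fit (the EM itself is
#'   deterministic given the data and initialization).
#' @param init Optional responsibilities (numeric in \[0, 1\]) overriding
#'   the top-count initialization.
#' @return An [AccessTFFit-class].
#' @export
fitAccessTF <- function(features, tol = 1e-6, maxIter = 500L,
                        topFraction = 0.05, threshold = 0.99,
                        seed = NA_integer_, init = NULL) {
  features <- as.data.frame(features)[c("f", "d", "c", "n")]
  gamma <- if (is.null(init)) initializePriorStates(features$n, topFraction)
           else init
  stopifnot(length(gamma) == nrow(features))
  params <- mStep(features, gamma)
  ll <- .observedLogLik(params, features)
  traj <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    gamma <- eStep(params, features)
    params <- mStep(features, gamma, previous = params)
    llNew <- .observedLogLik(params, features)
    if (llNew < ll - 1e-6 * max(1, abs(ll)))
      stop(sprintf(
        "EM log-likelihood decreased at iteration %d (%.6f -> %.6f)",
        iter, ll, llNew))
    traj <- c(traj, llNew)
    if (abs(llNew - ll) < tol * max(1, abs(ll))) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  ## ensure the "bound" component is the high-mean one
  m <- nbMeans(params)
  if (m[["bound"]] < m[["unbound"]]) {
    params <- accessTFParams(
      -params@beta[["beta0"]], -params@beta[["beta1"]],
      -params@beta[["beta2"]], -params@beta[["beta3"]],
      K0 = params@K1, r0 = params@r1, K1 = params@K0, r1 = params@r0)
  }
  gamma <- eStep(params, features)
  y <- logisticPrior(params, features$f, features$d, features$c)
  new("AccessTFFit",
      params = params,
      posterior = DataFrame(y = y, gamma = gamma,
                            call = gamma >= threshold),
      logLik = traj, iterations = iter,
      converged = converged, seed = as.integer(seed),
      threshold = threshold)
}

#' Predict posterior binding for new motifs
#'
#' One E-step pass with fixed, fitted parameters; no updates.
#'
#' @param fit An [AccessTFFit-class] (or bare [AccessTFParams-class]).
#' @param features `data.frame`-like with columns `f`, `d`, `c`, `n`.
#' @param threshold Posterior cutoff for hard calls; defaults to the
#'   fit's threshold (0.99 for bare parameters).
#' @return `DataFrame` with columns `y`, `gamma`, `call`.
#' @export
predictPosterior <- function(fit, features, threshold = NULL) {
  params <- if (is(fit, "AccessTFFit")) fit@params else fit
  if (is.null(threshold))
    threshold <- if (is(fit, "AccessTFFit")) fit@threshold else 0.99
  y <- logisticPrior(params, features$f, features$d, features$c)
  gamma <- eStep(params, features)
  DataFrame(y = y, gamma = gamma, call = gamma >= threshold)
}

#' Disjoint random train/test split
#'
#' Uniform sampling without replacement of `nTrain` + `nTest` indices.
#' If the population is smaller, both sizes are scaled down
#' proportionally (with a warning).
#'
#' @param n Population size (or a vector/data.frame whose length/rows
#'   define it).
#' @param nTrain,nTest Requested sample sizes (default 10,000 each).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(n, nTrain = 10000L, nTest = 10000L, seed = 1L) {
  if (is.data.frame(n) || is(n, "DataFrame")) n <- nrow(n)
  else if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < nTrain + nTest) {
    scale <- n / (nTrain + nTest)
    nTrain <- floor(nTrain * scale)
    nTest <- n - nTrain
    warning("population smaller than requested split; scaled to ",
            nTrain, " train + ", nTest, " test")
  }
  set.seed(seed)
  picked <- sample.int(n, nTrain + nTest)
  list(train = sort(picked[seq_len(nTrain)]),
       test = sort(picked[nTrain + seq_len(nTest)]))
}
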