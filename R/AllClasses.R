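#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' Parameters of the accessibility-aware binding model
#'
#' Holds the full parameter set of the Bayesian network that links motif
#' features to in-vivo binding: the logistic-prior coefficients on the
#' intercept, normalized motif score \eqn{f}, TSS-proximity \eqn{d} and
#' conservation \eqn{c}, plus the two negative-binomial emission components
#' for the DNase tag count \eqn{n} (unbound: \eqn{K_0, r_0}; bound:
#' \eqn{K_1, r_1}, parameterized so the mean is \eqn{K r / (1 - r)}).
#'
#' @slot beta Named numeric of length 4: `beta0` (intercept), `beta1` (motif
#'   score), `beta2` (TSS proximity), `beta3` (conservation).
#' @slot K0,r0 Unbound negative-binomial size and success probability.
#' @slot K1,r1 Bound negative-binomial size and success probability.
#'
#' @seealso [accessTFParams()] for the user-facing constructor.
#' @export
setClass("AccessTFParams",
  representation(
    beta = "numeric",
    K0 = "numeric", r0 = "numeric",
    K1 = "numeric", r1 = "numeric"
  )
)

setValidity("AccessTFParams", function(object) {
  msg <- character()
  if (length(object@beta) != 4L || !all(is.finite(object@beta)))
    msg <- c(msg, "'beta' must be 4 finite coefficients")
  if (!identical(names(object@beta), c("beta0", "beta1", "beta2", "beta3")))
    msg <- c(msg, "'beta' must be named beta0..beta3")
  for (s in c("K0", "K1")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  for (s in c("r0", "r1")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      msg <- c(msg, sprintf("'%s' must lie strictly in (0, 1)", s))
  }
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param beta0,beta1,beta2,beta3 Logistic-prior coefficients (intercept,
#'   motif score, TSS proximity, conservation).
#' @param K0,r0 Unbound negative-binomial parameters (`K0 > 0`,
#'   `0 < r0 < 1`); the unbound mean tag count is `K0 * r0 / (1 - r0)`.
#' @param K1,r1 Bound negative-binomial parameters, same constraints.
#'
#' @return An [AccessTFParams-class] object.
#' @examples
#' p <- accessTFParams(beta0 = -2, beta1 = 1, beta2 = 2, beta3 = 1,
#'                     K0 = 1, r0 = 0.5, K1 = 5, r1 = 0.8)
#' nbMeans(p)
#' @export
accessTFParams <- function(beta0, beta1, beta2, beta3, K0, r0, K1, r1) {
  new("AccessTFParams",
      beta = c(beta0 = unname(beta0), beta1 = unname(beta1),
               beta2 = unname(beta2), beta3 = unname(beta3)),
      K0 = unname(K0), r0 = unname(r0), K1 = unname(K1), r1 = unname(r1))
}

#' A fitted binding model with its EM trace
#'
#' Returned by [fitAccessTF()]. Bundles the converged parameters, the
#' per-motif responsibilities at convergence, and the observed-data
#' log-likelihood trajectory (non-decreasing across iterations by the EM
#' monotonicity guarantee, asserted during fitting).
#'
#' @slot params The fitted [AccessTFParams-class].
#' @slot posterior `DataFrame` with columns `y` (prior binding probability),
#'   `gamma` (posterior binding probability) and `call` (hard call).
#' @slot logLik Numeric vector, observed-data log-likelihood per iteration.
#' @slot iterations Number of EM iterations performed.
#' @slot converged Logical flag.
#' @slot seed Integer seed recorded for provenance (NA when none used).
#' @slot threshold Posterior cutoff used for the hard calls.
#' @export
setClass("AccessTFFit",
  representation(
    params = "AccessTFParams",
    posterior = "DataFrame",
    logLik = "numeric",
    iterations = "integer",
    converged = "logical",
    seed = "integer",
    threshold = "numeric"
  )
)

setValidity("AccessTFFit", function(object) {
  g <- object@posterior$gamma
  if (!is.null(g) && length(g) && (min(g) < 0 || max(g) > 1))
    return("posterior probabilities must lie in [0, 1]")
  TRUE
})

#' Genome-wide sequencing tag positions
#'
#' A minimal container for DNase-seq (or ChIP-seq) tag positions: one row
#' per distinct (chrom, pos) with its multiplicity. A tag's position is the
#' 5' end of the read on the reference strand; read strand is ignored for
#' counting (configurable at the call sites that consume tracks).
#'
#' @slot tags `data.frame` with columns `chrom` (character), `pos`
#'   (integer, 1-based) and `count` (integer multiplicity), sorted by
#'   chrom then pos.
#' @slot librarySize Total tag count (sum of multiplicities).
#' @export
setClass("TagTrack",
  representation(tags = "data.frame", librarySize = "numeric")
)

setValidity("TagTrack", function(object) {
  t <- object@tags
  if (!all(c("chrom", "pos", "count") %in% names(t)))
    return("tags must have columns chrom, pos, count")
  if (nrow(t) && any(t$count < 1))
    return("tag multiplicities must be >= 1")
  if (!isTRUE(all.equal(object@librarySize, sum(t$count))))
    return("librarySize must equal the sum of tag multiplicities")
  TRUE
})

#' Per-base conservation scores
#'
#' Wraps interval-valued conservation scores (e.g. averaged PhastCons over
#' placental mammals) read from a bedGraph. Bases not covered by any
#' interval take the `default` value (0 unless configured otherwise).
#'
#' @slot cov Disjoint `GRanges` with a numeric `score` column in \[0, 1\].
#' @slot default Score assigned to uncovered bases.
#' @export
setClass("ConservationTrack",
  representation(cov = "GRanges", default = "numeric")
)

setValidity("ConservationTrack", function(object) {
  sc <- object@cov$score
  if (is.null(sc)) return("coverage ranges need a 'score' column")
  if (length(sc) && (min(sc) < 0 || max(sc) > 1))
    return("conservation scores must lie in [0, 1]")
  if (length(object@cov) > 1L &&
      !isDisjoint(object@cov))
    return("conservation intervals must not overlap")
  if (length(object@default) != 1L || object@default < 0 || object@default > 1)
    return("'default' must be a single value in [0, 1]")
  TRUE
})

#' Specification of a synthetic study
#'
#' Describes one synthetic realization of the study design: how many motif
#' matches to simulate, the true generative model parameters, the sampling
#' ranges of the motif features, the fixture genome, and the expression
#' time course (two replicates per time point).
#'
#' Defaults reproduce the study conditions the model targets: 20,000
#' motifs (10,000 train + 10,000 test), bound tag counts ~20x the unbound
#' mean, time points 0/1/2/4/8/12/16/24 h with two replicates.
#'
#' @slot nMotifs Number of motif matches to simulate.
#' @slot trueParams Generative [AccessTFParams-class].
#' @slot fRange,dRange Uniform sampling ranges (within (0,1)) for the
#'   normalized motif score and TSS-proximity features.
#' @slot cShape Two Beta shape parameters for the conservation feature.
#' @slot motifWidth Width (bp) of simulated motif matches.
#' @slot genomeLength Minimum pseudo-chromosome length (bp); grown as
#'   needed so per-motif loci never collide.
#' @slot nGenes,deFraction Expression time course size and fraction of
#'   differentially expressed genes.
#' @slot foldChangeRange Range of true (linear) fold changes for DE genes.
#' @slot replicateNoiseSd Replicate noise SD on the log2 scale.
#' @slot timePoints Time points in hours (first is the baseline).
#' @slot seed Integer seed; fixes every simulated value and emitted byte.
#' @export
setClass("SimulationScenario",
  representation(
    nMotifs = "integer",
    trueParams = "AccessTFParams",
    fRange = "numeric", dRange = "numeric", cShape = "numeric",
    motifWidth = "integer",
    genomeLength = "numeric",
    nGenes = "integer", deFraction = "numeric",
    foldChangeRange = "numeric", replicateNoiseSd = "numeric",
    timePoints = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (object@nMotifs < 1L) msg <- c(msg, "nMotifs must be positive")
  for (s in c("fRange", "dRange")) {
    v <- slot(object, s)
    if (length(v) != 2L || v[1] >= v[2] || v[1] < 0 || v[2] > 1)
      msg <- c(msg, sprintf("'%s' must be an increasing range within (0, 1)", s))
  }
  if (length(object@cShape) != 2L || any(object@cShape <= 0))
    msg <- c(msg, "cShape must be two positive Beta shapes")
  if (object@genomeLength < 1e4)
    msg <- c(msg, "genomeLength must be at least 10 kb")
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must lie in [0, 1]")
  if (length(object@foldChangeRange) != 2L || any(object@foldChangeRange <= 1))
    msg <- c(msg, "foldChangeRange must be two fold changes > 1")
  if (object@replicateNoiseSd < 0)
    msg <- c(msg, "replicateNoiseSd must be non-negative")
  if (length(object@timePoints) < 2L || object@timePoints[1] != 0)
    msg <- c(msg, "timePoints must start at 0 with >= 2 points")
  if (length(msg)) msg else TRUE
})
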