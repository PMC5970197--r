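#' Accessors for fitted models and tracks
#'
#' `modelParams()` returns the [AccessTFParams-class] of a fit;
#' `posteriors()` the per-motif prior/posterior table;
#' `logLikTrajectory()` the observed-data log-likelihood per EM iteration;
#' `isConverged()` the convergence flag; `librarySize()` the total tag
#' count of a [TagTrack-class]; `nbMeans()` the two negative-binomial
#' component means `K r / (1 - r)`.
#'
#' @param object An [AccessTFFit-class], [AccessTFParams-class] or
#'   [TagTrack-class] as appropriate.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname accessors
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname accessors
#' @export
setGeneric("logLikTrajectory",
           function(object) standardGeneric("logLikTrajectory"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(object) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("nbMeans", function(object) standardGeneric("nbMeans"))

#' @rdname accessors
#' @export
setMethod("modelParams", "AccessTFFit", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("posteriors", "AccessTFFit", function(object) object@posterior)

#' @rdname accessors
#' @export
setMethod("logLikTrajectory", "AccessTFFit", function(object) object@logLik)

#' @rdname accessors
#' @export
setMethod("isConverged", "AccessTFFit", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("librarySize", "TagTrack", function(object) object@librarySize)

#' @rdname accessors
#' @export
setMethod("nbMeans", "AccessTFParams", function(object) {
  c(unbound = object@K0 * object@r0 / (1 - object@r0),
    bound = object@K1 * object@r1 / (1 - object@r1))
})

#' @rdname accessors
#' @export
setMethod("nbMeans", "AccessTFFit", function(object) nbMeans(object@params))

setMethod("show", "AccessTFParams", function(object) {
  cat("AccessTFParams\n")
  cat("  logistic prior: ",
      paste(sprintf("%s=%.4g", names(object@beta), object@beta),
            collapse = ", "), "\n", sep = "")
  m <- nbMeans(object)
  cat(sprintf("  unbound NB: K0=%.4g r0=%.4g (mean %.3g)\n",
              object@K0, object@r0, m["unbound"]))
  cat(sprintf("  bound   NB: K1=%.4g r1=%.4g (mean %.3g)\n",
              object@K1, object@r1, m["bound"]))
})

setMethod("show", "AccessTFFit", function(object) {
  cat(sprintf("AccessTFFit: %d motifs, %d EM iterations (%s)\n",
              nrow(object@posterior), object@iterations,
              if (object@converged) "converged" else "not converged"))
  cat(sprintf("  final log-likelihood: %.4f\n",
              object@logLik[length(object@logLik)]))
  show(object@params)
})

setMethod("show", "TagTrack", function(object) {
  cat(sprintf("TagTrack: %d tags at %d positions on %d chromosome(s)\n",
              object@librarySize, nrow(object@tags),
              length(unique(object@tags$chrom))))
})

setMethod("show", "ConservationTrack", function(object) {
  cat(sprintf("ConservationTrack: %d intervals, default %.3g for uncovered bases\n",
              length(object@cov), object@default))
})

setMethod("show", "SimulationScenario", function(object) {
  cat("SimulationScenario\n")
  cat(sprintf("  %d motifs (width %d bp), seed %d\n",
              object@nMotifs, object@motifWidth, object@seed))
  m <- nbMeans(object@trueParams)
  cat(sprintf("  true NB means: unbound %.3g, bound %.3g\n",
              m["unbound"], m["bound"]))
  cat(sprintf("  expression: %d genes, %.0f%% DE, %d time points, 2 replicates\n",
              object@nGenes, 100 * object@deFraction,
              length(object@timePoints)))
})
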