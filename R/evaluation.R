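#' @importFrom stats quantile
NULL

#' Label motifs by ChIP-seq peak overlap
#'
#' A motif is a true positive if its interval overlaps at least one peak
#' by at least `minOverlap` bp, a true negative otherwise.
#'
#' @param motifs `GRanges` of motif matches.
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param minOverlap Minimum overlap in bp (default 1).
#' @return Logical vector, `TRUE` for positives.
#' @export
labelByPeakOverlap <- function(motifs, peaks, minOverlap = 1L) {
  countOverlaps(motifs, peaks, minoverlap = minOverlap,
                ignore.strand = TRUE) > 0L
}

#' Area under the ROC curve
#'
#' Rank-statistic formulation: the probability that a uniformly chosen
#' positive outranks a uniformly chosen negative, with ties counted one
#' half. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical (or 0/1) truth labels.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC AUC is undefined without both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve
#'
#' Step-curve (no interpolation) convention: thresholds sweep the
#' distinct score values from high to low; the area is the sum over
#' operating points of precision times the recall increment. With all
#' scores tied this reduces to the class prevalence.
#'
#' @inheritParams rocAUC
#' @return PR AUC in \[0, 1\].
#' @export
prAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  if (nPos == 0L) stop("PR AUC is undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  ## operating points only at the last index of each tied score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / nPos
  dRecall <- diff(c(0, recall))
  sum(precision * dRecall)
}

#' Summarize a signal within posterior-probability bins
#'
#' Groups motifs by predicted binding probability and summarizes an
#' independent binding signal (e.g. ChIP read density in the 400 nt
#' around each motif) per bin: count and quartiles. Used to check that
#' predicted probabilities track measured binding levels.
#'
#' @param posterior Numeric posterior binding probabilities in \[0, 1\].
#' @param signal Numeric per-motif signal, same length.
#' @param edges Increasing bin edges covering \[0, 1\] (first must be 0,
#'   last 1).
#' @return `data.frame` with one row per bin: `bin`, `lower`, `upper`,
#'   `count`, `q1`, `median`, `q3` (quartiles `NA` for empty bins).
#' @export
posteriorBinSummary <- function(posterior, signal,
                                edges = seq(0, 1, by = 0.2)) {
  stopifnot(length(posterior) == length(signal))
  if (edges[1] != 0 || edges[length(edges)] != 1 || is.unsorted(edges))
    stop("bin edges must increase from 0 to 1")
  bin <- cut(posterior, breaks = edges, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin),
                    lower = edges[-length(edges)],
                    upper = edges[-1],
                    count = as.integer(table(bin)))
  qs <- t(vapply(levels(bin), function(b) {
    x <- signal[!is.na(bin) & bin == b]
    if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
    unname(quantile(x, c(0.25, 0.5, 0.75)))
  }, numeric(3)))
  out$q1 <- qs[, 1]; out$median <- qs[, 2]; out$q3 <- qs[, 3]
  rownames(out) <- NULL
  out
}
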