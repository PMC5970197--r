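#' @importFrom SummarizedExperiment assay colData rowData
#' @importFrom stats kmeans cor sd
NULL

## Fold changes are replicate-paired: replicate r at time t is compared
## to replicate r at time 0. This keeps the two replicate fold-change
## columns of a time point independent under the null (no shared
## baseline noise), which is what the per-column permutation scheme of
## the FDR estimator assumes.

#' Per-replicate fold changes versus baseline
#'
#' For every gene, the linear-scale fold change of each non-baseline
#' sample relative to the same replicate's baseline (t = 0) sample.
#' Genes with a zero baseline in either replicate get `NA` fold changes
#' (they are excluded from selection, with a warning there).
#'
#' @param se Expression `SummarizedExperiment` (see [readExpression()]).
#' @return Numeric matrix, genes x non-baseline samples, with the
#'   sample `time` and `replicate` kept as attributes.
#' @export
foldChangeMatrix <- function(se) {
  m <- assay(se, "abundance")
  time <- colData(se)$time
  repl <- colData(se)$replicate
  keep <- which(time != 0)
  fc <- vapply(keep, function(j) {
    base <- m[, time == 0 & repl == repl[j]]
    out <- m[, j] / base
    out[base == 0] <- NA_real_
    out
  }, numeric(nrow(m)))
  rownames(fc) <- rownames(m)
  attr(fc, "time") <- time[keep]
  attr(fc, "replicate") <- repl[keep]
  fc
}

## selection counts on a fold-change matrix; direction: "both", "up"
.selectFromFC <- function(fc, foldCutoff, direction = "both") {
  time <- attr(fc, "time")
  sel <- rep(FALSE, nrow(fc))
  for (t in unique(time)) {
    cols <- which(time == t)
    up <- fc[, cols[1]] > foldCutoff & fc[, cols[2]] > foldCutoff
    sel <- sel | (up %in% TRUE)
    if (direction == "both") {
      dn <- fc[, cols[1]] < 1 / foldCutoff & fc[, cols[2]] < 1 / foldCutoff
      sel <- sel | (dn %in% TRUE)
    }
  }
  sel
}

#' Select differentially expressed genes
#'
#' A gene is selected when, at one or more non-baseline time points, both
#' biological replicates change more than `foldCutoff`-fold relative to
#' their own baseline samples, in the same direction. Only genes flagged as
#' expressed are eligible; genes with zero baseline abundance are
#' excluded with a warning.
#'
#' @param se Expression `SummarizedExperiment`.
#' @param foldCutoff Linear fold-change cutoff (default 1.5).
#' @return `data.frame` with columns `gene`, `expressed`, `maxFold` (the
#'   replicate-consistent fold change of largest magnitude, < 1 for
#'   down-regulation) and `selected`.
#' @export
selectDEGenes <- function(se, foldCutoff = 1.5) {
  fc <- foldChangeMatrix(se)
  expressed <- rowData(se)$expressed
  zero <- rowSums(is.na(fc)) > 0
  if (any(zero & expressed))
    warning(sum(zero & expressed),
            " expressed gene(s) with zero baseline abundance excluded")
  time <- attr(fc, "time")
  maxFold <- rep(1, nrow(fc))
  selected <- rep(FALSE, nrow(fc))
  for (t in unique(time)) {
    cols <- which(time == t)
    f1 <- fc[, cols[1]]; f2 <- fc[, cols[2]]
    up <- (f1 > foldCutoff & f2 > foldCutoff) %in% TRUE
    dn <- (f1 < 1 / foldCutoff & f2 < 1 / foldCutoff) %in% TRUE
    consFold <- ifelse(up, pmin(f1, f2), ifelse(dn, pmax(f1, f2), 1))
    better <- abs(log(consFold)) > abs(log(maxFold))
    maxFold[better & (up | dn)] <- consFold[better & (up | dn)]
    selected <- selected | up | dn
  }
  selected <- selected & expressed & !zero
  data.frame(gene = rownames(fc), expressed = expressed,
             maxFold = maxFold, selected = selected,
             row.names = NULL)
}

#' Permutation-based FDR for the fold-change selection rule
#'
#' Randomizes the fold-change values across genes, independently for the
#' two replicates: each replicate's whole fold-change trajectory (its
#' values at every time point) is reassigned to a random gene. This
#' destroys the replicate consistency that the selection rule tests
#' while preserving each replicate's own across-time dependence (time
#' points share a baseline sample, so a gene's fold changes are
#' correlated over time even under the null). The selection rule is
#' re-applied to each randomized matrix and the false discovery rate is
#' estimated as the mean permuted selection count divided by the
#' observed count.
#'
#' @param se Expression `SummarizedExperiment`.
#' @param foldCutoff Linear fold-change cutoff (default 1.5).
#' @param nPerm Number of randomizations (the study-scale default is
#'   1e5; smaller values reproduce the estimate within Monte-Carlo
#'   error).
#' @param seed Integer seed.
#' @return List with `fdr` (`NA` when nothing is selected), `observed`
#'   selection count, `permMean`, and `nPerm`.
#' @export
permutationFDR <- function(se, foldCutoff = 1.5, nPerm = 100000L,
                           seed = 1L) {
  fc <- foldChangeMatrix(se)
  time <- attr(fc, "time")
  repl <- attr(fc, "replicate")
  expressed <- rowData(se)$expressed
  ok <- expressed & rowSums(is.na(fc)) == 0
  fc <- fc[ok, , drop = FALSE]
  attr(fc, "time") <- time
  attr(fc, "replicate") <- repl
  observed <- sum(.selectFromFC(fc, foldCutoff))
  set.seed(seed)
  g <- nrow(fc)
  r1 <- which(repl == repl[1])
  r2 <- which(repl != repl[1])
  permCounts <- vapply(seq_len(nPerm), function(i) {
    p <- fc
    p[, r1] <- fc[sample.int(g), r1]
    p[, r2] <- fc[sample.int(g), r2]
    attr(p, "time") <- attr(fc, "time")
    sum(.selectFromFC(p, foldCutoff))
  }, numeric(1))
  list(fdr = if (observed == 0) NA_real_ else mean(permCounts) / observed,
       observed = observed, permMean = mean(permCounts), nPerm = nPerm)
}

#' Cluster differentially expressed genes by trajectory
#'
#' Per-gene time profiles (replicate means on the log2 scale) are
#' mean-normalized and standardized, then partitioned with K-means
#' (`nstart` restarts, best inertia kept). Reports, per cluster, the
#' median pairwise Pearson correlation of member profiles as a coherence
#' check (the working threshold for "coherent" is 0.7).
#'
#' @param se Expression `SummarizedExperiment`.
#' @param genes Character vector of selected gene ids (e.g.
#'   `selected` genes from [selectDEGenes()]).
#' @param k Number of clusters (default 4).
#' @param nstart K-means restarts (default 50).
#' @param seed Integer seed.
#' @return List with `cluster` (named integer vector), `coherence`
#'   (median within-cluster pairwise correlation per cluster),
#'   `centers`, and `profiles` (the standardized matrix).
#' @export
clusterDEGenes <- function(se, genes, k = 4L, nstart = 50L, seed = 1L) {
  if (length(genes) < k)
    stop("need at least k = ", k, " selected genes to cluster")
  m <- assay(se, "abundance")[genes, , drop = FALSE]
  time <- colData(se)$time
  times <- sort(unique(time))
  prof <- vapply(times, function(t)
    rowMeans(log2(m[, time == t, drop = FALSE] + 1)), numeric(length(genes)))
  prof <- prof - rowMeans(prof)
  s <- apply(prof, 1, sd)
  s[s == 0] <- 1
  prof <- prof / s
  colnames(prof) <- paste0("t", times)
  set.seed(seed)
  km <- kmeans(prof, centers = k, nstart = nstart, iter.max = 100L)
  coher <- vapply(seq_len(k), function(cl) {
    x <- prof[km$cluster == cl, , drop = FALSE]
    if (nrow(x) < 2L) return(NA_real_)
    cc <- cor(t(x))
    stats::median(cc[upper.tri(cc)])
  }, numeric(1))
  list(cluster = km$cluster, coherence = coher, centers = km$centers,
       profiles = prof)
}

#' Flag up-regulated genes
#'
#' Same replicate-consistency rule as [selectDEGenes()], restricted to
#' up-regulation: both replicates above `fold` versus their baseline
#' samples at one or more time points.
#'
#' @param se Expression `SummarizedExperiment`.
#' @param fold Linear fold-change cutoff (default 1.5).
#' @return Named logical vector, one flag per gene.
#' @export
callUpregulatedFactors <- function(se, fold = 1.5) {
  fc <- foldChangeMatrix(se)
  up <- .selectFromFC(fc, fold, direction = "up")
  up <- up & rowData(se)$expressed & rowSums(is.na(fc)) == 0
  names(up) <- rownames(fc)
  up
}

#' Consistent transcriptional response across knockdowns
#'
#' Fraction of genes responding in the same direction, beyond a
#' magnitude threshold, in every condition (e.g. every factor
#' knockdown), compared to a null obtained by independently permuting
#' each condition's column.
#'
#' @param lfc Numeric matrix of log2 fold changes, genes x conditions
#'   (>= 2 conditions).
#' @param threshold Magnitude threshold on |log2 FC| (default 1, i.e.
#'   2-fold).
#' @param nRandom Number of column randomizations.
#' @param seed Integer seed.
#' @return List with `observed` (named fractions `up`, `down`),
#'   `backgroundMean`, `backgroundSd` (same names), and the per-run
#'   `background` matrix.
#' @export
consistentResponseFraction <- function(lfc, threshold = 1,
                                       nRandom = 1000L, seed = 1L) {
  lfc <- as.matrix(lfc)
  if (ncol(lfc) < 2L) stop("need at least 2 conditions")
  frac <- function(m) c(up = mean(rowSums(m >= threshold) == ncol(m)),
                        down = mean(rowSums(m <= -threshold) == ncol(m)))
  observed <- frac(lfc)
  set.seed(seed)
  g <- nrow(lfc)
  background <- t(vapply(seq_len(nRandom), function(i)
    frac(apply(lfc, 2, function(col) col[sample.int(g)])), numeric(2)))
  list(observed = observed,
       backgroundMean = colMeans(background),
       backgroundSd = apply(background, 2, sd),
       background = background)
}
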