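## Independent brute-force oracles used to pin down expected values.
## These deliberately avoid the package's own code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## Rand index between two partitions
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    same_a <- a[i] == a[(i + 1):n]
    same_b <- b[i] == b[(i + 1):n]
    agree <- agree + sum(same_a == same_b)
  }
  agree / choose(n, 2)
}

## exhaustive per-position window tag count for one motif
bruteWindowCount <- function(tagChrom, tagPos, motifChrom, motifStart,
                             motifEnd, window = 200L) {
  inWin <- function(a, b) sum(tagChrom == motifChrom &
                              tagPos >= max(a, 1L) & tagPos <= b)
  up <- inWin(motifStart - window, motifStart - 1L)
  down <- inWin(motifEnd + 1L, motifEnd + window)
  min(up, down)
}

## ROC AUC by exhaustive positive/negative pair enumeration
rocByEnumeration <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## PR AUC by manual threshold-by-threshold sweep (step curve)
prByThresholdSweep <- function(scores, labels) {
  labels <- as.logical(labels)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prevRecall <- 0
  for (th in thresholds) {
    called <- scores >= th
    tp <- sum(called & labels)
    precision <- tp / sum(called)
    recall <- tp / sum(labels)
    area <- area + precision * (recall - prevRecall)
    prevRecall <- recall
  }
  area
}

## one-sided (enrichment) Fisher p by hypergeometric tail enumeration:
## P(X >= a) where X ~ Hypergeom(m = a + c, n = b + d, k = a + b)
hyperTailEnumeration <- function(a, b, c, d) {
  k <- a + b
  xs <- a:min(k, a + c)
  sum(vapply(xs, function(x)
    choose(a + c, x) * choose(b + d, k - x) / choose(a + b + c + d, k),
    numeric(1)))
}

## tiny deterministic tag track builder
makeTrack <- function(pos, chrom = "chr1") tagTrack(chrom, pos)
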