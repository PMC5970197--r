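#' @importFrom GenomicRanges countOverlaps findOverlaps pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Normalize a raw motif match score
#'
#' Maps the raw FIMO log-likelihood-ratio score onto \[0, 1\] as
#' `f = (score - 10) / 10`, clamped into \[0, 1\]: raw scores below 10
#' or above 20 occur in practice while the model's feature range is the
#' unit interval.
#'
#' @param fimoScore Numeric vector of raw match scores.
#' @return Numeric vector `f` in \[0, 1\].
#' @examples
#' normalizePwmScore(c(10, 15, 20, 25))
#' @export
normalizePwmScore <- function(fimoScore) {
  stopifnot(all(is.finite(fimoScore)))
  pmin(1, pmax(0, (fimoScore - 10) / 10))
}

#' Normalize distance to the nearest TSS
#'
#' `d = 1 / (1 + dist / 1000)`: 1 at the TSS itself, 0.5 at 1 kb,
#' decreasing monotonically with distance.
#'
#' @param tssDistance Non-negative distances in bp.
#' @return Numeric vector `d` in (0, 1\].
#' @examples
#' normalizeTssDistance(c(0, 1000, 9000))
#' @export
normalizeTssDistance <- function(tssDistance) {
  if (any(tssDistance < 0)) stop("TSS distances must be non-negative")
  1 / (1 + tssDistance / 1000)
}

#' Mean conservation over intervals
#'
#' Arithmetic mean of the per-base conservation score across each query
#' interval; bases not covered by the track take its default value.
#'
#' @param track A [ConservationTrack-class].
#' @param intervals `GRanges` of query intervals (e.g. motif matches).
#' @return Numeric vector of per-interval means in \[0, 1\].
#' @export
meanConservation <- function(track, intervals) {
  cov <- track@cov
  res <- rep(track@default, length(intervals))
  if (length(cov) == 0L || length(intervals) == 0L) return(res)
  hits <- findOverlaps(intervals, cov, ignore.strand = TRUE)
  if (length(hits) == 0L) return(res)
  ov <- pintersect(intervals[queryHits(hits)], cov[subjectHits(hits)],
                   ignore.strand = TRUE)
  contrib <- width(ov) * cov$score[subjectHits(hits)]
  covered <- tapply(width(ov), queryHits(hits), sum)
  weighted <- tapply(contrib, queryHits(hits), sum)
  idx <- as.integer(names(covered))
  w <- width(intervals)[idx]
  res[idx] <- (weighted + (w - covered) * track@default) / w
  res
}

## tags in [a, b] (1-based closed) per query, via cumulative counts on the
## sorted per-chromosome tag table
.countTagsInRange <- function(track, chrom, a, b) {
  t <- track@tags
  res <- integer(length(chrom))
  if (nrow(t) == 0L) return(res)
  a <- pmax(a, 1L)
  for (ch in unique(chrom)) {
    sel <- t$chrom == ch
    if (!any(sel)) next
    pos <- t$pos[sel]
    csum <- cumsum(t$count[sel])
    q <- which(chrom == ch)
    hi <- findInterval(b[q], pos)
    lo <- findInterval(a[q] - 1L, pos)
    res[q] <- ifelse(hi > 0L, csum[pmax(hi, 1L)], 0L) -
              ifelse(lo > 0L, csum[pmax(lo, 1L)], 0L)
  }
  as.integer(res)
}

#' Flanking-window tag count for motifs
#'
#' Counts tags in the `window` bp immediately upstream of the motif start
#' and immediately downstream of the motif end (on the reference strand;
#' motif strand is ignored) and returns the smaller of the two. Motifs at
#' the edge or centre of an accessible region are thereby distinguished:
#' only motifs with tags on both sides score high. Windows running past
#' the chromosome start are truncated at position 1.
#'
#' @param track A [TagTrack-class].
#' @param motifs `GRanges` of motif matches.
#' @param window Flank size in bp (default 200).
#' @return Integer vector `n`, one count per motif.
#' @export
windowTagCount <- function(track, motifs, window = 200L) {
  stopifnot(window > 0)
  ch <- as.character(seqnames(motifs))
  up <- .countTagsInRange(track, ch, start(motifs) - window,
                          start(motifs) - 1L)
  down <- .countTagsInRange(track, ch, end(motifs) + 1L,
                            end(motifs) + window)
  pmin(up, down)
}

#' Library-normalized flanking read density
#'
#' Sum of tags in the upstream and downstream `window` bp flanks, scaled
#' to reads per million by the track's library size. This is the
#' accessibility statistic used when comparing time points.
#'
#' @inheritParams windowTagCount
#' @return Numeric vector of RPM values.
#' @export
rpmWindowCount <- function(track, motifs, window = 200L) {
  stopifnot(window > 0)
  if (librarySize(track) <= 0) stop("tag track has zero library size")
  ch <- as.character(seqnames(motifs))
  up <- .countTagsInRange(track, ch, start(motifs) - window,
                          start(motifs) - 1L)
  down <- .countTagsInRange(track, ch, end(motifs) + 1L,
                            end(motifs) + window)
  (up + down) / librarySize(track) * 1e6
}

## distance (bp) from each motif midpoint to the nearest TSS position
.nearestTssDistance <- function(motifs, tss) {
  if (length(tss) == 0L) stop("TSS table is empty")
  mid <- as.integer(floor((start(motifs) + end(motifs)) / 2))
  ch <- as.character(seqnames(motifs))
  tch <- as.character(seqnames(tss))
  res <- rep(NA_real_, length(motifs))
  for (c_ in unique(ch)) {
    pos <- sort(start(tss)[tch == c_])
    q <- which(ch == c_)
    if (!length(pos)) next
    i <- findInterval(mid[q], pos)
    dl <- ifelse(i >= 1L, mid[q] - pos[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(pos), pos[pmin(i + 1L, length(pos))] - mid[q], Inf)
    res[q] <- pmin(dl, dr)
  }
  if (anyNA(res))
    stop("no TSS on chromosome(s): ",
         paste(unique(ch[is.na(res)]), collapse = ", "))
  res
}

#' Extract the four model features for every motif
#'
#' Computes, per motif match: the normalized PWM score `f`, the
#' TSS-proximity feature `d` (distance from the motif midpoint to the
#' nearest TSS over all annotated genes), the mean conservation `c`, and
#' the flanking-window tag count `n`.
#'
#' @param motifs `GRanges` with `pwm_id` and `fimo_score` columns.
#' @param tagTrack A [TagTrack-class] of DNase-seq tags.
#' @param conservation A [ConservationTrack-class].
#' @param tss Width-1 `GRanges` TSS annotation (from [readTSS()]).
#' @param window Flank size in bp for the tag count.
#' @return The input `GRanges` with added metadata columns
#'   `tss_distance`, `f`, `d`, `c`, `n`.
#' @export
extractFeatures <- function(motifs, tagTrack, conservation, tss,
                            window = 200L) {
  dist <- .nearestTssDistance(motifs, tss)
  mcols(motifs)$tss_distance <- dist
  mcols(motifs)$f <- normalizePwmScore(motifs$fimo_score)
  mcols(motifs)$d <- normalizeTssDistance(dist)
  mcols(motifs)$c <- meanConservation(conservation, motifs)
  mcols(motifs)$n <- windowTagCount(tagTrack, motifs, window = window)
  motifs
}

#' Classify open-chromatin regions by histone modifications
#'
#' Assigns each region exactly one category by the standard precedence:
#' H3K27ac together with H3K4me3 marks an active promoter; H3K27ac
#' without H3K4me3 an active enhancer; H3K4me1 without either acetylation
#' mark a primed enhancer; H3K9me3 or H3K27me3 (absent all of the above)
#' heterochromatin/polycomb; anything unmarked is "other".
#'
#' @param regions `GRanges` of open-chromatin regions.
#' @param K4me3,K27ac,K4me1,K27me3,K9me3 `GRanges` peak sets for the five
#'   marks.
#' @return Factor of categories, one per region, with levels
#'   `active_promoter`, `active_enhancer`, `primed_enhancer`,
#'   `heterochromatin_polycomb`, `other`.
#' @export
classifyRegions <- function(regions, K4me3, K27ac, K4me1, K27me3, K9me3) {
  has <- function(peaks) countOverlaps(regions, peaks,
                                       ignore.strand = TRUE) > 0L
  h4me3 <- has(K4me3); h27ac <- has(K27ac); h4me1 <- has(K4me1)
  hrep <- has(K27me3) | has(K9me3)
  cat_ <- rep("other", length(regions))
  cat_[hrep] <- "heterochromatin_polycomb"
  cat_[h4me1 & !h27ac & !h4me3] <- "primed_enhancer"
  cat_[h27ac & !h4me3] <- "active_enhancer"
  cat_[h27ac & h4me3] <- "active_promoter"
  factor(cat_, levels = c("active_promoter", "active_enhancer",
                          "primed_enhancer", "heterochromatin_polycomb",
                          "other"))
}
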