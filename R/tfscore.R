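#' @importFrom stats fisher.test
NULL

#' The default TFScore rubric
#'
#' Bin edges and increments for the four criteria:
#' \describe{
#'   \item{criterion 1 (6 h)}{summed accessibility fold-change statistic;
#'     +0 up to 600, then +1 to 1000, +2 to 1500, +3 to 3000, +4 to
#'     5000, +5 above.}
#'   \item{criterion 1 (24 h)}{the published 24 h bins are internally
#'     inconsistent (the +1 bin overlaps the +2 bin), so the default
#'     keeps the 6 h structure rescaled to the first 24 h bin: +0 up to
#'     2000, then +1 to 4000, +2 to 6000, +3 to 9000, +4 to 15,000, +5
#'     above. Override via this rubric if you prefer other edges.}
#'   \item{criterion 2}{best per-cluster enrichment, binned on
#'     \eqn{-\log_{10} P}: +0 up to 8, +1 to 11, +2 to 14, +3 to 17,
#'     +4 to 20, +5 above.}
#'   \item{criterion 3}{+15 when the factor itself is up-regulated.}
#'   \item{criterion 4}{relative expression within a motif family with
#'     maximum E: +5 at E, +3 in (E/2, E), +0 in (E/4, E/2], -5 in
#'     (E/6, E/4], -10 at or below E/6.}
#' }
#'
#' All bins are half-open, closed on the upper edge (a statistic exactly
#' on an edge takes the lower score).
#'
#' @return A named list of rubric settings.
#' @export
defaultRubric <- function() {
  list(c1_6h_edges = c(600, 1000, 1500, 3000, 5000),
       c1_24h_edges = c(2000, 4000, 6000, 9000, 15000),
       c2_edges = c(8, 11, 14, 17, 20),
       c3_increment = 15,
       c4_scores = c(at_max = 5, above_half = 3, above_quarter = 0,
                     above_sixth = -5, low = -10))
}

## integer score = number of edges strictly exceeded
.binScore <- function(x, edges) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("rubric bin edges must be strictly increasing")
  vapply(x, function(v) sum(v > edges), numeric(1))
}

#' Accessible motifs across time points
#'
#' The union, over time points, of motifs whose posterior binding
#' probability passes the hard-call threshold.
#'
#' @param predictions List (one element per time point) of
#'   `data.frame`s with columns `motif_id` and `gamma`.
#' @param threshold Posterior cutoff (default 0.99).
#' @return Character vector of accessible motif ids.
#' @export
accessibleMotifs <- function(predictions, threshold = 0.99) {
  if (!length(predictions)) stop("need predictions for >= 1 time point")
  ids <- lapply(predictions, function(p)
    p$motif_id[p$gamma >= threshold])
  sort(unique(unlist(ids)))
}

#' Criterion 1: contribution to increased accessibility
#'
#' For one PWM, sums the per-accessible-motif accessibility fold change
#' (RPM at 6 h or 24 h over RPM at 0 h) and maps each time point's sum
#' through its rubric bins to a 0-5 score. Motifs with zero baseline RPM
#' contribute `RPM_t / eps` where `eps` is the RPM of a single read in
#' the baseline library, so newly opened sites are kept rather than
#' dropped.
#'
#' @param rpm0,rpm6,rpm24 Numeric RPM vectors over the PWM's accessible
#'   motifs (equal length; from [rpmWindowCount()] on the matching tag
#'   tracks). Empty vectors give statistic 0 and score 0.
#' @param rubric Rubric list (see [defaultRubric()]).
#' @param librarySize0 Baseline library size used for the zero-baseline
#'   pseudocount (default `1e6`, i.e. `eps = 1` RPM).
#' @return List with `stat6`, `stat24`, `score6`, `score24`.
#' @export
criterion1AccessibilityGain <- function(rpm0, rpm6, rpm24,
                                        rubric = defaultRubric(),
                                        librarySize0 = 1e6) {
  stopifnot(length(rpm0) == length(rpm6), length(rpm0) == length(rpm24))
  if (!length(rpm0))
    return(list(stat6 = 0, stat24 = 0, score6 = 0, score24 = 0))
  eps <- 1e6 / librarySize0
  base <- ifelse(rpm0 > 0, rpm0, eps)
  stat6 <- sum(rpm6 / base)
  stat24 <- sum(rpm24 / base)
  list(stat6 = stat6, stat24 = stat24,
       score6 = .binScore(stat6, rubric$c1_6h_edges),
       score24 = .binScore(stat24, rubric$c1_24h_edges))
}

#' Assign accessible motifs to their nearest expressed gene
#'
#' Each motif is assigned to the expressed gene whose TSS is nearest to
#' the motif midpoint, provided the distance does not exceed
#' `maxDistance` (100 kb by default; 20 kb is the stricter published
#' alternative).
#'
#' @param motifs `GRanges` of accessible motifs.
#' @param tss Width-1 `GRanges` TSS annotation with `gene` and
#'   `expressed` columns.
#' @param maxDistance Maximum motif-TSS distance in bp (default 1e5).
#' @return `data.frame` with one row per motif: `motif_id` (from
#'   `motifs$motif_id`, else the index), `gene` (`NA` when unassigned)
#'   and `distance`.
#' @export
assignMotifsToGenes <- function(motifs, tss, maxDistance = 1e5) {
  tss <- tss[tss$expressed]
  if (!length(tss)) stop("no expressed genes in the TSS table")
  mid <- as.integer(floor((start(motifs) + end(motifs)) / 2))
  ch <- as.character(seqnames(motifs))
  tch <- as.character(seqnames(tss))
  gene <- rep(NA_character_, length(motifs))
  dist <- rep(NA_real_, length(motifs))
  for (c_ in unique(ch)) {
    sel <- which(tch == c_)
    q <- which(ch == c_)
    if (!length(sel)) next
    ord <- sel[order(start(tss)[sel])]
    pos <- start(tss)[ord]
    i <- findInterval(mid[q], pos)
    dl <- ifelse(i >= 1L, mid[q] - pos[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(pos), pos[pmin(i + 1L, length(pos))] - mid[q],
                 Inf)
    pick <- ifelse(dl <= dr, pmax(i, 1L), pmin(i + 1L, length(pos)))
    gene[q] <- tss$gene[ord][pick]
    dist[q] <- pmin(dl, dr)
  }
  gene[!is.finite(dist) | dist > maxDistance] <- NA_character_
  ids <- if (!is.null(motifs$motif_id)) motifs$motif_id
         else as.character(seq_along(motifs))
  data.frame(motif_id = ids, gene = gene, distance = dist,
             row.names = NULL)
}

#' Criterion 2: motif enrichment in DE gene clusters
#'
#' For each differential-expression cluster, a one-sided Fisher exact
#' test compares the fraction of cluster genes carrying an assigned
#' accessible motif of this PWM against expressed genes with no
#' differential expression. The criterion score is the rubric bin of the
#' best (largest) \eqn{-\log_{10} P} across clusters.
#'
#' For a precomputed enrichment, pass `neglog10p` directly and omit the
#' gene sets.
#'
#' @param motifGenes Character vector of genes carrying >= 1 assigned
#'   accessible motif of the PWM.
#' @param clusters Named integer vector: cluster id per DE gene.
#' @param backgroundGenes Character vector of expressed, non-DE genes.
#' @param rubric Rubric list.
#' @param neglog10p Optional precomputed best \eqn{-\log_{10} P}; when
#'   given, only the binning is performed.
#' @return List with `tests` (per-cluster counts and p-values; `NULL`
#'   when precomputed), `best` (best \eqn{-\log_{10} P}) and `score`.
#' @export
criterion2ClusterEnrichment <- function(motifGenes = NULL, clusters = NULL,
                                        backgroundGenes = NULL,
                                        rubric = defaultRubric(),
                                        neglog10p = NULL) {
  if (!is.null(neglog10p)) {
    return(list(tests = NULL, best = neglog10p,
                score = .binScore(neglog10p, rubric$c2_edges)))
  }
  stopifnot(!is.null(motifGenes) || length(clusters),
            !is.null(clusters), !is.null(backgroundGenes))
  bgWith <- sum(backgroundGenes %in% motifGenes)
  bgWithout <- length(backgroundGenes) - bgWith
  rows <- lapply(sort(unique(clusters)), function(cl) {
    genes <- names(clusters)[clusters == cl]
    if (!length(genes)) return(NULL)
    a <- sum(genes %in% motifGenes)
    b <- length(genes) - a
    p <- fisher.test(matrix(c(a, b, bgWith, bgWithout), nrow = 2),
                     alternative = "greater")$p.value
    data.frame(cluster = cl, cluster_with = a, cluster_without = b,
               background_with = bgWith, background_without = bgWithout,
               p = p, neglog10p = -log10(p))
  })
  tests <- do.call(rbind, rows)
  if (is.null(tests) || !nrow(tests))
    return(list(tests = tests, best = 0, score = 0))
  best <- max(tests$neglog10p)
  list(tests = tests, best = best,
       score = .binScore(best, rubric$c2_edges))
}

#' Criterion 3: up-regulation of the factor itself
#'
#' @param gene Factor gene id.
#' @param upFlags Named logical vector from [callUpregulatedFactors()].
#' @param rubric Rubric list.
#' @return The increment (15 by default) if the factor is flagged
#'   up-regulated, otherwise 0. A factor absent from the flags scores 0
#'   with a warning.
#' @export
criterion3Upregulation <- function(gene, upFlags,
                                   rubric = defaultRubric()) {
  if (!gene %in% names(upFlags)) {
    warning("factor '", gene, "' absent from the expression matrix; ",
            "criterion 3 scored 0")
    return(0)
  }
  if (isTRUE(upFlags[[gene]])) rubric$c3_increment else 0
}

#' Criterion 4: relative expression within a motif family
#'
#' Members of a factor family sharing a binding motif are scored by
#' their expression relative to the family maximum E: +5 at E, +3 in
#' (E/2, E), +0 in (E/4, E/2], -5 in (E/6, E/4], -10 at or below E/6.
#' Ties at the maximum all score +5. An all-zero family scores every
#' member -10, with a warning.
#'
#' @param expression Named numeric vector of member expression levels
#'   (>= 0).
#' @param rubric Rubric list.
#' @return Named numeric vector of member scores.
#' @export
criterion4FamilyExpression <- function(expression,
                                       rubric = defaultRubric()) {
  stopifnot(length(expression) >= 1L, all(expression >= 0))
  s <- rubric$c4_scores
  E <- max(expression)
  if (E == 0) {
    warning("all family members have zero expression; all scored ",
            s[["low"]])
    out <- rep(s[["low"]], length(expression))
    names(out) <- names(expression)
    return(out)
  }
  out <- ifelse(expression >= E, s[["at_max"]],
         ifelse(expression > E / 2, s[["above_half"]],
         ifelse(expression > E / 4, s[["above_quarter"]],
         ifelse(expression > E / 6, s[["above_sixth"]], s[["low"]]))))
  names(out) <- names(expression)
  out
}

#' Total TFScore and rank order
#'
#' Sums the component scores per (PWM, factor), sorts by descending
#' total with ties broken alphabetically by factor gene, and assigns
#' ranks (1 = best).
#'
#' @param components `data.frame` with columns `pwm`, `gene`, `c1_6h`,
#'   `c1_24h`, `c2`, `c3`, `c4`.
#' @return The table with added `total` and `rank`, ordered by rank.
#' @export
totalTFScore <- function(components) {
  need <- c("pwm", "gene", "c1_6h", "c1_24h", "c2", "c3", "c4")
  if (!all(need %in% names(components)))
    stop("components must have columns: ", paste(need, collapse = ", "))
  tab <- as.data.frame(components)
  tab$total <- tab$c1_6h + tab$c1_24h + tab$c2 + tab$c3 + tab$c4
  tab <- tab[order(-tab$total, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
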