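#' @importFrom rtracklayer import export
#' @importFrom utils read.delim write.table head tail
#' @importFrom IRanges isDisjoint
#' @importFrom GenomicRanges sort.GenomicRanges
NULL

## All genomic containers in this package follow the Bioconductor
## convention: GRanges, 1-based, closed intervals. BED input (0-based
## half-open) and FIMO input (1-based inclusive) are normalized on read.

#' Read a motif-match table
#'
#' Reads motif matches either in FIMO tab-separated form (columns
#' `motif_id`, `sequence_name`, `start`, `stop`, `strand`, `score`;
#' 1-based inclusive coordinates) or as a BED6 file (0-based half-open;
#' the name column carries the PWM id, the score column the raw match
#' score).
#'
#' @param path Path to the file.
#' @param dialect `"fimo"` or `"bed"`.
#' @return A `GRanges` with metadata columns `pwm_id` and `fimo_score`.
#' @export
readMotifTable <- function(path, dialect = c("fimo", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed") {
    gr <- import(path, format = "BED")
    mcols(gr) <- DataFrame(pwm_id = as.character(gr$name),
                           fimo_score = as.numeric(gr$score))
    return(sort(gr, ignore.strand = TRUE))
  }
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("motif_id", "sequence_name", "start", "stop", "strand", "score")
  if (!all(need %in% names(tab)))
    stop("FIMO table must have columns: ", paste(need, collapse = ", "))
  start <- suppressWarnings(as.numeric(tab$start))
  stop_ <- suppressWarnings(as.numeric(tab$stop))
  score <- suppressWarnings(as.numeric(tab$score))
  bad <- which(!is.finite(start) | !is.finite(stop_) | !is.finite(score))
  if (length(bad))
    stop("malformed FIMO record at line ", bad[1] + 1L,
         " (non-numeric start/stop/score)")
  bad <- which(start > stop_)
  if (length(bad))
    stop("coordinate error at line ", bad[1] + 1L,
         ": start > stop after normalization")
  gr <- GRanges(tab$sequence_name,
                IRanges(as.integer(start), as.integer(stop_)),
                strand = ifelse(tab$strand %in% c("+", "-"), tab$strand, "*"))
  mcols(gr) <- DataFrame(pwm_id = as.character(tab$motif_id),
                         fimo_score = score)
  sort(gr, ignore.strand = TRUE)
}

#' Write motif matches
#'
#' `writeMotifTable()` emits the FIMO-style TSV dialect accepted by
#' [readMotifTable()]; `writeMotifBed()` emits BED6. Both sort by
#' coordinate so output is deterministic.
#'
#' @param motifs `GRanges` with `pwm_id` and `fimo_score` columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeMotifTable <- function(motifs, path) {
  motifs <- sort(motifs, ignore.strand = TRUE)
  tab <- data.frame(
    motif_id = motifs$pwm_id,
    sequence_name = as.character(seqnames(motifs)),
    start = start(motifs), stop = end(motifs),
    strand = ifelse(as.character(strand(motifs)) == "*", ".",
                    as.character(strand(motifs))),
    score = motifs$fimo_score)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotifTable
#' @export
writeMotifBed <- function(motifs, path) {
  motifs <- sort(motifs, ignore.strand = TRUE)
  tab <- data.frame(
    chrom = as.character(seqnames(motifs)),
    start = start(motifs) - 1L, end = end(motifs),
    name = motifs$pwm_id, score = motifs$fimo_score,
    strand = ifelse(as.character(strand(motifs)) == "*", ".",
                    as.character(strand(motifs))))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a tag track from positions
#'
#' @param chrom Character vector of chromosome names (recycled).
#' @param pos Integer vector of 1-based tag positions (5' ends).
#' @return A [TagTrack-class].
#' @export
tagTrack <- function(chrom, pos) {
  if (length(pos) == 0L) {
    return(new("TagTrack",
               tags = data.frame(chrom = character(), pos = integer(),
                                 count = integer()),
               librarySize = 0))
  }
  chrom <- rep_len(as.character(chrom), length(pos))
  agg <- stats::aggregate(list(count = rep(1L, length(pos))),
                          by = list(chrom = chrom, pos = as.integer(pos)),
                          FUN = sum)
  agg <- agg[order(agg$chrom, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  new("TagTrack", tags = agg, librarySize = sum(agg$count))
}

#' Read sequencing tags from BED
#'
#' Each BED record is one tag; its counted position is the 5' end of the
#' read (the BED start for `+`/unstranded records, the BED end for `-`).
#' Tag strand plays no further role in window counting.
#'
#' @param path BED3/BED6 file (one line per tag; duplicate lines allowed).
#' @return A [TagTrack-class].
#' @export
readTagBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (info$size == 0) return(tagTrack(character(), integer()))
  gr <- import(path, format = "BED")
  if (length(gr) == 0L) return(tagTrack(character(), integer()))
  pos <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  tagTrack(as.character(seqnames(gr)), pos)
}

#' Write a tag track as BED
#'
#' Emits one BED line per tag occurrence (positions expanded by their
#' multiplicity), sorted; round-trips through [readTagBed()].
#'
#' @param track A [TagTrack-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTagBed <- function(track, path) {
  t <- track@tags
  idx <- rep(seq_len(nrow(t)), t$count)
  tab <- data.frame(chrom = t$chrom[idx],
                    start = t$pos[idx] - 1L,
                    end = t$pos[idx])
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-base conservation from bedGraph
#'
#' @param path bedGraph file with scores in \[0, 1\].
#' @param default Score for bases not covered by any interval.
#' @return A [ConservationTrack-class].
#' @export
readBedGraph <- function(path, default = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- if (file.info(path)$size == 0) GRanges(score = numeric())
        else import(path, format = "bedGraph")
  if (length(gr) > 1L && !isDisjoint(gr))
    stop("overlapping bedGraph intervals are not allowed")
  new("ConservationTrack", cov = sort(gr), default = default)
}

#' Write a conservation track as bedGraph
#'
#' @param track A [ConservationTrack-class] (or `GRanges` with a `score`
#'   column).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(track, path) {
  gr <- if (is(track, "ConservationTrack")) track@cov else track
  gr <- sort(gr)
  tab <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    score = format(gr$score, digits = 10, trim = TRUE,
                                   scientific = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peak set
#'
#' Accepts BED3/BED6 or narrowPeak; columns beyond the interval (and
#' name/score/strand) are ignored.
#'
#' @param path Peak file.
#' @return A `GRanges` of peak intervals.
#' @export
readPeaks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.info(path)$size == 0) return(GRanges())
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  gr <- if (length(first) == 10L) {
    import(path, format = "BED",
           extraCols = c(signalValue = "numeric", pValue = "numeric",
                         qValue = "numeric", peak = "integer"))
  } else {
    import(path, format = "BED")
  }
  gr <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)))
  sort(gr)
}

#' Write a peak set as BED3
#'
#' @param peaks `GRanges`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePeaks <- function(peaks, path) {
  peaks <- sort(peaks)
  tab <- data.frame(chrom = as.character(seqnames(peaks)),
                    start = start(peaks) - 1L, end = end(peaks))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Tab-separated with header `gene`, `chrom`, `tss` (1-based position),
#' `strand`, `expressed` (TRUE/FALSE). Duplicate (gene, tss) rows are an
#' error.
#'
#' @param path TSV path.
#' @return Width-1 `GRanges` with metadata columns `gene` and `expressed`.
#' @export
readTSS <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand", "expressed")
  if (!all(need %in% names(tab)))
    stop("TSS table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[c("gene", "tss")]))
    stop("duplicate (gene, tss) rows in TSS table")
  gr <- GRanges(tab$chrom, IRanges(tab$tss, width = 1L),
                strand = ifelse(tab$strand %in% c("+", "-"), tab$strand, "*"))
  mcols(gr) <- DataFrame(gene = as.character(tab$gene),
                         expressed = as.logical(tab$expressed))
  sort(gr, ignore.strand = TRUE)
}

#' Write a TSS annotation table
#'
#' @param tss Width-1 `GRanges` with `gene` and `expressed` columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTSS <- function(tss, path) {
  tss <- sort(tss, ignore.strand = TRUE)
  tab <- data.frame(gene = tss$gene,
                    chrom = as.character(seqnames(tss)),
                    tss = start(tss),
                    strand = ifelse(as.character(strand(tss)) == "*", ".",
                                    as.character(strand(tss))),
                    expressed = tss$expressed)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression time-course matrix
#'
#' Tab-separated with a `gene` column, sample columns named
#' `t{hours}_rep{1,2}` (exactly two replicates per time point) and an
#' optional logical `expressed` column (defaults to all `TRUE`).
#'
#' @param path TSV path.
#' @return A `SummarizedExperiment` with assay `abundance`, `colData`
#'   columns `time` and `replicate`, and `rowData` column `expressed`.
#' @export
readExpression <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(tab)) stop("expression table needs a 'gene' column")
  samp <- grep("^t[0-9.]+_rep[0-9]+$", names(tab), value = TRUE)
  if (!length(samp)) stop("no sample columns of the form t{hours}_rep{n}")
  time <- as.numeric(sub("^t([0-9.]+)_rep[0-9]+$", "\\1", samp))
  rep_ <- as.integer(sub("^t[0-9.]+_rep([0-9]+)$", "\\1", samp))
  reps <- table(time)
  if (any(reps != 2L))
    stop("schema error: each time point needs exactly 2 replicate columns; ",
         "offending time(s): ",
         paste(names(reps)[reps != 2L], collapse = ", "))
  m <- as.matrix(tab[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  rownames(m) <- tab$gene
  expressed <- if ("expressed" %in% names(tab)) as.logical(tab$expressed)
               else rep(TRUE, nrow(m))
  ord <- order(time, rep_)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m[, ord, drop = FALSE]),
    colData = DataFrame(time = time[ord], replicate = rep_[ord],
                        row.names = samp[ord]),
    rowData = DataFrame(expressed = expressed))
}

#' Write an expression time-course matrix
#'
#' @param se `SummarizedExperiment` as returned by [readExpression()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeExpression <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "abundance")
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
  tab$expressed <- SummarizedExperiment::rowData(se)$expressed
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-motif posterior predictions
#'
#' Columns `motif_id`, `y` (prior), `gamma` (posterior) and `call`,
#' sorted by motif id for deterministic output.
#'
#' @param predictions `data.frame`-like with those columns.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePredictions <- function(predictions, path) {
  tab <- as.data.frame(predictions)[c("motif_id", "y", "gamma", "call")]
  tab <- tab[order(tab$motif_id), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a posterior prediction table
#'
#' @param path TSV written by [writePredictions()].
#' @return A `data.frame` with columns `motif_id`, `y`, `gamma`, `call`.
#' @export
readPredictions <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("motif_id", "y", "gamma", "call")
  if (!all(need %in% names(tab)))
    stop("prediction table must have columns: ", paste(need, collapse = ", "))
  tab$call <- as.logical(tab$call)
  tab
}

#' Write a ranked TF score table
#'
#' Fixed column order (`pwm`, `gene`, `c1_6h`, `c1_24h`, `c2`, `c3`,
#' `c4`, `total`, `rank`), sorted by rank.
#'
#' @param scores Ranked table from [totalTFScore()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTFScores <- function(scores, path) {
  cols <- c("pwm", "gene", "c1_6h", "c1_24h", "c2", "c3", "c4",
            "total", "rank")
  tab <- as.data.frame(scores)[cols]
  tab <- tab[order(tab$rank), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
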