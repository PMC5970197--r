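#' @importFrom stats runif rbeta rbinom rnbinom rnorm
NULL

#' Build a simulation scenario
#'
#' Returns a [SimulationScenario-class] describing one synthetic
#' realization of the study design. The defaults reproduce the study
#' conditions the model targets: 20,000 motif matches (a 10,000-motif
#' training sample plus a 10,000-motif held-out sample), bound motifs
#' whose flanking tag counts average ~20x the unbound mean
#' (unbound NB(K=1, r=0.5), mean 1; bound NB(K=5, r=0.8), mean 20),
#' and an eight-point expression time course (0-24 h) with two
#' replicates per time point.
#'
#' Feature sampling: `f ~ U(0, 1)`, `d ~ U(0.05, 1)` (the implied TSS
#' distances then stay below ~19 kb so each simulated motif's own TSS is
#' its nearest), `c ~ Beta(2, 2)`.
#'
#' @param nMotifs Number of motif matches.
#' @param trueParams Generative [AccessTFParams-class].
#' @param fRange,dRange Uniform ranges for `f` and `d`.
#' @param cShape Beta shapes for `c`.
#' @param motifWidth Motif width in bp.
#' @param genomeLength Minimum fixture genome length (bp).
#' @param nGenes,deFraction Expression course size and DE fraction.
#' @param foldChangeRange True linear fold-change range for DE genes.
#' @param replicateNoiseSd Replicate noise SD (log2 scale).
#' @param timePoints Time points in hours (first = baseline 0).
#' @param seed Integer seed.
#' @return A [SimulationScenario-class].
#' @export
simulationScenario <- function(nMotifs = 20000L,
                               trueParams = accessTFParams(
                                 beta0 = -2, beta1 = 1, beta2 = 2,
                                 beta3 = 1, K0 = 1, r0 = 0.5,
                                 K1 = 5, r1 = 0.8),
                               fRange = c(0, 1), dRange = c(0.05, 1),
                               cShape = c(2, 2), motifWidth = 10L,
                               genomeLength = 1e7,
                               nGenes = 2000L, deFraction = 0.1,
                               foldChangeRange = c(2, 4),
                               replicateNoiseSd = 0.1,
                               timePoints = c(0, 1, 2, 4, 8, 12, 16, 24),
                               seed = 1L) {
  new("SimulationScenario",
      nMotifs = as.integer(nMotifs), trueParams = trueParams,
      fRange = fRange, dRange = dRange, cShape = cShape,
      motifWidth = as.integer(motifWidth),
      genomeLength = genomeLength,
      nGenes = as.integer(nGenes), deFraction = deFraction,
      foldChangeRange = foldChangeRange,
      replicateNoiseSd = replicateNoiseSd,
      timePoints = timePoints, seed = as.integer(seed))
}

#' Simulate motif features, binding states and tag counts
#'
#' Draws each motif's features from the scenario's distributions,
#' computes its true prior binding probability from the generative
#' logistic coefficients, samples the hidden binding state
#' `b ~ Bernoulli(y)`, and emits the tag count from the matching
#' negative-binomial component. The TSS-proximity feature is realized
#' through an integer TSS distance (`d = 1 / (1 + dist / 1000)`), so
#' the feature table is exactly reproducible from fixture files.
#'
#' @param scenario A [SimulationScenario-class].
#' @return `data.frame` with columns `motif_id`, `f`, `d`, `c`,
#'   `tss_distance`, `n`, `y` (true prior) and `b` (true state).
#' @export
simulateMotifDataset <- function(scenario) {
  validObject(scenario)
  set.seed(scenario@seed)
  nm <- scenario@nMotifs
  p <- scenario@trueParams
  f <- round(runif(nm, scenario@fRange[1], scenario@fRange[2]), 4)
  dRaw <- runif(nm, scenario@dRange[1], scenario@dRange[2])
  tssDist <- round(1000 * (1 / dRaw - 1))
  d <- 1 / (1 + tssDist / 1000)
  c_ <- round(rbeta(nm, scenario@cShape[1], scenario@cShape[2]), 4)
  y <- logisticPrior(p, f, d, c_)
  b <- rbinom(nm, 1L, y)
  n <- integer(nm)
  n[b == 1L] <- rnbinom(sum(b == 1L), size = p@K1, prob = 1 - p@r1)
  n[b == 0L] <- rnbinom(sum(b == 0L), size = p@K0, prob = 1 - p@r0)
  data.frame(motif_id = sprintf("m%06d", seq_len(nm)),
             f = f, d = d, c = c_, tss_distance = tssDist,
             n = n, y = y, b = b)
}

#' Write a complete genomic fixture to disk
#'
#' Realizes [simulateMotifDataset()] on a single pseudo-chromosome and
#' writes every file the downstream readers consume: a FIMO-style motif
#' table, a tag BED (each motif gets its simulated count of tags placed
#' in both 200-bp flanks, so the window count recomputed from the file
#' equals the simulated `n`), a conservation bedGraph (constant score
#' over each motif), a TSS table (one gene per motif locus, at the
#' motif's simulated TSS distance), a ChIP-like peak BED covering
#' exactly the bound motifs, and the truth table as TSV.
#'
#' Motifs are laid out on a fixed-pitch grid of loci wide enough that
#' counting windows never overlap between motifs and each motif's own
#' TSS is its nearest, making feature extraction on the files reproduce
#' the simulated table.
#'
#' @param scenario A [SimulationScenario-class].
#' @param dir Output directory (created if needed).
#' @param pwmId PWM identifier recorded in the motif table.
#' @return List with the written `paths`, the `truth` table, and the
#'   motif `GRanges`.
#' @export
simulateGenomeFixture <- function(scenario, dir, pwmId = "PWM1") {
  if (scenario@genomeLength < 1e4) stop("genome must be at least 10 kb")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulateMotifDataset(scenario)
  nm <- nrow(truth)
  w <- scenario@motifWidth
  window <- 200L
  pitch <- max(2 * (max(truth$tss_distance) + 2 * window + w) + 2000,
               4000)
  pitch <- max(pitch, ceiling(scenario@genomeLength / nm))
  mid <- as.integer(round((seq_len(nm) - 0.5) * pitch))
  start <- mid - w %/% 2L
  end <- start + w - 1L
  chrom <- "chrS"
  motifs <- GRanges(chrom, IRanges(start, end), strand = "+")
  mcols(motifs) <- DataFrame(pwm_id = pwmId,
                             fimo_score = 10 + 10 * truth$f,
                             motif_id = truth$motif_id)

  ## tags: n in each flank, uniform positions (seed continues from the
  ## dataset draw, so the whole fixture is fixed by the scenario seed)
  nTags <- truth$n
  upPos <- unlist(lapply(seq_len(nm), function(i) {
    if (nTags[i] == 0L) return(integer())
    sample((start[i] - window):(start[i] - 1L), nTags[i], replace = TRUE)
  }))
  downPos <- unlist(lapply(seq_len(nm), function(i) {
    if (nTags[i] == 0L) return(integer())
    sample((end[i] + 1L):(end[i] + window), nTags[i], replace = TRUE)
  }))
  track <- tagTrack(chrom, c(upPos, downPos))

  ## per-motif constant conservation
  cons <- GRanges(chrom, IRanges(start, end))
  cons$score <- truth$c

  ## one gene per locus at the simulated TSS distance (alternating side),
  ## measured from the motif midpoint as feature extraction defines it
  side <- rep_len(c(1L, -1L), nm)
  emid <- as.integer(floor((start + end) / 2))
  tssPos <- emid + side * as.integer(truth$tss_distance)
  tss <- GRanges(chrom, IRanges(tssPos, width = 1L), strand = "+")
  mcols(tss) <- DataFrame(gene = sprintf("g%06d", seq_len(nm)),
                          expressed = TRUE)

  peaks <- GRanges(chrom, IRanges(start[truth$b == 1L] - 100L,
                                  end[truth$b == 1L] + 100L))

  paths <- list(
    motifs = file.path(dir, "motifs.fimo.tsv"),
    tags = file.path(dir, "tags.bed"),
    conservation = file.path(dir, "conservation.bedGraph"),
    tss = file.path(dir, "tss.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    truth = file.path(dir, "truth.tsv"))
  writeMotifTable(motifs, paths$motifs)
  writeTagBed(track, paths$tags)
  writeBedGraph(cons, paths$conservation)
  writeTSS(tss, paths$tss)
  writePeaks(peaks, paths$peaks)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(paths = paths, truth = truth, motifs = motifs)
}

#' Simulate an expression time course
#'
#' Generates a genes x (time x 2 replicates) abundance matrix. A
#' `deFraction` share of the expressed genes follow one of four
#' trajectory archetypes on the log2 scale -- continuously up, early up
#' (saturating by 2 h), intermediate up (saturating by 12 h), and
#' continuously down -- with true fold changes drawn from
#' `foldChangeRange`; all other genes are flat. Replicate noise is
#' i.i.d. normal on the log2 scale.
#'
#' @param scenario A [SimulationScenario-class].
#' @return A `SummarizedExperiment` (assay `abundance`; `rowData`
#'   columns `expressed`, `archetype` (0 = not DE) and `trueFold`).
#' @export
simulateExpressionTimecourse <- function(scenario) {
  validObject(scenario)
  set.seed(scenario@seed + 1L)
  ng <- scenario@nGenes
  tp <- scenario@timePoints
  stopifnot(ng > 0L, length(tp) >= 2L)
  expressed <- rep(TRUE, ng)
  expressed[sample.int(ng, round(0.1 * ng))] <- FALSE
  base <- ifelse(expressed, rnorm(ng, 6, 1.5), rnorm(ng, 2, 0.5))
  nDE <- min(round(scenario@deFraction * ng), sum(expressed))
  arch <- integer(ng)
  if (nDE > 0) {
    deGenes <- sample(which(expressed), nDE)
    arch[deGenes] <- rep_len(1:4, nDE)
  }
  fc <- runif(ng, scenario@foldChangeRange[1], scenario@foldChangeRange[2])
  fc[arch == 0L] <- 1
  A <- log2(fc)
  tmax <- max(tp)
  shape <- function(a, t) switch(a + 1L,
    0,                       # flat
    t / tmax,                # continuous up
    pmin(t / 2, 1),          # early up, saturating at 2 h
    pmin(t / 12, 1),         # intermediate up, saturating at 12 h
    -t / tmax)               # continuous down
  cols <- as.vector(t(outer(tp, 1:2, function(t, r)
    paste0("t", t, "_rep", r))))
  m <- matrix(0, ng, length(cols), dimnames = list(
    sprintf("g%05d", seq_len(ng)), cols))
  time <- rep(tp, each = 2)
  repl <- rep(1:2, times = length(tp))
  for (j in seq_along(cols)) {
    mu <- base + vapply(arch, function(a) shape(a, time[j]), numeric(1)) * A
    m[, j] <- 2^(mu + rnorm(ng, 0, scenario@replicateNoiseSd))
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m),
    colData = DataFrame(time = time, replicate = repl, row.names = cols),
    rowData = DataFrame(expressed = expressed, archetype = arch,
                        trueFold = fc))
}
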