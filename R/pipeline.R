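#' @importFrom jsonlite write_json read_json
#' @importFrom tools md5sum
#' @importFrom utils modifyList
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-to-ranking pipeline
#'
#' Sequences every stage of the toolkit on a synthetic study with
#' plain-file handoff between stages: simulate a genomic fixture and
#' expression time course; extract per-motif features from the files;
#' fit the binding model on a random training sample; predict held-out
#' posteriors; evaluate against the ChIP-like truth peaks; call, test
#' and cluster differentially expressed genes; and score the PWM with
#' the four-criterion rubric. Accessibility at 6 h and 24 h is emulated
#' by doubling and quadrupling the tag counts of truly bound motifs.
#'
#' Every output lands under `config$outdir` and is listed, with its MD5
#' checksum, in `manifest.json`; all randomness flows from
#' `config$seed`.
#'
#' @param config Either a named list or the path to a JSON file with
#'   (all optional except `outdir`): `outdir`, `seed` (default 1),
#'   `nMotifs` (4000), `nGenes` (1000), `nTrain`/`nTest` (1000 each),
#'   `threshold` (0.99), `tol` (1e-6), `maxIter` (200), `nPerm` (200),
#'   `k` (4).
#' @return Invisibly, the manifest (list of artifact paths, checksums
#'   and headline metrics).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- read_json(config, simplifyVector = TRUE)
  stopifnot(!is.null(config$outdir))
  cfg <- modifyList(list(seed = 1L, nMotifs = 4000L, nGenes = 1000L,
                         nTrain = 1000L, nTest = 1000L, threshold = 0.99,
                         tol = 1e-6, maxIter = 200L, nPerm = 200L, k = 4L),
                    config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$outdir, ...)

  ## -- simulate ------------------------------------------------------
  fix <- .stage("simulate", {
    scen <- simulationScenario(nMotifs = cfg$nMotifs, nGenes = cfg$nGenes,
                               seed = cfg$seed)
    fix <- simulateGenomeFixture(scen, out("fixture"))
    se <- simulateExpressionTimecourse(scen)
    rownames(se) <- sprintf("g%06d", seq_len(nrow(se)))
    writeExpression(se, out("fixture", "expression.tsv"))
    ## later time points: bound motifs gain accessibility 2x / 4x
    truth <- fix$truth
    mot <- fix$motifs
    for (spec in list(c(6, 2), c(24, 4))) {
      n <- truth$n * ifelse(truth$b == 1L, spec[2], 1)
      pos <- unlist(lapply(seq_along(mot), function(i) {
        if (n[i] == 0) return(integer())
        c(sample((start(mot)[i] - 200L):(start(mot)[i] - 1L), n[i],
                 replace = TRUE),
          sample((end(mot)[i] + 1L):(end(mot)[i] + 200L), n[i],
                 replace = TRUE))
      }))
      writeTagBed(tagTrack("chrS", pos),
                  out("fixture", sprintf("tags_%dh.bed", spec[1])))
    }
    file.rename(fix$paths$tags, out("fixture", "tags_0h.bed"))
    fix$paths$tags <- out("fixture", "tags_0h.bed")
    fix
  })

  ## -- extract features ---------------------------------------------
  feat <- .stage("extract-features", {
    motifs <- readMotifTable(fix$paths$motifs)
    ## fixture motifs are generated in coordinate order and the writer
    ## sorts by coordinate, so ids map by position
    motifs$motif_id <- fix$truth$motif_id
    track0 <- readTagBed(out("fixture", "tags_0h.bed"))
    cons <- readBedGraph(fix$paths$conservation)
    tss <- readTSS(fix$paths$tss)
    feats <- extractFeatures(motifs, track0, cons, tss)
    tab <- data.frame(motif_id = feats$motif_id, f = feats$f, d = feats$d,
                      c = feats$c, n = feats$n,
                      tss_distance = feats$tss_distance)
    write.table(tab, out("features.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(motifs = feats, table = tab)
  })

  ## -- fit -----------------------------------------------------------
  fit <- .stage("fit", {
    split <- splitTrainTest(nrow(feat$table), cfg$nTrain, cfg$nTest,
                            seed = cfg$seed)
    fit <- fitAccessTF(feat$table[split$train, ], tol = cfg$tol,
                       maxIter = cfg$maxIter, threshold = cfg$threshold,
                       seed = cfg$seed)
    p <- modelParams(fit)
    write_json(list(beta = as.list(p@beta), K0 = p@K0, r0 = p@r0,
                    K1 = p@K1, r1 = p@r1),
               out("params.json"), auto_unbox = TRUE, digits = NA)
    write_json(list(iterations = fit@iterations,
                    converged = isConverged(fit),
                    logLik = logLikTrajectory(fit), seed = cfg$seed),
               out("fit_report.json"), auto_unbox = TRUE, digits = NA)
    list(fit = fit, split = split)
  })

  ## -- predict -------------------------------------------------------
  pred <- .stage("predict", {
    test <- feat$table[fit$split$test, ]
    post <- predictPosterior(fit$fit, test)
    tab <- data.frame(motif_id = test$motif_id, y = post$y,
                      gamma = post$gamma, call = post$call)
    writePredictions(tab, out("posteriors_test.tsv"))
    all_ <- predictPosterior(fit$fit, feat$table)
    allTab <- data.frame(motif_id = feat$table$motif_id, y = all_$y,
                         gamma = all_$gamma, call = all_$call)
    writePredictions(allTab, out("posteriors_all.tsv"))
    list(test = tab, all = allTab)
  })

  ## -- evaluate ------------------------------------------------------
  metrics <- .stage("evaluate", {
    peaks <- readPeaks(fix$paths$peaks)
    testMotifs <- feat$motifs[match(pred$test$motif_id,
                                    feat$motifs$motif_id)]
    labels <- labelByPeakOverlap(testMotifs, peaks)
    m <- list(roc_auc = rocAUC(pred$test$gamma, labels),
              pr_auc = prAUC(pred$test$gamma, labels),
              n_pos = sum(labels), n_neg = sum(!labels))
    write_json(m, out("metrics.json"), auto_unbox = TRUE, digits = NA)
    m
  })

  ## -- de-cluster ----------------------------------------------------
  de <- .stage("de-cluster", {
    se <- readExpression(out("fixture", "expression.tsv"))
    deTab <- selectDEGenes(se)
    fdr <- permutationFDR(se, nPerm = cfg$nPerm, seed = cfg$seed)
    cl <- clusterDEGenes(se, deTab$gene[deTab$selected], k = cfg$k,
                         seed = cfg$seed)
    deTab$cluster <- NA_integer_
    deTab$cluster[match(names(cl$cluster), deTab$gene)] <- cl$cluster
    write.table(deTab, out("de_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_json(list(fdr = fdr$fdr, observed = fdr$observed,
                    permMean = fdr$permMean, nPerm = fdr$nPerm,
                    coherence = cl$coherence),
               out("fdr.json"), auto_unbox = TRUE, digits = NA)
    list(se = se, table = deTab, clusters = cl$cluster)
  })

  ## -- tfscore -------------------------------------------------------
  scores <- .stage("tfscore", {
    acc <- accessibleMotifs(list(pred$all), threshold = cfg$threshold)
    accMotifs <- feat$motifs[feat$motifs$motif_id %in% acc]
    tr0 <- readTagBed(out("fixture", "tags_0h.bed"))
    tr6 <- readTagBed(out("fixture", "tags_6h.bed"))
    tr24 <- readTagBed(out("fixture", "tags_24h.bed"))
    c1 <- criterion1AccessibilityGain(
      rpmWindowCount(tr0, accMotifs), rpmWindowCount(tr6, accMotifs),
      rpmWindowCount(tr24, accMotifs), librarySize0 = librarySize(tr0))
    tss <- readTSS(fix$paths$tss)
    assign_ <- assignMotifsToGenes(accMotifs, tss)
    motifGenes <- unique(assign_$gene[!is.na(assign_$gene)])
    clusters <- de$clusters
    background <- de$table$gene[de$table$expressed & !de$table$selected]
    c2 <- criterion2ClusterEnrichment(motifGenes, clusters, background)
    up <- callUpregulatedFactors(de$se)
    factorGene <- de$table$gene[1]
    c3 <- criterion3Upregulation(factorGene, up)
    c4 <- criterion4FamilyExpression(
      structure(mean(assay(de$se, "abundance")[factorGene, ]),
                names = factorGene))
    comp <- data.frame(pwm = "PWM1", gene = factorGene,
                       c1_6h = c1$score6, c1_24h = c1$score24,
                       c2 = c2$score, c3 = c3, c4 = unname(c4))
    ranked <- totalTFScore(comp)
    writeTFScores(ranked, out("tfscores.tsv"))
    write_json(list(c1 = c1[c("stat6", "stat24")], c2_best = c2$best,
                    n_accessible = length(accMotifs)),
               out("tfscore_audit.json"), auto_unbox = TRUE, digits = NA)
    ranked
  })

  artifacts <- c(out("features.tsv"), out("params.json"),
                 out("fit_report.json"), out("posteriors_test.tsv"),
                 out("posteriors_all.tsv"), out("metrics.json"),
                 out("de_genes.tsv"), out("fdr.json"),
                 out("tfscores.tsv"), out("tfscore_audit.json"),
                 unlist(fix$paths, use.names = FALSE),
                 out("fixture", "expression.tsv"),
                 out("fixture", "tags_6h.bed"),
                 out("fixture", "tags_24h.bed"))
  manifest <- list(seed = cfg$seed,
                   artifacts = data.frame(
                     path = artifacts,
                     md5 = unname(md5sum(artifacts))),
                   metrics = metrics)
  write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(manifest)
}
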