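## small hand-built expression container: genes x (time x 2 reps)
makeSE <- function(m, times, expressed = rep(TRUE, nrow(m))) {
  cols <- as.vector(t(outer(times, 1:2, function(t, r)
    paste0("t", t, "_rep", r))))
  colnames(m) <- cols
  SummarizedExperiment(
    assays = list(abundance = m),
    colData = S4Vectors::DataFrame(time = rep(times, each = 2),
                                   replicate = rep(1:2, length(times)),
                                   row.names = cols),
    rowData = S4Vectors::DataFrame(expressed = expressed))
}

test_that("the replicate-consistent fold-change rule selects correctly", {
  ## baseline 10/10; gene1: 16 and 17 at 24 h (selected);
  ## gene2: 16 and 14 (inconsistent); gene3: down 2x both reps
  m <- rbind(g1 = c(10, 10, 16, 17),
             g2 = c(10, 10, 16, 14),
             g3 = c(10, 10, 5, 4.8))
  se <- makeSE(m, c(0, 24))
  de <- selectDEGenes(se)
  expect_equal(de$selected, c(TRUE, FALSE, TRUE))
  expect_gt(de$maxFold[1], 1.5)
  expect_lt(de$maxFold[3], 1 / 1.5)
})

test_that("zero-baseline genes are excluded with a warning", {
  m <- rbind(g1 = c(0, 0, 50, 60), g2 = c(10, 10, 30, 32))
  se <- makeSE(m, c(0, 24))
  expect_warning(de <- selectDEGenes(se), "zero baseline")
  expect_equal(de$selected, c(FALSE, TRUE))
})

test_that("selection recovers exactly the simulated DE genes at low noise", {
  scen <- simulationScenario(nMotifs = 100, nGenes = 500, deFraction = 0.1,
                             replicateNoiseSd = 0.01, seed = 15)
  se <- simulateExpressionTimecourse(scen)
  de <- selectDEGenes(se)
  truth <- SummarizedExperiment::rowData(se)$archetype > 0
  expect_equal(de$selected, unname(truth))
})

test_that("selection is monotone in the fold cutoff", {
  scen <- simulationScenario(nMotifs = 100, nGenes = 300,
                             replicateNoiseSd = 0.3, seed = 19)
  se <- simulateExpressionTimecourse(scen)
  sel15 <- selectDEGenes(se, 1.5)$selected
  sel20 <- selectDEGenes(se, 2.0)$selected
  expect_true(all(!sel20 | sel15))  # raising the cutoff never adds genes
})

test_that("permutation FDR calibrates to ~1 on null data and is small on
           signal", {
  null_ <- simulateExpressionTimecourse(
    simulationScenario(nMotifs = 100, nGenes = 800, deFraction = 0,
                       replicateNoiseSd = 0.5, seed = 23))
  fdrNull <- permutationFDR(null_, nPerm = 200, seed = 1)
  expect_gt(fdrNull$observed, 0)
  expect_gt(fdrNull$fdr, 0.8)
  expect_lt(fdrNull$fdr, 1.25)

  ## study-like prevalence: ~5% DE genes with clear fold changes
  strong <- simulateExpressionTimecourse(
    simulationScenario(nMotifs = 100, nGenes = 2000, deFraction = 0.05,
                       replicateNoiseSd = 0.1, seed = 23))
  fdrSig <- permutationFDR(strong, nPerm = 200, seed = 1)
  expect_lt(fdrSig$fdr, 0.05)
})

test_that("a reduced permutation count reproduces the estimate", {
  se <- simulateExpressionTimecourse(
    simulationScenario(nMotifs = 100, nGenes = 600, deFraction = 0.05,
                       replicateNoiseSd = 0.45, seed = 29))
  a <- permutationFDR(se, nPerm = 300, seed = 1)
  b <- permutationFDR(se, nPerm = 1500, seed = 2)
  expect_lt(abs(a$fdr - b$fdr) / b$fdr, 0.15)
})

test_that("clustering recovers the four injected archetypes", {
  scen <- simulationScenario(nMotifs = 100, nGenes = 800, deFraction = 0.25,
                             replicateNoiseSd = 0.1, seed = 31)
  se <- simulateExpressionTimecourse(scen)
  de <- selectDEGenes(se)
  cl <- clusterDEGenes(se, de$gene[de$selected], seed = 31)
  truth <- SummarizedExperiment::rowData(se)$archetype[
    match(de$gene[de$selected], rownames(se))]
  expect_gt(randIndex(cl$cluster, truth), 0.9)
  ## coherent clusters: median within-cluster correlation above 0.7
  expect_true(all(cl$coherence > 0.7))
})

test_that("standardized profiles have mean 0 and unit variance", {
  scen <- simulationScenario(nMotifs = 100, nGenes = 300, deFraction = 0.2,
                             replicateNoiseSd = 0.1, seed = 37)
  se <- simulateExpressionTimecourse(scen)
  de <- selectDEGenes(se)
  cl <- clusterDEGenes(se, de$gene[de$selected], seed = 1)
  expect_equal(unname(rowMeans(cl$profiles)),
               rep(0, nrow(cl$profiles)), tolerance = 1e-12)
  expect_equal(unname(apply(cl$profiles, 1, sd)),
               rep(1, nrow(cl$profiles)), tolerance = 1e-12)
})

test_that("duplicate profiles land in one cluster", {
  base <- c(10, 10, 10, 10, 40, 41)  # strong up at 24 h
  m <- rbind(a = base, b = base, c = base,
             d = c(10, 10, 40, 41, 10, 10),
             e = c(10, 10, 5, 5, 2, 2),
             f = c(10, 10, 20, 21, 30, 31))
  se <- makeSE(m, c(0, 12, 24))
  cl <- clusterDEGenes(se, rownames(m), k = 3, seed = 1)
  expect_length(unique(cl$cluster[c("a", "b", "c")]), 1L)
})

test_that("up-regulation calls are direction-specific", {
  m <- rbind(up = c(10, 10, 21, 20),
             down = c(10, 10, 5, 5),
             mixed = c(10, 10, 20, 9))
  se <- makeSE(m, c(0, 24))
  up <- callUpregulatedFactors(se)
  expect_equal(unname(up), c(TRUE, FALSE, FALSE))
})

test_that("consistent-response fractions match hand enumeration", {
  ## 3 genes x 2 conditions, threshold 1 (2-fold in log2)
  lfc <- rbind(g1 = c(1.5, 2.0),   # common up
               g2 = c(-1.2, -3),   # common down
               g3 = c(1.5, -2))    # discordant
  out <- consistentResponseFraction(lfc, nRandom = 10, seed = 1)
  expect_equal(unname(out$observed), c(1 / 3, 1 / 3))
})

test_that("identical columns far exceed the randomized background", {
  set.seed(41)
  col <- rnorm(400, sd = 1.2)
  lfc <- cbind(col, col, col)
  out <- consistentResponseFraction(lfc, nRandom = 200, seed = 2)
  expect_gt(out$observed[["up"]],
            out$backgroundMean[["up"]] + 5 * out$backgroundSd[["up"]])
})

test_that("independent columns sit within 3 SD of the background", {
  set.seed(43)
  lfc <- matrix(rnorm(500 * 3, sd = 1.3), ncol = 3)
  out <- consistentResponseFraction(lfc, nRandom = 300, seed = 3)
  for (dir in c("up", "down")) {
    expect_lt(abs(out$observed[[dir]] - out$backgroundMean[[dir]]),
              3 * max(out$backgroundSd[[dir]], 1e-4))
  }
})
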