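test_that("criterion-1 statistics map through the published 6 h bins", {
  r <- defaultRubric()
  ## one motif with baseline RPM 1 and 6 h RPM equal to the target sum
  c1 <- function(stat6) criterion1AccessibilityGain(
    rpm0 = 1, rpm6 = stat6, rpm24 = 0)$score6
  expect_equal(c1(800), 1)
  expect_equal(c1(0), 0)
  expect_equal(c1(600), 0)    # boundary closed below
  expect_equal(c1(601), 1)
  expect_equal(c1(1500), 2)
  expect_equal(c1(5002), 5)
  ## no accessible motifs -> statistic 0, score 0
  empty <- criterion1AccessibilityGain(numeric(), numeric(), numeric())
  expect_equal(empty$stat6, 0)
  expect_equal(empty$score6, 0)
})

test_that("the corrected 24 h bins are monotone and applied", {
  r <- defaultRubric()
  expect_true(all(diff(r$c1_24h_edges) > 0))
  c24 <- function(stat) criterion1AccessibilityGain(
    rpm0 = 1, rpm6 = 0, rpm24 = stat)$score24
  expect_equal(c24(2000), 0)
  expect_equal(c24(2001), 1)
  expect_equal(c24(7000), 3)
  expect_equal(c24(20000), 5)
})

test_that("zero-baseline motifs contribute via the library pseudocount", {
  ## RPM0 = 0 -> denominator is the RPM of one read (1e6 / library size)
  out <- criterion1AccessibilityGain(rpm0 = c(1, 0), rpm6 = c(10, 5),
                                     rpm24 = c(0, 0),
                                     librarySize0 = 2e6)
  expect_equal(out$stat6, 10 / 1 + 5 / 0.5)
})

test_that("criterion-1 score never drops when the statistic grows", {
  stats <- sort(runif(50, 0, 8000))
  sc <- vapply(stats, function(s)
    criterion1AccessibilityGain(1, s, 0)$score6, numeric(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("criterion-2 binning matches the published -log10 P edges", {
  expect_equal(criterion2ClusterEnrichment(neglog10p = 12)$score, 2)
  expect_equal(criterion2ClusterEnrichment(neglog10p = 3)$score, 0)
  expect_equal(criterion2ClusterEnrichment(neglog10p = 8)$score, 0)
  expect_equal(criterion2ClusterEnrichment(neglog10p = 25)$score, 5)
  neg <- sort(runif(50, 0, 30))
  sc <- vapply(neg, function(x)
    criterion2ClusterEnrichment(neglog10p = x)$score, numeric(1))
  expect_true(all(diff(sc) >= 0))
})

test_that("the exact test equals hypergeometric tail enumeration", {
  ## 20-gene toy: cluster of 8 (6 with motif), background of 12 (2 with)
  clusterGenes <- paste0("c", 1:8)
  background <- paste0("b", 1:12)
  motifGenes <- c(clusterGenes[1:6], background[1:2])
  clusters <- setNames(rep(1L, 8), clusterGenes)
  out <- criterion2ClusterEnrichment(motifGenes, clusters, background)
  expect_equal(out$tests$cluster_with, 6)
  expect_equal(out$tests$p,
               hyperTailEnumeration(6, 2, 2, 10), tolerance = 1e-12)
  ## best cluster wins when several clusters are tested
  clusters2 <- setNames(c(rep(1L, 8), rep(2L, 4)),
                        c(clusterGenes, paste0("d", 1:4)))
  out2 <- criterion2ClusterEnrichment(motifGenes, clusters2, background)
  expect_equal(out2$best, max(out2$tests$neglog10p))
})

test_that("criterion 3 adds 15 only for up-regulated factors", {
  flags <- c(STAT3 = TRUE, CTCF = FALSE)
  expect_equal(criterion3Upregulation("STAT3", flags), 15)
  expect_equal(criterion3Upregulation("CTCF", flags), 0)
  expect_warning(sc <- criterion3Upregulation("NOVEL", flags), "absent")
  expect_equal(sc, 0)
})

test_that("criterion 4 bins family members relative to the maximum", {
  sc <- criterion4FamilyExpression(c(FOS = 100, FOSL1 = 40, FOSB = 10))
  expect_equal(unname(sc), c(5, 0, -10))  # 40 in (E/4, E/2]; 10 <= E/6
  expect_equal(unname(criterion4FamilyExpression(c(a = 80, b = 10))[["b"]]),
               -10)  # one eighth of the maximum
  expect_equal(unname(criterion4FamilyExpression(c(a = 100, b = 60))[["b"]]),
               3)    # 0.6 E in (E/2, E)
  ## boundary closures: E/2 scores 0, E/4 scores -5, E/6 scores -10
  sc2 <- criterion4FamilyExpression(c(a = 120, b = 60, c = 30, d = 20))
  expect_equal(unname(sc2), c(5, 0, -5, -10))
  ## ties at the maximum all take +5
  expect_equal(unname(criterion4FamilyExpression(c(a = 7, b = 7))),
               c(5, 5))
  expect_warning(z <- criterion4FamilyExpression(c(a = 0, b = 0)), "zero")
  expect_equal(unname(z), c(-10, -10))
})

test_that("accessible motifs are the union over time points", {
  p1 <- data.frame(motif_id = c("m1", "m2", "m3"),
                   gamma = c(0.999, 0.5, 0.2))
  p2 <- data.frame(motif_id = c("m1", "m2", "m3"),
                   gamma = c(0.1, 0.995, 0.0))
  expect_equal(accessibleMotifs(list(p1, p2)), c("m1", "m2"))
  expect_equal(accessibleMotifs(list(p1)), "m1")
  ## gamma = 1 in, gamma = 0 out
  expect_equal(accessibleMotifs(list(data.frame(
    motif_id = c("a", "b"), gamma = c(1, 0)))), "a")
})

test_that("motif-gene assignment picks the nearest expressed TSS within
           range", {
  tss <- GRanges("chr1", IRanges(c(5000, 30000, 250000), width = 1),
                 strand = "+")
  mcols(tss) <- S4Vectors::DataFrame(
    gene = c("near", "mid", "far"), expressed = c(TRUE, TRUE, TRUE))
  motifs <- GRanges("chr1", IRanges(c(10000, 500000), width = 10))
  motifs$motif_id <- c("mA", "mB")
  out <- assignMotifsToGenes(motifs, tss)
  expect_equal(out$gene, c("near", NA))  # 5 kb assigned; 250 kb away not
  ## non-expressed genes are invisible to the assignment
  tss$expressed <- c(FALSE, TRUE, TRUE)
  out2 <- assignMotifsToGenes(motifs, tss)
  expect_equal(out2$gene[1], "mid")
})

test_that("nearest-gene choice matches a brute-force distance scan", {
  set.seed(47)
  tssPos <- sort(sample.int(2e6, 40))
  tss <- GRanges("chr1", IRanges(tssPos, width = 1), strand = "+")
  mcols(tss) <- S4Vectors::DataFrame(gene = paste0("g", seq_along(tssPos)),
                                     expressed = TRUE)
  mStart <- sample.int(2e6 - 10, 60)
  motifs <- GRanges("chr1", IRanges(mStart, width = 10))
  out <- assignMotifsToGenes(motifs, tss, maxDistance = 1e5)
  mid <- floor((mStart + mStart + 9) / 2)
  for (i in seq_along(motifs)) {
    dists <- abs(mid[i] - tssPos)
    expected <- if (min(dists) > 1e5) NA_character_
                else paste0("g", which.min(dists))
    expect_identical(out$gene[i], expected)
  }
})

test_that("totals, ordering and ties behave deterministically", {
  comp <- data.frame(pwm = c("P1", "P2", "P3"),
                     gene = c("B", "A", "C"),
                     c1_6h = c(3, 3, 0), c1_24h = c(4, 4, 0),
                     c2 = c(2, 2, 1), c3 = c(15, 15, 0),
                     c4 = c(5, 5, -10))
  ranked <- totalTFScore(comp)
  expect_equal(ranked$total, c(29, 29, -9))  # (3,4,2,15,5) sums to 29
  expect_equal(ranked$gene, c("A", "B", "C"))  # tie broken by name
  expect_equal(ranked$rank, 1:3)
  ## permuting input order leaves the ranking unchanged
  expect_identical(totalTFScore(comp[c(3, 1, 2), ]), ranked)
})

test_that("component scores stay inside their rubric ranges", {
  set.seed(53)
  for (i in 1:30) {
    s6 <- criterion1AccessibilityGain(1, runif(1, 0, 1e4),
                                      runif(1, 0, 3e4))
    expect_true(s6$score6 %in% 0:5 && s6$score24 %in% 0:5)
    expect_true(criterion2ClusterEnrichment(
      neglog10p = runif(1, 0, 40))$score %in% 0:5)
  }
  expect_true(all(criterion4FamilyExpression(
    setNames(runif(6, 0, 50), letters[1:6])) %in% c(-10, -5, 0, 3, 5)))
})

test_that("a constructed dominant PWM ranks first end-to-end", {
  ## PWM "hot" gains accessibility, is enriched near up-regulated genes
  ## and is itself up-regulated; "cold" is flat everywhere
  hot <- criterion1AccessibilityGain(rpm0 = rep(1, 10),
                                     rpm6 = rep(200, 10),
                                     rpm24 = rep(500, 10))
  cold <- criterion1AccessibilityGain(rpm0 = rep(1, 10),
                                      rpm6 = rep(1, 10), rpm24 = rep(1, 10))
  up <- c(HOT1 = TRUE, COLD1 = FALSE)
  comp <- data.frame(
    pwm = c("hot", "cold"), gene = c("HOT1", "COLD1"),
    c1_6h = c(hot$score6, cold$score6),
    c1_24h = c(hot$score24, cold$score24),
    c2 = c(criterion2ClusterEnrichment(neglog10p = 15)$score,
           criterion2ClusterEnrichment(neglog10p = 1)$score),
    c3 = c(criterion3Upregulation("HOT1", up),
           criterion3Upregulation("COLD1", up)),
    c4 = c(5, 5))
  ranked <- totalTFScore(comp)
  expect_equal(ranked$pwm[1], "hot")
  ## byte-identical output for identical inputs
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeTFScores(ranked, f1); writeTFScores(ranked, f2)
  expect_identical(readLines(f1), readLines(f2))
})
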