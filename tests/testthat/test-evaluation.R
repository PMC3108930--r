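test_that("precision counts only exact top ranks, ties as failures", {
  expect_equal(precisionFromRanks(c(1, 3, 1, 2)), 50.0)
  expect_equal(precisionFromRanks(rep(1, 7)), 100.0)
  expect_equal(precisionFromRanks(c(1.5, 1.5)), 0.0)
})

test_that("mean rank ratio is the average in percent", {
  expect_equal(meanRankRatio(c(0.01, 0.05)), 3.0)
  expect_equal(meanRankRatio(1.0), 100.0)
  set.seed(31)
  expect_lt(abs(meanRankRatio(runif(1000)) - 50), 3)
})

test_that("AUC matches brute-force pairwise comparison", {
  expect_equal(aucFromRankRatios(0.01, 0.5), 100.0)
  expect_equal(aucFromRankRatios(c(0.2, 0.6), c(0.4, 0.8)), 75.0)
  expect_equal(aucFromRankRatios(c(0.1, 0.3), c(0.1, 0.3)), 50.0)
  expect_error(aucFromRankRatios(numeric(0), 0.5), "empty")
  set.seed(32)
  for (i in 1:100) {
    dd <- round(runif(sample(1:6, 1)), 2)
    cc <- round(runif(sample(1:6, 1)), 2)
    expect_equal(aucFromRankRatios(dd, cc), bruteForceAuc(dd, cc))
  }
})

test_that("fold enrichment is b/a with a zero guard", {
  expect_equal(foldEnrichment(5, 5), 1.0)
  expect_error(foldEnrichment(5, 0), "undefined enrichment")
  expect_equal(round(foldEnrichment(100 * 207 / 2847, 100 * 1 / 14944)),
               1087)
})

test_that("LOOCV runs once per evaluated association and respects the
          genome-wide candidate count", {
  b <- simulateScenario(nDomains = 80, nPhenotypes = 30, seed = 41)
  prox <- diffusionKernel(b$network, 0.05)
  pairs3 <- associationPairs(b$associations)[1:3, ]
  ev <- runLOOCV(b$associations, prox, b$similarity,
                 protocol = "genome_wide", seed = 2, pairs = pairs3)
  pr <- perRunResults(ev)
  expect_equal(nrow(pr), 3)
  expect_true(all(pr$nCandidates == numDomains(b$network)))
  expect_true(all(pr$rankRatio > 0 & pr$rankRatio <= 1))
  # deterministic given the seed
  ev2 <- runLOOCV(b$associations, prox, b$similarity,
                  protocol = "genome_wide", seed = 2, pairs = pairs3)
  expect_equal(perRunResults(ev2), pr)
})

test_that("random controls exclude the true domain's phenotype seeds and
          cap at the pool size", {
  b <- simulateScenario(nDomains = 50, nPhenotypes = 20, seed = 43)
  prox <- diffusionKernel(b$network, 0.05)
  ev <- runLOOCV(b$associations, prox, b$similarity,
                 protocol = "random_control", nControls = 9, seed = 3)
  pr <- perRunResults(ev)
  expect_true(all(pr$nCandidates <= 10))
  expect_true(all(pr$nCandidates >= 2))
})

test_that("linkage-interval candidates are the genomic neighbours of the
          true domain", {
  # 4 domains on one chromosome at 0, 5, 12 and 40 Mbp; 10 Mbp window
  loci <- domainLocusMap(rep("chr1", 4),
                         c(0, 5e6, 12e6, 40e6),
                         c(0, 5e6, 12e6, 40e6) + 5e4,
                         c("a", "b", "c", "d"))
  near <- domainRBF:::.domainsNear("b", loci, 1e7)
  expect_setequal(near, c("a", "b", "c"))
  expect_setequal(domainRBF:::.domainsNear("d", loci, 1e7), "d")
})

test_that("planted signal beats the similarity-shuffled null on the same
          scenario", {
  b <- simulateScenario(nDomains = 120, nPhenotypes = 50,
                        signalStrength = 0.9, seed = 44)
  prox <- diffusionKernel(b$network, 0.05)
  ev <- runLOOCV(b$associations, prox, b$similarity,
                 protocol = "random_control", nControls = 49, seed = 4)
  evNull <- runLOOCV(b$associations, prox, b$similarity,
                     protocol = "random_control", nControls = 49, seed = 4,
                     shuffleSimilarity = TRUE)
  expect_gt(aucOf(ev), aucOf(evNull))
  expect_gt(precisionOf(ev), precisionOf(evNull))
})

test_that("robustness shuffles preserve their marginals and are seeded", {
  b <- simulateScenario(nDomains = 60, nPhenotypes = 25, seed = 45)
  s1 <- robustnessSuite(b$associations, b$network, b$similarity,
                        which = "shuffle_associations", seed = 9,
                        protocol = "random_control", nControls = 19)
  s2 <- robustnessSuite(b$associations, b$network, b$similarity,
                        which = "shuffle_associations", seed = 9,
                        protocol = "random_control", nControls = 19)
  expect_equal(perRunResults(s1), perRunResults(s2))
})

test_that("seed subsampling and similarity-top filtering shrink the
          profile as configured", {
  b <- simulateScenario(nDomains = 80, nPhenotypes = 40, seed = 46)
  prox <- diffusionKernel(b$network, 0.05)
  pairs5 <- associationPairs(b$associations)[1:5, ]
  evFrac <- runLOOCV(b$associations, prox, b$similarity,
                     protocol = "random_control", nControls = 9, seed = 5,
                     pairs = pairs5, seedFraction = 0.5,
                     similarityTopFraction = 0.3)
  expect_equal(nrow(perRunResults(evFrac)), 5)
})

test_that("linkage-interval and ab initio protocols run end to end on a
          synthetic genome", {
  b <- simulateScenario(nDomains = 100, nPhenotypes = 40, seed = 47)
  prox <- diffusionKernel(b$network, 0.05)
  pairs6 <- associationPairs(b$associations)[1:6, ]
  evL <- runLOOCV(b$associations, prox, b$similarity,
                  protocol = "linkage_interval", windowBp = 1e7,
                  seed = 6, loci = b$loci, pairs = pairs6)
  prL <- perRunResults(evL)
  expect_gt(nrow(prL), 0)
  expect_true(all(prL$nCandidates >= 2))
  # every candidate set is a genomic neighbourhood, far below genome-wide
  expect_true(all(prL$nCandidates < numDomains(b$network)))
  expect_error(runLOOCV(b$associations, prox, b$similarity,
                        protocol = "linkage_interval", seed = 6),
               "requires domain loci")
  evA <- runLOOCV(b$associations, prox, b$similarity,
                  protocol = "random_control", nControls = 9, seed = 6,
                  mode = "ab_initio", pairs = pairs6)
  expect_equal(nrow(perRunResults(evA)), 6)
})
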