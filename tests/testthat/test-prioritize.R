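test_that("candidate rankings satisfy their invariants on the toy problem", {
  toy <- toyProblem()
  prox <- diffusionKernel(toy$net, 0.05)
  sc <- scoreCandidates("p1", domainIds(toy$net), toy$assoc, prox, toy$sim)
  expect_identical(sc$rank, rank(-sc$log10bf, ties.method = "average"))
  expect_equal(sc$rankRatio, sc$rank / nrow(sc))
  expect_true(all(diff(sc$log10bf) <= 0))
  expect_true(all(sc$rankRatio > 0 & sc$rankRatio <= 1))
  # single candidate
  one <- scoreCandidates("p1", "d4", toy$assoc, prox, toy$sim)
  expect_equal(one$rank, 1)
  expect_equal(one$rankRatio, 1.0)
  # deterministic: identical on repeat
  expect_identical(sc, scoreCandidates("p1", domainIds(toy$net), toy$assoc,
                                       prox, toy$sim))
})

test_that("ab initio mode on a single-pair phenotype equals holding out
          that pair", {
  toy <- toyProblem()
  prox <- diffusionKernel(toy$net, 0.05)
  # p3 has exactly one association: d4
  ab <- scoreCandidates("p3", domainIds(toy$net), toy$assoc, prox, toy$sim,
                        mode = "ab_initio")
  loo <- scoreCandidates("p3", domainIds(toy$net), toy$assoc, prox,
                         toy$sim, mode = "loo_pair",
                         heldOut = c("d4", "p3"))
  expect_equal(ab$log10bf, loo$log10bf)
  expect_identical(ab$domain, loo$domain)
})

test_that("planted domains outrank decoys in a synthetic scenario", {
  b <- simulateScenario(nDomains = 150, nPhenotypes = 60,
                        signalStrength = 0.9, seed = 21)
  prox <- diffusionKernel(b$network, 0.05)
  pp <- b$plantedPairs[1:25, ]
  rrTrue <- numeric(0); rrDecoyMedian <- numeric(0)
  for (i in seq_len(nrow(pp))) {
    sc <- scoreCandidates(pp$phenotype[i], domainIds(b$network),
                          b$associations, prox, b$similarity,
                          mode = "loo_pair",
                          heldOut = c(pp$domain[i], pp$phenotype[i]))
    rrTrue <- c(rrTrue, sc$rankRatio[sc$domain == pp$domain[i]])
    rrDecoyMedian <- c(rrDecoyMedian,
                       median(sc$rankRatio[sc$domain != pp$domain[i]]))
  }
  expect_lt(median(rrTrue), median(rrDecoyMedian))
})

test_that("gene scores take the maximum Bayes factor over a gene's
          domains", {
  bfs <- c(a = 2, b = 7, c = -1, d = 0.5)
  gm <- data.frame(gene = c("g1", "g1", "g2", "g3", "g3"),
                   domain = c("a", "b", "b", "c", "d"))
  gs <- geneScores(gm, bfs)
  expect_equal(gs$score[gs$gene == "g1"], 7)
  expect_equal(gs$score[gs$gene == "g2"], 7)  # shared maximal domain
  expect_equal(gs$score[gs$gene == "g3"], 0.5)
  # brute-force oracle on a random map
  set.seed(22)
  doms <- letters[1:10]
  bfs2 <- setNames(rnorm(10), doms)
  gm2 <- data.frame(gene = rep(paste0("g", 1:5), each = 3),
                    domain = sample(doms, 15, replace = TRUE))
  gs2 <- geneScores(gm2, bfs2)
  manual <- sort(vapply(split(gm2$domain, gm2$gene),
                        function(d) max(bfs2[d]), numeric(1)),
                 decreasing = TRUE)
  expect_equal(setNames(gs2$score, gs2$gene)[names(manual)], manual)
  # genes without scored domains are dropped with a warning; all-missing
  # errors
  expect_warning(gs3 <- geneScores(rbind(gm, data.frame(gene = "gX",
                                                        domain = "zz")),
                                   bfs), "dropped")
  expect_false("gX" %in% gs3$gene)
  expect_error(geneScores(data.frame(gene = "g", domain = "zz"), bfs),
               "no gene has a scored domain")
})

test_that("the landscape matrix matches per-phenotype scoring and the
          export filter keeps qualifying rows", {
  toy <- toyProblem()
  prox <- diffusionKernel(toy$net, 0.05)
  phen <- c("p1", "p2", "p4")
  doms <- c("d1", "d3", "d5", "d6")
  L <- bfLandscape(phen, doms, toy$assoc, prox, toy$sim)
  for (p in phen) {
    sc <- scoreCandidates(p, doms, toy$assoc, prox, toy$sim)
    expect_equal(L[p, sc$domain], setNames(sc$log10bf, sc$domain))
  }
  # checkpointed chunks reproduce the straight run
  ck <- file.path(tempdir(), "ck_landscape")
  unlink(ck, recursive = TRUE)
  L2 <- bfLandscape(phen, doms, toy$assoc, prox, toy$sim, chunkSize = 1,
                    checkpointDir = ck)
  expect_equal(L, L2)
  expect_length(list.files(ck), 3)

  m <- rbind(low = c(0.01, 0.05), high = c(0.05, 0.3))
  expect_identical(rownames(filterLandscape(m, 0.1)), "high")
  expect_equal(nrow(filterLandscape(m, 0.5)), 0)
  expect_equal(nrow(filterLandscape(m, 0.01)), 2)
})

test_that("rank ratios of uninformative scores are centred near one half", {
  set.seed(23)
  mrr <- mean(replicate(1000, {
    r <- rank(-rnorm(25), ties.method = "average")
    mean(r / 25)
  }))
  expect_lt(abs(mrr - 0.5), 0.05)
})
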