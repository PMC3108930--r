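# shared toy structures, built in code

pathGraph3 <- function() domainNetwork(rbind(c("u", "w"), c("w", "v")))

triangleGraph <- function() {
  domainNetwork(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
}

fourCycle <- function() {
  domainNetwork(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d")))
}

# two components: a-b edge and isolated pair c-d
disconnectedGraph <- function() {
  domainNetwork(rbind(c("a", "b"), c("c", "d")))
}

randomGraph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  e <- t(combn(ids, 2))
  e <- e[runif(nrow(e)) < p, , drop = FALSE]
  domainNetwork(e, nodes = ids)
}

# a deterministic 6-domain / 5-phenotype toy problem with hand-set
# associations and similarities
toyProblem <- function() {
  net <- domainNetwork(rbind(
    c("d1", "d2"), c("d2", "d3"), c("d3", "d4"), c("d4", "d5"),
    c("d1", "d3"), c("d5", "d6")))
  assoc <- associationSet(
    domain = c("d1", "d2", "d3", "d4", "d5", "d6"),
    phenotype = c("p1", "p1", "p2", "p3", "p4", "p5"))
  set.seed(42)
  m <- matrix(runif(25, 0, 0.6), 5, 5)
  m <- round((m + t(m)) / 2, 4)
  diag(m) <- 1
  dimnames(m) <- list(paste0("p", 1:5), paste0("p", 1:5))
  list(net = net, assoc = assoc, sim = phenotypeSimilarity(m))
}

finitePriors <- function(sigmaMuSq = 1, sigma1Sq = 1, n0 = 1,
                         sigma0Sq = 1) {
  regressionPriors(mu0 = c(0, 0), sigmaMuSq = sigmaMuSq,
                   sigma1Sq = sigma1Sq, n0 = n0, sigma0Sq = sigma0Sq)
}

# brute-force Mann-Whitney AUC by pairwise comparison
bruteForceAuc <- function(dd, cc) {
  s <- 0
  for (d in dd) for (c0 in cc)
    s <- s + (d < c0) + 0.5 * (d == c0)
  100 * s / (length(dd) * length(cc))
}
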