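test_that("domain-phenotype proximity sums kernel entries over D(p)", {
  toy <- toyProblem()
  prox <- diffusionKernel(toy$net, 0.05)
  v <- proximityValues(prox)
  # p1 has D(p1) = {d1, d2}
  expect_equal(domainPhenotypeProximity("d5", "p1", prox, toy$assoc),
               v["d5", "d1"] + v["d5", "d2"])
  # SG self-proximity: D(p2) = {d3}
  sg <- sgKernel(toy$net, 1)
  expect_equal(domainPhenotypeProximity("d3", "p2", sg, toy$assoc), 1.0)
  # brute-force oracle over all (domain, phenotype) combinations
  for (d in domainIds(toy$net)) for (p in seedPhenotypes(toy$assoc)) {
    manual <- sum(vapply(domainsOf(toy$assoc, p),
                         function(dd) v[d, dd], numeric(1)))
    expect_equal(domainPhenotypeProximity(d, p, prox, toy$assoc), manual)
  }
  expect_error(domainPhenotypeProximity("nope", "p1", prox, toy$assoc),
               "domain not in network")
})

test_that("proximity profiles respect exclusions and match a rebuilt
          association set", {
  toy <- toyProblem()
  prox <- diffusionKernel(toy$net, 0.05)
  full <- proximityProfile("d2", toy$assoc, prox)
  expect_identical(names(full), seedPhenotypes(toy$assoc))
  for (p in names(full))
    expect_equal(full[[p]],
                 domainPhenotypeProximity("d2", p, prox, toy$assoc))
  # excluding a phenotype's only pair drops it from the index
  ex <- data.frame(domain = "d4", phenotype = "p3")
  prof <- proximityProfile("d2", toy$assoc, prox, excludePairs = ex)
  expect_false("p3" %in% names(prof))
  # oracle: rebuild from scratch on the reduced set
  reduced <- associationSet(
    domain = c("d1", "d2", "d3", "d5", "d6"),
    phenotype = c("p1", "p1", "p2", "p4", "p5"))
  expect_equal(prof, proximityProfile("d2", reduced, prox))
  # dropping too many phenotypes errors
  exAll <- associationPairs(toy$assoc)[1:4, ]
  expect_error(proximityProfile("d2", toy$assoc, prox,
                                excludePairs = exAll),
               "insufficient seed phenotypes")
})

test_that("similarity profiles extract the query row over seed phenotypes
          with optional self-exclusion", {
  toy <- toyProblem()
  m <- similarityValues(toy$sim)
  p <- similarityProfile("p2", toy$sim, toy$assoc, excludeQuery = TRUE)
  expect_identical(names(p), setdiff(seedPhenotypes(toy$assoc), "p2"))
  expect_equal(unname(p), unname(m["p2", names(p)]))
  pAll <- similarityProfile("p2", toy$sim, toy$assoc, excludeQuery = FALSE)
  expect_identical(names(pAll), seedPhenotypes(toy$assoc))
  expect_equal(pAll[["p2"]], 1)
  expect_error(similarityProfile("zz", toy$sim, toy$assoc),
               "phenotype not in similarity matrix")
})

test_that("inverse-normal transform maps ranks to Blom normal scores", {
  z <- inverseNormalTransform(c(0.3, 0.1, 0.9))
  # middle value -> plotting position 0.5 -> exactly 0
  expect_equal(z[[1]], 0)
  expect_equal(z[[2]], qnorm(0.625 / 3.25), tolerance = 1e-6)
  expect_equal(z[[3]], -qnorm(0.625 / 3.25), tolerance = 1e-6)
  expect_equal(unname(round(abs(z[2:3]), 4)), c(0.8694, 0.8694))

  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(20)
    z <- inverseNormalTransform(x)
    expect_equal(cor(rank(z), rank(x)), 1, tolerance = 1e-12)
    expect_lt(abs(mean(z)), 1e-6)  # symmetric plotting positions
  }
  # ties get averaged ranks: equal inputs -> equal outputs
  zt <- inverseNormalTransform(c(0, 0, 1, 2))
  expect_equal(zt[1], zt[2])
  expect_error(inverseNormalTransform(rep(1, 5)),
               "degenerate response")
  expect_error(inverseNormalTransform(c(1, 2)), "too short")
  # configurable offset
  z0 <- inverseNormalTransform(c(3, 1, 2),
                               new("RankTransform", offset = 0))
  expect_equal(unname(z0), qnorm(c(3, 1, 2) / 4))
})

test_that("association shuffles preserve per-phenotype counts and are
          seeded", {
  toy <- toyProblem()
  allDoms <- domainIds(toy$net)
  countsOf <- function(a) table(associationPairs(a)$phenotype)
  for (mode in c("permute", "random_replace")) {
    s1 <- shuffleAssociations(toy$assoc, allDoms, mode = mode, seed = 3)
    s2 <- shuffleAssociations(toy$assoc, allDoms, mode = mode, seed = 3)
    expect_identical(associationPairs(s1), associationPairs(s2))
    expect_equal(countsOf(s1), countsOf(toy$assoc))
  }
  sp <- shuffleAssociations(toy$assoc, allDoms, mode = "permute", seed = 8)
  expect_identical(sort(associationPairs(sp)$domain),
                   sort(associationPairs(toy$assoc)$domain))
})

test_that("profile shuffling preserves the value multiset, is seeded, and
          visits both orders of a pair", {
  v <- c(a = 0.1, b = 0.7, c = 0.3)
  s1 <- shuffleProfile(v, seed = 2)
  expect_identical(names(s1), names(v))
  expect_identical(sort(unname(s1)), sort(unname(v)))
  expect_identical(s1, shuffleProfile(v, seed = 2))
  orders <- vapply(0:9, function(s)
    paste(shuffleProfile(c(x = 1, y = 2), seed = s), collapse = ","),
    character(1))
  expect_setequal(unique(orders), c("1,2", "2,1"))
})
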