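#' Simulate a domain interaction network
#'
#' `"preferential_attachment"` grows a connected scale-free-ish graph (a
#' preferential-attachment tree topped up with random extra edges to reach
#' the requested density); `"erdos_renyi"` draws a G(n, m) graph. The
#' realized mean degree is 2 * edges / n, close to `meanDegree`.
#'
#' @param n number of domains.
#' @param model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param meanDegree target mean degree (default 2.3, a sparse
#'   structural-interaction regime; dense predicted-interaction networks are
#'   closer to 18).
#' @param seed integer seed.
#' @return A [DomainNetwork-class] with ids `D0001`, `D0002`, ...
#' @export
simulateNetwork <- function(n, model = c("preferential_attachment",
                                         "erdos_renyi"),
                            meanDegree = 2.3, seed = 1) {
  model <- match.arg(model)
  if (n < 1) stop("n must be >= 1")
  ids <- sprintf("D%04d", seq_len(n))
  if (n == 1) return(domainNetwork(NULL, nodes = ids))
  nEdges <- max(1, round(n * meanDegree / 2))
  g <- .withSeed(seed, {
    if (model == "preferential_attachment") {
      g <- igraph::sample_pa(n, m = 1, directed = FALSE)
      extra <- nEdges - igraph::ecount(g)
      while (extra > 0) {
        cand <- matrix(sample(n, 2 * extra, replace = TRUE), ncol = 2)
        cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
        if (nrow(cand) > 0) {
          g <- igraph::add_edges(g, t(cand))
          g <- igraph::simplify(g)
        }
        extra <- nEdges - igraph::ecount(g)
      }
      g
    } else {
      igraph::sample_gnm(n, nEdges)
    }
  })
  e <- igraph::as_edgelist(g)
  domainNetwork(cbind(ids[e[, 1]], ids[e[, 2]]), nodes = ids)
}

#' Simulate a complete synthetic study scenario
#'
#' Generates a bundle with the statistical structure the regression model
#' assumes - phenotypically similar diseases are caused by interacting
#' domains - with a tunable, recoverable planted signal:
#'
#' 1. a domain network ([simulateNetwork()]);
#' 2. each phenotype draws its causal seed domain(s) uniformly at random,
#'    without replacement across phenotypes while unused domains remain,
#'    so distinct diseases are caused by distinct domains;
#' 3. pairwise phenotype similarity is derived from the interactions
#'    between the two seed sets: the number of network edges linking them
#'    (self-pairs excluded) is mapped through 1 - exp(-count), scaled by
#'    `signalStrength`, perturbed by N(0, `noiseSd`) noise and clipped to
#'    \[0, 1\] - similar diseases are the ones whose distinct causal
#'    domains interact;
#' 4. domain loci are tiled across a synthetic genome, background SNPs are
#'    scattered uniformly, and `nPlantedSnps` SNPs are planted within 1 Mbp
#'    of 10 designated seed domains (recorded in `plantedSnpDomains`);
#' 5. genes are mapped onto 1-3 domains each, covering every domain.
#'
#' Because similarity is generated from seed-set interactions with
#' self-pairs excluded, all planted signal is carried by the network
#' wiring: a degree-preserving rewire, an association permutation or a
#' similarity permutation each drive cross-validation to chance level,
#' while at `signalStrength = 0` the similarity matrix is pure noise.
#' Deterministic given `seed` (each component uses a derived substream).
#'
#' @param nDomains,nPhenotypes scenario size.
#' @param networkModel,meanDegree passed to [simulateNetwork()]; the
#'   default mean degree of 8 sits between the sparse structural (about
#'   2.3) and dense predicted (about 18) interaction regimes.
#' @param nPlantedPairs optional cap: evaluate only this many sampled
#'   (domain, phenotype) pairs (`plantedPairs`); NULL keeps all.
#' @param signalStrength planted signal in \[0, 1\].
#' @param noiseSd similarity noise standard deviation.
#' @param seedCountProbs probabilities of a phenotype having 1, 2 or 3
#'   seed domains; the default plants exactly one causal domain per
#'   phenotype.
#' @param nChromosomes,chromosomeLengthBp synthetic genome shape.
#' @param nBackgroundSnps,nPlantedSnps SNP counts.
#' @param seed integer master seed.
#' @return list with elements `network`, `associations`, `similarity`,
#'   `loci`, `snps`, `geneMap`, `plantedPairs`, `plantedSnpDomains`,
#'   `config`.
#' @export
simulateScenario <- function(nDomains = 400, nPhenotypes = 150,
                             networkModel = "erdos_renyi",
                             meanDegree = 8, nPlantedPairs = NULL,
                             signalStrength = 0.9, noiseSd = 0.05,
                             seedCountProbs = c(1, 0, 0),
                             nChromosomes = 5, chromosomeLengthBp = 1e8,
                             nBackgroundSnps = 60, nPlantedSnps = 40,
                             seed = 1) {
  if (nDomains < 2 || nPhenotypes < 4) stop("scenario too small")
  if (signalStrength < 0 || signalStrength > 1)
    stop("signalStrength must lie in [0,1]")
  if (!is.null(nPlantedPairs) && nPlantedPairs > nDomains * nPhenotypes)
    stop("more planted pairs than domain-phenotype combinations")
  s <- signalStrength
  net <- simulateNetwork(nDomains, networkModel, meanDegree,
                         seed = .subSeed(seed, 1))
  ids <- domainIds(net)
  phen <- sprintf("P%04d", seq_len(nPhenotypes))

  # adjacency with the diagonal kept at zero: sharing a domain does not by
  # itself make two diseases similar, so the planted signal cannot survive
  # a degree-preserving rewire
  A <- -laplacianMatrix(net)
  diag(A) <- 0

  # seed domains: uniform draws, without replacement across phenotypes
  # while unused domains remain
  assoc <- .withSeed(.subSeed(seed, 4), {
    dom <- character(0); ph <- character(0)
    unused <- ids
    for (i in seq_len(nPhenotypes)) {
      k <- sample(1:3, 1, prob = seedCountProbs)
      if (length(unused) >= k) {
        picked <- sample(unused, k)
        unused <- setdiff(unused, picked)
      } else {
        picked <- sample(ids, min(k, nDomains))
      }
      dom <- c(dom, picked)
      ph <- c(ph, rep(phen[i], length(picked)))
    }
    associationSet(dom, ph)
  })

  # similarity from the interaction count between seed sets
  pp <- associationPairs(assoc)
  M <- matrix(0, nDomains, nPhenotypes, dimnames = list(ids, phen))
  M[cbind(match(pp$domain, ids), match(pp$phenotype, phen))] <- 1
  E <- 1 - exp(-(t(M) %*% A %*% M))
  sim <- .withSeed(.subSeed(seed, 3), {
    noise <- matrix(rnorm(nPhenotypes^2, sd = noiseSd), nPhenotypes)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- pmin(pmax(s * E + noise, 0), 1)
    dimnames(m) <- list(phen, phen)
    phenotypeSimilarity(round(m, 6))
  })

  plantedPairs <- associationPairs(assoc)
  if (!is.null(nPlantedPairs) && nPlantedPairs < nrow(plantedPairs)) {
    keep <- .withSeed(.subSeed(seed, 5),
                      sort(sample(nrow(plantedPairs), nPlantedPairs)))
    plantedPairs <- plantedPairs[keep, , drop = FALSE]
    rownames(plantedPairs) <- NULL
  }

  # loci: shuffle domains, tile across chromosomes with ~50 kb footprints
  loci <- .withSeed(.subSeed(seed, 6), {
    ord <- sample(ids)
    chrom <- rep(sprintf("chr%d", seq_len(nChromosomes)),
                 length.out = nDomains)
    perChrom <- table(chrom)[sprintf("chr%d", seq_len(nChromosomes))]
    starts <- numeric(nDomains)
    pos <- 1L
    for (ci in seq_len(nChromosomes)) {
      k <- as.integer(perChrom[ci])
      gap <- floor((chromosomeLengthBp - 6e4) / max(1, k))
      starts[pos:(pos + k - 1)] <- round(seq(1e4, by = gap,
                                             length.out = k))
      pos <- pos + k
    }
    domainLocusMap(chrom, starts, starts + 5e4, ord)
  })

  # SNPs: background uniform + planted within 1 Mbp of designated domains
  seedDomains <- unique(associationPairs(assoc)$domain)
  plantedSnpDomains <- .withSeed(.subSeed(seed, 7),
                                 sample(seedDomains,
                                        min(10, length(seedDomains))))
  snps <- .withSeed(.subSeed(seed, 8), {
    chromB <- sample(sprintf("chr%d", seq_len(nChromosomes)),
                     nBackgroundSnps, replace = TRUE)
    posB <- round(runif(nBackgroundSnps, 0, chromosomeLengthBp - 1))
    tgt <- loci[match(sample(plantedSnpDomains, nPlantedSnps,
                             replace = TRUE), loci$domain)]
    off <- round(runif(nPlantedSnps, -1e6, 1e6))
    posP <- pmax(0, GenomicRanges::start(tgt) - 1 + off)
    chromP <- as.character(GenomicRanges::seqnames(tgt))
    snpSet(c(chromB, chromP), c(posB, posP),
           sprintf("rs%06d", seq_len(nBackgroundSnps + nPlantedSnps)))
  })

  geneMap <- .withSeed(.subSeed(seed, 9), {
    genes <- sprintf("G%04d", seq_len(nDomains))
    rows <- lapply(seq_len(nDomains), function(i) {
      extra <- sample(ids, sample(0:2, 1))
      data.frame(gene = genes[i], domain = union(ids[i], extra),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  list(network = net, associations = assoc, similarity = sim, loci = loci,
       snps = snps, geneMap = geneMap, plantedPairs = plantedPairs,
       plantedSnpDomains = plantedSnpDomains,
       config = list(nDomains = nDomains, nPhenotypes = nPhenotypes,
                     networkModel = networkModel, meanDegree = meanDegree,
                     nPlantedPairs = nPlantedPairs,
                     signalStrength = signalStrength, noiseSd = noiseSd,
                     nChromosomes = nChromosomes,
                     chromosomeLengthBp = chromosomeLengthBp,
                     nBackgroundSnps = nBackgroundSnps,
                     nPlantedSnps = nPlantedSnps, seed = seed))
}

#' Write a scenario bundle as plain-text fixtures
#'
#' Emits every external format the readers consume: `edges.tsv`,
#' `associations.tsv`, `similarity.tsv` (square with id header),
#' `loci.bed`, `snps.bed`, `gene_map.tsv`. Writing, reading back with
#' [readInputBundle()] and writing again is byte-identical.
#'
#' @param bundle list from [simulateScenario()] (or [readInputBundle()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeFixtures <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(dir, "edges.tsv"),
    associations = file.path(dir, "associations.tsv"),
    similarity = file.path(dir, "similarity.tsv"),
    loci = file.path(dir, "loci.bed"),
    snps = file.path(dir, "snps.bed"),
    geneMap = file.path(dir, "gene_map.tsv"))
  writeEdgeList(bundle$network, paths["edges"])
  writeAssociations(bundle$associations, paths["associations"])
  writePhenotypeSimilarity(bundle$similarity, paths["similarity"])
  writeDomainLoci(bundle$loci, paths["loci"])
  writeSnps(bundle$snps, paths["snps"])
  write.table(bundle$geneMap, paths["geneMap"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
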