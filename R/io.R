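#' Read a gene-to-domain map from a two-column TSV (gene_id, domain_id)
#' @param path file path.
#' @return data.frame with columns `gene` and `domain`.
#' @export
readGeneDomainMap <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = "character", header = FALSE)
  if (ncol(tab) < 2) stop("gene map must have two columns: ", path)
  out <- data.frame(gene = tab[, 1], domain = tab[, 2],
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene)) || any(!nzchar(out$domain)))
    stop("empty identifier in gene map: ", path)
  out
}

#' Read and cross-validate a full input bundle
#'
#' Loads the fixture/file set produced by [writeFixtures()] (or compiled
#' externally in the same formats), validates all cross-references and
#' attaches a validation report. Associations whose domain is absent from
#' the network are retained - such domains simply contribute zero proximity
#' - but are listed in the report; associations whose phenotype is missing
#' from the similarity matrix are dropped.
#'
#' @param dir directory containing `edges.tsv`, `associations.tsv`,
#'   `similarity.tsv` and optionally `loci.bed`, `snps.bed`,
#'   `gene_map.tsv`; individual paths can be overridden.
#' @param edges,associations,similarity,loci,snps,geneMap explicit paths
#'   (override `dir`-derived defaults; loci/snps/geneMap may be absent).
#' @return list with the parsed objects plus a `report` list (unknown
#'   domains, dropped phenotypes, counts).
#' @export
readInputBundle <- function(dir = NULL,
                            edges = file.path(dir, "edges.tsv"),
                            associations = file.path(dir,
                                                     "associations.tsv"),
                            similarity = file.path(dir, "similarity.tsv"),
                            loci = file.path(dir, "loci.bed"),
                            snps = file.path(dir, "snps.bed"),
                            geneMap = file.path(dir, "gene_map.tsv")) {
  for (f in c(edges, associations, similarity))
    if (!file.exists(f)) stop("required input missing: ", f)
  net <- readEdgeList(edges)
  assoc <- readAssociations(associations)
  sim <- readPhenotypeSimilarity(similarity)
  unknownDomains <- sort(setdiff(unique(associationPairs(assoc)$domain),
                                 domainIds(net)))
  unknownPhen <- sort(setdiff(seedPhenotypes(assoc), phenotypeIds(sim)))
  if (length(unknownPhen) > 0) {
    keep <- associationPairs(assoc)$phenotype %in% phenotypeIds(sim)
    assoc <- new("AssociationSet",
                 pairs = associationPairs(assoc)[keep, , drop = FALSE])
  }
  if (length(seedPhenotypes(assoc)) == 0)
    stop("no phenotype is shared between associations and similarity")
  lociGr <- if (file.exists(loci)) readDomainLoci(loci) else NULL
  snpGr <- if (file.exists(snps)) readSnps(snps) else NULL
  gmap <- if (file.exists(geneMap)) readGeneDomainMap(geneMap) else NULL
  list(network = net, associations = assoc, similarity = sim,
       loci = lociGr, snps = snpGr, geneMap = gmap,
       report = list(
         unknownAssociationDomains = unknownDomains,
         droppedPhenotypes = unknownPhen,
         nDomains = numDomains(net),
         nAssociations = nrow(associationPairs(assoc)),
         nSeedPhenotypes = length(seedPhenotypes(assoc))))
}
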