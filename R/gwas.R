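#' Construct a domain locus map
#'
#' Genomic intervals occupied by domains, as a GRanges with a `domain`
#' metadata column. Coordinates are 1-based closed internally (GRanges
#' convention); the BED reader/writer converts from/to 0-based half-open.
#'
#' @param chrom,start,end,domain vectors describing the intervals; `start`
#'   and `end` are 0-based half-open (BED semantics), start < end.
#' @return GRanges with a `domain` column.
#' @export
domainLocusMap <- function(chrom, start, end, domain) {
  if (any(start >= end)) stop("locus start must be < end")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end))
  gr$domain <- as.character(domain)
  gr
}

#' Read domain loci from a BED file (chrom, start, end, domain_id)
#' @param path BED file path.
#' @return GRanges with a `domain` column.
#' @export
readDomainLoci <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character"))
  domainLocusMap(tab[, 1], tab[, 2], tab[, 3], tab[, 4])
}

#' Write domain loci as BED
#' @param loci GRanges with a `domain` column.
#' @param path output path.
#' @export
writeDomainLoci <- function(loci, path) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(loci)),
    start = GenomicRanges::start(loci) - 1,
    end = GenomicRanges::end(loci),
    name = loci$domain)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Construct a SNP set
#'
#' Reported susceptibility SNPs as width-1 GRanges with an `snp` metadata
#' column.
#'
#' @param chrom chromosome names.
#' @param pos 0-based positions.
#' @param snp unique SNP identifiers.
#' @return GRanges of width-1 positions with an `snp` column.
#' @export
snpSet <- function(chrom, pos, snp) {
  if (any(pos < 0)) stop("SNP positions must be >= 0")
  if (anyDuplicated(snp)) stop("duplicate SNP identifiers")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start = pos + 1, width = 1))
  gr$snp <- as.character(snp)
  gr
}

#' Read SNPs from a BED-like TSV (chrom, pos, pos+1, snp_id)
#' @param path file path.
#' @return GRanges with an `snp` column.
#' @export
readSnps <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                    colClasses = c("character", "numeric", "numeric",
                                   "character"))
  snpSet(tab[, 1], tab[, 2], tab[, 4])
}

#' Write SNPs as BED-like TSV
#' @param snps GRanges with an `snp` column.
#' @param path output path.
#' @export
writeSnps <- function(snps, path) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(snps)),
    start = GenomicRanges::start(snps) - 1,
    end = GenomicRanges::end(snps),
    name = snps$snp)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# SNP x domain incidence within windowBp (closed boundary), from locus
# boundaries; plus the SNP-locus distance for category breakdowns
.snpDomainHits <- function(snps, loci, windowBp) {
  win <- suppressWarnings(GenomicRanges::resize(
    loci, width = GenomicRanges::width(loci) + 2 * windowBp,
    fix = "center"))
  win <- GenomicRanges::trim(win)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snps, win))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::distance(snps[q], loci[s])
  # hits share a chromosome by construction, so pairwise range overlap
  # suffices for "inside"
  inside <- IRanges::poverlaps(GenomicRanges::ranges(snps[q]),
                               GenomicRanges::ranges(loci[s]))
  data.frame(snp = q, locus = s, domain = loci$domain[s],
             distance = dist, inside = as.logical(inside),
             stringsAsFactors = FALSE)
}

#' Count reported SNPs near a set of domains
#'
#' A SNP counts once toward the total if its distance to the nearest locus
#' boundary of any listed domain on the same chromosome is at most
#' `windowBp` (0 if inside; the boundary is closed, a SNP exactly
#' `windowBp` away counts). The per-domain breakdown counts SNP-domain
#' incidences - a SNP near several domains appears once per domain - in
#' three nested distance categories: inside a locus, within 1 Mbp, within
#' `windowBp`.
#'
#' @param snps GRanges of SNPs (see [snpSet()]).
#' @param domains character vector of domain ids to test.
#' @param loci GRanges domain locus map (see [domainLocusMap()]).
#' @param windowBp window in bp (default 5 Mbp).
#' @return list with `total` (SNP-level count) and `perDomain` (data.frame
#'   domain, inside, within1Mbp, withinWindow).
#' @export
countSnpsNearDomains <- function(snps, domains, loci, windowBp = 5e6) {
  if (windowBp <= 0) stop("windowBp must be > 0")
  missing <- setdiff(domains, unique(loci$domain))
  if (length(missing) > 0)
    warning("domain(s) without loci excluded: ",
            paste(missing, collapse = ", "))
  use <- loci[loci$domain %in% domains]
  if (length(use) == 0)
    return(list(total = 0L,
                perDomain = data.frame(domain = character(),
                                       inside = integer(),
                                       within1Mbp = integer(),
                                       withinWindow = integer())))
  h <- .snpDomainHits(snps, use, windowBp)
  perDom <- do.call(rbind, lapply(split(h, h$domain), function(g) {
    # one incidence per (snp, domain), at the smallest distance
    g <- g[order(g$distance), ]
    g <- g[!duplicated(g$snp), ]
    data.frame(domain = g$domain[1],
               inside = sum(g$inside),
               within1Mbp = sum(g$distance <= 1e6),
               withinWindow = sum(g$distance <= windowBp))
  }))
  if (is.null(perDom))
    perDom <- data.frame(domain = character(), inside = integer(),
                         within1Mbp = integer(), withinWindow = integer())
  rownames(perDom) <- NULL
  list(total = length(unique(h$snp)), perDomain = perDom)
}

#' SNP-proximity permutation test for top-ranked domains
#'
#' Tests whether reported susceptibility SNPs are enriched near the
#' top-ranked domains of a genome-wide inference: (1) count the SNPs within
#' `windowBp` of the `topK` top-ranked domains (N0); (2) for each of `M`
#' permutations draw `topK` domains uniformly without replacement from the
#' candidate universe and count again (Ni); (3) the p-value is the fraction
#' of permutations with Ni >= N0 (p = m/M, no continuity correction).
#'
#' @param rankedDomains character vector of domains in rank order (best
#'   first).
#' @param snps GRanges of reported SNPs.
#' @param loci GRanges domain locus map.
#' @param universe candidate pool the permutations draw from (default: all
#'   domains with loci).
#' @param topK number of top domains tested (default 10).
#' @param M number of permutations (default 10000).
#' @param windowBp proximity window (default 5 Mbp).
#' @param seed integer seed.
#' @return An [EnrichmentResult-class].
#' @export
snpEnrichmentTest <- function(rankedDomains, snps, loci,
                              universe = unique(loci$domain), topK = 10,
                              M = 10000, windowBp = 5e6, seed = 1) {
  if (M < 1) stop("M must be >= 1")
  if (topK > length(universe)) stop("topK exceeds the universe size")
  top <- head(rankedDomains, topK)
  obs <- countSnpsNearDomains(snps, top, loci, windowBp)
  # incidence matrix once, over the universe, for fast permutation counts
  uloci <- loci[loci$domain %in% universe]
  h <- .snpDomainHits(snps, uloci, windowBp)
  doms <- sort(unique(uloci$domain))
  inc <- matrix(FALSE, length(snps), length(doms),
                dimnames = list(NULL, doms))
  if (nrow(h) > 0)
    inc[cbind(h$snp, match(h$domain, doms))] <- TRUE
  counts <- .withSeed(seed, {
    vapply(seq_len(M), function(i) {
      pick <- sample(universe, topK)
      pick <- intersect(pick, doms)
      if (length(pick) == 0) return(0L)
      sum(rowSums(inc[, pick, drop = FALSE]) > 0)
    }, integer(1))
  })
  m <- sum(counts >= obs$total)
  new("EnrichmentResult", n0 = as.integer(obs$total), pValue = m / M,
      m = as.integer(m), M = as.integer(M), perDomain = obs$perDomain)
}

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(paste0("EnrichmentResult: N0 = %d SNPs near top domains\n",
                     "  p = %g (m = %d of M = %d permutations)\n"),
              object@n0, object@pValue, object@m, object@M))
})

#' @describeIn snpEnrichmentTest Permutation p-value of a result.
#' @param object an [EnrichmentResult-class].
#' @export
enrichmentPValue <- function(object) object@pValue
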