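#' Construct a set of domain-phenotype associations
#'
#' @param domain,phenotype character vectors of equal length; duplicated
#'   pairs are merged.
#' @return An [AssociationSet-class].
#' @export
associationSet <- function(domain, phenotype) {
  p <- data.frame(domain = as.character(domain),
                  phenotype = as.character(phenotype),
                  stringsAsFactors = FALSE)
  p <- p[!duplicated(paste(p$domain, p$phenotype, sep = "\r")), , drop = FALSE]
  p <- p[order(p$phenotype, p$domain), , drop = FALSE]
  rownames(p) <- NULL
  new("AssociationSet", pairs = p)
}

#' Read associations from a two-column TSV (domain, phenotype)
#' @param path file path.
#' @return An [AssociationSet-class].
#' @export
readAssociations <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = "character", header = FALSE)
  if (ncol(tab) < 2) stop("association table must have two columns: ", path)
  associationSet(tab[, 1], tab[, 2])
}

#' Write associations as a two-column TSV
#' @param assoc an [AssociationSet-class].
#' @param path output file path.
#' @export
writeAssociations <- function(assoc, path) {
  write.table(assoc@pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn associationSet The association pairs as a data.frame.
#' @param assoc an [AssociationSet-class].
#' @export
associationPairs <- function(assoc) assoc@pairs

#' @describeIn associationSet Seed phenotypes p_1..p_m (phenotypes with at
#'   least one associated domain), in sorted order.
#' @export
seedPhenotypes <- function(assoc) sort(unique(assoc@pairs$phenotype))

#' @describeIn associationSet Set of domains D(p) associated with phenotype
#'   `p`.
#' @param p phenotype id.
#' @export
domainsOf <- function(assoc, p) {
  assoc@pairs$domain[assoc@pairs$phenotype == p]
}

setMethod("show", "AssociationSet", function(object) {
  cat("AssociationSet:", nrow(object@pairs), "associations between",
      length(unique(object@pairs$domain)), "domains and",
      length(unique(object@pairs$phenotype)), "phenotypes\n")
})

#' Construct a phenotype similarity matrix
#'
#' @param values square numeric matrix in \[0,1\] with phenotype ids as
#'   dimnames; symmetrized by the elementwise maximum, diagonal forced to 1.
#' @return A [PhenotypeSimilarity-class].
#' @export
phenotypeSimilarity <- function(values) {
  v <- as.matrix(values)
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("similarity out of [0,1]")
  v <- pmax(v, t(v))
  diag(v) <- 1
  new("PhenotypeSimilarity", values = v)
}

#' Read a phenotype similarity matrix from TSV
#'
#' Accepts either a square matrix with a header row/column of phenotype ids,
#' or a 3-column long form (id, id, score) which is symmetrized by the
#' maximum; missing long-form pairs default to 0.
#'
#' @param path file path.
#' @return A [PhenotypeSimilarity-class].
#' @export
readPhenotypeSimilarity <- function(path) {
  first <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                      nrows = 1, colClasses = "character")
  if (ncol(first) == 3 && !is.na(suppressWarnings(as.numeric(first[1, 3])))) {
    tab <- read.table(path, sep = "\t", comment.char = "#", header = FALSE,
                      colClasses = c("character", "character", "numeric"))
    ids <- sort(unique(c(tab[, 1], tab[, 2])))
    v <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    v[cbind(match(tab[, 1], ids), match(tab[, 2], ids))] <- tab[, 3]
    return(phenotypeSimilarity(v))
  }
  tab <- read.table(path, sep = "\t", comment.char = "#", header = TRUE,
                    row.names = 1, check.names = FALSE)
  phenotypeSimilarity(as.matrix(tab))
}

#' Write a phenotype similarity matrix as a square TSV with id headers
#' @param sim a [PhenotypeSimilarity-class].
#' @param path output file path.
#' @export
writePhenotypeSimilarity <- function(sim, path) {
  v <- sim@values
  out <- data.frame(id = rownames(v), v, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn phenotypeSimilarity Similarity values matrix.
#' @param sim a [PhenotypeSimilarity-class].
#' @export
similarityValues <- function(sim) sim@values

#' @describeIn phenotypeSimilarity Phenotype ids.
#' @export
phenotypeIds <- function(sim) rownames(sim@values)

setMethod("show", "PhenotypeSimilarity", function(object) {
  cat("PhenotypeSimilarity over", nrow(object@values), "phenotypes\n")
})

#' Proximity between a domain and a phenotype
#'
#' The proximity x_dp of a candidate domain d to a phenotype p is the sum of
#' kernel proximities between d and every domain known to be associated with
#' p. Associated domains absent from the network contribute 0.
#'
#' @param d domain id (must be a network domain present in `prox`).
#' @param p phenotype id (must be a seed phenotype of `assoc`).
#' @param prox a [ProximityMatrix-class].
#' @param assoc an [AssociationSet-class].
#' @return nonnegative scalar.
#' @export
domainPhenotypeProximity <- function(d, p, prox, assoc) {
  v <- proximityValues(prox)
  if (!d %in% rownames(v)) stop("domain not in network: ", d)
  if (!p %in% seedPhenotypes(assoc)) stop("not a seed phenotype: ", p)
  dp <- intersect(domainsOf(assoc, p), colnames(v))
  sum(v[d, dp])
}

# membership matrix (network domains x seed phenotypes) of an association
# set restricted to a phenotype index; entry 1 iff domain in D(p)
.membershipMatrix <- function(assoc, networkIds, phenIndex) {
  pairs <- assoc@pairs
  pairs <- pairs[pairs$phenotype %in% phenIndex &
                 pairs$domain %in% networkIds, , drop = FALSE]
  M <- matrix(0, length(networkIds), length(phenIndex),
              dimnames = list(networkIds, phenIndex))
  if (nrow(pairs) > 0)
    M[cbind(match(pairs$domain, networkIds),
            match(pairs$phenotype, phenIndex))] <- 1
  M
}

# drop excluded pairs and return the surviving association set
.excludePairs <- function(assoc, excludePairs) {
  if (is.null(excludePairs) || nrow(excludePairs) == 0) return(assoc)
  key <- paste(assoc@pairs$domain, assoc@pairs$phenotype, sep = "\r")
  drop <- key %in% paste(excludePairs[[1]], excludePairs[[2]], sep = "\r")
  new("AssociationSet", pairs = assoc@pairs[!drop, , drop = FALSE])
}

#' Domain proximity profile
#'
#' The predictor of the regression: for a candidate domain d, the vector of
#' proximities x_dp over the seed phenotypes. `excludePairs` removes
#' associations before the profile is built (the held-out pair in
#' cross-validation, or all pairs of the query phenotype in ab initio mode);
#' phenotypes left without any associated domain are dropped from the index.
#'
#' @param d domain id.
#' @param assoc an [AssociationSet-class].
#' @param prox a [ProximityMatrix-class].
#' @param excludePairs NULL or a 2-column data.frame (domain, phenotype) of
#'   associations to treat as unknown; must be a subset of the known pairs.
#' @return named numeric vector over the surviving seed phenotypes.
#' @export
proximityProfile <- function(d, assoc, prox, excludePairs = NULL) {
  v <- proximityValues(prox)
  if (!d %in% rownames(v)) stop("domain not in network: ", d)
  reduced <- .excludePairs(assoc, excludePairs)
  idx <- seedPhenotypes(reduced)
  if (length(idx) < 3) stop("insufficient seed phenotypes")
  M <- .membershipMatrix(reduced, colnames(v), idx)
  drop(v[d, , drop = FALSE] %*% M)[idx]
}

#' Phenotype similarity profile
#'
#' The response of the regression: similarity scores between the query
#' phenotype and the seed phenotypes. When the query is itself a seed
#' phenotype it is omitted by default (`excludeQuery = TRUE`), since its
#' self-similarity of 1 would leak the answer into the response.
#'
#' @param p query phenotype id (must be in the similarity matrix).
#' @param sim a [PhenotypeSimilarity-class].
#' @param assoc an [AssociationSet-class] defining the seed phenotypes.
#' @param excludeQuery drop the query itself from the profile index.
#' @return named numeric vector over seed phenotypes (present in `sim`).
#' @export
similarityProfile <- function(p, sim, assoc, excludeQuery = TRUE) {
  v <- similarityValues(sim)
  if (!p %in% rownames(v)) stop("phenotype not in similarity matrix: ", p)
  idx <- intersect(seedPhenotypes(assoc), rownames(v))
  if (excludeQuery) idx <- setdiff(idx, p)
  v[p, idx]
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles of their plotting positions:
#' z_i = Phi^-1((r_i - c) / (m - 2c + 1)) with r_i the ascending rank (ties
#' averaged), m the vector length and c the offset of `transform`. The
#' output is a monotone function of the input ranks.
#'
#' @param values numeric vector, length >= 3, not constant.
#' @param transform a [RankTransform-class]; default Blom offset c = 3/8.
#' @return numeric vector of normal scores (names preserved).
#' @examples
#' inverseNormalTransform(c(0.2, 0.5, 0.9))
#' @export
inverseNormalTransform <- function(values, transform = new("RankTransform")) {
  if (length(values) < 3) stop("profile too short (need >= 3 values)")
  if (max(values) - min(values) <= 0) stop("degenerate response (constant)")
  c0 <- transform@offset
  r <- rank(values, ties.method = "average")
  z <- qnorm((r - c0) / (length(values) - 2 * c0 + 1))
  names(z) <- names(values)
  z
}

#' Permutation nulls for the association set
#'
#' Destroys the domain-phenotype relationship while preserving every
#' phenotype's number of associated domains. `mode = "permute"` redistributes
#' the existing multiset of domains over the pair list; `mode =
#' "random_replace"` replaces each associated domain by one drawn uniformly
#' from `allDomains`. Duplicate pairs within a phenotype are repaired so the
#' per-phenotype counts are preserved exactly. Deterministic given `seed`.
#'
#' @param assoc an [AssociationSet-class].
#' @param allDomains candidate pool for `random_replace`.
#' @param mode `"permute"` or `"random_replace"`.
#' @param seed integer seed.
#' @return A shuffled [AssociationSet-class].
#' @export
shuffleAssociations <- function(assoc, allDomains,
                                mode = c("permute", "random_replace"), seed) {
  mode <- match.arg(mode)
  if (length(allDomains) == 0) stop("allDomains must be nonempty")
  pairs <- assoc@pairs
  .withSeed(seed, {
    n <- nrow(pairs)
    dom <- if (mode == "permute") sample(pairs$domain) else
      sample(allDomains, n, replace = TRUE)
    # repair collisions: a phenotype may not receive the same domain twice
    for (tries in 1:200) {
      key <- paste(dom, pairs$phenotype, sep = "\r")
      bad <- which(duplicated(key))
      if (length(bad) == 0) break
      if (mode == "permute") {
        swap <- sample(n, length(bad), replace = TRUE)
        tmp <- dom[bad]; dom[bad] <- dom[swap]; dom[swap] <- tmp
      } else {
        dom[bad] <- sample(allDomains, length(bad), replace = TRUE)
      }
    }
    key <- paste(dom, pairs$phenotype, sep = "\r")
    if (any(duplicated(key)))
      warning("could not fully repair duplicate pairs after shuffling")
    out <- pairs
    out$domain <- dom
    out <- out[!duplicated(paste(out$domain, out$phenotype, sep = "\r")), ,
               drop = FALSE]
    out <- out[order(out$phenotype, out$domain), , drop = FALSE]
    rownames(out) <- NULL
    new("AssociationSet", pairs = out)
  })
}

#' Permute a similarity profile
#'
#' Destroys the disease-disease relationship by permuting the response
#' values uniformly at random over the profile index, preserving the value
#' multiset. Deterministic given `seed`.
#'
#' @param values named numeric profile vector, length >= 2.
#' @param seed integer seed.
#' @return numeric vector with the original names and permuted values.
#' @export
shuffleProfile <- function(values, seed) {
  if (length(values) < 2) stop("profile must have length >= 2")
  .withSeed(seed, {
    out <- sample(unname(values))
    names(out) <- names(values)
    out
  })
}
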