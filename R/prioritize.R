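#' Score and rank candidate domains for a query phenotype
#'
#' Builds the query's similarity profile once (inverse-normal transformed
#' once), computes one Bayes factor per candidate domain against it, and
#' ranks candidates by descending log10 Bayes factor (ties receive averaged
#' ranks). `mode` controls which known associations are treated as unknown
#' while building the proximity profiles: none (`"plain"`), one held-out
#' pair (`"loo_pair"`, give `heldOut`), or every association of the query
#' phenotype (`"ab_initio"`).
#'
#' @param p query phenotype id.
#' @param candidates character vector of candidate domain ids (must be in
#'   the proximity matrix).
#' @param assoc an [AssociationSet-class].
#' @param prox a [ProximityMatrix-class].
#' @param sim a [PhenotypeSimilarity-class].
#' @param mode `"plain"`, `"loo_pair"` or `"ab_initio"`.
#' @param heldOut for `mode = "loo_pair"`: length-2 character vector
#'   (domain, phenotype) naming the association assumed unknown.
#' @param transform a [RankTransform-class].
#' @param priors a [RegressionPriors-class].
#' @param excludeQuery drop the query phenotype from the profile index when
#'   it is itself a seed phenotype (avoids self-similarity leakage).
#' @param statistic rank candidates by `"bf"` (default) or by the
#'   non-Bayesian `"r2"` baseline.
#' @param standardize rescale each candidate's proximity profile to unit
#'   variance inside the regression (default TRUE), so that the slope
#'   prior compares profile shapes rather than raw kernel amplitudes; see
#'   [bayesFactor()].
#' @return data.frame with columns domain, log10bf, rSquared, rank,
#'   rankRatio, sorted by decreasing score; attributes `phenotype`, `mode`
#'   and `profileLength`.
#' @export
scoreCandidates <- function(p, candidates, assoc, prox, sim,
                            mode = c("plain", "loo_pair", "ab_initio"),
                            heldOut = NULL,
                            transform = new("RankTransform"),
                            priors = regressionPriors(),
                            excludeQuery = TRUE,
                            statistic = c("bf", "r2"),
                            standardize = TRUE) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  v <- proximityValues(prox)
  if (!all(candidates %in% rownames(v)))
    stop("candidate domain not in network")
  excl <- switch(mode,
    plain = NULL,
    loo_pair = {
      if (is.null(heldOut) || length(heldOut) != 2)
        stop("mode 'loo_pair' needs heldOut = c(domain, phenotype)")
      data.frame(domain = heldOut[1], phenotype = heldOut[2])
    },
    ab_initio = data.frame(
      domain = domainsOf(assoc, p),
      phenotype = rep(p, length(domainsOf(assoc, p)))))
  reduced <- .excludePairs(assoc, excl)
  idx <- intersect(seedPhenotypes(reduced), phenotypeIds(sim))
  if (excludeQuery) idx <- setdiff(idx, p)
  if (length(idx) < 3) stop("insufficient seed phenotypes")
  y <- similarityValues(sim)[p, idx]
  yt <- inverseNormalTransform(y, transform)
  .rankCandidates(p, candidates, reduced, v, yt, idx, priors, mode,
                  statistic, standardize)
}

# shared scoring core: builds the candidate x phenotype predictor matrix by
# one matrix product and evaluates all Bayes factors vectorized
.rankCandidates <- function(p, candidates, reducedAssoc, v, yt, idx, priors,
                            mode, statistic = "bf", standardize = TRUE) {
  M <- .membershipMatrix(reducedAssoc, colnames(v), idx)
  X <- v[candidates, , drop = FALSE] %*% M   # candidates x m
  if (.isLimitPriors(priors)) {
    l10 <- .log10bfLimit(yt, t(X), priors@sigma1Sq, standardize)
  } else {
    l10 <- vapply(seq_along(candidates), function(i)
      bayesFactor(yt, X[i, ], priors,
                  standardize = standardize)@log10bf, numeric(1))
  }
  ytc <- yt - mean(yt)
  xc <- X - rowMeans(X)
  sdx <- sqrt(rowSums(xc^2))
  r2 <- ifelse(sdx > 0,
               (as.vector(xc %*% ytc) / (sdx * sqrt(sum(ytc^2))))^2, 0)
  score <- if (statistic == "bf") l10 else r2
  rk <- rank(-score, ties.method = "average")
  out <- data.frame(domain = candidates, log10bf = l10, rSquared = r2,
                    rank = rk, rankRatio = rk / length(candidates),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- p
  attr(out, "mode") <- mode
  attr(out, "profileLength") <- length(yt)
  out
}

#' Aggregate domain Bayes factors to gene scores
#'
#' A gene's association score for a query phenotype is the maximum log10
#' Bayes factor over the domains contained in its protein products. Genes
#' none of whose domains were scored are dropped with a warning.
#'
#' @param geneMap data.frame with character columns `gene` and `domain`
#'   (see [readGeneDomainMap()]).
#' @param domainBfs named numeric vector of log10 Bayes factors by domain.
#' @return data.frame (gene, score, rank) sorted by decreasing score.
#' @export
geneScores <- function(geneMap, domainBfs) {
  stopifnot(all(c("gene", "domain") %in% colnames(geneMap)))
  known <- geneMap[geneMap$domain %in% names(domainBfs), , drop = FALSE]
  dropped <- setdiff(unique(geneMap$gene), unique(known$gene))
  if (length(unique(known$gene)) == 0)
    stop("no gene has a scored domain")
  if (length(dropped) > 0)
    warning(length(dropped), " gene(s) without scored domains dropped")
  sc <- tapply(domainBfs[known$domain], known$gene, max)
  out <- data.frame(gene = names(sc), score = as.numeric(sc),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$score, ties.method = "average")
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genome-wide landscape of domain-phenotype Bayes factors
#'
#' Computes the full matrix of log10 Bayes factors for every (phenotype,
#' domain) combination, in chunks of phenotypes with optional progress
#' messages. Scoring uses all known associations (`"plain"` mode) by
#' default; `"ab_initio"` excludes each query phenotype's own seeds.
#'
#' @param phenotypes phenotype ids (rows).
#' @param domains domain ids (columns).
#' @inheritParams scoreCandidates
#' @param chunkSize number of phenotypes per chunk.
#' @param checkpointDir optional directory; each finished chunk is written
#'   there as a TSV so long runs can be resumed by rerunning (existing chunk
#'   files are reloaded, not recomputed).
#' @param progress emit a message per chunk.
#' @return numeric matrix (phenotype x domain) of log10 Bayes factors.
#' @seealso [filterLandscape()] for the export filter.
#' @export
bfLandscape <- function(phenotypes, domains, assoc, prox, sim,
                        mode = c("plain", "ab_initio"),
                        transform = new("RankTransform"),
                        priors = regressionPriors(),
                        excludeQuery = TRUE, chunkSize = 50,
                        checkpointDir = NULL, progress = FALSE) {
  mode <- match.arg(mode)
  out <- matrix(NA_real_, length(phenotypes), length(domains),
                dimnames = list(phenotypes, domains))
  chunks <- split(phenotypes,
                  ceiling(seq_along(phenotypes) / chunkSize))
  for (ci in seq_along(chunks)) {
    ckfile <- if (!is.null(checkpointDir))
      file.path(checkpointDir, sprintf("landscape_chunk_%04d.tsv", ci))
    if (!is.null(ckfile) && file.exists(ckfile)) {
      got <- as.matrix(read.table(ckfile, sep = "\t", header = TRUE,
                                  row.names = 1, check.names = FALSE))
      out[rownames(got), colnames(got)] <- got
      next
    }
    for (p in chunks[[ci]]) {
      sc <- scoreCandidates(p, domains, assoc, prox, sim, mode = mode,
                            transform = transform, priors = priors,
                            excludeQuery = excludeQuery)
      out[p, sc$domain] <- sc$log10bf
    }
    if (!is.null(ckfile)) {
      dir.create(dirname(ckfile), showWarnings = FALSE, recursive = TRUE)
      write.table(out[chunks[[ci]], , drop = FALSE], ckfile, sep = "\t",
                  quote = FALSE, col.names = NA)
    }
    if (progress)
      message("landscape chunk ", ci, "/", length(chunks), " done")
  }
  out
}

#' Export filter for the landscape matrix
#'
#' Drops the rows of a log10 Bayes-factor matrix in which every value is
#' smaller than the threshold (default 0.1), the filter applied before
#' clustering/export of the genome-wide landscape. Apply to `t(landscape)`
#' to filter domains instead of phenotypes.
#'
#' @param mat numeric matrix of log10 Bayes factors.
#' @param threshold keep rows with at least one value >= threshold.
#' @return the filtered matrix (possibly with zero rows).
#' @export
filterLandscape <- function(mat, threshold = 0.1) {
  keep <- apply(mat, 1, function(r) any(r >= threshold))
  mat[keep, , drop = FALSE]
}

#' Write a candidate ranking as TSV
#'
#' @param ranking data.frame from [scoreCandidates()].
#' @param path output file path.
#' @export
writeRanking <- function(ranking, path) {
  out <- cbind(phenotype = attr(ranking, "phenotype"), ranking)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
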