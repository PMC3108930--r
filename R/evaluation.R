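#' Precision of a set of validation runs
#'
#' A prediction is successful only when the true disease domain's (tie-
#' averaged) rank equals exactly 1; tied-top candidates count as failures.
#'
#' @param ranks numeric vector of the true domains' ranks across runs.
#' @return percent of successful runs.
#' @export
precisionFromRanks <- function(ranks) 100 * mean(ranks == 1)

#' Mean rank ratio of true disease domains
#'
#' @param rankRatios numeric vector of rank ratios in (0, 1].
#' @return mean rank ratio in percent.
#' @export
meanRankRatio <- function(rankRatios) 100 * mean(rankRatios)

#' AUC from disease and control rank ratios
#'
#' Area under the ROC obtained by sweeping a rank-ratio threshold:
#' sensitivity is the fraction of disease domains ranked above (i.e. with a
#' rank ratio below) the threshold, specificity the fraction of controls
#' ranked below it. Equals the Mann-Whitney statistic
#' P(disease < control) + P(tie)/2, computed by midranks.
#'
#' @param diseaseRR rank ratios of true disease domains (nonempty).
#' @param controlRR rank ratios of control domains (nonempty).
#' @return AUC in percent.
#' @examples
#' aucFromRankRatios(c(0.2, 0.6), c(0.4, 0.8))  # 75
#' @export
aucFromRankRatios <- function(diseaseRR, controlRR) {
  nd <- length(diseaseRR); nc <- length(controlRR)
  if (nd == 0 || nc == 0) stop("empty rank-ratio list")
  r <- rank(c(diseaseRR, controlRR), ties.method = "average")
  u <- sum(r[seq_len(nd)]) - nd * (nd + 1) / 2   # pairs disease > control
  100 * (1 - u / (nd * nc))
}

#' Fold enrichment b/a
#'
#' For a method that ranks true entities among the top a percent of
#' candidates in b percent of validation runs, the fold enrichment is b/a.
#'
#' @param bPercent percent of runs reaching the rank band.
#' @param aPercent the rank band as a percent of candidates; must be > 0.
#' @return fold enrichment.
#' @export
foldEnrichment <- function(bPercent, aPercent) {
  if (aPercent <= 0) stop("undefined enrichment")
  bPercent / aPercent
}

#' Leave-one-out cross-validation of domain prioritization
#'
#' For every known (domain, phenotype) association in turn, assumes the
#' association unknown, scores the true domain against a protocol-dependent
#' candidate set, and records its rank. Protocols:
#' \describe{
#'   \item{random_control}{true domain plus `nControls` domains drawn
#'     without replacement from the network, excluding the true domain and
#'     the phenotype's other known domains.}
#'   \item{linkage_interval}{true domain plus every domain with a locus
#'     within `windowBp` of any of the true domain's loci on the same
#'     chromosome (requires `loci`).}
#'   \item{genome_wide}{all network domains.}
#' }
#' `mode = "loo_pair"` hides only the evaluated association;
#' `mode = "ab_initio"` hides all associations of the query phenotype.
#'
#' @param assoc an [AssociationSet-class].
#' @param prox a [ProximityMatrix-class].
#' @param sim a [PhenotypeSimilarity-class].
#' @param protocol candidate-set protocol, see Details.
#' @param nControls number of random controls (default 99).
#' @param windowBp linkage-interval half-width in bp (default 10 Mbp).
#' @param seed integer seed driving all random draws.
#' @param mode `"loo_pair"` or `"ab_initio"`.
#' @param loci GRanges of domain loci with a `domain` metadata column
#'   (required for `linkage_interval`).
#' @param transform a [RankTransform-class].
#' @param priors a [RegressionPriors-class].
#' @param statistic rank candidates by `"bf"` or the `"r2"` baseline.
#' @param standardize rescale proximity profiles to unit variance inside
#'   the regression (default TRUE); see [bayesFactor()].
#' @param excludeQuery drop the query phenotype from the profile index.
#' @param pairs optional data.frame (domain, phenotype) restricting the
#'   evaluated associations (default: all known pairs).
#' @param seedFraction fraction of the remaining known associations kept
#'   (sampled per run) when building profiles; 1 keeps all.
#' @param similarityTopFraction keep only this top fraction of seed
#'   phenotypes, by similarity to the query; 1 keeps all.
#' @param shuffleSimilarity permute each run's similarity profile (the
#'   phenotype-similarity permutation null).
#' @return An [EvaluationSummary-class].
#' @export
runLOOCV <- function(assoc, prox, sim,
                     protocol = c("random_control", "linkage_interval",
                                  "genome_wide"),
                     nControls = 99, windowBp = 1e7, seed = 1,
                     mode = c("loo_pair", "ab_initio"), loci = NULL,
                     transform = new("RankTransform"),
                     priors = regressionPriors(),
                     statistic = c("bf", "r2"), excludeQuery = TRUE,
                     standardize = TRUE,
                     pairs = NULL, seedFraction = 1,
                     similarityTopFraction = 1,
                     shuffleSimilarity = FALSE) {
  protocol <- match.arg(protocol)
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  if (protocol == "linkage_interval" && is.null(loci))
    stop("protocol 'linkage_interval' requires domain loci")
  v <- proximityValues(prox)
  netIds <- rownames(v)
  simIds <- phenotypeIds(sim)
  allPairs <- associationPairs(assoc)
  if (is.null(pairs)) pairs <- allPairs
  pairs <- pairs[pairs$domain %in% netIds & pairs$phenotype %in% simIds, ,
                 drop = FALSE]
  ranks <- numeric(0); rrs <- numeric(0); ctrl <- numeric(0)
  rows <- vector("list", nrow(pairs))
  nSkipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$domain[i]; p <- pairs$phenotype[i]
    runSeed <- .subSeed(seed, i)
    excl <- if (mode == "loo_pair")
      data.frame(domain = d, phenotype = p)
    else data.frame(domain = domainsOf(assoc, p),
                    phenotype = rep(p, length(domainsOf(assoc, p))))
    reduced <- .excludePairs(assoc, excl)
    if (seedFraction < 1) {
      keep <- .withSeed(.subSeed(runSeed, 7), {
        n <- nrow(reduced@pairs)
        sort(sample(n, max(3, round(seedFraction * n))))
      })
      reduced <- new("AssociationSet",
                     pairs = reduced@pairs[keep, , drop = FALSE])
    }
    idx <- intersect(seedPhenotypes(reduced), simIds)
    if (excludeQuery) idx <- setdiff(idx, p)
    if (length(idx) < 3) { nSkipped <- nSkipped + 1L; next }
    y <- similarityValues(sim)[p, idx]
    if (similarityTopFraction < 1) {
      kTop <- max(3, round(similarityTopFraction * length(idx)))
      idx <- idx[order(y, decreasing = TRUE)[seq_len(kTop)]]
      y <- similarityValues(sim)[p, idx]
    }
    if (shuffleSimilarity) y <- shuffleProfile(y, .subSeed(runSeed, 13))
    yt <- tryCatch(inverseNormalTransform(y, transform),
                   error = function(e) NULL)
    if (is.null(yt)) { nSkipped <- nSkipped + 1L; next }
    cand <- switch(protocol,
      random_control = {
        pool <- setdiff(netIds, c(d, domainsOf(assoc, p)))
        picks <- .withSeed(.subSeed(runSeed, 3),
                           sample(pool, min(nControls, length(pool))))
        c(d, picks)
      },
      linkage_interval = {
        near <- .domainsNear(d, loci, windowBp)
        c(d, setdiff(intersect(near, netIds), d))
      },
      genome_wide = netIds)
    if (length(cand) < 2) {
      warning("run skipped (fewer than 2 candidates): ", d, " / ", p)
      nSkipped <- nSkipped + 1L
      next
    }
    sc <- .rankCandidates(p, cand, reduced, v, yt, idx, priors, mode,
                          statistic, standardize)
    hit <- sc[sc$domain == d, ]
    ranks <- c(ranks, hit$rank)
    rrs <- c(rrs, hit$rankRatio)
    ctrl <- c(ctrl, sc$rankRatio[sc$domain != d])
    rows[[i]] <- data.frame(domain = d, phenotype = p,
                            nCandidates = length(cand), rank = hit$rank,
                            rankRatio = hit$rankRatio,
                            stringsAsFactors = FALSE)
  }
  perRun <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(perRun))
    perRun <- data.frame(domain = character(), phenotype = character(),
                         nCandidates = integer(), rank = numeric(),
                         rankRatio = numeric())
  new("EvaluationSummary",
      precision = precisionFromRanks(ranks),
      meanRankRatio = meanRankRatio(rrs),
      auc = aucFromRankRatios(rrs, ctrl),
      perRun = perRun, controlRankRatios = ctrl, nSkipped = nSkipped)
}

# domains with any locus within windowBp of any locus of `d` on the same
# chromosome (distance between interval boundaries; 0 if overlapping)
.domainsNear <- function(d, loci, windowBp) {
  own <- loci[loci$domain == d]
  if (length(own) == 0) return(character(0))
  win <- suppressWarnings(GenomicRanges::resize(
    own, width = GenomicRanges::width(own) + 2 * windowBp, fix = "center"))
  win <- GenomicRanges::trim(win)
  hits <- GenomicRanges::findOverlaps(win, loci)
  unique(loci$domain[S4Vectors::subjectHits(hits)])
}

setMethod("show", "EvaluationSummary", function(object) {
  cat(sprintf(paste0("EvaluationSummary: %d runs (%d skipped)\n",
                     "  precision      %6.2f %%\n",
                     "  mean rank ratio%6.2f %%\n",
                     "  AUC            %6.2f %%\n"),
              nrow(object@perRun), object@nSkipped, object@precision,
              object@meanRankRatio, object@auc))
})

#' @describeIn runLOOCV Accessors for the summary criteria (percent).
#' @param object an [EvaluationSummary-class].
#' @export
precisionOf <- function(object) object@precision

#' @describeIn runLOOCV Mean rank ratio (percent).
#' @export
meanRankRatioOf <- function(object) object@meanRankRatio

#' @describeIn runLOOCV Pooled AUC (percent).
#' @export
aucOf <- function(object) object@auc

#' @describeIn runLOOCV Per-run rank table.
#' @export
perRunResults <- function(object) object@perRun

#' Permutation-null robustness suite
#'
#' Destroys exactly one layer of the data's connectivity and reruns the
#' cross-validation: `"shuffle_network"` rewires the domain network
#' degree-preservingly and recomputes the kernel, `"shuffle_associations"`
#' permutes the domain-phenotype associations keeping each phenotype's
#' count (or replaces domains at random with `assocMode = "random_replace"`),
#' and `"shuffle_similarity"` permutes each query's similarity profile.
#' With informative structure removed the expected AUC is about 50 percent.
#'
#' @param assoc an [AssociationSet-class].
#' @param net the [DomainNetwork-class] underlying the kernel.
#' @param sim a [PhenotypeSimilarity-class].
#' @param which which null to apply.
#' @param seed integer seed (drives both the shuffle and the validation).
#' @param kernelKind `"DK"` or `"SG"` (kernel recomputed after a network
#'   shuffle and used throughout).
#' @param kernelParam gamma for DK, beta for SG.
#' @param assocMode shuffle flavour for `"shuffle_associations"`.
#' @param nReplicates number of independent shuffle replicates; the
#'   summary pools all replicates' rank ratios, sharpening the estimate of
#'   the null's operating characteristics.
#' @param ... further arguments passed to [runLOOCV()] (protocol,
#'   nControls, priors, ...).
#' @return An [EvaluationSummary-class] (pooled over replicates).
#' @export
robustnessSuite <- function(assoc, net, sim,
                            which = c("shuffle_network",
                                      "shuffle_associations",
                                      "shuffle_similarity"),
                            seed = 1, kernelKind = c("DK", "SG"),
                            kernelParam = NULL,
                            assocMode = c("permute", "random_replace"),
                            nReplicates = 1, ...) {
  which <- match.arg(which)
  kernelKind <- match.arg(kernelKind)
  assocMode <- match.arg(assocMode)
  if (is.null(kernelParam))
    kernelParam <- if (kernelKind == "DK") 0.05 else 1
  reps <- lapply(seq_len(nReplicates), function(r) {
    repSeed <- if (r == 1) seed else .subSeed(seed, 1000 + r)
    useNet <- net
    useAssoc <- assoc
    shuffleSim <- FALSE
    if (which == "shuffle_network")
      useNet <- shuffleNetwork(net, seed = .subSeed(repSeed, 101))
    if (which == "shuffle_associations")
      useAssoc <- shuffleAssociations(assoc, domainIds(net),
                                      mode = assocMode,
                                      seed = .subSeed(repSeed, 102))
    if (which == "shuffle_similarity") shuffleSim <- TRUE
    prox <- if (kernelKind == "DK") diffusionKernel(useNet, kernelParam)
            else sgKernel(useNet, kernelParam)
    runLOOCV(useAssoc, prox, sim, seed = repSeed,
             shuffleSimilarity = shuffleSim, ...)
  })
  if (length(reps) == 1) return(reps[[1]])
  perRun <- do.call(rbind, lapply(reps, perRunResults))
  ctrl <- unlist(lapply(reps, function(r) r@controlRankRatios))
  new("EvaluationSummary",
      precision = precisionFromRanks(perRun$rank),
      meanRankRatio = meanRankRatio(perRun$rankRatio),
      auc = aucFromRankRatios(perRun$rankRatio, ctrl),
      perRun = perRun, controlRankRatios = ctrl,
      nSkipped = sum(vapply(reps, function(r) r@nSkipped, integer(1))))
}
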