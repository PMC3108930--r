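#' @import methods
#' @importFrom stats qnorm rnorm runif rbinom cor sd setNames ks.test wilcox.test
#' @importFrom utils read.table write.table head
NULL

#' Domain-domain interaction network
#'
#' An undirected simple graph over protein domains. Node order is fixed at
#' construction (sorted domain identifiers) so that all derived matrices are
#' reproducible bit-for-bit.
#'
#' @slot nodes character vector of domain identifiers, sorted, unique.
#' @slot edges two-column character matrix; each row one undirected edge with
#'   endpoints in canonical (lexicographic) order; no duplicates, no
#'   self-loops.
#'
#' @exportClass DomainNetwork
setClass("DomainNetwork",
  representation(nodes = "character", edges = "matrix"))

setValidity("DomainNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (is.unsorted(object@nodes))
    msg <- c(msg, "nodes must be sorted")
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (!all(e %in% object@nodes))
      msg <- c(msg, "edge endpoint not among nodes")
    if (any(e[, 1] > e[, 2]))
      msg <- c(msg, "edge endpoints must be in canonical order")
    if (anyDuplicated(paste(e[, 1], e[, 2], sep = "\r")))
      msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Domain-domain proximity matrix
#'
#' Symmetric nonnegative proximity between all pairs of network domains,
#' either from the diffusion kernel (\code{kind = "DK"}) or the shortest-path
#' Gaussian kernel (\code{kind = "SG"}). Row/column order matches the
#' originating [DomainNetwork].
#'
#' @slot values symmetric numeric matrix with dimnames equal to the node ids.
#' @slot kind `"DK"` or `"SG"`.
#' @slot param the kernel parameter used (gamma for DK, beta for SG).
#'
#' @exportClass ProximityMatrix
setClass("ProximityMatrix",
  representation(values = "matrix", kind = "character", param = "numeric"))

setValidity("ProximityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "matrix must be symmetric")
  if (any(v < -1e-12)) msg <- c(msg, "entries must be nonnegative")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must carry matching domain ids")
  if (!object@kind %in% c("DK", "SG")) msg <- c(msg, "kind must be DK or SG")
  if (length(msg)) msg else TRUE
})

#' Known domain-phenotype associations
#'
#' The seed knowledge used by the regression: a set of (domain, phenotype)
#' pairs. Phenotypes with at least one associated domain are the seed
#' phenotypes p_1..p_m over which both profiles are indexed.
#'
#' @slot pairs data.frame with character columns `domain` and `phenotype`;
#'   no duplicated pairs.
#'
#' @exportClass AssociationSet
setClass("AssociationSet", representation(pairs = "data.frame"))

setValidity("AssociationSet", function(object) {
  p <- object@pairs
  msg <- character()
  if (!identical(colnames(p), c("domain", "phenotype")))
    msg <- c(msg, "pairs must have columns 'domain' and 'phenotype'")
  else {
    if (!is.character(p$domain) || !is.character(p$phenotype))
      msg <- c(msg, "pair columns must be character")
    if (anyDuplicated(paste(p$domain, p$phenotype, sep = "\r")))
      msg <- c(msg, "duplicate association pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Phenotype-phenotype similarity matrix
#'
#' Pairwise similarity scores between disease phenotypes in \[0, 1\]
#' (typically derived upstream from text mining of clinical descriptions),
#' symmetric with unit diagonal.
#'
#' @slot values symmetric numeric matrix in \[0,1\], unit diagonal, dimnames
#'   carrying phenotype ids.
#'
#' @exportClass PhenotypeSimilarity
setClass("PhenotypeSimilarity", representation(values = "matrix"))

setValidity("PhenotypeSimilarity", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must carry matching phenotype ids")
  if (any(v < -1e-9) || any(v > 1 + 1e-9))
    msg <- c(msg, "similarity out of [0,1]")
  if (nrow(v) > 0 && any(abs(diag(v) - 1) > 1e-9))
    msg <- c(msg, "diagonal must be 1")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Conjugate priors for the Bayesian regression
#'
#' Priors of the normal--scaled-inverse-chi-squared conjugate family for the
#' simple linear regression of the (transformed) phenotype similarity profile
#' on the domain proximity profile: beta | sigma^2 ~ N(mu0, sigma^2 Sigma0)
#' with Sigma0 = diag(sigmaMuSq, sigma1Sq), and sigma^2 ~
#' Scaled-Inv-chi^2(n0, sigma0Sq).
#'
#' The default is the improper limit used for scoring: sigmaMuSq = Inf
#' (flat intercept), n0 = 0, sigma0Sq = 0 (non-informative variance), mu0 =
#' (0, 0) and sigma1Sq = 1; with these sentinels the Bayes factor is computed
#' from its analytic limiting form.
#'
#' @slot mu0 numeric length-2 prior mean (intercept, slope).
#' @slot sigmaMuSq prior variance scale of the intercept; `Inf` for flat.
#' @slot sigma1Sq prior variance scale of the slope; must be finite positive.
#' @slot n0 prior degrees of freedom for sigma^2 (0 allowed as limit).
#' @slot sigma0Sq prior scale for sigma^2 (0 allowed as limit).
#'
#' @exportClass RegressionPriors
setClass("RegressionPriors",
  representation(mu0 = "numeric", sigmaMuSq = "numeric", sigma1Sq = "numeric",
                 n0 = "numeric", sigma0Sq = "numeric"),
  prototype(mu0 = c(0, 0), sigmaMuSq = Inf, sigma1Sq = 1, n0 = 0,
            sigma0Sq = 0))

setValidity("RegressionPriors", function(object) {
  msg <- character()
  if (length(object@mu0) != 2) msg <- c(msg, "mu0 must have length 2")
  if (object@sigma1Sq <= 0 || !is.finite(object@sigma1Sq))
    msg <- c(msg, "sigma1Sq must be finite and positive")
  if (object@sigmaMuSq <= 0) msg <- c(msg, "sigmaMuSq must be positive")
  if (object@n0 < 0) msg <- c(msg, "n0 must be >= 0")
  if (object@sigma0Sq < 0) msg <- c(msg, "sigma0Sq must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Rank-based inverse-normal transform settings
#'
#' The response profile is mapped through
#' z_i = Phi^-1((r_i - c) / (m - 2c + 1)) where r_i is the ascending rank
#' (ties averaged), m the profile length and c the plotting-position offset.
#' The default c = 3/8 is the Blom position.
#'
#' @slot offset plotting-position constant c in \[0, 0.5\].
#'
#' @exportClass RankTransform
setClass("RankTransform", representation(offset = "numeric"),
  prototype(offset = 3 / 8))

setValidity("RankTransform", function(object) {
  if (object@offset < 0 || object@offset > 0.5)
    "offset must lie in [0, 0.5]" else TRUE
})

#' Result of one Bayes-factor computation
#'
#' @slot log10bf log10 Bayes factor of the slope-included model against the
#'   intercept-only model.
#' @slot rSquared squared Pearson correlation between response and predictor.
#' @slot sampleSize profile length used as the likelihood sample size.
#' @slot posterior list of posterior quantities (muN, SigmaN, nN, sigmaNSq
#'   for the alternative model and their null-model analogues) when finite
#'   priors are used; empty list under the limiting priors.
#'
#' @exportClass BayesFactorResult
setClass("BayesFactorResult",
  representation(log10bf = "numeric", rSquared = "numeric",
                 sampleSize = "integer", posterior = "list"))

#' Summary of a cross-validation or robustness experiment
#'
#' @slot precision percent of validation runs in which the true disease
#'   domain ranked exactly first.
#' @slot meanRankRatio mean rank ratio of true domains, in percent.
#' @slot auc area under the pooled ROC of disease versus control rank
#'   ratios, in percent (Mann-Whitney convention, ties credited 1/2).
#' @slot perRun data.frame with one row per validation run (domain,
#'   phenotype, nCandidates, rank, rankRatio).
#' @slot controlRankRatios numeric vector of pooled control rank ratios.
#' @slot nSkipped number of runs skipped (degenerate response or too few
#'   candidates).
#'
#' @exportClass EvaluationSummary
setClass("EvaluationSummary",
  representation(precision = "numeric", meanRankRatio = "numeric",
                 auc = "numeric", perRun = "data.frame",
                 controlRankRatios = "numeric", nSkipped = "integer"))

#' Result of the SNP-proximity enrichment permutation test
#'
#' @slot n0 observed number of reported SNPs within the window of any
#'   top-ranked domain.
#' @slot pValue permutation p-value m/M.
#' @slot m number of permutations with N_i >= N_0.
#' @slot M number of permutations.
#' @slot perDomain data.frame of per-domain SNP incidence counts in the
#'   nested distance categories (inside, within 1 Mbp, within the test
#'   window).
#'
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(n0 = "integer", pValue = "numeric", m = "integer",
                 M = "integer", perDomain = "data.frame"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@M < 1) msg <- c(msg, "M must be >= 1")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0,1]")
  if (length(msg)) msg else TRUE
})
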