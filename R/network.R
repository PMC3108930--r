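#' Construct a domain-domain interaction network
#'
#' Builds an undirected simple graph over protein domains. Edges are
#' canonicalized (unordered pairs stored once), reversed duplicates are
#' merged, and self-loops are dropped with a warning. Isolated nodes can be
#' included through `nodes`.
#'
#' @param edges two-column character matrix or data.frame of edges, or NULL
#'   for an edgeless network.
#' @param nodes optional character vector of node ids to include in addition
#'   to all edge endpoints (e.g. isolated domains).
#' @return A [DomainNetwork-class] object.
#' @examples
#' net <- domainNetwork(cbind(c("a", "b"), c("b", "c")))
#' numDomains(net)
#' @export
domainNetwork <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    e <- matrix(character(), 0, 2)
  } else {
    e <- as.matrix(edges)
    storage.mode(e) <- "character"
    if (ncol(e) != 2) stop("edges must have two columns")
  }
  allEndpoints <- as.vector(e)
  loops <- e[, 1] == e[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    e <- e[!loops, , drop = FALSE]  # endpoint kept as an isolated node
  }
  swap <- e[, 1] > e[, 2]
  e[swap, ] <- e[swap, c(2, 1)]
  e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
  ids <- sort(unique(c(allEndpoints, nodes)))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- NULL
  new("DomainNetwork", nodes = ids, edges = e)
}

#' Read a domain interaction network from a TSV edge list
#'
#' Expects two tab-separated columns of domain ids; lines starting with `#`
#' are comments. Duplicate and reversed-duplicate edges are merged and
#' self-loops dropped.
#'
#' @param path file path.
#' @param nodes optional extra node ids (isolated domains).
#' @return A [DomainNetwork-class].
#' @export
readEdgeList <- function(path, nodes = NULL) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = "character", header = FALSE)
  if (ncol(tab) < 2) stop("edge list must have two columns: ", path)
  domainNetwork(tab[, 1:2], nodes = nodes)
}

#' Write a network as a TSV edge list
#' @param net a [DomainNetwork-class].
#' @param path output file path.
#' @export
writeEdgeList <- function(net, path) {
  write.table(edgeTable(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @describeIn domainNetwork Domain identifiers (node order of all matrices).
#' @param net a [DomainNetwork-class].
#' @export
domainIds <- function(net) net@nodes

#' @describeIn domainNetwork Number of domains.
#' @export
numDomains <- function(net) length(net@nodes)

#' @describeIn domainNetwork Canonical edge table (two-column character
#'   matrix).
#' @export
edgeTable <- function(net) net@edges

#' @describeIn domainNetwork Named vector of node degrees.
#' @export
nodeDegrees <- function(net) {
  d <- setNames(integer(numDomains(net)), domainIds(net))
  tab <- table(factor(as.vector(net@edges), levels = domainIds(net)))
  d[names(tab)] <- as.integer(tab)
  d
}

setMethod("show", "DomainNetwork", function(object) {
  cat("DomainNetwork with", numDomains(object), "domains and",
      nrow(object@edges), "interactions\n")
  if (numDomains(object) > 0)
    cat("  mean degree:",
        round(2 * nrow(object@edges) / numDomains(object), 2), "\n")
})

# igraph view of the network, preserving node order
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = domainIds(net), stringsAsFactors = FALSE))
}

#' Graph Laplacian of the domain network
#'
#' Returns L = D - A where A is the adjacency matrix and D the diagonal
#' matrix of node degrees. Rows and columns are ordered and named by
#' [domainIds()]; all row sums are zero.
#'
#' @param net a [DomainNetwork-class].
#' @return numeric matrix (n x n).
#' @export
laplacianMatrix <- function(net) {
  n <- numDomains(net)
  if (n == 0) stop("empty network")
  ids <- domainIds(net)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net@edges) > 0) {
    i <- match(net@edges[, 1], ids)
    j <- match(net@edges[, 2], ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  diag(rowSums(A)) - A
}

#' Diffusion kernel K = exp(-gamma L)
#'
#' Global network proximity by the matrix exponential of the negative
#' Laplacian, computed exactly through the symmetric eigendecomposition of
#' L. The result is symmetric positive semi-definite and each row sums to 1
#' (L has zero row sums).
#'
#' @param net a [DomainNetwork-class].
#' @param gamma diffusion magnitude, normally in (0, 1); values outside the
#'   interval are allowed with a warning for robustness sweeps.
#' @return A [ProximityMatrix-class] of kind `"DK"`.
#' @examples
#' net <- domainNetwork(cbind("u", "v"))
#' proximityValues(diffusionKernel(net, 0.05))
#' @export
diffusionKernel <- function(net, gamma = 0.05) {
  if (gamma <= 0 || gamma >= 1)
    warning("gamma outside (0, 1): ", gamma)
  L <- laplacianMatrix(net)
  eig <- eigen(L, symmetric = TRUE)
  K <- eig$vectors %*% (exp(-gamma * eig$values) * t(eig$vectors))
  if (any(!is.finite(K))) stop("kernel computation failed")
  K <- (K + t(K)) / 2
  K[K < 0] <- 0  # clip eigendecomposition noise; exact entries are >= 0
  dimnames(K) <- dimnames(L)
  new("ProximityMatrix", values = K, kind = "DK", param = gamma)
}

#' All-pairs shortest path lengths
#'
#' @param net a [DomainNetwork-class].
#' @return integer-valued numeric matrix; `Inf` for disconnected pairs, 0 on
#'   the diagonal.
#' @export
shortestPathLengths <- function(net) {
  if (numDomains(net) == 0) stop("empty network")
  d <- igraph::distances(.asIgraph(net))
  d[domainIds(net), domainIds(net)]
}

#' Shortest-path Gaussian kernel SG(u,v) = exp(-beta SP(u,v)^2)
#'
#' Local network proximity from shortest-path lengths SP through a Gaussian
#' kernel with bandwidth `beta`. Diagonal entries are 1; disconnected pairs
#' (SP = Inf) map to 0.
#'
#' @param net a [DomainNetwork-class].
#' @param beta positive bandwidth.
#' @return A [ProximityMatrix-class] of kind `"SG"`.
#' @export
sgKernel <- function(net, beta = 1) {
  if (!is.numeric(beta) || beta <= 0) stop("invalid bandwidth")
  sp <- shortestPathLengths(net)
  v <- exp(-beta * sp^2)
  v[is.infinite(sp)] <- 0
  new("ProximityMatrix", values = v, kind = "SG", param = beta)
}

#' @describeIn sgKernel Numeric matrix of proximities of a
#'   [ProximityMatrix-class].
#' @param prox a [ProximityMatrix-class].
#' @export
proximityValues <- function(prox) prox@values

#' @describeIn sgKernel Kernel kind ("DK" or "SG") of a
#'   [ProximityMatrix-class].
#' @export
proximityKind <- function(prox) prox@kind

setMethod("show", "ProximityMatrix", function(object) {
  cat(sprintf("ProximityMatrix (%s, parameter %g) over %d domains\n",
              object@kind, object@param, nrow(object@values)))
})

#' Degree-preserving network shuffle
#'
#' Rewires the network by repeated double-edge swaps, preserving every node's
#' degree exactly while destroying the specific wiring; this is the
#' network-level permutation null. Deterministic given `seed`.
#'
#' @param net a [DomainNetwork-class] with at least 2 edges.
#' @param seed integer seed.
#' @param nSwaps number of attempted swaps; default 10 x edge count.
#' @return A [DomainNetwork-class] with the same degree sequence.
#' @export
shuffleNetwork <- function(net, seed, nSwaps = 10 * nrow(edgeTable(net))) {
  ne <- nrow(net@edges)
  if (ne < 2) stop("network must have at least 2 edges")
  if (nSwaps < 1) stop("nSwaps must be >= 1")
  g <- .asIgraph(net)
  out <- .withSeed(seed, {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = nSwaps))
  })
  e <- igraph::as_edgelist(out)
  shuffled <- domainNetwork(e, nodes = domainIds(net))
  if (!identical(sort(nodeDegrees(shuffled)), sort(nodeDegrees(net)))) {
    warning("no valid degree-preserving swap found; returning input")
    return(net)
  }
  shuffled
}

# run code with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-seed derivation: keeps derived seeds in [0, 2^31)
.subSeed <- function(seed, k) {
  (as.double(seed) * 48271 + 101 * k) %% 2147483647
}
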