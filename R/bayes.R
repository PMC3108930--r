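#' Construct regression priors
#'
#' Convenience constructor for [RegressionPriors-class]. With no arguments
#' this yields the limiting non-informative prior used for scoring
#' (flat intercept, unit slope scale, non-informative residual variance),
#' under which the Bayes factor has an analytic closed form.
#'
#' @param mu0 length-2 prior mean (intercept, slope).
#' @param sigmaMuSq intercept prior variance scale; `Inf` for flat.
#' @param sigma1Sq slope prior variance scale (finite, positive).
#' @param n0 prior degrees of freedom of the residual variance.
#' @param sigma0Sq prior scale of the residual variance.
#' @return A [RegressionPriors-class].
#' @export
regressionPriors <- function(mu0 = c(0, 0), sigmaMuSq = Inf, sigma1Sq = 1,
                             n0 = 0, sigma0Sq = 0) {
  new("RegressionPriors", mu0 = mu0, sigmaMuSq = sigmaMuSq,
      sigma1Sq = sigma1Sq, n0 = n0, sigma0Sq = sigma0Sq)
}

.isLimitPriors <- function(priors) {
  is.infinite(priors@sigmaMuSq) && priors@n0 == 0 && priors@sigma0Sq == 0
}

# log marginal likelihood of the conjugate normal--scaled-inv-chi^2 linear
# model with arbitrary design matrix X (finite priors only):
#   p(y|X) = pi^{-n/2} Gamma(nn/2)/Gamma(n0/2) (n0 s0^2)^{n0/2}
#            (nn sn^2)^{-nn/2} sqrt(|Sigma_n|/|Sigma_0|)
.logMarginal <- function(y, X, mu0, Sigma0, n0, s0sq) {
  n <- length(y)
  Si <- solve(Sigma0)
  prec <- crossprod(X) + Si
  Sn <- tryCatch(solve(prec), error = function(e) stop("singular design"))
  mun <- Sn %*% (crossprod(X, y) + Si %*% mu0)
  nn <- n + n0
  nnsn <- n0 * s0sq + sum(y * y) + drop(t(mu0) %*% Si %*% mu0) -
    drop(t(mun) %*% prec %*% mun)
  if (nnsn <= 0) stop("singular design")
  as.numeric(-n / 2 * log(pi) + lgamma(nn / 2) - lgamma(n0 / 2) +
    n0 / 2 * log(n0 * s0sq) - nn / 2 * log(nnsn) +
    0.5 * (determinant(Sn)$modulus - determinant(Sigma0)$modulus))
}

.posteriorRecord <- function(y, X, mu0, Sigma0, n0, s0sq) {
  Si <- solve(Sigma0)
  prec <- crossprod(X) + Si
  Sn <- solve(prec)
  mun <- Sn %*% (crossprod(X, y) + Si %*% mu0)
  nn <- length(y) + n0
  nnsn <- n0 * s0sq + sum(y * y) + drop(t(mu0) %*% Si %*% mu0) -
    drop(t(mun) %*% prec %*% mun)
  list(muN = drop(mun), SigmaN = Sn, nN = nn, sigmaNSq = nnsn / nn)
}

#' Log marginal likelihood of the alternative (slope-included) model
#'
#' Marginal likelihood of the response under the conjugate Bayesian simple
#' linear regression with design (1, x), integrating out coefficients and
#' residual variance analytically. Requires proper (finite) priors; the
#' improper limit enters only through the Bayes-factor ratio, see
#' [bayesFactor()].
#'
#' @param y response vector (length >= 3).
#' @param x predictor vector, same length.
#' @param priors a finite [RegressionPriors-class].
#' @return log marginal likelihood (natural log).
#' @export
logMarginalAlternative <- function(y, x, priors) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (.isLimitPriors(priors)) stop("finite priors required")
  .logMarginal(y, cbind(1, x), priors@mu0,
               diag(c(priors@sigmaMuSq, priors@sigma1Sq)),
               priors@n0, priors@sigma0Sq)
}

#' Log marginal likelihood of the null (intercept-only) model
#'
#' @inheritParams logMarginalAlternative
#' @return log marginal likelihood (natural log).
#' @export
logMarginalNull <- function(y, priors) {
  stopifnot(length(y) >= 3)
  if (.isLimitPriors(priors)) stop("finite priors required")
  .logMarginal(y, matrix(1, length(y), 1), priors@mu0[1],
               matrix(priors@sigmaMuSq), priors@n0, priors@sigma0Sq)
}

# limiting log10 Bayes factor, vectorized over the columns of xMat;
# standardize rescales each predictor to unit variance first (the slope
# prior sigma1^2 acts on the standardized scale, making the shrinkage
# factor Cxx/(Cxx + 1/sigma1^2) and the Occam penalty identical across
# candidates instead of proportional to raw profile amplitude).
# Derived from the ratio of the two conjugate marginals at sigmaMu^2 -> Inf,
# n0 -> 0, sigma0^2 -> 0, mu0 = 0:
#   log BF = -1/2 log(1 + sigma1^2 Cxx)
#            + n/2 log( Cyy / (Cyy - Cxy^2 / (Cxx + 1/sigma1^2)) )
# with Cxx, Cyy, Cxy centered sums of squares / cross-products. Only
# centered moments enter, so the value is invariant to shifting y or x.
.log10bfLimit <- function(y, xMat, sigma1Sq = 1, standardize = FALSE) {
  n <- length(y)
  cy <- y - mean(y)
  Cyy <- sum(cy^2)
  if (Cyy <= 0) stop("degenerate response (constant)")
  xc <- sweep(xMat, 2, colMeans(xMat))
  if (standardize) {
    sdx <- sqrt(colSums(xc^2) / (n - 1))
    xc <- sweep(xc, 2, pmax(sdx, .Machine$double.xmin), "/")
    xc[, sdx == 0] <- 0
  }
  Cxx <- colSums(xc^2)
  Cxy <- colSums(xc * cy)
  S1 <- Cyy - Cxy^2 / (Cxx + 1 / sigma1Sq)
  S1 <- pmax(S1, .Machine$double.xmin)
  out <- (-0.5 * log1p(sigma1Sq * Cxx) + n / 2 * (log(Cyy) - log(S1))) /
    log(10)
  out[Cxx <= 0] <- 0  # constant predictor: no evidence either way
  out
}

#' Bayes factor for one (domain, phenotype) profile pair
#'
#' Ratio of the marginal likelihood of the response under the slope-included
#' regression on the proximity profile against the intercept-only null.
#' Under the default limiting priors (flat intercept, non-informative
#' residual variance) the analytically derived closed form is used; with
#' finite priors the two marginal likelihoods are evaluated and differenced
#' in log space. A predictor with zero variance yields BF = 1 by convention
#' (no evidence either way); a constant response is an error.
#'
#' @param y response vector (inverse-normal transformed similarity profile),
#'   length >= 3.
#' @param x predictor vector (proximity profile), same length.
#' @param priors a [RegressionPriors-class]; default [regressionPriors()]
#'   limit.
#' @param standardize rescale the predictor to unit variance before the
#'   regression. The slope prior then acts on a scale-free axis, so
#'   candidates are compared by the shape of their profiles rather than
#'   their raw amplitude; this is the default in the scoring layer
#'   ([scoreCandidates()], [runLOOCV()]).
#' @return A [BayesFactorResult-class].
#' @examples
#' y <- inverseNormalTransform(c(0.1, 0.4, 0.2, 0.9, 0.7))
#' bayesFactor(y, c(0.0, 0.5, 0.1, 1.2, 0.8))
#' @export
bayesFactor <- function(y, x, priors = regressionPriors(),
                        standardize = FALSE) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (max(y) - min(y) <= 0) stop("degenerate response (constant)")
  constantX <- (max(x) - min(x)) == 0
  if (standardize && !constantX) x <- (x - mean(x)) / sd(x)
  if (.isLimitPriors(priors)) {
    if (any(priors@mu0 != 0))
      warning("mu0 is ignored under the limiting priors (flat intercept)")
    l10 <- if (constantX) 0 else
      .log10bfLimit(y, matrix(x, ncol = 1), priors@sigma1Sq)
    post <- list()
  } else {
    l10 <- if (constantX) 0 else
      (logMarginalAlternative(y, x, priors) -
         logMarginalNull(y, priors)) / log(10)
    post <- list(
      alternative = .posteriorRecord(y, cbind(1, x), priors@mu0,
        diag(c(priors@sigmaMuSq, priors@sigma1Sq)), priors@n0,
        priors@sigma0Sq),
      null = .posteriorRecord(y, matrix(1, length(y), 1), priors@mu0[1],
        matrix(priors@sigmaMuSq), priors@n0, priors@sigma0Sq))
  }
  new("BayesFactorResult", log10bf = as.numeric(l10),
      rSquared = rSquared(y, x), sampleSize = length(y), posterior = post)
}

#' @describeIn bayesFactor log10 Bayes factor of a result.
#' @param object a [BayesFactorResult-class].
#' @export
log10BayesFactor <- function(object) object@log10bf

setMethod("show", "BayesFactorResult", function(object) {
  cat(sprintf("BayesFactorResult: log10 BF = %.4f (R^2 = %.4f, m = %d)\n",
              object@log10bf, object@rSquared, object@sampleSize))
})

#' Ordinary coefficient of determination
#'
#' Squared Pearson correlation between response and predictor; equal to the
#' OLS R-squared of the simple regression. The non-Bayesian baseline score.
#' Returns 0 by convention if either vector is constant.
#'
#' @param y,x numeric vectors of equal length >= 3.
#' @return value in \[0, 1\].
#' @export
rSquared <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (sd(y) == 0 || sd(x) == 0) return(0)
  as.numeric(cor(y, x)^2)
}

#' Brute-force quadrature oracle for the Bayes factor
#'
#' Computes the Bayes factor by dense 3-D numerical integration of the
#' unnormalized joint density over (beta0, beta1, log sigma^2) using Simpson
#' product grids, with the beta grid of every sigma^2 slice scaled by
#' sqrt(sigma^2). Intended for testing the analytic marginals on short
#' profiles (length <= 10); it is slow by design and independent of the
#' closed-form path.
#'
#' @param y,x numeric vectors (length >= 3; keep short).
#' @param priors finite [RegressionPriors-class].
#' @param nBeta,nSigma odd grid sizes for the coefficient and variance grids.
#' @param check if TRUE, re-integrate at double resolution and error if the
#'   two estimates differ by more than `tol` ("grid too coarse").
#' @param tol convergence tolerance on the log10 Bayes factor.
#' @return log10 Bayes factor by quadrature.
#' @export
bfQuadratureOracle <- function(y, x, priors, nBeta = 121, nSigma = 241,
                               check = FALSE, tol = 1e-5) {
  stopifnot(length(y) == length(x), length(y) >= 3)
  if (.isLimitPriors(priors)) stop("finite priors required")
  est <- (.quadMarginal(y, cbind(1, x), priors@mu0,
                        diag(c(priors@sigmaMuSq, priors@sigma1Sq)),
                        priors@n0, priors@sigma0Sq, nBeta, nSigma) -
          .quadMarginal(y, matrix(1, length(y), 1), priors@mu0[1],
                        matrix(priors@sigmaMuSq), priors@n0,
                        priors@sigma0Sq, nBeta, nSigma)) / log(10)
  if (check) {
    fine <- (.quadMarginal(y, cbind(1, x), priors@mu0,
                           diag(c(priors@sigmaMuSq, priors@sigma1Sq)),
                           priors@n0, priors@sigma0Sq,
                           2 * nBeta - 1, 2 * nSigma - 1) -
             .quadMarginal(y, matrix(1, length(y), 1), priors@mu0[1],
                           matrix(priors@sigmaMuSq), priors@n0,
                           priors@sigma0Sq,
                           2 * nBeta - 1, 2 * nSigma - 1)) / log(10)
    if (abs(fine - est) > tol) stop("grid too coarse")
    est <- fine
  }
  est
}

# Simpson-grid numeric marginal likelihood (natural log). Integrates
# p(y|b,s2) p(b|s2) p(s2) over b and log(s2).
.quadMarginal <- function(y, X, mu0, Sigma0, n0, s0sq, nBeta, nSigma) {
  if (nBeta %% 2 == 0 || nSigma %% 2 == 0) stop("grid sizes must be odd")
  n <- length(y); k <- ncol(X)
  Si <- solve(Sigma0)
  ldS0 <- as.numeric(determinant(Sigma0)$modulus)
  fit <- qr.solve(X, y)
  s2hat <- sum((y - X %*% fit)^2) / max(1, n - k) +
    n0 * s0sq / max(n0, 0.5) + 0.05
  simp <- function(m) c(1, rep(c(4, 2), (m - 3) / 2), 4, 1)
  ls <- seq(log(s2hat) - 14, log(s2hat) + 14, length.out = nSigma)
  wS <- simp(nSigma) * diff(ls[1:2]) / 3
  simB <- simp(nBeta)
  Sy <- sum(y^2); S1y <- sum(y)
  if (k == 2) {
    Sx <- sum(X[, 2]); Sxx <- sum(X[, 2]^2); Sxy <- sum(X[, 2] * y)
  }
  acc <- -Inf
  for (is in seq_along(ls)) {
    s2 <- exp(ls[is])
    # log prior on s2 (scaled-inv-chi^2) plus log-Jacobian of s2 = e^u
    lpS2 <- (n0 / 2) * log(n0 * s0sq / 2) - lgamma(n0 / 2) -
      (n0 / 2 + 1) * log(s2) - n0 * s0sq / (2 * s2) + log(s2)
    hw <- 9 * sqrt(s2 * max(diag(Sigma0), 1)) + 2 * max(abs(fit - mu0))
    b0 <- seq(fit[1] - hw, fit[1] + hw, length.out = nBeta)
    w0 <- simB * diff(b0[1:2]) / 3
    if (k == 2) {
      b1 <- seq(fit[2] - hw, fit[2] + hw, length.out = nBeta)
      B0 <- matrix(b0, nBeta, nBeta)
      B1 <- matrix(b1, nBeta, nBeta, byrow = TRUE)
      RSS <- Sy - 2 * B0 * S1y - 2 * B1 * Sxy + n * B0^2 +
        2 * B0 * B1 * Sx + B1^2 * Sxx
      integ <- -n / 2 * log(2 * pi * s2) - RSS / (2 * s2) -
        k / 2 * log(2 * pi * s2) - 0.5 * ldS0 -
        ((B0 - mu0[1])^2 * Si[1, 1] + (B1 - mu0[2])^2 * Si[2, 2]) /
          (2 * s2) + lpS2
      mx <- max(integ)
      val <- mx + log(sum(exp(integ - mx) * outer(w0, w0)))
    } else {
      RSS <- Sy - 2 * b0 * S1y + n * b0^2
      integ <- -n / 2 * log(2 * pi * s2) - RSS / (2 * s2) -
        0.5 * log(2 * pi * s2) - 0.5 * ldS0 -
        (b0 - mu0[1])^2 * Si[1, 1] / (2 * s2) + lpS2
      mx <- max(integ)
      val <- mx + log(sum(exp(integ - mx) * w0))
    }
    term <- val + log(wS[is])
    mm <- max(acc, term)
    acc <- mm + log(exp(acc - mm) + exp(term - mm))
  }
  acc
}
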