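test_that("analytic marginals agree with the quadrature oracle", {
  set.seed(10)
  for (i in 1:3) {
    y <- rnorm(3); x <- rnorm(3)
    pri <- finitePriors()
    qa <- domainRBF:::.quadMarginal(y, cbind(1, x), c(0, 0), diag(2), 1, 1,
                                    241, 361)
    q0 <- domainRBF:::.quadMarginal(y, matrix(1, 3, 1), 0, matrix(1), 1, 1,
                                    241, 361)
    expect_equal(logMarginalAlternative(y, x, pri), qa, tolerance = 1e-5)
    expect_equal(logMarginalNull(y, pri), q0, tolerance = 1e-5)
  }
})

test_that("the Bayes factor ratio is invariant to consistent rescaling
          while each marginal shifts", {
  set.seed(11)
  y <- rnorm(5); x <- rnorm(5)
  p1 <- finitePriors(sigmaMuSq = 1, sigma1Sq = 1, n0 = 2, sigma0Sq = 1)
  # scale y by c and the variance scales by c^2: BF unchanged
  cc <- 3
  p2 <- finitePriors(sigmaMuSq = 1, sigma1Sq = 1, n0 = 2,
                     sigma0Sq = cc^2)
  bf1 <- logMarginalAlternative(y, x, p1) - logMarginalNull(y, p1)
  bf2 <- logMarginalAlternative(cc * y, x, p2) - logMarginalNull(cc * y, p2)
  expect_equal(bf1, bf2, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(logMarginalNull(y, p1),
                                logMarginalNull(cc * y, p2))))
})

test_that("a zero predictor column makes the alternative marginal collapse
          onto the null", {
  set.seed(12)
  y <- rnorm(4)
  pri <- finitePriors()
  expect_equal(logMarginalAlternative(y, rep(0, 4), pri),
               logMarginalNull(y, pri), tolerance = 1e-12)
})

test_that("limiting closed form matches the finite-prior Bayes factor as
          priors approach the limit", {
  set.seed(13)
  for (i in 1:20) {
    y <- rnorm(50); x <- rexp(50)
    lim <- bayesFactor(y, x)@log10bf
    nearly <- finitePriors(sigmaMuSq = 1e6, sigma1Sq = 1, n0 = 1e-6,
                           sigma0Sq = 1e-6)
    fin <- (logMarginalAlternative(y, x, nearly) -
              logMarginalNull(y, nearly)) / log(10)
    expect_equal(lim, fin, tolerance = 0.01)
  }
})

test_that("Bayes factor conventions: constant predictor gives BF = 1,
          constant response errors", {
  y <- inverseNormalTransform(c(0.1, 0.5, 0.3, 0.8))
  r <- bayesFactor(y, rep(2, 4))
  expect_equal(r@log10bf, 0)
  expect_equal(r@rSquared, 0)
  expect_error(bayesFactor(rep(1, 4), rnorm(4)), "degenerate response")
})

test_that("a perfect monotone signal yields BF > 1, with sign confirmed by
          the quadrature oracle", {
  set.seed(14)
  x <- rexp(50)
  y <- inverseNormalTransform(x)  # response = normal scores of x's ranks
  expect_gt(bayesFactor(y, x)@log10bf, 0)
  xs <- rexp(6); ys <- inverseNormalTransform(xs)
  expect_gt(bfQuadratureOracle(ys, xs, finitePriors()), 0)
})

test_that("limit BF is location-invariant and monotone in the signal", {
  set.seed(15)
  y <- rnorm(30); x <- rexp(30)
  b0 <- bayesFactor(y, x)@log10bf
  expect_equal(bayesFactor(y + 5, x)@log10bf, b0, tolerance = 1e-8)
  expect_equal(bayesFactor(y, x + 11)@log10bf, b0, tolerance = 1e-8)
  # mix a fixed orthogonalized noise vector with the predictor at
  # increasing weight, so the sample correlation grows monotonically
  e <- rnorm(30)
  xs <- scale(x)[, 1]
  es <- scale(residuals(lm(e ~ xs)))[, 1]
  bfs <- vapply(seq(0, 1, by = 0.1), function(w) {
    yy <- w * xs + (1 - w) * es
    bayesFactor(yy, x)@log10bf
  }, numeric(1))
  expect_true(all(diff(bfs) > -1e-8))
})

test_that("log-space computation survives long, near-collinear profiles", {
  set.seed(16)
  x <- rnorm(5000)
  y <- x + rnorm(5000, sd = 0.3)
  b <- bayesFactor(y, x)@log10bf
  expect_true(is.finite(b))
  expect_gt(b, 300)
})

test_that("R-squared equals the explicit least-squares decomposition", {
  expect_equal(rSquared(2 * (1:5) + 1, as.numeric(1:5)), 1.0)
  expect_equal(rSquared(rnorm(5), rep(3, 5)), 0.0)
  set.seed(17)
  y <- rnorm(10); x <- rnorm(10)
  fit <- lm(y ~ x)
  expect_equal(rSquared(y, x),
               1 - sum(residuals(fit)^2) / sum((y - mean(y))^2))
})

test_that("quadrature oracle is internally convergent and symmetric in the
          predictor sign", {
  set.seed(18)
  y <- rnorm(5); x <- rnorm(5)
  pri <- finitePriors()
  expect_silent(b <- bfQuadratureOracle(y, x, pri, nBeta = 61, nSigma = 121,
                                        check = TRUE, tol = 1e-3))
  expect_equal(bfQuadratureOracle(y, x, pri),
               bfQuadratureOracle(y, -x, pri), tolerance = 1e-8)
  expect_error(bfQuadratureOracle(y, x, pri, nBeta = 11, nSigma = 21,
                                  check = TRUE, tol = 1e-10),
               "grid too coarse")
})
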