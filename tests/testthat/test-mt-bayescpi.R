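# Multi-trait BayesC-pi sampler: bookkeeping, determinism, conjugate
# building blocks and degenerate-prior behaviour. The heavier enumeration
# and conjugacy oracles live in the acceptance suite.

mkPriors <- function(t = 2, tau2 = 1) {
  new("PriorConfig", Se = diag(t), nuE = t + 2, seDiag = rep(1, t),
      Sb = diag(t), nuB = t + 2, lambda0 = 0, tau2 = tau2)
}

test_that("retained-sample bookkeeping and seeded determinism hold", {
  sim <- tinySim()
  cfg <- ChainConfig(nIter = 10, burnIn = 5, thin = 1, seed = 3)
  fit <- runMtChain(sim$pheno, sim$geno, chain = cfg)
  expect_equal(nSamples(fit), 5)

  cfg2 <- ChainConfig(nIter = 40, burnIn = 13, thin = 4, seed = 3)
  fit2 <- runMtChain(sim$pheno, sim$geno, chain = cfg2)
  expect_equal(nSamples(fit2), (40 - 13) %/% 4)

  refit <- runMtChain(sim$pheno, sim$geno, chain = cfg)
  expect_identical(fit@mu, refit@mu)
  expect_identical(fit@alpha, refit@alpha)
  expect_identical(fit@R, refit@R)
  expect_identical(fit@pi, refit@pi)
})

test_that("label bookkeeping: counts sum to p and Pi sums to 1", {
  sim <- tinySim()
  fit <- runMtChain(sim$pheno, sim$geno,
                    chain = ChainConfig(nIter = 60, burnIn = 20, seed = 1))
  expect_true(all(abs(rowSums(piSamples(fit)) - 1) < 1e-12))
  # label counts recomputed from retained delta samples always sum to p
  for (s in seq_len(nSamples(fit))) {
    d <- deltaSamples(fit)[, , s]
    labs <- 1L + as.integer(d %*% c(1L, 2L))
    expect_equal(sum(tabulate(labs, 4)), ncol(genoMatrix(sim$geno)))
  }
})

test_that("mu full conditional matches N(wbar, R/n) moments with p = 0", {
  set.seed(9)
  n <- 4; t <- 2
  Y <- matrix(rnorm(n * t), n, t) + rep(c(1, 2), each = n)
  R <- diag(t)
  W <- Y                                  # p = 0: w_i = y_i
  draws <- t(replicate(20000, sembayes:::sampleMu(W, R)))
  expect_equal(colMeans(draws), colMeans(Y), tolerance = 0.02)
  expect_equal(unname(apply(draws, 2, var)), rep(1 / n, t),
               tolerance = 0.05)
})

test_that("G update matches the inverse-Wishart closed-form mean", {
  set.seed(11)
  t <- 2
  beta <- matrix(rnorm(10 * t), 10, t)
  delta <- matrix(1L, 10, t)              # all loci active
  Sb <- diag(c(1, 2)); nuB <- 4.5
  draws <- replicate(40000, sembayes:::sampleG(beta, delta, Sb, nuB))
  S <- Sb * nuB + crossprod(beta)
  expected <- S / (nuB + 10 - t - 1)
  expect_equal(apply(draws, c(1, 2), mean), expected, tolerance = 0.03)
  # no included loci -> prior draw (df large enough for finite variance)
  nuB2 <- 8
  priorDraws <- replicate(40000,
    sembayes:::sampleG(beta, matrix(0L, 10, t), Sb, nuB2))
  expect_equal(apply(priorDraws, c(1, 2), mean), Sb * nuB2 / (nuB2 - t - 1),
               tolerance = 0.03)
})

test_that("full residual covariance update matches its closed-form mean", {
  set.seed(13)
  n <- 30; t <- 2
  E <- matrix(rnorm(n * t), n, t)
  Se <- diag(t); nuE <- 4
  draws <- replicate(40000, sembayes:::sampleRFull(E, Se, nuE))
  expected <- (Se * nuE + crossprod(E)) / (nuE + n - t - 1)
  expect_equal(apply(draws, c(1, 2), mean), expected, tolerance = 0.03)
})

test_that("Pi update is Dirichlet(1 + counts) with the all-zero label first", {
  # p = 0: uniform Dirichlet(1,1,1,1)
  set.seed(17)
  draws <- t(replicate(20000, sembayes:::samplePi(matrix(0L, 0, 2))))
  expect_equal(colMeans(draws), rep(0.25, 4), tolerance = 0.02)
  # 100 loci all at the all-zero label -> Dirichlet(101, 1, 1, 1)
  draws2 <- t(replicate(20000, sembayes:::samplePi(matrix(0L, 100, 2))))
  expect_equal(colMeans(draws2), c(101, 1, 1, 1) / 104, tolerance = 0.02)
})

test_that("degenerate Pi mass on the all-zero label switches all effects off", {
  sim <- tinySim()
  fit <- runMtChain(sim$pheno, sim$geno,
                    chain = ChainConfig(nIter = 30, burnIn = 10, seed = 2),
                    init = list(pi = c(1, 0, 0, 0)),
                    update = list(pi = FALSE))
  expect_true(all(deltaSamples(fit) == 0))
  expect_true(all(alphaSamples(fit) == 0))
})

test_that("a monomorphic all-zero marker falls back to the prior inclusion odds", {
  set.seed(21)
  n <- 200
  g <- GenotypeData(cbind(mono = rep(0, n)))
  y <- PhenotypeData(matrix(rnorm(n * 2), n, 2))
  piFix <- c(0.4, 0.1, 0.2, 0.3)
  fit <- runMtChain(y, g, priors = mkPriors(),
                    chain = ChainConfig(nIter = 4000, burnIn = 500, seed = 4),
                    init = list(pi = piFix, G = diag(2), R = diag(2),
                                mu = c(0, 0)),
                    update = list(pi = FALSE, G = FALSE, R = FALSE,
                                  mu = FALSE))
  # marginal inclusion of trait 1 under Pi alone: labels 2 and 4
  pInc <- mean(deltaSamples(fit)[1, 1, ])
  expect_lt(abs(pInc - (piFix[2] + piFix[4])), 0.05)
})

test_that("posterior genetic signal is recovered on simulated data", {
  sim <- tinySim(n = 300, p = 100, nQtl = 10, seed = 8)
  fit <- runMtChain(sim$pheno, sim$geno,
                    chain = ChainConfig(nIter = 1500, burnIn = 500, seed = 1))
  # posterior mean genetic values should correlate strongly with truth
  aHat <- apply(alphaSamples(fit), c(1, 2), mean)
  uHat <- genoMatrix(sim$geno) %*% aHat
  uTrue <- genoMatrix(sim$geno) %*% sim$truth$alphaDirect
  # trait 1 is free of causal propagation: direct comparison
  expect_gt(cor(uHat[, 1], uTrue[, 1]), 0.75)
})

test_that("divergence aborts with the iteration index", {
  sim <- tinySim()
  expect_error(
    runMtChain(sim$pheno, sim$geno,
               chain = ChainConfig(nIter = 10, burnIn = 2, seed = 1),
               init = list(mu = c(NaN, NaN)), update = list(mu = FALSE)),
    "iteration")
})
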