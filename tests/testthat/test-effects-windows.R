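# Effect decomposition, window definitions, variance proportions, WPPA
# and pleiotropy proportions.

eq2Lambda <- function() {
  lam <- matrix(0, 3, 3)
  lam[2, 1] <- 0.5; lam[3, 1] <- 0.2; lam[3, 2] <- 0.3
  lam
}

test_that("decomposition reproduces the worked three-trait expansion", {
  lam <- eq2Lambda()
  dec <- decomposeEffects(matrix(c(1, 0, 0), 1), lam)
  expect_equal(drop(dec$indirect), c(0, 0.5, 0.2 + 0.5 * 0.3))
  expect_equal(drop(dec$overall), c(1, 0.5, 0.35))
  dec2 <- decomposeEffects(matrix(c(0, 1, 0), 1), lam)
  expect_equal(drop(dec2$indirect), c(0, 0, 0.3))
  expect_equal(drop(dec2$overall), c(0, 1, 0.3))
  # Lambda = 0: indirect vanishes
  dec0 <- decomposeEffects(matrix(rnorm(6), 2), matrix(0, 3, 3))
  expect_equal(dec0$indirect, matrix(0, 2, 3))
  expect_equal(dec0$overall, dec0$direct)
})

test_that("power-series identity and decomposition invariants hold per sample", {
  set.seed(44)
  for (r in 1:15) {
    t <- sample(2:4, 1)
    lam <- matrix(0, t, t)
    for (k in 2:t) for (l in 1:(k - 1))
      if (runif(1) < 0.7) lam[k, l] <- rnorm(1)
    # sum_{rho=0}^{t-1} Lambda^rho equals (I - Lambda)^{-1}
    acc <- diag(t); pow <- diag(t)
    for (rho in seq_len(t - 1)) { pow <- pow %*% lam; acc <- acc + pow }
    expect_equal(acc, solve(diag(t) - lam), tolerance = 1e-10)
    alpha <- matrix(rnorm(5 * t), 5, t)
    dec <- decomposeEffects(alpha, lam)
    expect_lt(max(abs(dec$overall - dec$direct - dec$indirect)), 1e-10)
    expect_lt(max(abs(dec$overall %*% t(diag(t) - lam) - dec$direct)), 1e-10)
  }
})

test_that("windows tile chromosomes without spanning boundaries", {
  map1 <- data.frame(chrom = rep("1", 250))
  w1 <- defineWindows(map1, 100)
  expect_equal(w1$n_markers, c(100, 100, 50))
  map2 <- data.frame(chrom = rep(c("1", "2"), each = 150))
  w2 <- defineWindows(map2, 100)
  expect_equal(w2$n_markers, c(100, 50, 100, 50))
  expect_equal(w2$first, c(1, 101, 151, 251))
  expect_equal(w2$last, c(100, 150, 250, 300))
  # genome-scale arithmetic ignoring chromosome breaks
  mapBig <- data.frame(chrom = rep("1", 33519))
  expect_equal(nrow(defineWindows(mapBig, 100)), 336)
})

test_that("window variance proportions match an independent reimplementation", {
  # population-variance arithmetic: a_w = (1,2,3) -> 2/3
  expect_equal(sembayes:::popVar(c(1, 2, 3)), (1 + 4 + 9) / 3 - 4)
  set.seed(46)
  n <- 20; p <- 10; t <- 2
  g <- simulateGenotypes(n, p)
  M <- genoMatrix(g)
  windows <- defineWindows(g, 5)
  lam <- matrix(0, 2, 2); lam[2, 1] <- 0.8
  alpha <- matrix(rnorm(p * t, 0, 0.5), p, t)
  dec <- decomposeEffects(alpha, lam)
  q <- windowVarianceProportions(dec, g, windows)
  # independent recomputation: mean of squares minus square of mean
  vpop <- function(x) mean(x^2) - mean(x)^2
  for (k in 1:2) {
    tot <- vpop(M %*% dec$overall[, k])
    for (w in 1:2) {
      cols <- windows$first[w]:windows$last[w]
      for (e in 1:3) {
        eff <- list(dec$direct, dec$indirect, dec$overall)[[e]]
        expect_equal(unname(q[w, k, e]), drop(vpop(M[, cols] %*% eff[cols, k]) / tot),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("variance proportions conserve a single active window", {
  set.seed(47)
  g <- simulateGenotypes(30, 10)
  windows <- defineWindows(g, 5)
  alpha <- matrix(0, 10, 2)
  alpha[2:4, 1] <- rnorm(3)         # all effects inside window 1, trait 1
  dec <- decomposeEffects(alpha, matrix(0, 2, 2))
  q <- windowVarianceProportions(dec, g, windows)
  expect_equal(unname(q[1, 1, "overall"]), 1)
  expect_equal(unname(q[2, 1, "overall"]), 0)
  expect_equal(unname(q[1, 1, "direct"]), 1)
  # zero total genetic variance: q = 0 with a warning
  decZero <- decomposeEffects(matrix(0, 10, 2), matrix(0, 2, 2))
  expect_warning(q0 <- windowVarianceProportions(decZero, g, windows),
                 "zero")
  expect_true(all(q0 == 0))
})

test_that("WPPA counts strict exceedances and is monotone in T", {
  expect_equal(wppa(c(0.02, 0.005, 0.03), 0.01), 2 / 3)
  expect_equal(wppa(c(0.01, 0.01), 0.01), 0)   # ties do not exceed
  expect_equal(wppa(c(0.5, 0.2), 0), 1)
  qs <- runif(200)
  thresholds <- seq(0, 1, by = 0.1)
  vals <- vapply(thresholds, wppa, numeric(1), qSamples = qs)
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("significant windows respect the WPPA threshold", {
  sim <- tinySim(n = 120, p = 40, nQtl = 4, seed = 21)
  fit <- runSemChain(sim$pheno, sim$geno, sim$truth$structure,
                     chain = ChainConfig(nIter = 400, burnIn = 100, seed = 3))
  wt <- computeWindowResults(fit, sim$geno, windowSize = 10)
  expect_equal(wt@threshold, 1 / nrow(wt@windows))
  sig <- significantWindows(wt, 0)
  expect_equal(nrow(sig), nrow(wt@windows) * 2 * 3)  # every combination
  sigStrict <- significantWindows(wt, 1.0)
  if (nrow(sigStrict) > 0) expect_true(all(sigStrict$wppa == 1))
  sig08 <- significantWindows(wt, 0.8)
  if (nrow(sig08) > 0) expect_true(all(sig08$wppa >= 0.8))
})

test_that("traits without inbound causal edges have zero indirect effects", {
  sim <- tinySim(n = 80, p = 20, nQtl = 4, seed = 23)
  fit <- runSemChain(sim$pheno, sim$geno, sim$truth$structure,
                     chain = ChainConfig(nIter = 100, burnIn = 50, seed = 2))
  dec <- decomposeChain(fit)
  expect_true(all(dec@direct + dec@indirect == dec@overall))
  expect_true(all(dec@indirect[, 1, ] == 0))  # trait 1 has no ancestors
})

test_that("pleiotropy proportions follow causal reachability", {
  # chain 1 -> 2, one locus with delta = (1, 0) in every sample: the
  # overall effect touches both traits with probability 1
  sim <- tinySim(n = 40, p = 1, nQtl = 1, seed = 25)
  fit <- runSemChain(sim$pheno, sim$geno, sim$truth$structure,
                     chain = ChainConfig(nIter = 60, burnIn = 20, seed = 2),
                     init = list(delta = matrix(c(1L, 0L), 1),
                                 lambda = 1.0),
                     update = list(markers = FALSE, lambda = FALSE))
  pp <- pleiotropyProportions(fit)
  expect_equal(pp$overall[pp$combination == "trait1+trait2"], 1)
  # direct proportions are the posterior mean of Pi
  expect_equal(pp$direct, colMeans(piSamples(fit)))
  # three-trait reachability: lam pattern 1 -> 2 -> 3 with delta (1,0,0)
  lam <- matrix(0, 3, 3); lam[2, 1] <- 0.5; lam[3, 2] <- 0.3
  reach <- solve(diag(3) - lam)
  od <- (c(1, 0, 0) %*% t((abs(reach) > 1e-12) * 1)) > 0
  expect_equal(drop(od), c(TRUE, TRUE, TRUE))
})
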