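# Partial correlations, HPD intervals, independence decisions, the IC
# algorithm and equivalence-class enumeration.

test_that("partial correlation matches marginal and regression-residual oracles", {
  expect_equal(partialCorrelation(diag(3), 1, 2), 0)
  expect_equal(partialCorrelation(diag(3), 1, 3, h = 2), 0)
  R <- rbind(c(1, 0.6), c(0.6, 1))
  expect_equal(partialCorrelation(R, 1, 2), 0.6)
  # marginal case equals R_ij / sqrt(R_ii R_jj) exactly
  set.seed(2)
  A <- crossprod(matrix(rnorm(16), 4, 4)) + diag(4)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(partialCorrelation(A, i, j),
                 A[i, j] / sqrt(A[i, i] * A[j, j]))
  # chain y1 -> y2 -> y3 with unit residual variances:
  # Sigma = [[1,1,1],[1,2,2],[1,2,3]]; 1 and 3 independent given 2
  Sigma <- rbind(c(1, 1, 1), c(1, 2, 2), c(1, 2, 3))
  expect_equal(partialCorrelation(Sigma, 1, 3, h = 2), 0, tolerance = 1e-12)
  # regression-residual oracle on sampled data
  set.seed(4)
  n <- 5000
  y1 <- rnorm(n); y2 <- y1 + rnorm(n); y3 <- y2 + rnorm(n)
  S <- cov(cbind(y1, y2, y3))
  r13 <- cor(resid(lm(y1 ~ y2)), resid(lm(y3 ~ y2)))
  expect_equal(partialCorrelation(S, 1, 3, h = 2), r13, tolerance = 1e-10)
})

test_that("HPD interval is the shortest window with lower-start tie-breaking", {
  expect_equal(hpdInterval(1:10, 0.9), c(1, 9))
  expect_equal(hpdInterval(rep(3.7, 60), 0.5), c(3.7, 3.7))
  set.seed(6)
  x <- rnorm(1e5)
  hpd <- hpdInterval(x, 0.9)
  expect_equal(hpd[1], -1.645, tolerance = 0.05)
  expect_equal(hpd[2], 1.645, tolerance = 0.05)
  # exhaustive-scan oracle: no window of ceiling(mass m) sorted samples
  # is shorter, and the interval contains at least that many samples
  for (m in c(20, 57)) {
    x <- sort(rgamma(m, 2))
    k <- ceiling(0.8 * m)
    hpd <- hpdInterval(x, 0.8)
    expect_gte(sum(x >= hpd[1] & x <= hpd[2]), k)
    widths <- x[k:m] - x[1:(m - k + 1)]
    expect_equal(hpd[2] - hpd[1], min(widths))
  }
  expect_error(hpdInterval(numeric(0), 0.9), "fewer samples")
})

test_that("independence tables cover every pair and conditioning subset", {
  Rsamples <- replicate(80, diag(3) + 0, simplify = FALSE)
  dec <- independenceTable(Rsamples, mass = 0.9)
  expect_equal(nrow(dec), 6)   # 3 pairs x (empty set + 1 third trait)
  expect_true(all(dec$independent))
  # four traits, maxCond limits the subsets
  Rsamples4 <- replicate(60, diag(4) + 0, simplify = FALSE)
  dec4 <- independenceTable(Rsamples4, mass = 0.9, maxCond = 1)
  expect_equal(nrow(dec4), 6 * 3)  # per pair: empty + 2 singletons
})

test_that("sampled chain covariances yield the single expected independence", {
  # residual covariance of the chain y1 -> y2 -> y3: posterior-like
  # samples via Wishart draws around Sigma
  Sigma <- rbind(c(1, 1, 1), c(1, 2, 2), c(1, 2, 3))
  set.seed(8)
  n <- 600
  Rsamples <- lapply(seq_len(300), function(s)
    rWishart(1, n, Sigma / n)[, , 1])
  dec <- independenceTable(Rsamples, mass = 0.9)
  indep <- dec[dec$independent, ]
  expect_equal(nrow(indep), 1)
  expect_equal(c(indep$i, indep$j, indep$cond), c("1", "3", "2"))
})

test_that("IC recovers the chain skeleton with both edges undirected", {
  D <- matrix(0L, 3, 3); D[1, 2] <- 1L; D[2, 3] <- 1L  # 1 -> 2 -> 3
  cp <- icAlgorithm(dsepDecisions(D))
  expected <- matrix(0L, 3, 3)
  expected[1, 2] <- expected[2, 1] <- 1L
  expected[2, 3] <- expected[3, 2] <- 1L
  expect_identical(cp@amat, expected)
})

test_that("IC orients the collider", {
  D <- matrix(0L, 3, 3); D[1, 3] <- 1L; D[2, 3] <- 1L  # 1 -> 3 <- 2
  cp <- icAlgorithm(dsepDecisions(D))
  expected <- matrix(0L, 3, 3)
  expected[1, 3] <- 1L; expected[2, 3] <- 1L
  expect_identical(cp@amat, expected)
})

test_that("IC with all pairs independent returns the empty graph", {
  cp <- icAlgorithm(dsepDecisions(matrix(0L, 3, 3)))
  expect_identical(cp@amat, matrix(0L, 3, 3))
})

test_that("IC agrees with the d-separation reference on every 3-node DAG", {
  dags <- allThreeNodeDags()
  expect_length(dags, 25)
  for (D in dags) {
    cp <- icAlgorithm(dsepDecisions(D))
    expect_identical(cp@amat, referenceCpdag(D))
  }
})

test_that("equivalence-class enumeration matches Markov equivalence", {
  # undirected chain 1 - 2 - 3: exactly three members
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  members <- enumerateOrientations(new("Cpdag", amat = A,
                                       traitNames = paste0("y", 1:3)))
  expect_length(members, 3)
  supports <- vapply(members, function(m)
    paste(which(structureMatrix(m) != 0), collapse = ","), character(1))
  # 1->2->3 gives lam[2,1], lam[3,2]; reversed chain lam[1,2], lam[2,3];
  # common cause lam[1,2], lam[3,2]
  expect_setequal(supports, c("2,6", "4,8", "4,6"))

  # fully directed input: singleton
  Ad <- matrix(0L, 3, 3); Ad[1, 2] <- 1L; Ad[2, 3] <- 1L
  expect_length(enumerateOrientations(new("Cpdag", amat = Ad,
                                          traitNames = paste0("y", 1:3))), 1)
  # single undirected edge: two members
  Au <- matrix(0L, 2, 2); Au[1, 2] <- Au[2, 1] <- 1L
  expect_length(enumerateOrientations(new("Cpdag", amat = Au,
                                          traitNames = c("a", "b"))), 2)
})

test_that("a marginally independent pair with a common neighbour orients a collider", {
  decisions <- rbind(
    data.frame(i = 1, j = 2, cond = c("", "3"), hpd_low = 1, hpd_high = 2,
               independent = FALSE),
    data.frame(i = 1, j = 3, cond = c("", "2"), hpd_low = 1, hpd_high = 2,
               independent = FALSE),
    data.frame(i = 2, j = 3, cond = c("", "1"), hpd_low = c(-1, 1),
               hpd_high = c(1, 2), independent = c(TRUE, FALSE))
  )
  # 2 and 3 marginally independent, dependent given 1: v-structure 2 -> 1 <- 3
  cp <- icAlgorithm(decisions)
  expect_identical(cp@amat[2, 1], 1L)
  expect_identical(cp@amat[1, 2], 0L)
  expect_identical(cp@amat[3, 1], 1L)
  expect_identical(cp@amat[1, 3], 0L)
})

test_that("conflicting orientations warn and leave the edge undirected", {
  # skeleton 4 - 1 - 2 - 3 with separating sets chosen so the (1,3) pair
  # forces 1 -> 2 <- 3 and the (2,4) pair forces 2 -> 1 <- 4: edge 1-2 is
  # pushed both ways (not realisable from any single DAG)
  dep <- function(i, j, cond) data.frame(i = i, j = j, cond = cond,
                                         hpd_low = 1, hpd_high = 2,
                                         independent = FALSE)
  ind <- function(i, j, cond) data.frame(i = i, j = j, cond = cond,
                                         hpd_low = -1, hpd_high = 1,
                                         independent = TRUE)
  conds <- function(i, j) {
    rest <- setdiff(1:4, c(i, j))
    c("", as.character(rest), paste(rest[1], rest[2], sep = ","))
  }
  alldep <- function(i, j) do.call(rbind, lapply(conds(i, j), dep, i = i, j = j))
  decisions <- rbind(
    alldep(1, 2), alldep(2, 3), alldep(1, 4),
    ind(1, 3, ""), do.call(rbind, lapply(setdiff(conds(1, 3), ""), dep, i = 1, j = 3)),
    ind(2, 4, ""), do.call(rbind, lapply(setdiff(conds(2, 4), ""), dep, i = 2, j = 4)),
    ind(3, 4, ""), do.call(rbind, lapply(setdiff(conds(3, 4), ""), dep, i = 3, j = 4))
  )
  expect_warning(cp <- icAlgorithm(decisions), "conflict")
  # the unconflicted collider arms stay directed into 2 and 1
  expect_identical(cp@amat[3, 2], 1L)
  expect_identical(cp@amat[2, 3], 0L)
  expect_identical(cp@amat[4, 1], 1L)
  expect_identical(cp@amat[1, 4], 0L)
})
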