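# Multi-trait BayesC-pi Gibbs sampler with mixture priors over all 2^t
# trait-combination inclusion labels and an unstructured (full) residual
# covariance. Used standalone and as step 1 of causal-structure search.
#
# Model: y_i = mu + sum_j m_ij alpha_j + e_i, alpha_j = D_j beta_j,
# beta_j ~ N(0, G), e_i ~ N(0, R), delta_j distributed over the 2^t labels
# with probabilities Pi (uniform Dirichlet prior), G ~ IW, R ~ IW.
# Conjugate updates use effective inverse-Wishart scales Se*nuE and Sb*nuB
# with posterior scale Se*nuE + sum e_i e_i' etc.

# Draw mu from its full conditional N(wbar, R/n) where w_i = y_i - M alpha.
# W is the n x t matrix of w_i.
sampleMu <- function(W, R) {
  n <- nrow(W)
  colMeans(W) + drop(crossprod(chol(R), rnorm(ncol(W)))) / sqrt(n)
}

# Draw G from IW(Sb*nuB + sum_{j in J} beta_j beta_j', nuB + |J|) where J
# is the set of loci with at least one nonzero inclusion indicator.
sampleG <- function(beta, delta, Sb, nuB) {
  J <- rowSums(delta) > 0
  S <- Sb * nuB + crossprod(beta[J, , drop = FALSE])
  rinvwishart1(S, nuB + sum(J))
}

# Draw the full residual covariance from IW(Se*nuE + sum e_i e_i', nuE + n).
sampleRFull <- function(E, Se, nuE) {
  rinvwishart1(Se * nuE + crossprod(E), nuE + nrow(E))
}

# Draw Pi ~ Dirichlet(1 + c_1, ..., 1 + c_l), c_i = loci at label i
# (all-zero label first; bit k of label-1 is delta_k).
samplePi <- function(delta) {
  t <- ncol(delta)
  l <- 2L^t
  if (nrow(delta) == 0) counts <- rep(0L, l)
  else {
    labs <- 1L + as.integer(delta %*% 2^(seq_len(t) - 1L))
    counts <- tabulate(labs, nbins = l)
  }
  rdirichlet1(1 + counts)
}

# Conditional prior of beta_jk given beta_j,-k under beta_j ~ N(0, G):
# returns coefficient matrix (row k = regression coefficients on the other
# traits) and conditional variances.
gConditionals <- function(G) {
  t <- nrow(G)
  coef <- matrix(0, t, t)
  v <- numeric(t)
  for (k in seq_len(t)) {
    if (t == 1) { v[k] <- G[1, 1]; next }
    inv <- solve(G[-k, -k, drop = FALSE])
    ck <- G[k, -k, drop = FALSE] %*% inv
    coef[k, -k] <- ck
    v[k] <- G[k, k] - drop(ck %*% G[-k, k])
  }
  list(coef = coef, var = v)
}

# Single-site update of all (delta_jk, beta_jk); modifies E, beta, delta,
# alpha in place (they are owned by the chain driver).
sampleMarkerEffects <- function(E, M, xpx, beta, delta, alpha, G, Rinv, pi,
                                diagR = FALSE) {
  gc <- gConditionals(G)
  cpp_update_markers(E, M, xpx, beta, delta, alpha, Rinv, pi,
                     gc$coef, gc$var, diagR)
  invisible(NULL)
}

# Shared Gibbs driver for the multi-trait sampler (full or diagonal R) and
# the SEM sampler (diagonal R plus structural coefficients). `support` is
# an s x 2 matrix of (k, l) Lambda positions; s = 0 gives plain
# multi-trait BayesC-pi.
gibbsDriver <- function(Y, M, priors, chain, support, init, update,
                        diagR, traitNamesV, markerIdsV) {
  n <- nrow(Y); t <- ncol(Y); p <- ncol(M); l <- 2L^t
  s <- nrow(support)
  upd <- modifyList(list(mu = TRUE, markers = TRUE, G = TRUE, R = TRUE,
                         pi = TRUE, lambda = TRUE), update)
  set.seed(chain@seed)

  mu <- if (!is.null(init$mu)) init$mu else colMeans(Y)
  beta <- if (!is.null(init$beta)) init$beta else matrix(0, p, t)
  delta <- if (!is.null(init$delta)) init$delta else matrix(0L, p, t)
  storage.mode(delta) <- "integer"
  alpha <- beta * delta
  G <- if (!is.null(init$G)) init$G else priors@Sb * priors@nuB / (priors@nuB - t - 1)
  R <- if (!is.null(init$R)) {
    if (is.matrix(init$R)) init$R else diag(init$R, t)
  } else if (diagR) diag(priors@seDiag * priors@nuE / (priors@nuE - t - 1), t)
  else priors@Se * priors@nuE / (priors@nuE - t - 1)
  pi <- if (!is.null(init$pi)) init$pi else rep(1 / l, l)
  lambda <- if (!is.null(init$lambda)) init$lambda else numeric(s)

  ylam <- function(lam) {
    out <- matrix(0, n, t)
    for (c in seq_len(s))
      out[, support[c, 1]] <- out[, support[c, 1]] + lam[c] * Y[, support[c, 2]]
    out
  }
  Ylam <- ylam(lambda)
  Z <- Y - Ylam                       # working response (I - Lambda) y
  E <- Z - matrix(mu, n, t, byrow = TRUE) - M %*% alpha
  xpx <- colSums(M * M)

  nKeep <- (chain@nIter - chain@burnIn) %/% chain@thin
  muS <- matrix(NA_real_, nKeep, t)
  alphaS <- array(NA_real_, c(p, t, nKeep))
  deltaS <- array(NA_integer_, c(p, t, nKeep))
  GS <- array(NA_real_, c(t, t, nKeep))
  RS <- array(NA_real_, c(t, t, nKeep))
  piS <- matrix(NA_real_, nKeep, l)
  lambdaS <- matrix(NA_real_, nKeep, s)
  kept <- 0L

  for (iter in seq_len(chain@nIter)) {
    if (upd$mu) {
      wbar <- colMeans(E) + mu
      muNew <- wbar + drop(crossprod(chol(R), rnorm(t))) / sqrt(n)
      E <- E + matrix(mu - muNew, n, t, byrow = TRUE)
      mu <- muNew
    }
    if (upd$markers && p > 0) {
      Rinv <- chol2inv(chol(R))
      sampleMarkerEffects(E, M, xpx, beta, delta, alpha, G, Rinv, pi, diagR)
    }
    if (upd$G) G <- sampleG(beta, delta, priors@Sb, priors@nuB)
    if (upd$R) {
      R <- if (diagR) diag(sampleRDiag(E, priors@seDiag, priors@nuE), t)
           else sampleRFull(E, priors@Se, priors@nuE)
    }
    if (upd$pi) pi <- samplePi(delta)
    if (s > 0 && upd$lambda) {
      W <- E + Ylam                    # w_i = y_i - mu - sum_j m_ij alpha_j
      fc <- lambdaFullConditional(W, Y, support, chol2inv(chol(R)),
                                  priors@tau2, priors@lambda0)
      lambda <- drop(fc$mean + crossprod(chol(fc$var), rnorm(s)))
      YlamNew <- ylam(lambda)
      E <- E + Ylam - YlamNew
      Ylam <- YlamNew
      Z <- Y - Ylam
    }
    if (iter %% 1000L == 0L)           # cap floating-point drift
      E <- Z - matrix(mu, n, t, byrow = TRUE) - M %*% alpha
    if (!all(is.finite(mu)) || !all(is.finite(diag(R))) ||
        !all(is.finite(lambda)))
      stop("sampler diverged (non-finite state) at iteration ", iter)
    if (chain@outputEvery > 0 && iter %% chain@outputEvery == 0L)
      message("iteration ", iter, "/", chain@nIter)
    if (iter > chain@burnIn && (iter - chain@burnIn) %% chain@thin == 0L) {
      kept <- kept + 1L
      muS[kept, ] <- mu
      alphaS[, , kept] <- alpha
      deltaS[, , kept] <- delta
      GS[, , kept] <- G
      RS[, , kept] <- R
      piS[kept, ] <- pi
      if (s > 0) lambdaS[kept, ] <- lambda
    }
  }

  if (s > 0)
    colnames(lambdaS) <- paste0(traitNamesV[support[, 2]], "->",
                                traitNamesV[support[, 1]])
  new("ChainSamples", mu = muS, alpha = alphaS, delta = deltaS, G = GS,
      R = RS, pi = piS, lambda = lambdaS, support = support,
      traitNames = traitNamesV, markerIds = markerIdsV,
      seed = chain@seed, nIter = chain@nIter, burnIn = chain@burnIn,
      thin = chain@thin)
}

#' Run the multi-trait BayesC-pi Gibbs sampler
#'
#' Full Gibbs sweep per iteration in fixed order: overall means, marker
#' effects (single-site over loci and traits with the effect integrated
#' out of the inclusion draw), marker-effect covariance G, residual
#' covariance R, mixture probabilities Pi. Retains thinned post-burn-in
#' samples of every parameter, including the residual covariance samples
#' used by causal-structure search.
#'
#' @param pheno a [PhenotypeData-class] object.
#' @param geno a [GenotypeData-class] object (same individuals, or
#'   alignable by id).
#' @param priors a [PriorConfig-class]; defaults to [defaultPriors()].
#' @param chain a [ChainConfig-class].
#' @param init optional named list of initial values (mu, beta, delta, G,
#'   R, pi) — mainly for validation studies.
#' @param update optional named list of logicals switching individual
#'   parameter updates off (fixing them at their initial values).
#' @param diagR constrain the residual covariance to be diagonal.
#' @return A [ChainSamples-class] object.
#' @examples
#' sim <- simulateDataset(SimConfig(n = 80, p = 60, nQtl = 6, seed = 1))
#' fit <- runMtChain(sim$pheno, sim$geno,
#'                   chain = ChainConfig(nIter = 200, burnIn = 100, seed = 1))
#' fit
#' @export
runMtChain <- function(pheno, geno, priors = NULL, chain = ChainConfig(),
                       init = list(), update = list(), diagR = FALSE) {
  al <- ensureAligned(geno, pheno)
  if (is.null(priors)) priors <- defaultPriors(al$pheno, al$geno)
  gibbsDriver(phenoMatrix(al$pheno), genoMatrix(al$geno), priors, chain,
              support = matrix(integer(), 0, 2), init = init,
              update = update, diagR = diagR,
              traitNamesV = traitNames(al$pheno),
              markerIdsV = markerMap(al$geno)$marker_id)
}

ensureAligned <- function(geno, pheno) {
  if (identical(individualIds(geno), individualIds(pheno)))
    list(geno = geno, pheno = pheno)
  else alignIndividuals(geno, pheno)
}
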