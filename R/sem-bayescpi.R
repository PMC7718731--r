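# SEM-BayesC-pi: the multi-trait variable-selection sampler with recursive
# structural coefficients among traits and a diagonal residual covariance
# (required for identifiability of the structural coefficients).
#
# Model: (I - Lambda) y_i = mu + sum_j m_ij D_j beta_j + e_i with
# lambda | lambda0, tau2 ~ N(1 lambda0, I tau2). Because det(I - Lambda) = 1
# for any recursive system, the full conditional of lambda is the exact
# multivariate normal N(lambdaHat, Vlambda) below.

#' Transformed structural matrix I - Lambda
#'
#' @param structure a [CausalStructure-class] object (or bare matrix).
#' @return The t x t matrix \eqn{\Lambda^* = I - \Lambda};
#'   \eqn{\det(\Lambda^*) = 1} for any recursive structure.
#' @examples
#' lam <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.2, 0.3, 0))
#' buildLambdaStar(CausalStructure(lam))
#' @export
buildLambdaStar <- function(structure) {
  lam <- if (is(structure, "CausalStructure")) structureMatrix(structure)
         else as.matrix(structure)
  diag(nrow(lam)) - lam
}

#' Per-individual design matrix of the structural coefficients
#'
#' Builds the t x s matrix \eqn{Y_i} with entry \code{y[l]} at row k,
#' column c for the c-th support element (k, l) and zeros elsewhere, so
#' that \eqn{(I - \Lambda) y_i = y_i - Y_i \lambda} identically.
#'
#' @param y numeric vector of one individual's t trait values.
#' @param support integer s x 2 matrix of (k, l) coefficient positions.
#' @return t x s numeric matrix.
#' @export
buildYi <- function(y, support) {
  s <- nrow(support)
  out <- matrix(0, length(y), s)
  for (c in seq_len(s)) out[support[c, 1], c] <- y[support[c, 2]]
  out
}

# Mean and covariance of the full conditional of lambda:
# Vlambda = (sum_i Yi' R^-1 Yi + tau^-2 I)^-1,
# lambdaHat = Vlambda (sum_i Yi' R^-1 w_i + tau^-2 1 lambda0),
# with w_i = y_i - mu - sum_j m_ij alpha_j. Exploits the sparsity of Yi:
# (Yi' R^-1 Yi)[c, c'] = Rinv[k_c, k_c'] y_i[l_c] y_i[l_c'].
lambdaFullConditional <- function(W, Y, support, Rinv, tau2, lambda0) {
  s <- nrow(support)
  Cyy <- crossprod(Y)
  Cyw <- crossprod(Y, W)
  A <- matrix(0, s, s)
  b <- numeric(s)
  for (c in seq_len(s)) {
    kc <- support[c, 1]; lc <- support[c, 2]
    for (c2 in seq_len(s))
      A[c, c2] <- Rinv[kc, support[c2, 1]] * Cyy[lc, support[c2, 2]]
    b[c] <- sum(Rinv[kc, ] * Cyw[lc, ])
  }
  V <- solve(A + diag(1 / tau2, s))
  V <- (V + t(V)) / 2
  list(mean = drop(V %*% (b + lambda0 / tau2)), var = V)
}

# Draw lambda from N(lambdaHat, Vlambda) given the current residuals.
sampleLambda <- function(W, Y, support, Rinv, tau2, lambda0) {
  fc <- lambdaFullConditional(W, Y, support, Rinv, tau2, lambda0)
  drop(fc$mean + crossprod(chol(fc$var), rnorm(length(fc$mean))))
}

# Draw each diagonal residual variance from its scaled inverse chi-square
# full conditional with scale se_k*nuE + sum_i e_ik^2 and df nuE + n.
sampleRDiag <- function(E, seDiag, nuE) {
  n <- nrow(E)
  sse <- colSums(E * E)
  (seDiag * nuE + sse) / rchisq(ncol(E), df = nuE + n)
}

#' Run the SEM-BayesC-pi Gibbs sampler
#'
#' Fits the structural equation model
#' \eqn{(I - \Lambda) y_i = \mu + \sum_j m_{ij} D_j \beta_j + e_i} by Gibbs
#' sampling. Each iteration updates, in fixed order, the overall means, the
#' marker effects and inclusion indicators, G, the diagonal residual
#' variances, Pi, and finally the structural coefficients \eqn{\lambda}
#' drawn jointly from their multivariate-normal full conditional; the
#' working response \eqn{(I - \Lambda) y} is refreshed immediately after
#' the \eqn{\lambda} update.
#'
#' @param pheno,geno data objects (alignable by individual id).
#' @param structure a [CausalStructure-class] giving the (acyclic) support
#'   of \eqn{\Lambda}; nonzero entries locate the coefficients to sample
#'   and serve as their initial values.
#' @param priors a [PriorConfig-class]; defaults to [defaultPriors()].
#' @param chain a [ChainConfig-class].
#' @param init,update as in [runMtChain()]; \code{init$lambda} overrides
#'   the structure's values, \code{update$lambda = FALSE} fixes them.
#' @return A [ChainSamples-class] object with \eqn{\lambda} samples.
#' @examples
#' sim <- simulateDataset(SimConfig(n = 100, p = 60, nQtl = 6, seed = 2))
#' fit <- runSemChain(sim$pheno, sim$geno, sim$truth$structure,
#'                    chain = ChainConfig(nIter = 300, burnIn = 150, seed = 1))
#' posteriorSummary(fit)
#' @export
runSemChain <- function(pheno, geno, structure, priors = NULL,
                        chain = ChainConfig(), init = list(),
                        update = list()) {
  al <- ensureAligned(geno, pheno)
  if (is.null(priors)) priors <- defaultPriors(al$pheno, al$geno)
  support <- structureSupport(structure)
  lam0 <- structureMatrix(structure)
  if (is.null(init$lambda) && nrow(support) > 0)
    init$lambda <- lam0[support]
  gibbsDriver(phenoMatrix(al$pheno), genoMatrix(al$geno), priors, chain,
              support = support, init = init, update = update, diagR = TRUE,
              traitNamesV = traitNames(al$pheno),
              markerIdsV = markerMap(al$geno)$marker_id)
}
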