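# Synthetic two-trait (generalisable) causal genetic architectures:
# genotypes, gamma-distributed QTL effects under two scenarios, causal
# propagation through a recursive structure, and heritability-controlled
# phenotypes, with full truth records for benchmarking.
#
# Scenario 1 QTL have direct effects on both traits; scenario 2 QTL have a
# direct effect only on trait 1, so their effect on trait 2 is entirely
# indirect (transmitted through the causal path).

#' Simulation configuration
#'
#' @slot n number of individuals.
#' @slot p number of markers.
#' @slot nQtl number of QTL (placed among the p genotyped markers).
#' @slot gammaShape shape of the unit-scale gamma distribution of QTL
#'   effect magnitudes (0.18 = few large effects, 1.48 intermediate,
#'   3.0 = many moderate effects).
#' @slot lambdaTrue structural coefficient of trait 1 on trait 2.
#' @slot h2 per-trait heritability on the structural-equation scale.
#' @slot scenarioSplit fraction of QTL following scenario 1 (default 0.5).
#' @slot freqRange allele-frequency range of simulated markers.
#' @slot ldMix adjacent-marker gamete-copying probability (0 = linkage
#'   equilibrium).
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
  representation(n = "integer", p = "integer", nQtl = "integer",
                 gammaShape = "numeric", lambdaTrue = "numeric",
                 h2 = "numeric", scenarioSplit = "numeric",
                 freqRange = "numeric", ldMix = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nQtl > object@p) msg <- c(msg, "nQtl must not exceed p")
  if (any(object@h2 <= 0) || any(object@h2 >= 1))
    msg <- c(msg, "h2 must lie in (0, 1)")
  if (object@gammaShape <= 0) msg <- c(msg, "gammaShape must be positive")
  if (any(object@freqRange <= 0) || any(object@freqRange >= 1))
    msg <- c(msg, "freqRange must lie within (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param n,p,nQtl,gammaShape,lambdaTrue,h2,scenarioSplit,freqRange,ldMix,seed
#'   see the class slots.
#' @export
SimConfig <- function(n = 500, p = 1000, nQtl = 30, gammaShape = 0.18,
                      lambdaTrue = 1.0, h2 = 0.5, scenarioSplit = 0.5,
                      freqRange = c(0.05, 0.5), ldMix = 0, seed = 1) {
  new("SimConfig", n = as.integer(n), p = as.integer(p),
      nQtl = as.integer(nQtl), gammaShape = gammaShape,
      lambdaTrue = lambdaTrue, h2 = rep(h2, length.out = 2),
      scenarioSplit = scenarioSplit, freqRange = freqRange, ldMix = ldMix,
      seed = as.integer(seed))
}

#' Simulate genotypes
#'
#' Per marker, an allele frequency is drawn uniformly from
#' \code{freqRange}; genotypes are sums of two gametes with
#' Bernoulli(f) alleles. A first-order mixing parameter \code{ldMix}
#' copies the adjacent marker's allele with that probability to mimic
#' linkage disequilibrium.
#'
#' @param n individuals; @param p markers.
#' @param freqRange allele-frequency range.
#' @param ldMix adjacent-marker copying probability in [0, 1).
#' @param seed optional seed (set before drawing when non-NULL).
#' @return A [GenotypeData-class] object.
#' @export
simulateGenotypes <- function(n, p, freqRange = c(0.05, 0.5), ldMix = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- runif(p, freqRange[1], freqRange[2])
  gamete <- function() {
    H <- matrix(0L, n, p)
    H[, 1] <- rbinom(n, 1, f[1])
    for (j in seq_len(p)[-1]) {
      fresh <- rbinom(n, 1, f[j])
      if (ldMix > 0) {
        copy <- runif(n) < ldMix
        H[, j] <- ifelse(copy, H[, j - 1], fresh)
      } else H[, j] <- fresh
    }
    H
  }
  G <- gamete() + gamete()
  GenotypeData(G)
}

#' Simulate QTL positions and direct effects
#'
#' QTL positions are sampled uniformly without replacement among the p
#' markers. Effect magnitudes are gamma(shape, scale = 1) draws with
#' random signs. A fraction \code{scenarioSplit} of the QTL (rounded up)
#' follow scenario 1 (direct effects on both traits); the rest follow
#' scenario 2 (direct effect on trait 1 only).
#'
#' @param config a [SimConfig-class] object.
#' @param seed optional seed.
#' @return list with \code{qtl} (data.frame: marker index, scenario,
#'   per-trait direct effect), \code{alphaDirect} (p x 2 matrix) and
#'   \code{structure} (the true [CausalStructure-class]).
#' @export
simulateQtlEffects <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config@p; nQtl <- config@nQtl
  pos <- sort(sample.int(p, nQtl))
  n1 <- ceiling(config@scenarioSplit * nQtl)
  if (nQtl %% 2 == 1 && config@scenarioSplit == 0.5)
    message("odd nQtl: ", n1, " scenario-1 and ", nQtl - n1, " scenario-2 QTL")
  scenario <- sample(rep(c(1L, 2L), c(n1, nQtl - n1)))
  drawEffect <- function(m) {
    rgamma(m, shape = config@gammaShape, scale = 1) *
      sample(c(-1, 1), m, replace = TRUE)
  }
  alphaDirect <- matrix(0, p, 2)
  alphaDirect[pos, 1] <- drawEffect(nQtl)
  s1 <- pos[scenario == 1L]
  alphaDirect[s1, 2] <- drawEffect(length(s1))
  lam <- matrix(0, 2, 2)
  lam[2, 1] <- config@lambdaTrue
  structure <- CausalStructure(lam, traitNames = c("trait1", "trait2"))
  qtl <- data.frame(marker = pos, scenario = scenario,
                    effect_trait1 = alphaDirect[pos, 1],
                    effect_trait2 = alphaDirect[pos, 2])
  list(qtl = qtl, alphaDirect = alphaDirect, structure = structure)
}

#' Simulate phenotypes through the recursive causal system
#'
#' Direct genetic values are \eqn{u_k = M \alpha^{direct}_k}. Residual
#' variances are set so that, per trait,
#' \eqn{var(u_k) / (var(u_k) + var(e_k))} equals the target heritability
#' on the structural-equation scale. Phenotypes are generated in
#' topological order: \eqn{y_k = \sum_l \Lambda_{kl} y_l + u_k + e_k}
#' (for the two-trait chain, \eqn{y_1 = u_1 + e_1},
#' \eqn{y_2 = \lambda y_1 + u_2 + e_2}).
#'
#' @param geno a [GenotypeData-class] object.
#' @param truth output of [simulateQtlEffects()].
#' @param config a [SimConfig-class] object.
#' @param seed optional seed.
#' @return A [PhenotypeData-class] object.
#' @export
simulatePhenotypes <- function(geno, truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- genoMatrix(geno)
  U <- M %*% truth$alphaDirect
  t <- ncol(U)
  lam <- structureMatrix(truth$structure)
  h2 <- rep(config@h2, length.out = t)
  n <- nrow(M)
  Y <- matrix(0, n, t)
  for (k in topologicalOrder(lam)) {
    vu <- popVar(U[, k])
    if (vu == 0)
      stop("trait ", k, " has zero genetic variance; use a scenario mix ",
           "that gives every trait at least one direct QTL effect")
    ve <- vu * (1 - h2[k]) / h2[k]
    Y[, k] <- drop(lam[k, , drop = FALSE] %*% t(Y)) + U[, k] +
      rnorm(n, 0, sqrt(ve))
  }
  PhenotypeData(Y, traitNames = traitNames(truth$structure),
                individualIds = individualIds(geno))
}

#' Window-level truth flags
#'
#' A window is truly associated with trait k through direct effects iff it
#' contains a QTL with a nonzero direct effect on k; through indirect
#' effects iff it contains a QTL with a nonzero direct effect on a causal
#' ancestor of k; overall = direct or indirect.
#'
#' @param truth output of [simulateQtlEffects()].
#' @param windows data.frame from [defineWindows()].
#' @return array windows x traits x 3 (direct, indirect, overall) of
#'   logicals.
#' @export
truthWindows <- function(truth, windows) {
  lam <- structureMatrix(truth$structure)
  t <- nrow(lam)
  reach <- solve(diag(t) - lam)
  strictReach <- (abs(reach) > 1e-12) & !diag(TRUE, t)  # proper ancestors
  nwin <- nrow(windows)
  out <- array(FALSE, c(nwin, t, 3),
               dimnames = list(NULL, traitNames(truth$structure),
                               c("direct", "indirect", "overall")))
  directQtl <- truth$alphaDirect != 0                    # p x t
  for (w in seq_len(nwin)) {
    rows <- seq(windows$first[w], windows$last[w])
    dHere <- directQtl[rows, , drop = FALSE]
    for (k in seq_len(t)) {
      direct <- any(dHere[, k])
      ancestors <- which(strictReach[k, ])
      indirect <- length(ancestors) > 0 && any(dHere[, ancestors])
      out[w, k, ] <- c(direct, indirect, direct || indirect)
    }
  }
  out
}

#' Simulate a complete dataset
#'
#' Seeds the generator from \code{config@seed}, then draws genotypes, QTL
#' effects and phenotypes. Identical configurations give identical
#' datasets.
#'
#' @param config a [SimConfig-class] object.
#' @return list with \code{geno}, \code{pheno} and \code{truth} (the
#'   output of [simulateQtlEffects()]).
#' @export
simulateDataset <- function(config) {
  set.seed(config@seed)
  geno <- simulateGenotypes(config@n, config@p, config@freqRange,
                            config@ldMix)
  truth <- simulateQtlEffects(config)
  pheno <- simulatePhenotypes(geno, truth, config)
  list(geno = geno, pheno = pheno, truth = truth)
}
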