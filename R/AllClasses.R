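#' @import methods
#' @importFrom stats rnorm runif rgamma rchisq rbinom rWishart var cor sd
#' @importFrom utils read.csv write.csv modifyList
#' @useDynLib sembayes, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Genotype matrix with marker map
#'
#' Holds an \eqn{n \times p} matrix of additive genotype covariates coded
#' 0/1/2 (counts of one allele), together with a marker map giving, for each
#' marker, its chromosome and position (map order). Markers are kept sorted
#' by (chromosome, position) and marker identifiers are unique.
#'
#' @slot geno numeric matrix, \eqn{n \times p}, entries in \{0, 1, 2\}.
#' @slot map data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos}; one row per marker, in column order of \code{geno}.
#' @slot individualIds character vector of length \eqn{n}.
#'
#' @seealso [GenotypeData()] for the constructor, [loadGenotypes()],
#'   [filterMAF()]
#' @export
setClass("GenotypeData",
  representation(
    geno = "matrix",
    map = "data.frame",
    individualIds = "character"
  )
)

setValidity("GenotypeData", function(object) {
  g <- object@geno
  msg <- character()
  if (nrow(object@map) != ncol(g))
    msg <- c(msg, "map must have one row per marker column")
  if (!all(c("marker_id", "chrom", "pos") %in% names(object@map)))
    msg <- c(msg, "map must have columns marker_id, chrom, pos")
  if (length(object@individualIds) != nrow(g))
    msg <- c(msg, "individualIds length must equal nrow(geno)")
  if (anyNA(g))
    msg <- c(msg, "genotypes contain missing values")
  else if (!all(g %in% c(0, 1, 2)))
    msg <- c(msg, "genotype entries must be coded 0, 1 or 2")
  if (anyDuplicated(object@map$marker_id))
    msg <- c(msg, "marker ids must be unique")
  if (nrow(object@map) > 1) {
    o <- order(object@map$chrom, object@map$pos)
    if (!identical(o, seq_len(nrow(object@map))))
      msg <- c(msg, "markers must be sorted by (chrom, pos)")
  }
  if (length(msg)) msg else TRUE
})

#' Phenotype matrix
#'
#' An \eqn{n \times t} matrix of trait values with trait names and
#' individual identifiers. SEM analyses require \eqn{t \ge 2}.
#'
#' @slot pheno numeric matrix, \eqn{n \times t}.
#' @slot traitNames character vector of length \eqn{t}.
#' @slot individualIds character vector of length \eqn{n}.
#'
#' @seealso [PhenotypeData()], [loadPhenotypes()], [alignIndividuals()]
#' @export
setClass("PhenotypeData",
  representation(
    pheno = "matrix",
    traitNames = "character",
    individualIds = "character"
  )
)

setValidity("PhenotypeData", function(object) {
  msg <- character()
  if (length(object@traitNames) != ncol(object@pheno))
    msg <- c(msg, "traitNames length must equal ncol(pheno)")
  if (length(object@individualIds) != nrow(object@pheno))
    msg <- c(msg, "individualIds length must equal nrow(pheno)")
  if (anyNA(object@pheno))
    msg <- c(msg, "phenotypes contain missing values (drop or align first)")
  if (length(msg)) msg else TRUE
})

#' Recursive causal structure among traits
#'
#' A \eqn{t \times t} matrix of structural coefficients \eqn{\Lambda}.
#' Entry \code{lam[k, l]} is the effect of a one-unit increase of trait
#' \eqn{l} on trait \eqn{k} (edge \eqn{l \to k}). The diagonal is zero and
#' the directed graph of the nonzero support must be acyclic (a recursive
#' system), which implies \eqn{\det(I - \Lambda) = 1}.
#'
#' @slot lam numeric matrix of structural coefficients.
#' @slot traitNames character vector of trait names.
#'
#' @seealso [CausalStructure()], [loadStructure()], [buildLambdaStar()]
#' @export
setClass("CausalStructure",
  representation(
    lam = "matrix",
    traitNames = "character"
  )
)

setValidity("CausalStructure", function(object) {
  L <- object@lam
  msg <- character()
  if (nrow(L) != ncol(L)) msg <- c(msg, "lam must be square")
  if (length(object@traitNames) != nrow(L))
    msg <- c(msg, "traitNames length must equal nrow(lam)")
  if (nrow(L) == ncol(L)) {
    if (any(diag(L) != 0)) msg <- c(msg, "diagonal of lam must be zero")
    if (!isAcyclic(L != 0))
      msg <- c(msg, "non-recursive structure: support graph contains a cycle")
  }
  if (length(msg)) msg else TRUE
})

#' Prior configuration for the Gibbs samplers
#'
#' Hyperparameters of the inverse-Wishart priors on the residual covariance
#' \eqn{R} and the marker-effect covariance \eqn{G}, the per-trait residual
#' scales used by the diagonal-residual SEM sampler, and the normal prior on
#' the structural coefficients \eqn{\lambda}. The conjugate updates use
#' effective scale matrices \code{Se * nuE} and \code{Sb * nuB}.
#'
#' @slot Se numeric matrix: residual scale for the full-R sampler.
#' @slot nuE numeric: residual degrees of freedom (> t - 1).
#' @slot seDiag numeric vector: per-trait residual scales (diagonal-R SEM).
#' @slot Sb numeric matrix: marker-effect covariance scale.
#' @slot nuB numeric: marker-effect degrees of freedom (> t - 1).
#' @slot lambda0 numeric: prior mean shared by all structural coefficients.
#' @slot tau2 numeric: prior variance of structural coefficients (> 0).
#'
#' @seealso [defaultPriors()]
#' @export
setClass("PriorConfig",
  representation(
    Se = "matrix",
    nuE = "numeric",
    seDiag = "numeric",
    Sb = "matrix",
    nuB = "numeric",
    lambda0 = "numeric",
    tau2 = "numeric"
  ),
  prototype(lambda0 = 0, tau2 = 1)
)

setValidity("PriorConfig", function(object) {
  t <- nrow(object@Se)
  msg <- character()
  if (object@nuE <= t - 1) msg <- c(msg, "nuE must exceed t - 1")
  if (object@nuB <= t - 1) msg <- c(msg, "nuB must exceed t - 1")
  if (object@tau2 <= 0) msg <- c(msg, "tau2 must be positive")
  if (!isSymmetric(unname(object@Se)) || any(eigen(object@Se, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msg <- c(msg, "Se must be symmetric positive definite")
  if (!isSymmetric(unname(object@Sb)) || any(eigen(object@Sb, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msg <- c(msg, "Sb must be symmetric positive definite")
  if (any(object@seDiag <= 0)) msg <- c(msg, "seDiag entries must be positive")
  if (length(msg)) msg else TRUE
})

#' MCMC chain settings
#'
#' @slot nIter total number of Gibbs iterations.
#' @slot burnIn number of initial iterations discarded (< nIter).
#' @slot thin retain every thin-th post-burn-in iteration.
#' @slot seed integer seed for the chain's random-number stream.
#' @slot outputEvery progress-log interval in iterations (0 = silent).
#'
#' @export
setClass("ChainConfig",
  representation(
    nIter = "integer",
    burnIn = "integer",
    thin = "integer",
    seed = "integer",
    outputEvery = "integer"
  ),
  prototype(nIter = 1000L, burnIn = 500L, thin = 1L, seed = 1L,
            outputEvery = 0L)
)

setValidity("ChainConfig", function(object) {
  msg <- character()
  if (object@nIter < 1) msg <- c(msg, "nIter must be positive")
  if (object@burnIn < 0 || object@burnIn >= object@nIter)
    msg <- c(msg, "burnIn must satisfy 0 <= burnIn < nIter")
  if (object@thin < 1) msg <- c(msg, "thin must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Retained posterior samples of a Gibbs chain
#'
#' Stores thinned post-burn-in samples of every model parameter: overall
#' means, marker effects \eqn{\alpha = D\beta} with inclusion indicators
#' \eqn{\delta}, the marker-effect covariance \eqn{G}, the residual
#' covariance \eqn{R} (full or diagonal), the mixture probabilities
#' \eqn{\Pi} over all \eqn{2^t} trait-combination labels, and (for the SEM
#' sampler) the structural coefficients \eqn{\lambda}.
#'
#' @slot mu numeric matrix, samples x traits.
#' @slot alpha numeric array, markers x traits x samples (effective effects).
#' @slot delta integer array, markers x traits x samples (inclusion).
#' @slot G numeric array, t x t x samples.
#' @slot R numeric array, t x t x samples.
#' @slot pi numeric matrix, samples x 2^t mixture probabilities.
#' @slot lambda numeric matrix, samples x s structural coefficients
#'   (zero columns when no structure is fitted).
#' @slot support integer matrix, s x 2, rows (k, l) locating each
#'   coefficient in Lambda (edge l -> k).
#' @slot traitNames,markerIds character identifiers.
#' @slot seed,nIter,burnIn,thin chain bookkeeping.
#'
#' @seealso [runMtChain()], [runSemChain()], [lambdaSamples()],
#'   [posteriorSummary()]
#' @export
setClass("ChainSamples",
  representation(
    mu = "matrix",
    alpha = "array",
    delta = "array",
    G = "array",
    R = "array",
    pi = "matrix",
    lambda = "matrix",
    support = "matrix",
    traitNames = "character",
    markerIds = "character",
    seed = "integer",
    nIter = "integer",
    burnIn = "integer",
    thin = "integer"
  )
)

setValidity("ChainSamples", function(object) {
  ns <- nrow(object@mu)
  msg <- character()
  if (dim(object@alpha)[3] != ns || dim(object@delta)[3] != ns)
    msg <- c(msg, "alpha/delta sample dimension must match mu")
  if (nrow(object@lambda) != ns) msg <- c(msg, "lambda samples must match mu")
  if (ncol(object@lambda) != nrow(object@support))
    msg <- c(msg, "lambda columns must match support rows")
  if (length(msg)) msg else TRUE
})

#' Completed partially directed acyclic graph (CPDAG)
#'
#' Output of the IC algorithm: a mixed graph over traits whose directed
#' edges are shared by every member of the Markov equivalence class and
#' whose undirected edges admit either orientation. Encoded as an adjacency
#' matrix \code{amat} with \code{amat[l, k] = 1} meaning an edge
#' \eqn{l \to k}; \code{amat[l, k] = amat[k, l] = 1} encodes an undirected
#' edge.
#'
#' @slot amat integer adjacency matrix.
#' @slot traitNames character node names.
#'
#' @seealso [icAlgorithm()], [enumerateOrientations()]
#' @export
setClass("Cpdag",
  representation(amat = "matrix", traitNames = "character")
)

setValidity("Cpdag", function(object) {
  A <- object@amat
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "amat must be square")
  if (length(object@traitNames) != nrow(A))
    msg <- c(msg, "traitNames must match amat dimension")
  directed <- (A == 1) & (t(A) == 0)
  if (nrow(A) > 0 && !isAcyclic(directed))
    msg <- c(msg, "directed part of the CPDAG contains a cycle")
  if (length(msg)) msg else TRUE
})

#' Genomic-window association table
#'
#' Window definitions (consecutive blocks of markers in map order, never
#' spanning a chromosome boundary) together with the per-sample posterior
#' draws of the window variance proportion \eqn{q_w} and the window
#' posterior probability of association (WPPA) for each of the three effect
#' types (direct, indirect, overall) and each trait.
#'
#' @slot windows data.frame with columns \code{window}, \code{chrom},
#'   \code{first}, \code{last}, \code{n_markers} (1-based inclusive marker
#'   index span in map order).
#' @slot q numeric array, windows x traits x effect types x samples.
#' @slot wppa numeric array, windows x traits x effect types.
#' @slot threshold numeric: the variance-proportion threshold T used by
#'   WPPA (default 1/N for N windows).
#' @slot traitNames character trait names.
#'
#' @seealso [defineWindows()], [computeWindowResults()], [wppa()],
#'   [significantWindows()]
#' @export
setClass("WindowTable",
  representation(
    windows = "data.frame",
    q = "array",
    wppa = "array",
    threshold = "numeric",
    traitNames = "character"
  )
)

#' Per-sample decomposition of marker effects
#'
#' Direct (\eqn{\alpha_j}), indirect
#' (\eqn{\sum_{\rho \ge 1} \Lambda^\rho \alpha_j}) and overall
#' (\eqn{(I-\Lambda)^{-1} \alpha_j}) marker effects per retained MCMC
#' sample, computed from the joint posterior samples of \eqn{\Lambda} and
#' \eqn{\alpha}.
#'
#' @slot direct,indirect,overall numeric arrays, markers x traits x samples.
#'
#' @seealso [decomposeEffects()], [decomposeChain()]
#' @export
setClass("EffectDecomposition",
  representation(direct = "array", indirect = "array", overall = "array")
)

setValidity("EffectDecomposition", function(object) {
  if (!identical(dim(object@direct), dim(object@indirect)) ||
      !identical(dim(object@direct), dim(object@overall)))
    "direct, indirect and overall must share dimensions"
  else TRUE
})
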