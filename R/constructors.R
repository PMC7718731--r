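#' Construct a GenotypeData object
#'
#' @param geno numeric matrix of 0/1/2 genotype covariates, individuals in
#'   rows, markers in columns.
#' @param map optional data.frame with columns \code{marker_id},
#'   \code{chrom}, \code{pos}; defaults to a single-chromosome map in
#'   column order using \code{colnames(geno)} (or generated ids) as
#'   marker ids.
#' @param individualIds optional character ids; defaults to rownames or
#'   \code{ind1..indn}.
#' @param sort reorder markers by (chrom, pos) if needed (default TRUE).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(geno, map = NULL, individualIds = NULL, sort = TRUE) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (is.null(map)) {
    ids <- colnames(geno)
    if (is.null(ids))
      ids <- sprintf("m%d", seq_len(ncol(geno)))  # character(0) when p = 0
    map <- data.frame(marker_id = ids, chrom = rep("1", ncol(geno)),
                      pos = seq_len(ncol(geno)), stringsAsFactors = FALSE)
  }
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  if (is.null(individualIds)) {
    individualIds <- rownames(geno)
    if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(geno)))
  }
  if (sort && nrow(map) > 1) {
    o <- order(map$chrom, map$pos)
    geno <- geno[, o, drop = FALSE]
    map <- map[o, , drop = FALSE]
    rownames(map) <- NULL
  }
  colnames(geno) <- map$marker_id
  rownames(geno) <- individualIds
  new("GenotypeData", geno = geno, map = map, individualIds = individualIds)
}

#' Construct a PhenotypeData object
#'
#' @param pheno numeric matrix of trait values (individuals x traits).
#' @param traitNames optional trait names (default: colnames).
#' @param individualIds optional individual ids (default: rownames).
#' @return A [PhenotypeData-class] object.
#' @export
PhenotypeData <- function(pheno, traitNames = NULL, individualIds = NULL) {
  pheno <- as.matrix(pheno)
  storage.mode(pheno) <- "double"
  if (is.null(traitNames)) {
    traitNames <- colnames(pheno)
    if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(ncol(pheno)))
  }
  if (is.null(individualIds)) {
    individualIds <- rownames(pheno)
    if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(pheno)))
  }
  colnames(pheno) <- traitNames
  rownames(pheno) <- individualIds
  new("PhenotypeData", pheno = pheno, traitNames = traitNames,
      individualIds = individualIds)
}

#' Construct a CausalStructure object
#'
#' @param lam square numeric matrix of structural coefficients; entry
#'   \code{lam[k, l]} is the causal effect of trait l on trait k.
#' @param traitNames optional trait names.
#' @return A [CausalStructure-class] object.
#' @export
CausalStructure <- function(lam, traitNames = NULL) {
  lam <- as.matrix(lam)
  storage.mode(lam) <- "double"
  if (is.null(traitNames)) {
    traitNames <- rownames(lam)
    if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(nrow(lam)))
  }
  dimnames(lam) <- list(traitNames, traitNames)
  new("CausalStructure", lam = lam, traitNames = traitNames)
}

#' Construct a ChainConfig object
#'
#' @param nIter total Gibbs iterations.
#' @param burnIn discarded initial iterations.
#' @param thin retain every thin-th post-burn-in sample.
#' @param seed integer RNG seed for the chain.
#' @param outputEvery progress-message interval (0 = silent).
#' @return A [ChainConfig-class] object.
#' @export
ChainConfig <- function(nIter = 1000, burnIn = 500, thin = 1, seed = 1,
                        outputEvery = 0) {
  new("ChainConfig", nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      thin = as.integer(thin), seed = as.integer(seed),
      outputEvery = as.integer(outputEvery))
}

#' Weakly informative default priors
#'
#' Degrees of freedom default to \eqn{t + 2}. Scale matrices are chosen so
#' that the prior mean of the residual covariance and of the total genetic
#' covariance each equal half the sample phenotypic covariance: the genetic
#' part is divided by \eqn{\sum_j 2 f_j (1 - f_j)} (the sum of marker
#' variances under Hardy-Weinberg at observed allele frequencies) and by
#' the prior expected inclusion proportion.
#'
#' @param pheno a [PhenotypeData-class] object.
#' @param geno a [GenotypeData-class] object.
#' @param piExpect prior expected per-trait marker inclusion proportion
#'   used to scale the marker-effect prior (default 0.5, the mean of the
#'   uniform prior on \eqn{\Pi}).
#' @param lambda0,tau2 prior mean and variance of structural coefficients.
#' @return A [PriorConfig-class] object.
#' @export
defaultPriors <- function(pheno, geno, piExpect = 0.5, lambda0 = 0, tau2 = 1) {
  Y <- phenoMatrix(pheno)
  t <- ncol(Y)
  nu <- t + 2
  Sp <- stats::cov(Y)
  # prior mean of IW with effective scale S*nu and df nu is S*nu/(nu-t-1)
  Se <- 0.5 * Sp * (nu - t - 1) / nu
  f <- colMeans(genoMatrix(geno)) / 2
  sum2pq <- sum(2 * f * (1 - f))
  if (sum2pq <= 0) sum2pq <- 1
  Sb <- 0.5 * Sp / (sum2pq * piExpect) * (nu - t - 1) / nu
  new("PriorConfig", Se = Se, nuE = nu, seDiag = diag(Se), Sb = Sb,
      nuB = nu, lambda0 = lambda0, tau2 = tau2)
}
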