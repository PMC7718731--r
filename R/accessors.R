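# Accessors and show methods for the core S4 containers.

#' @rdname GenotypeData-class
#' @param object a GenotypeData object.
#' @export
setGeneric("genoMatrix", function(object) standardGeneric("genoMatrix"))

#' @rdname GenotypeData-class
#' @export
setMethod("genoMatrix", "GenotypeData", function(object) object@geno)

#' @rdname GenotypeData-class
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))

#' @rdname GenotypeData-class
#' @export
setMethod("markerMap", "GenotypeData", function(object) object@map)

#' @rdname PhenotypeData-class
#' @param object a PhenotypeData object.
#' @export
setGeneric("phenoMatrix", function(object) standardGeneric("phenoMatrix"))

#' @rdname PhenotypeData-class
#' @export
setMethod("phenoMatrix", "PhenotypeData", function(object) object@pheno)

#' Individual identifiers
#' @param object a GenotypeData or PhenotypeData object.
#' @export
setGeneric("individualIds", function(object) standardGeneric("individualIds"))

#' @rdname individualIds
#' @export
setMethod("individualIds", "GenotypeData", function(object) object@individualIds)

#' @rdname individualIds
#' @export
setMethod("individualIds", "PhenotypeData", function(object) object@individualIds)

#' Trait names
#' @param object an object carrying trait names.
#' @export
setGeneric("traitNames", function(object) standardGeneric("traitNames"))

#' @rdname traitNames
#' @export
setMethod("traitNames", "PhenotypeData", function(object) object@traitNames)

#' @rdname traitNames
#' @export
setMethod("traitNames", "CausalStructure", function(object) object@traitNames)

#' @rdname traitNames
#' @export
setMethod("traitNames", "ChainSamples", function(object) object@traitNames)

#' @rdname CausalStructure-class
#' @param object a CausalStructure object.
#' @export
setGeneric("structureMatrix", function(object) standardGeneric("structureMatrix"))

#' @rdname CausalStructure-class
#' @export
setMethod("structureMatrix", "CausalStructure", function(object) object@lam)

#' Nonzero support of a causal structure
#'
#' Returns the s x 2 integer matrix of (k, l) positions of nonzero entries
#' of Lambda, ordered column-major (by source trait l, then target k);
#' each row is one structural coefficient, edge l -> k.
#'
#' @param object a CausalStructure object.
#' @export
setGeneric("structureSupport", function(object) standardGeneric("structureSupport"))

#' @rdname structureSupport
#' @export
setMethod("structureSupport", "CausalStructure", function(object) {
  idx <- which(object@lam != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  out <- matrix(as.integer(idx), ncol = 2)
  colnames(out) <- c("k", "l")
  out
})

#' Number of retained posterior samples
#' @param object a ChainSamples object.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "ChainSamples", function(object) nrow(object@mu))

#' Posterior samples of structural coefficients
#' @param object a ChainSamples object.
#' @return numeric matrix samples x coefficients (named "k<-l").
#' @export
setGeneric("lambdaSamples", function(object) standardGeneric("lambdaSamples"))

#' @rdname lambdaSamples
#' @export
setMethod("lambdaSamples", "ChainSamples", function(object) object@lambda)

#' Posterior samples of effective marker effects alpha = D beta
#' @param object a ChainSamples object.
#' @export
setGeneric("alphaSamples", function(object) standardGeneric("alphaSamples"))

#' @rdname alphaSamples
#' @export
setMethod("alphaSamples", "ChainSamples", function(object) object@alpha)

#' Posterior samples of the residual covariance matrix
#' @param object a ChainSamples object.
#' @return list of t x t matrices, one per retained sample.
#' @export
setGeneric("residualCovSamples", function(object) standardGeneric("residualCovSamples"))

#' @rdname residualCovSamples
#' @export
setMethod("residualCovSamples", "ChainSamples", function(object) {
  lapply(seq_len(nSamples(object)), function(s) object@R[, , s])
})

#' Posterior samples of the mixture probabilities Pi
#' @param object a ChainSamples object.
#' @export
setGeneric("piSamples", function(object) standardGeneric("piSamples"))

#' @rdname piSamples
#' @export
setMethod("piSamples", "ChainSamples", function(object) object@pi)

#' @rdname ChainSamples-class
#' @param object a ChainSamples object.
#' @export
setGeneric("deltaSamples", function(object) standardGeneric("deltaSamples"))

#' @rdname ChainSamples-class
#' @export
setMethod("deltaSamples", "ChainSamples", function(object) object@delta)

#' Posterior summary of structural coefficients
#'
#' Mean, standard deviation and highest-posterior-density interval for
#' each structural coefficient.
#'
#' @param object a ChainSamples object.
#' @param mass HPD probability mass (default 0.90).
#' @return data.frame with one row per coefficient.
#' @export
setGeneric("posteriorSummary", function(object, mass = 0.90) standardGeneric("posteriorSummary"))

#' @rdname posteriorSummary
#' @export
setMethod("posteriorSummary", "ChainSamples", function(object, mass = 0.90) {
  L <- object@lambda
  if (ncol(L) == 0)
    return(data.frame(coefficient = character(), mean = numeric(),
                      sd = numeric(), hpd_low = numeric(), hpd_high = numeric()))
  hp <- t(apply(L, 2, hpdInterval, mass = mass))
  data.frame(
    coefficient = colnames(L),
    mean = colMeans(L),
    sd = apply(L, 2, sd),
    hpd_low = hp[, 1],
    hpd_high = hp[, 2],
    row.names = NULL
  )
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@geno), "individuals x",
      ncol(object@geno), "markers on",
      length(unique(object@map$chrom)), "chromosome(s)\n")
})

setMethod("show", "PhenotypeData", function(object) {
  cat("PhenotypeData:", nrow(object@pheno), "individuals x",
      ncol(object@pheno), "traits (", paste(object@traitNames, collapse = ", "),
      ")\n")
})

setMethod("show", "CausalStructure", function(object) {
  s <- structureSupport(object)
  cat("CausalStructure over", length(object@traitNames), "traits;",
      nrow(s), "structural coefficient(s)\n")
  if (nrow(s) > 0) {
    for (r in seq_len(nrow(s)))
      cat(sprintf("  %s -> %s: %.4g\n", object@traitNames[s[r, 2]],
                  object@traitNames[s[r, 1]], object@lam[s[r, 1], s[r, 2]]))
  }
})

setMethod("show", "ChainSamples", function(object) {
  cat("ChainSamples:", nSamples(object), "retained samples (nIter =",
      object@nIter, ", burnIn =", object@burnIn, ", thin =", object@thin,
      ");", length(object@markerIds), "markers,",
      length(object@traitNames), "traits,",
      ncol(object@lambda), "structural coefficient(s)\n")
})

setMethod("show", "Cpdag", function(object) {
  A <- object@amat
  nm <- object@traitNames
  cat("CPDAG over", length(nm), "traits\n")
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (A[i, j] == 1 && A[j, i] == 1 && i < j)
      cat("  ", nm[i], "---", nm[j], "\n")
    else if (A[i, j] == 1 && A[j, i] == 0)
      cat("  ", nm[i], "-->", nm[j], "\n")
  }
})

setMethod("show", "WindowTable", function(object) {
  cat("WindowTable:", nrow(object@windows), "windows,",
      length(object@traitNames), "traits; WPPA threshold T =",
      signif(object@threshold, 4), "\n")
})
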