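# Decomposition of sampled marker effects into direct / indirect / overall
# components, genomic-window variance proportions q_w, WPPA, and
# pleiotropy proportions.

#' Decompose marker effects for one posterior sample
#'
#' Direct effects are the sampled \eqn{\alpha}; indirect effects are
#' \eqn{\sum_{\rho=1}^{t-1} \Lambda^\rho \alpha_j} (the effect transmitted
#' through intermediate traits); overall effects are
#' \eqn{(I-\Lambda)^{-1} \alpha_j}, the sum of the two.
#'
#' @param alpha p x t matrix of sampled effective marker effects.
#' @param structure a [CausalStructure-class] (or bare Lambda matrix) from
#'   the same joint posterior sample.
#' @return list with p x t matrices \code{direct}, \code{indirect},
#'   \code{overall}.
#' @examples
#' lam <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.2, 0.3, 0))
#' decomposeEffects(matrix(c(1, 0, 0), 1), CausalStructure(lam))
#' @export
decomposeEffects <- function(alpha, structure) {
  lam <- if (is(structure, "CausalStructure")) structureMatrix(structure)
         else as.matrix(structure)
  overall <- alpha %*% t(solve(diag(nrow(lam)) - lam))
  list(direct = alpha, indirect = overall - alpha, overall = overall)
}

#' Decompose every retained sample of a chain
#'
#' Applies [decomposeEffects()] to the joint posterior samples of
#' \eqn{\Lambda} and \eqn{\alpha} from a fitted chain.
#'
#' @param chain a [ChainSamples-class] object.
#' @return An [EffectDecomposition-class] object.
#' @export
decomposeChain <- function(chain) {
  ns <- nSamples(chain)
  p <- dim(chain@alpha)[1]; t <- dim(chain@alpha)[2]
  direct <- chain@alpha
  indirect <- array(0, c(p, t, ns))
  overall <- array(0, c(p, t, ns))
  for (s in seq_len(ns)) {
    lam <- lambdaMatrixAt(chain, s)
    dec <- decomposeEffects(chain@alpha[, , s, drop = FALSE][, , 1], lam)
    indirect[, , s] <- dec$indirect
    overall[, , s] <- dec$overall
  }
  new("EffectDecomposition", direct = direct, indirect = indirect,
      overall = overall)
}

# Lambda matrix of sample s reconstructed from the chain's support.
lambdaMatrixAt <- function(chain, s) {
  t <- length(chain@traitNames)
  lam <- matrix(0, t, t)
  if (ncol(chain@lambda) > 0) lam[chain@support] <- chain@lambda[s, ]
  lam
}

#' Define non-overlapping genomic windows
#'
#' Consecutive blocks of \code{windowSize} markers in map order; blocks
#' never span a chromosome boundary, so the last window of each chromosome
#' may be smaller.
#'
#' @param geno a [GenotypeData-class] object, or a map data.frame with a
#'   \code{chrom} column in marker order.
#' @param windowSize markers per window (default 100).
#' @return data.frame with columns \code{window}, \code{chrom},
#'   \code{first}, \code{last}, \code{n_markers} (1-based inclusive marker
#'   indices in map order).
#' @export
defineWindows <- function(geno, windowSize = 100) {
  map <- if (is(geno, "GenotypeData")) markerMap(geno) else geno
  chroms <- rle(as.character(map$chrom))
  out <- list()
  offset <- 0L
  for (ci in seq_along(chroms$values)) {
    len <- chroms$lengths[ci]
    starts <- seq(1L, len, by = windowSize)
    for (st in starts) {
      en <- min(st + windowSize - 1L, len)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chroms$values[ci], first = offset + st, last = offset + en,
        n_markers = en - st + 1L
      )
    }
    offset <- offset + len
  }
  df <- do.call(rbind, out)
  cbind(window = seq_len(nrow(df)), df)
}

#' Window variance proportions for one posterior sample
#'
#' For each effect type, trait and window: the genetic values attributed
#' to the window are \eqn{a_w = M_w \alpha_w}; their population variance
#' (divide-by-n, exactly as defined) is divided by the total genetic
#' variance \eqn{\sigma^2_a}, the population variance of the genetic
#' values of the overall effects of all markers. \eqn{q_w} is not clamped
#' and may exceed 1 when window effects anti-correlate with the rest. A
#' zero total genetic variance yields q = 0 with a warning.
#'
#' @param effects list with p x t matrices \code{direct}, \code{indirect},
#'   \code{overall} (one posterior sample, see [decomposeEffects()]).
#' @param geno a [GenotypeData-class] object.
#' @param windows data.frame from [defineWindows()].
#' @return array windows x traits x 3 (effect order direct, indirect,
#'   overall).
#' @export
windowVarianceProportions <- function(effects, geno, windows) {
  M <- genoMatrix(geno)
  if (all(effects$overall == 0))
    warning("total genetic variance is zero; q set to 0")
  q <- cpp_window_q(M, effects$direct, effects$indirect, effects$overall,
                    as.integer(windows$first), as.integer(windows$last))
  dimnames(q) <- list(NULL, colnames(effects$direct),
                      c("direct", "indirect", "overall"))
  q
}

#' Window posterior probability of association
#'
#' The proportion of MCMC samples in which the window variance proportion
#' strictly exceeds the threshold T.
#'
#' @param qSamples numeric vector of posterior q_w draws for one window.
#' @param threshold the variance-proportion threshold T (typically 1/N for
#'   N windows).
#' @return probability in [0, 1].
#' @export
wppa <- function(qSamples, threshold) {
  stopifnot(length(qSamples) >= 1)
  mean(qSamples > threshold)
}

#' Window-level association results for a fitted chain
#'
#' Decomposes every retained sample, computes per-sample window variance
#' proportions for the three effect types, and summarises them as WPPA
#' with threshold \code{T} (default 1/N, N = number of windows).
#'
#' @param chain a [ChainSamples-class] object.
#' @param geno the [GenotypeData-class] the chain was fitted to.
#' @param windowSize markers per window (default 100).
#' @param threshold optional explicit T; default 1/N.
#' @return A [WindowTable-class] object.
#' @export
computeWindowResults <- function(chain, geno, windowSize = 100,
                                 threshold = NULL) {
  windows <- defineWindows(geno, windowSize)
  N <- nrow(windows)
  if (is.null(threshold)) threshold <- 1 / N
  ns <- nSamples(chain)
  t <- length(chain@traitNames)
  M <- genoMatrix(geno)
  q <- array(NA_real_, c(N, t, 3, ns),
             dimnames = list(NULL, chain@traitNames,
                             c("direct", "indirect", "overall"), NULL))
  for (s in seq_len(ns)) {
    dec <- decomposeEffects(chain@alpha[, , s, drop = FALSE][, , 1],
                            lambdaMatrixAt(chain, s))
    q[, , , s] <- cpp_window_q(M, dec$direct, dec$indirect, dec$overall,
                               as.integer(windows$first),
                               as.integer(windows$last))
  }
  wp <- apply(q > threshold, c(1, 2, 3), mean)
  new("WindowTable", windows = windows, q = q, wppa = wp,
      threshold = threshold, traitNames = chain@traitNames)
}

#' Significant genomic windows
#'
#' Windows whose WPPA reaches the declaration threshold (default 0.8,
#' which restricts the proportion of false positives among declared
#' windows to below 0.2).
#'
#' @param table a [WindowTable-class] object.
#' @param wppaThreshold WPPA cutoff (default 0.8).
#' @return data.frame of significant windows with columns trait,
#'   effect type and WPPA.
#' @export
significantWindows <- function(table, wppaThreshold = 0.8) {
  idx <- which(table@wppa >= wppaThreshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(window = integer(), chrom = character(),
                      trait = character(), effect = character(),
                      wppa = numeric()))
  data.frame(
    window = table@windows$window[idx[, 1]],
    chrom = table@windows$chrom[idx[, 1]],
    trait = table@traitNames[idx[, 2]],
    effect = c("direct", "indirect", "overall")[idx[, 3]],
    wppa = table@wppa[idx]
  )
}

#' Pleiotropy proportions for direct and overall effects
#'
#' For direct effects: the posterior mean of the mixture probabilities
#' \eqn{\Pi} over trait-combination labels. For overall effects: per
#' sample and locus, a trait is affected if the locus has a nonzero direct
#' effect on it or on any causal ancestor (a nonzero \eqn{\Lambda} path in
#' that sample); label frequencies are averaged over samples.
#'
#' @param chain a [ChainSamples-class] object.
#' @return data.frame with one row per trait-combination label and columns
#'   \code{label}, \code{combination}, \code{direct}, \code{overall}.
#' @export
pleiotropyProportions <- function(chain) {
  t <- length(chain@traitNames)
  l <- 2L^t
  labels <- labelMatrix(t)
  ns <- nSamples(chain)
  p <- dim(chain@delta)[1]
  direct <- colMeans(chain@pi)
  overall <- numeric(l)
  pow <- 2^(seq_len(t) - 1L)
  for (s in seq_len(ns)) {
    lam <- lambdaMatrixAt(chain, s)
    reach <- solve(diag(t) - lam)          # [k, l] != 0 <=> path l ~> k
    reach <- (abs(reach) > 1e-12) * 1
    delta <- chain@delta[, , s, drop = FALSE][, , 1, drop = FALSE]
    dim(delta) <- c(p, t)
    od <- (delta %*% t(reach)) > 0         # overall-effect indicators
    labs <- 1L + as.integer(od %*% pow)
    overall <- overall + tabulate(labs, nbins = l) / p
  }
  overall <- overall / ns
  data.frame(
    label = seq_len(l),
    combination = apply(labels, 1, function(d)
      if (!any(d == 1)) "none" else paste(chain@traitNames[d == 1], collapse = "+")),
    direct = direct,
    overall = overall
  )
}
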