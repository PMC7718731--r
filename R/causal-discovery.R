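# Recovery of the phenotypic causal structure from posterior samples of
# the residual covariance matrix: residual partial correlations, an HPD
# decision rule for conditional independence, the Pearl-Verma IC algorithm
# with Meek orientation closure, and enumeration of the Markov equivalence
# class.

#' Partial correlation from a covariance matrix
#'
#' Computes the partial correlation of traits i and j given the
#' conditioning set h, from the inverse of the (i, j, h) submatrix:
#' \eqn{-\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}}. An empty h returns
#' the marginal correlation.
#'
#' @param R symmetric positive definite covariance matrix.
#' @param i,j trait indices (i != j).
#' @param h integer vector of conditioning trait indices (may be empty).
#' @return The partial correlation, in [-1, 1].
#' @export
partialCorrelation <- function(R, i, j, h = integer(0)) {
  stopifnot(i != j, !(i %in% h), !(j %in% h))
  idx <- c(i, j, h)
  om <- solve(R[idx, idx, drop = FALSE])
  -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
}

#' Empirical shortest highest-posterior-density interval
#'
#' The shortest interval containing \code{ceiling(mass * m)} of the m
#' sorted samples; ties between equally short windows are broken toward
#' the lower start.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass probability mass in (0, 1) (default 0.9).
#' @return numeric vector \code{c(low, high)}.
#' @export
hpdInterval <- function(samples, mass = 0.9) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  m <- length(x)
  k <- ceiling(mass * m)
  if (m < 1 || k < 1 || k > m)
    stop("fewer samples (", m, ") than required interval count")
  if (k == m) return(c(x[1], x[m]))
  starts <- seq_len(m - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  s <- which.min(widths)           # first minimum = lowest start
  c(x[s], x[s + k - 1])
}

#' Conditional-independence decisions from residual covariance samples
#'
#' For every unordered trait pair (i, j) and every subset h of the
#' remaining traits (up to \code{maxCond} conditioning traits), computes
#' the residual partial correlation for each posterior sample of R, takes
#' its HPD interval, and declares conditional independence when the
#' interval contains zero.
#'
#' @param Rsamples list of t x t posterior covariance samples (or a
#'   [ChainSamples-class] object, whose R samples are used).
#' @param mass HPD mass (default 0.9).
#' @param maxCond maximum conditioning-set size (default: all t - 2).
#' @return data.frame with columns i, j, cond (comma-separated indices,
#'   "" for the empty set), hpd_low, hpd_high, independent.
#' @export
independenceTable <- function(Rsamples, mass = 0.9, maxCond = Inf) {
  if (is(Rsamples, "ChainSamples")) Rsamples <- residualCovSamples(Rsamples)
  t <- nrow(Rsamples[[1]])
  out <- list()
  for (i in seq_len(t - 1)) for (j in seq(i + 1, t)) {
    rest <- setdiff(seq_len(t), c(i, j))
    subsets <- allSubsets(rest, maxCond)
    for (h in subsets) {
      pc <- vapply(Rsamples, partialCorrelation, numeric(1), i = i, j = j, h = h)
      hpd <- hpdInterval(pc, mass)
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j, cond = paste(h, collapse = ","),
        hpd_low = hpd[1], hpd_high = hpd[2],
        independent = hpd[1] <= 0 && hpd[2] >= 0
      )
    }
  }
  do.call(rbind, out)
}

#' Inductive Causation (IC) algorithm
#'
#' Pearl-Verma IC on a table of conditional-independence decisions:
#' (a) connect i--j iff no conditioning set renders them independent;
#' (b) for each nonadjacent pair (i, j) with a common neighbour k, orient
#' the v-structure i -> k <- j iff k lies in no separating set of (i, j);
#' (c) close under the Meek orientation rules. Orientation conflicts
#' (both directions forced) are reported with a warning and the edge left
#' undirected.
#'
#' @param decisions data.frame as produced by [independenceTable()].
#' @param traitNames optional node names.
#' @return A [Cpdag-class] object.
#' @export
icAlgorithm <- function(decisions, traitNames = NULL) {
  t <- max(decisions$i, decisions$j)
  if (is.null(traitNames)) traitNames <- paste0("trait", seq_len(t))
  sepsets <- vector("list", t * t)  # separating sets per ordered pair
  A <- matrix(0L, t, t)             # 1 at [i,j] and [j,i]: undirected edge
  for (i in seq_len(t - 1)) for (j in seq(i + 1, t)) {
    rows <- decisions[decisions$i == i & decisions$j == j, , drop = FALSE]
    indep <- rows[rows$independent, , drop = FALSE]
    if (nrow(indep) == 0) {
      A[i, j] <- A[j, i] <- 1L
    } else {
      sepsets[[(i - 1) * t + j]] <- lapply(indep$cond, function(cs) {
        if (!nzchar(cs)) integer(0) else as.integer(strsplit(cs, ",")[[1]])
      })
    }
  }
  # v-structures: directed edge encoded by zeroing the reverse entry
  orientTargets <- matrix(FALSE, t, t)  # [a, b]: a -> b forced
  for (i in seq_len(t - 1)) for (j in seq(i + 1, t)) {
    if (A[i, j] == 1) next
    seps <- sepsets[[(i - 1) * t + j]]
    if (is.null(seps)) next
    for (k in seq_len(t)) {
      if (k == i || k == j) next
      if (A[i, k] == 1 && A[j, k] == 1 &&
          !any(vapply(seps, function(s) k %in% s, logical(1)))) {
        orientTargets[i, k] <- TRUE
        orientTargets[j, k] <- TRUE
      }
    }
  }
  conflict <- which(orientTargets & t(orientTargets), arr.ind = TRUE)
  if (nrow(conflict) > 0) {
    warning("conflicting orientations; edge(s) left undirected: ",
            paste(apply(conflict, 1, function(r)
              paste(traitNames[r], collapse = "-")), collapse = ", "))
    orientTargets[conflict] <- FALSE
  }
  A[t(orientTargets)] <- 0L  # a -> b: remove b -> a half
  A <- meekClosure(A)
  new("Cpdag", amat = A, traitNames = traitNames)
}

# Meek rules R1-R3 applied to convergence. amat[a, b] = 1 & amat[b, a] = 0
# encodes a -> b; both 1 encode an undirected edge.
meekClosure <- function(A) {
  t <- nrow(A)
  undirected <- function(a, b) A[a, b] == 1 && A[b, a] == 1
  directed <- function(a, b) A[a, b] == 1 && A[b, a] == 0
  adjacent <- function(a, b) A[a, b] == 1 || A[b, a] == 1
  repeat {
    changed <- FALSE
    for (b in seq_len(t)) for (c in seq_len(t)) {
      if (b == c || !undirected(b, c)) next
      orient <- FALSE
      # R1: a -> b, b -- c, a and c nonadjacent  =>  b -> c
      for (a in seq_len(t))
        if (a != b && a != c && directed(a, b) && !adjacent(a, c)) orient <- TRUE
      # R2: b -> a -> c with b -- c  =>  b -> c
      for (a in seq_len(t))
        if (a != b && a != c && directed(b, a) && directed(a, c)) orient <- TRUE
      # R3: b -- a1, b -- a2, a1 -> c, a2 -> c, a1, a2 nonadjacent => b -> c
      for (a1 in seq_len(t)) for (a2 in seq_len(t)) {
        if (a1 >= a2 || a1 == b || a2 == b || a1 == c || a2 == c) next
        if (undirected(b, a1) && undirected(b, a2) && directed(a1, c) &&
            directed(a2, c) && !adjacent(a1, a2)) orient <- TRUE
      }
      if (orient) { A[c, b] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  A
}

#' Enumerate the Markov equivalence class of a CPDAG
#'
#' Lists every acyclic orientation of the undirected edges that creates no
#' new v-structure (and destroys none), i.e. all DAG members of the
#' equivalence class, as support patterns for the structural coefficient
#' matrix Lambda.
#'
#' @param cpdag a [Cpdag-class] object.
#' @return list of [CausalStructure-class] objects whose nonzero entries
#'   (set to 1) mark the support of each orientation.
#' @export
enumerateOrientations <- function(cpdag) {
  A <- cpdag@amat
  t <- nrow(A)
  und <- which(A == 1 & t(A) == 1 & upper.tri(A), arr.ind = TRUE)
  nu <- nrow(und)
  base <- A
  base[A == 1 & t(A) == 1] <- 0L       # directed skeleton only
  skel <- (A + t(A)) > 0
  ref <- vStructures(adjTo(A), skel)    # v-structures of the CPDAG itself
  out <- list()
  for (mask in seq_len(2^nu) - 1L) {
    D <- base
    for (e in seq_len(nu)) {
      i <- und[e, 1]; j <- und[e, 2]
      if (bitwAnd(bitwShiftR(mask, e - 1L), 1L) == 1L) D[i, j] <- 1L
      else D[j, i] <- 1L
    }
    # D[a, b] = 1 means a -> b; acyclic + identical v-structures required
    if (!isAcyclic(t(D))) next
    if (!identical(vStructures(D, skel), ref)) next
    lam <- matrix(0, t, t)
    lam[t(D) == 1] <- 1                 # lam[k, l] nonzero <=> edge l -> k
    out[[length(out) + 1L]] <- CausalStructure(lam, traitNames = cpdag@traitNames)
  }
  out
}

# Directed adjacency (a -> b at [a, b]) of the fully directed part of a
# CPDAG adjacency matrix.
adjTo <- function(A) {
  D <- matrix(0L, nrow(A), ncol(A))
  D[A == 1 & t(A) == 0] <- 1L
  D
}

# Sorted list of v-structures (a -> c <- b, a and b nonadjacent) of a
# directed graph D (D[a, b] = 1 means a -> b). Nonadjacency is judged
# against `skel` (a symmetric skeleton matrix), which defaults to the
# skeleton of D itself.
vStructures <- function(D, skel = NULL) {
  if (is.null(skel)) skel <- (D + t(D)) > 0
  t <- nrow(D)
  out <- character(0)
  for (c in seq_len(t)) {
    parents <- which(D[, c] == 1)
    if (length(parents) < 2) next
    for (a in parents) for (b in parents) {
      if (a >= b) next
      if (!skel[a, b]) out <- c(out, paste(a, c, b, sep = "-"))
    }
  }
  sort(out)
}
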