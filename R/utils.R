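# Small internal helpers shared across modules.

# Acyclicity of a directed graph given as a logical/numeric adjacency
# matrix with edge l -> k stored at [k, l] (column = source, row = target).
# Repeatedly strips sink-free... (Kahn's algorithm on in-degrees).
isAcyclic <- function(adj) {
  A <- (adj != 0) * 1L
  t <- nrow(A)
  if (t == 0L) return(TRUE)
  remaining <- rep(TRUE, t)
  repeat {
    # nodes with no incoming edge among remaining: row sum zero
    indeg <- rowSums(A[, remaining, drop = FALSE])[remaining]
    if (!length(indeg)) return(TRUE)
    src <- which(remaining)[indeg == 0]
    if (!length(src)) return(FALSE)
    remaining[src] <- FALSE
  }
}

# Topological order of trait indices for an acyclic structure matrix
# (lam[k, l] != 0 <=> edge l -> k); parents precede children.
topologicalOrder <- function(adj) {
  A <- (adj != 0) * 1L
  t <- nrow(A)
  order <- integer(0)
  remaining <- rep(TRUE, t)
  while (any(remaining)) {
    indeg <- rowSums(A[, remaining, drop = FALSE])[remaining]
    src <- which(remaining)[indeg == 0]
    if (!length(src)) stop("cycle detected in structure graph")
    order <- c(order, src)
    remaining[src] <- FALSE
  }
  order
}

# Label index (1-based) of a 0/1 inclusion vector delta; the all-zero
# combination is label 1, then bit k of (label - 1) is delta[k].
labelIndex <- function(delta) {
  1L + as.integer(sum(delta * 2^(seq_along(delta) - 1L)))
}

# All 2^t inclusion vectors in label order (rows), all-zero first.
labelMatrix <- function(t) {
  l <- 2L^t
  m <- matrix(0L, l, t)
  for (k in seq_len(t)) m[, k] <- rep(rep(0:1, each = 2^(k - 1)), length.out = l)
  m
}

# Draw one Dirichlet vector.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

# Draw X ~ inverse-Wishart with effective scale matrix S and df nu
# (density parameterised so that E[X] = S / (nu - t - 1)).
rinvwishart1 <- function(S, nu) {
  W <- rWishart(1, df = nu, Sigma = solve(S))[, , 1]
  solve(W)
}

# All subsets of an index vector up to size maxSize (empty set first);
# safe for length-1 vectors (combn would misread a scalar as a range).
allSubsets <- function(x, maxSize = Inf) {
  x <- as.integer(x)
  subsets <- list(integer(0))
  if (length(x) == 0) return(subsets)
  if (length(x) == 1) return(c(subsets, list(x)))
  for (size in seq_len(min(length(x), maxSize)))
    subsets <- c(subsets, combn(x, size, simplify = FALSE))
  subsets
}

# Population variance (divide by n, no Bessel correction) of a vector.
popVar <- function(x) {
  n <- length(x)
  sum(x * x) / n - (sum(x) / n)^2
}
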