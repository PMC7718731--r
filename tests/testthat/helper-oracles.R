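# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Multivariate normal log density (zero mean).
mvnLogDensity <- function(y, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

# Exact posterior over the 4 inclusion labels for a single-locus two-trait
# model with fixed G, R, Pi and mu = 0: marginalises beta analytically via
# the stacked 2n x 2n covariance (m m') kron (D G D) + I kron R.
enumLabelPosterior <- function(Y, m, G, R, pi) {
  t <- ncol(Y); n <- nrow(Y)
  stopifnot(t == 2)
  yvec <- as.vector(t(Y))              # per-individual blocks
  labs <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  logp <- numeric(4)
  for (i in 1:4) {
    D <- diag(labs[i, ], t)
    Sigma <- kronecker(tcrossprod(m), D %*% G %*% D) +
      kronecker(diag(n), R)
    logp[i] <- log(pi[i]) + mvnLogDensity(yvec, Sigma)
  }
  w <- exp(logp - max(logp))
  w / sum(w)
}

# Batch-means Monte Carlo standard error of the mean of a (possibly
# autocorrelated) chain.
batchSE <- function(x, nBatch = 50) {
  m <- floor(length(x) / nBatch)
  means <- vapply(seq_len(nBatch), function(b)
    mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
  sd(means) / sqrt(nBatch)
}

# d-separation of i and j given set h in a DAG (D[a, b] = 1 means a -> b),
# via moralisation of the ancestral subgraph.
dSeparated <- function(D, i, j, h = integer(0)) {
  t <- nrow(D)
  # ancestral closure of {i, j} union h
  anc <- sort(unique(c(i, j, h)))
  repeat {
    parents <- unique(unlist(lapply(anc, function(v) which(D[, v] == 1))))
    newAnc <- sort(unique(c(anc, parents)))
    if (identical(newAnc, anc)) break
    anc <- newAnc
  }
  Ds <- D[anc, anc, drop = FALSE]
  # moralise: undirect and marry parents of every child
  U <- (Ds + t(Ds)) > 0
  for (c in seq_along(anc)) {
    par <- which(Ds[, c] == 1)
    if (length(par) > 1)
      for (a in par) for (b in par) if (a != b) U[a, b] <- TRUE
  }
  # path search from i to j avoiding h (within the ancestral subgraph)
  ii <- match(i, anc); jj <- match(j, anc)
  blocked <- match(intersect(h, anc), anc)
  visited <- rep(FALSE, length(anc))
  queue <- ii; visited[ii] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == jj) return(FALSE)
    nb <- which(U[v, ] & !visited)
    nb <- setdiff(nb, blocked)
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  TRUE
}

# Exact conditional-independence decision table of a DAG via d-separation,
# in the format expected by icAlgorithm().
dsepDecisions <- function(D) {
  t <- nrow(D)
  out <- list()
  for (i in seq_len(t - 1)) for (j in seq(i + 1, t)) {
    rest <- setdiff(seq_len(t), c(i, j))
    subsets <- list(integer(0))
    if (length(rest) == 1) subsets <- c(subsets, list(rest))
    else if (length(rest) > 1)
      for (size in seq_along(rest))
        subsets <- c(subsets, combn(rest, size, simplify = FALSE))
    for (h in subsets) {
      indep <- dSeparated(D, i, j, h)
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j, cond = paste(h, collapse = ","),
        hpd_low = if (indep) -1 else 1, hpd_high = 1,
        independent = indep)
    }
  }
  do.call(rbind, out)
}

# Reference CPDAG of a DAG, computed WITHOUT Meek rules: enumerate all
# DAGs on t nodes, group those with an identical d-separation signature,
# and mark an edge directed only when every equivalent DAG agrees.
referenceCpdag <- function(D) {
  t <- nrow(D)
  sig <- function(G) paste(dsepDecisions(G)$independent, collapse = "")
  target <- sig(D)
  pairs <- which(upper.tri(matrix(0, t, t)), arr.ind = TRUE)
  members <- list()
  # enumerate all graphs: each unordered pair absent / i->j / j->i
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  for (r in seq_len(nrow(states))) {
    G <- matrix(0L, t, t)
    for (e in seq_len(nrow(pairs))) {
      st <- states[r, e]
      if (st == 1) G[pairs[e, 1], pairs[e, 2]] <- 1L
      if (st == 2) G[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (!isAcyclicOracle(G)) next
    if (sig(G) == target) members[[length(members) + 1L]] <- G
  }
  A <- matrix(0L, t, t)
  for (G in members) A <- A + G
  out <- matrix(0L, t, t)
  n <- length(members)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (i == j) next
    if (A[i, j] == n && A[j, i] == 0) out[i, j] <- 1L            # always i->j
    else if (A[i, j] > 0 && A[j, i] > 0) out[i, j] <- out[j, i] <- 1L
  }
  out
}

# Acyclicity check independent of the package (DFS colouring).
isAcyclicOracle <- function(D) {
  t <- nrow(D)
  colr <- rep(0L, t)
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return()
    colr[v] <<- 1L
    for (w in which(D[v, ] == 1)) {
      if (colr[w] == 1L) { ok <<- FALSE; return() }
      if (colr[w] == 0L) visit(w)
    }
    colr[v] <<- 2L
  }
  for (v in seq_len(t)) if (colr[v] == 0L) visit(v)
  ok
}

# All 25 labelled DAGs on 3 nodes.
allThreeNodeDags <- function() {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  states <- expand.grid(e1 = 0:2, e2 = 0:2, e3 = 0:2)
  for (r in seq_len(nrow(states))) {
    G <- matrix(0L, 3, 3)
    for (e in 1:3) {
      st <- states[r, e]
      if (st == 1) G[pairs[e, 1], pairs[e, 2]] <- 1L
      if (st == 2) G[pairs[e, 2], pairs[e, 1]] <- 1L
    }
    if (isAcyclicOracle(G)) out[[length(out) + 1L]] <- G
  }
  out
}

# Threshold-sweep partial-AUC oracle: explicit (FPR, TPR) points at every
# candidate threshold, trapezoid over the strip with interpolation.
paucSweepOracle <- function(scores, labels, fprMax = 0.05) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(c) {
    pred <- scores >= c
    c(fpr = sum(pred & !labels) / sum(!labels),
      tpr = sum(pred & labels) / sum(labels))
  }, numeric(2)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  area <- 0
  for (v in seq_len(nrow(pts) - 1)) {
    x0 <- pts[v, 1]; x1 <- pts[v + 1, 1]
    y0 <- pts[v, 2]; y1 <- pts[v + 1, 2]
    if (x0 >= fprMax) break
    if (x1 > fprMax) {
      y1 <- y0 + (y1 - y0) * (fprMax - x0) / (x1 - x0)
      x1 <- fprMax
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
  }
  unname(area)
}

# Small deterministic two-trait dataset for sampler tests.
tinySim <- function(n = 60, p = 20, nQtl = 4, seed = 42, ...) {
  simulateDataset(SimConfig(n = n, p = p, nQtl = nQtl, seed = seed, ...))
}
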