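# Brute-force oracles, independent of the package implementations.

# Between-class-variance threshold search over all candidate cuts placed
# between adjacent sorted unique values; returns the foreground pixel count.
bruteOtsuArea <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(0L)
  cuts <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cuts, function(t) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    length(g0) * length(g1) * (mean(g0) - mean(g1))^2
  }, numeric(1))
  sum(v > cuts[which.max(bcv)])
}

# Per-pixel loop mask algebra.
bruteMaskSet <- function(p14, p19) {
  a14 <- 0L; a19 <- 0L; aAnd <- 0L; aOr <- 0L
  for (i in seq_along(p14)) {
    if (p14[i]) a14 <- a14 + 1L
    if (p19[i]) a19 <- a19 + 1L
    if (p14[i] && p19[i]) aAnd <- aAnd + 1L
    if (p14[i] || p19[i]) aOr <- aOr + 1L
  }
  c(a14 = a14, a19 = a19, a_and = aAnd, a_or = aOr)
}

# Hypergeometric upper tail by explicit summation of choose() products.
bruteFisherGreater <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  ks <- a:min(K, n)
  ks <- ks[n - ks <= N - K]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Exact two-sided Mann-Whitney by enumeration of all group assignments.
bruteMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Umin <- min(U1, n1 * n2 - U1)
  sets <- combn(n1 + n2, n1)
  Us <- apply(sets, 2, function(id) sum(rank(pooled)[id]) - n1 * (n1 + 1) / 2)
  min(1, mean(Us <= Umin) + mean(Us >= n1 * n2 - Umin))
}

# First-principles Pearson chi-square from margins.
bruteChiSquare <- function(O) {
  n <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    E <- sum(O[i, ]) * sum(O[, j]) / n
    stat <- stat + (O[i, j] - E)^2 / E
  }
  unname(stat)
}

# Greedy centroid matching of segmented labels to ground-truth cells.
matchCentroids <- function(labels, truth, maxDist) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) return(list(tp = 0, fp = 0, fn = nrow(truth)))
  cy <- vapply(ids, function(k) mean(row(labels)[labels == k]), numeric(1))
  cx <- vapply(ids, function(k) mean(col(labels)[labels == k]), numeric(1))
  used <- rep(FALSE, length(ids)); tp <- 0
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((cy - truth$y[i])^2 + (cx - truth$x[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= maxDist) { used[j] <- TRUE; tp <- tp + 1 }
  }
  list(tp = tp, fp = sum(!used), fn = nrow(truth) - tp)
}
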