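# Brute-force oracles, written independently of the package implementation:
# explicit loops and path enumeration only.

# Patristic distance by breadth-first path enumeration on the tree graph.
oraclePatristic <- function(tree) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  adj <- vector("list", nNode)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist1 <- function(from) {
    d <- rep(NA_real_, nNode)
    d[from] <- 0
    queue <- from
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1L]
        if (is.na(d[u])) { d[u] <- d[v] + adj[[v]][k, 2L]; queue <- c(queue, u) }
      }
    }
    d
  }
  D <- matrix(0, nTip, nTip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nTip)) D[i, ] <- dist1(i)[seq_len(nTip)]
  D
}

oracleMPD <- function(sp, D, ab = NULL) {
  if (length(sp) < 2) return(NA_real_)
  num <- 0; den <- 0
  for (i in seq_along(sp)) for (j in seq_along(sp)) if (i < j) {
    w <- if (is.null(ab)) 1 else ab[i] * ab[j]
    num <- num + w * D[sp[i], sp[j]]
    den <- den + w
  }
  unname(num / den)
}

oracleMNTD <- function(sp, D, ab = NULL) {
  if (length(sp) < 2) return(NA_real_)
  num <- 0; den <- 0
  for (i in seq_along(sp)) {
    m <- Inf
    for (j in seq_along(sp)) if (j != i) m <- min(m, D[sp[i], sp[j]])
    w <- if (is.null(ab)) 1 else ab[i]
    num <- num + w * m; den <- den + w
  }
  unname(num / den)
}

oracleDpw <- function(s1, s2, D) {
  tot <- 0; cnt <- 0
  for (a in s1) for (b in s2) { tot <- tot + D[a, b]; cnt <- cnt + 1 }
  tot / cnt
}

oracleDnn <- function(s1, s2, D) {
  m1 <- sapply(s1, function(a) min(sapply(s2, function(b) D[a, b])))
  m2 <- sapply(s2, function(b) min(sapply(s1, function(a) D[a, b])))
  (mean(m1) + mean(m2)) / 2
}

oracleImpurity <- function(Y) {
  tot <- 0
  for (s in seq_len(ncol(Y))) {
    mu <- mean(Y[, s])
    for (p in seq_len(nrow(Y))) tot <- tot + (Y[p, s] - mu)^2
  }
  tot
}

# Exhaustive best split: every predictor, every midpoint between consecutive
# sorted unique values, impurities recomputed from scratch.
oracleBestSplit <- function(Y, X, predictors, min_leaf) {
  best <- NULL
  parent <- oracleImpurity(Y)
  for (v in predictors) {
    x <- X[[v]]
    u <- sort(unique(x))
    if (length(u) < 2) next
    for (k in seq_len(length(u) - 1)) {
      thr <- (u[k] + u[k + 1]) / 2
      left <- x < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- parent - oracleImpurity(Y[left, , drop = FALSE]) -
        oracleImpurity(Y[!left, , drop = FALSE])
      if (is.null(best) || gain > best$gain + 1e-12) {
        best <- list(var = v, threshold = thr, gain = gain)
      }
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

# Rand index of two partitions.
randIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- sum(choose(tab, 2))
  r <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * s - r - cc) / choose(n, 2)
}

# A random community drawn on the tip set of a tree.
randomAssemblage <- function(tree, kmin = 2, kmax = NULL) {
  tips <- tree$tip.label
  if (is.null(kmax)) kmax <- length(tips)
  sample(tips, sample(kmin:kmax, 1))
}
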