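# Independent brute-force oracles for the graph metrics, used to verify
# the production implementations on small instances. These deliberately
# use different algorithms (Floyd-Warshall, exhaustive path enumeration,
# dense linear solves) from the package code.

rand_weighted_graph <- function(n, density = 0.6, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  on <- runif(nrow(ut)) < density
  W[ut[on, , drop = FALSE]] <- runif(sum(on), 0.05, 1)
  W + t(W)
}

oracle_strength <- function(W) colSums(W)

oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, n))
  Wh <- W / mx
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (u in nb) for (w in nb) {
      if (u != w) s <- s + (Wh[v, u] * Wh[v, w] * Wh[u, w])^(1 / 3)
    }
    out[v] <- s / (k * (k - 1))
  }
  out
}

# all-pairs shortest path lengths under d = 1/w, by Floyd-Warshall
oracle_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[W > 0] <- 1 / W[W > 0]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_local_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    m <- length(nb)
    if (m < 2) next
    d <- oracle_distances(W[nb, nb, drop = FALSE])
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out[v] <- sum(inv) / (m * (m - 1))
  }
  out
}

oracle_closeness <- function(W) {
  n <- nrow(W)
  d <- oracle_distances(W)
  off <- d
  diag(off) <- NA
  if (all(is.finite(d))) {
    (n - 1) / rowSums(off, na.rm = TRUE)
  } else {
    inv <- 1 / off
    inv[!is.finite(inv)] <- 0
    rowSums(inv, na.rm = TRUE) / (n - 1)
  }
}

# exhaustive enumeration of simple paths for fractional betweenness
oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (u in which(W[v, ] > 0)) {
        if (!(u %in% path)) walk(c(path, u))
      }
    }
    walk(s)
    found
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, function(p) {
      sum(1 / W[cbind(p[-length(p)], p[-1])])
    }, 0)
    best <- min(lens)
    sp <- ps[lens <= best + tol]
    sigma <- length(sp)
    for (p in sp) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / sigma
    }
  }
  btw
}

oracle_eigenvector <- function(W, iters = 10000) {
  n <- nrow(W)
  # spectral shift: same eigenvectors, strictly dominant top eigenvalue
  # (plain power iteration oscillates on bipartite graphs, where
  # lambda_min = -lambda_max)
  S <- W + diag(1 + max(rowSums(W)), n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(iters)) {
    nv <- as.vector(S %*% v)
    nrm <- sqrt(sum(nv^2))
    if (nrm == 0) return(v)
    nv <- nv / nrm
    if (max(abs(nv - v)) < 1e-13) return(nv)
    v <- nv
  }
  v
}

# dense linear solve of the PageRank fixed point
oracle_pagerank <- function(W, damping = 0.85) {
  n <- nrow(W)
  s <- colSums(W)
  M <- matrix(1 / n, n, n)
  for (u in seq_len(n)) if (s[u] > 0) M[, u] <- W[, u] / s[u]
  p <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  p / sum(p)
}

oracle_disassortativity <- function(W) {
  s <- colSums(W)
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    num <- 0; den <- 0
    for (u in seq_len(n)) {
      if (W[v, u] > 0) {
        num <- num + W[v, u] * abs(s[v] - s[u])
        den <- den + W[v, u]
      }
    }
    if (den > 0) out[v] <- num / den
  }
  out
}

oracle_assortativity <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  s <- colSums(W)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  cor(x, y)
}

# brute-force step-up BH definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in seq(m, 1)) {
    val <- min(1, m / i * p[o[i]], prev)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
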