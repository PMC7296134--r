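# Node-level graph metrics for FA-weighted structural connectivity matrices.
#
# Edge weights are mean fractional anisotropy (FA) along inter-regional
# tracts, in [0, 1]. Path-based metrics use the distance d = 1/w, the usual
# convention for FA-weighted connectomes (stronger tracts are "shorter").

METRIC_NAMES <- c(
  "strength", "clustering", "local_efficiency", "betweenness",
  "closeness", "eigenvector", "pagerank", "local_disassortativity"
)

#' Validate a connectivity matrix
#'
#' Checks the invariants every connectivity matrix must satisfy: square,
#' symmetric (within `tol`), zero diagonal, no negative entries, no
#' missing values.
#'
#' @param W Numeric matrix of edge weights (mean FA per region pair).
#' @param tol Symmetry tolerance.
#' @return `W`, invisibly, with the diagonal forced to exact zero.
#' @export
validate_connectivity <- function(W, tol = 1e-10) {
  if (!is.matrix(W) || !is.numeric(W)) {
    abort_load("connectivity matrix must be a numeric matrix")
  }
  if (nrow(W) != ncol(W)) {
    abort_load(sprintf("connectivity matrix must be square, got %d x %d",
                       nrow(W), ncol(W)))
  }
  if (anyNA(W)) abort_load("connectivity matrix contains missing values")
  if (any(W < 0)) abort_load("connectivity matrix contains negative weights")
  if (max(abs(W - t(W))) > tol) {
    abort_load(sprintf("connectivity matrix is not symmetric (max |W - t(W)| = %.3g)",
                       max(abs(W - t(W)))))
  }
  if (max(abs(diag(W))) > tol) {
    abort_load("connectivity matrix has a non-zero diagonal")
  }
  diag(W) <- 0
  invisible(W)
}

#' @keywords internal
#' @noRd
as_igraph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node strength
#'
#' Sum of all connection weights incident to each region.
#'
#' @param W Symmetric connectivity matrix.
#' @return Numeric vector of strengths, one per region.
#' @export
node_strength <- function(W) {
  W <- validate_connectivity(W)
  unname(rowSums(W))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean weighted clustering: with normalized weights
#' \eqn{\hat w = w / \max(w)},
#' \eqn{C(v) = \frac{1}{k_v(k_v-1)} \sum_{u,w} (\hat w_{vu}\hat w_{vw}\hat w_{uw})^{1/3}}
#' where \eqn{k_v} is the binary degree. Nodes with fewer than two
#' neighbours get 0.
#'
#' @param W Symmetric connectivity matrix.
#' @return Numeric vector of clustering coefficients in \[0, 1\].
#' @export
weighted_clustering <- function(W) {
  W <- validate_connectivity(W)
  mx <- max(W)
  n <- nrow(W)
  if (mx == 0) return(rep(0, n))
  Wh <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  num <- diag(Wh %*% Wh %*% Wh)  # 2 x (sum over unordered triangles)
  denom <- k * (k - 1)
  out <- ifelse(denom > 0, num / denom, 0)
  unname(out)
}

#' @keywords internal
#' @noRd
distance_graph <- function(W) {
  g <- as_igraph(W)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$dist <- 1 / igraph::E(g)$weight
  }
  g
}

#' Local efficiency
#'
#' Latora-Marchiori local efficiency: for each node, the efficiency of the
#' subgraph induced by its neighbours, where efficiency is the mean of
#' inverse shortest-path lengths over ordered node pairs and path length is
#' computed under the distance d = 1/w. Nodes with fewer than two
#' neighbours get 0; unreachable pairs contribute 0.
#'
#' @param W Symmetric connectivity matrix.
#' @return Numeric vector of local efficiencies.
#' @export
local_efficiency <- function(W) {
  W <- validate_connectivity(W)
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    m <- length(nb)
    if (m < 2) next
    sub <- W[nb, nb, drop = FALSE]
    gs <- distance_graph(sub)
    d <- igraph::distances(gs, weights = igraph::E(gs)$dist)
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    out[v] <- sum(inv) / (m * (m - 1))
  }
  out
}

#' Betweenness and closeness centrality
#'
#' Shortest-path centralities under the distance d = 1/w. Betweenness uses
#' fractional counting over equal-length shortest paths. Closeness is
#' \eqn{(n-1)/\sum_u d(v,u)} on connected graphs; on disconnected graphs a
#' harmonic form \eqn{\sum_u 1/d(v,u) / (n-1)} is used so unreachable
#' pairs contribute zero rather than infinity.
#'
#' @param W Symmetric connectivity matrix.
#' @return List with numeric vectors `betweenness` and `closeness`.
#' @export
path_centralities <- function(W) {
  W <- validate_connectivity(W)
  n <- nrow(W)
  if (n == 1 || max(W) == 0) {
    return(list(betweenness = numeric(n), closeness = numeric(n)))
  }
  g <- distance_graph(W)
  btw <- igraph::betweenness(g, weights = igraph::E(g)$dist, directed = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$dist)
  offdiag <- d
  diag(offdiag) <- NA
  if (all(is.finite(d))) {
    clo <- (n - 1) / rowSums(offdiag, na.rm = TRUE)
  } else {
    inv <- 1 / offdiag
    inv[!is.finite(inv)] <- 0
    clo <- rowSums(inv, na.rm = TRUE) / (n - 1)
  }
  list(betweenness = unname(btw), closeness = unname(clo))
}

#' Eigenvector and PageRank centrality
#'
#' Eigenvector centrality is the non-negative principal eigenvector of the
#' weight matrix, normalized to unit Euclidean norm. PageRank is computed
#' on the weighted graph by power iteration with damping factor `damping`,
#' converging when the L1 change between iterates falls below `tol`;
#' strength-zero (dangling) nodes redistribute their mass uniformly.
#'
#' @param W Symmetric connectivity matrix.
#' @param damping PageRank damping factor.
#' @param tol L1 convergence tolerance for the PageRank iteration.
#' @param max_iter Iteration cap; exceeding it raises a numeric error
#'   carrying the last iterate residual.
#' @return List with numeric vectors `eigenvector` and `pagerank`
#'   (the latter sums to 1).
#' @export
spectral_centralities <- function(W, damping = 0.85, tol = 1e-9,
                                  max_iter = 1000L) {
  W <- validate_connectivity(W)
  n <- nrow(W)
  if (max(W) == 0) {
    return(list(eigenvector = rep(1 / sqrt(n), n), pagerank = rep(1 / n, n)))
  }
  ev <- eigen(W, symmetric = TRUE)
  v <- ev$vectors[, 1]
  # Perron vector of a non-negative matrix: fix the sign to non-negative.
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))

  s <- rowSums(W)
  p <- rep(1 / n, n)
  res <- Inf
  for (it in seq_len(max_iter)) {
    contrib <- ifelse(s > 0, p / s, 0)
    dangling <- sum(p[s == 0])
    p_new <- (1 - damping) / n + damping * (as.vector(W %*% contrib) + dangling / n)
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) break
  }
  if (res >= tol) {
    abort_numeric(sprintf(
      "PageRank did not converge in %d iterations (L1 residual %.3g)",
      max_iter, res), residual = res)
  }
  list(eigenvector = unname(v), pagerank = unname(p / sum(p)))
}

#' Local disassortativity
#'
#' Per-node contribution to network disassortativity: the edge-weighted
#' mean absolute strength difference between a node and its neighbours,
#' \deqn{\delta(v) = \sum_{u \in N(v)} w_{vu} |s(v) - s(u)| / \sum_{u \in N(v)} w_{vu}.}
#' \eqn{\delta(v)} shrinks when the strength gap between a region and its
#' neighbourhood closes (by strengthening or weakening on either side) and
#' grows as that gap widens. Isolated nodes get 0. "Local assortativity"
#' is reported as the negated, across-region standardized value
#' (see [local_assortativity()]).
#'
#' @param W Symmetric connectivity matrix.
#' @return Numeric vector of disassortativities (non-negative).
#' @export
local_disassortativity <- function(W) {
  W <- validate_connectivity(W)
  s <- rowSums(W)
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    wv <- W[v, ]
    tot <- sum(wv)
    if (tot > 0) out[v] <- sum(wv * abs(s[v] - s)) / tot
  }
  out
}

#' Local assortativity (sign/scale convention)
#'
#' Negated local disassortativity, standardized across regions (z-scored),
#' so that positive values mark regions whose neighbourhood strengths are
#' unusually similar to their own.
#'
#' @param W Symmetric connectivity matrix.
#' @return Numeric vector, mean 0 and sd 1 across regions (all-equal
#'   disassortativities return all zeros).
#' @export
local_assortativity <- function(W) {
  delta <- local_disassortativity(W)
  if (stats::sd(delta) == 0) return(rep(0, length(delta)))
  as.vector(-scale(delta))
}

#' Global assortativity
#'
#' Pearson correlation of endpoint strengths over the edge list, each
#' undirected edge contributing both orientations. Quantifies the tendency
#' of regions to connect to regions of similar strength.
#'
#' @param W Symmetric connectivity matrix.
#' @return Scalar correlation in \[-1, 1\].
#' @export
global_assortativity <- function(W) {
  W <- validate_connectivity(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort_undefined("graph has no edges")
  s <- rowSums(W)
  x <- c(s[idx[, 1]], s[idx[, 2]])
  y <- c(s[idx[, 2]], s[idx[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_undefined(
      "global assortativity undefined: endpoint strengths have zero variance")
  }
  stats::cor(x, y)
}

#' Compute the full node metric table
#'
#' Assembles all node-level metric families in fixed column order, plus the
#' graph-level global assortativity (as an attribute and a list element).
#'
#' @param W Symmetric connectivity matrix.
#' @param region_labels Optional character vector of region names; defaults
#'   to the matrix dimnames or `R001`-style labels.
#' @return A `data.frame` with columns `region` and the eight node metrics
#'   (`strength`, `clustering`, `local_efficiency`, `betweenness`,
#'   `closeness`, `eigenvector`, `pagerank`, `local_disassortativity`),
#'   with attribute `global_assortativity`.
#' @export
compute_metric_table <- function(W, region_labels = NULL) {
  W <- validate_connectivity(W)
  n <- nrow(W)
  if (is.null(region_labels)) {
    region_labels <- rownames(W) %||% sprintf("R%03d", seq_len(n))
  }
  stopifnot(length(region_labels) == n)

  call_metric <- function(name, fn) {
    tryCatch(fn(W), error = function(e) {
      stop(errorCondition(
        sprintf("metric '%s' failed: %s", name, conditionMessage(e)),
        metric = name, class = c("netrecov_metric_error", "netrecov_error")))
    })
  }

  pc <- call_metric("path_centralities", path_centralities)
  sc <- call_metric("spectral_centralities", spectral_centralities)
  tab <- data.frame(
    region = region_labels,
    strength = call_metric("strength", node_strength),
    clustering = call_metric("clustering", weighted_clustering),
    local_efficiency = call_metric("local_efficiency", local_efficiency),
    betweenness = pc$betweenness,
    closeness = pc$closeness,
    eigenvector = sc$eigenvector,
    pagerank = sc$pagerank,
    local_disassortativity = call_metric("local_disassortativity",
                                         local_disassortativity),
    stringsAsFactors = FALSE
  )
  attr(tab, "global_assortativity") <-
    call_metric("global_assortativity", global_assortativity)
  tab
}

#' Tidy (long) form of one or more metric tables
#'
#' @param tables Named list of metric tables from [compute_metric_table()],
#'   names of the form `subject_timepoint` (e.g. `"P01_early"`).
#' @return Long `data.frame` with columns subject, timepoint, region,
#'   metric, value; the graph-level assortativity appears with region
#'   `"global"` and metric `"global_assortativity"`.
#' @export
metric_tables_to_tidy <- function(tables) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  rows <- lapply(names(tables), function(key) {
    tab <- tables[[key]]
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    tp <- parts[length(parts)]
    subj <- paste(parts[-length(parts)], collapse = "_")
    long <- do.call(rbind, lapply(METRIC_NAMES, function(m) {
      data.frame(subject = subj, timepoint = tp, region = tab$region,
                 metric = m, value = tab[[m]], stringsAsFactors = FALSE)
    }))
    rbind(long, data.frame(subject = subj, timepoint = tp, region = "global",
                           metric = "global_assortativity",
                           value = attr(tab, "global_assortativity"),
                           stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}

#' Read a connectivity matrix from CSV/TSV
#'
#' Accepts labeled (header row of region names) or headerless numeric
#' files; the separator is sniffed from the first line.
#'
#' @param path File path.
#' @return Validated numeric matrix with region dimnames when labeled.
#' @export
read_connectivity_matrix <- function(path) {
  if (!file.exists(path)) abort_load(sprintf("matrix file not found: %s", path),
                                     file = path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  labeled <- grepl("[A-Za-z]", first)
  df <- tryCatch(
    utils::read.table(path, header = labeled, sep = sep,
                      check.names = FALSE, row.names = NULL),
    error = function(e) abort_load(
      sprintf("cannot parse matrix file %s: %s", path, conditionMessage(e)),
      file = path))
  M <- as.matrix(df)
  if (!is.numeric(M)) abort_load(
    sprintf("matrix file %s contains non-numeric entries", path), file = path)
  if (labeled) rownames(M) <- colnames(M)
  out <- tryCatch(validate_connectivity(M), error = function(e) abort_load(
    sprintf("invalid connectivity matrix in %s: %s", path, conditionMessage(e)),
    file = path))
  M
}

#' Write a connectivity matrix to CSV
#'
#' @param W Matrix; @param path destination file.
#' @export
write_connectivity_matrix <- function(W, path) {
  labels <- rownames(W) %||% sprintf("R%03d", seq_len(nrow(W)))
  df <- as.data.frame(W)
  names(df) <- labels
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
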