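#' Channel-correlation connectivity matrix of one epoch
#'
#' Entry `(i, j)` is the absolute Pearson correlation between channels `i`
#' and `j` within the epoch; the diagonal is zeroed. A constant channel has
#' undefined correlations; its entries are set to 0 with a notice.
#'
#' @param epoch Numeric matrix, channels x samples (>= 2 channels).
#' @return Symmetric matrix with entries in `[0, 1]`, zero diagonal.
#' @export
connectivity <- function(epoch) {
  if (nrow(epoch) < 2) stop("need at least 2 channels")
  sds <- apply(epoch, 1, sd)
  if (any(sds == 0))
    message("connectivity: ", sum(sds == 0),
            " constant channel(s); their correlations set to 0")
  cm <- suppressWarnings(abs(cor(t(epoch))))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  cm
}

#' Threshold a connectivity matrix into a binary graph
#'
#' Edge `(i, j)` present iff the connectivity entry is `>= threshold`
#' (the boundary is included).
#'
#' @param conn Connectivity matrix ([connectivity()]).
#' @param threshold Fraction in `(0, 1)`; default 0.7.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal, class
#'   `binary_graph`.
#' @export
binarize <- function(conn, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  adj <- (conn >= threshold) * 1
  diag(adj) <- 0
  structure(adj, class = c("binary_graph", "matrix", "array"))
}

#' Mean clustering coefficient
#'
#' Per node, `C_i = 2 e_i / (k_i (k_i - 1))` where `e_i` counts edges among
#' the neighbors of node `i` and `k_i` is its degree; `C_i` is defined as 0
#' when `k_i < 2`. Returns the mean over nodes.
#'
#' @param adj Symmetric 0/1 adjacency matrix (zero diagonal).
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj) {
  adj <- unclass(adj)
  k <- rowSums(adj)
  # 2*e_i = number of ordered neighbor pairs of i that are connected
  e2 <- diag(adj %*% adj %*% adj)
  ci <- ifelse(k < 2, 0, e2 / (k * (k - 1)))
  mean(ci)
}

# All-pairs shortest-path matrix (edge counts) via igraph BFS.
shortest_paths_matrix <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(unclass(adj), mode = "undirected")
  igraph::distances(g)
}

#' Characteristic path length
#'
#' Mean shortest-path length `l_ij` over ordered node pairs `i != j`.
#' Disconnected pairs are excluded from the average; the connected
#' fraction is attached as attribute `connected_fraction` (1 for a
#' connected graph). An empty graph has no defined path length and
#' returns `NA`.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Scalar >= 1, or `NA` for an edgeless graph.
#' @export
path_length <- function(adj) {
  if (sum(adj) == 0) return(NA_real_)
  d <- shortest_paths_matrix(adj)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  structure(mean(off[finite]),
            connected_fraction = mean(finite))
}

#' Global efficiency
#'
#' Mean of `1 / l_ij` over ordered node pairs, with `1 / Inf = 0` for
#' disconnected pairs — well-defined for any graph, including disconnected
#' and empty ones.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(adj) {
  d <- shortest_paths_matrix(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

# Degree-preserving rewired null graph (double-edge swaps).
rewire_null <- function(adj, n_swaps) {
  g <- igraph::graph_from_adjacency_matrix(unclass(adj), mode = "undirected")
  g <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps))
  igraph::as_adjacency_matrix(g, sparse = FALSE)
}

#' Small-worldness
#'
#' `sigma = gamma / delta`, where `gamma` is the clustering coefficient
#' divided by the mean clustering of `n_random` degree-preserving rewired
#' null graphs and `delta` is the analogous path-length ratio. Null graphs
#' are produced by seeded double-edge swaps (10 x edge-count swap attempts
#' each). When rewiring cannot change the graph (e.g. complete or empty
#' graphs) the null equals the original and `sigma = 1`; `sigma > 1`
#' indicates small-world organization.
#'
#' @param adj Symmetric 0/1 adjacency matrix.
#' @param n_random Number of null graphs (default 20).
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Scalar > 0, or `NA` when the path length is undefined.
#' @export
small_worldness <- function(adj, n_random = 20, seed = 1) {
  stopifnot(n_random >= 1)
  c0 <- clustering_coefficient(adj)
  l0 <- as.numeric(path_length(adj))
  if (is.na(l0)) return(NA_real_)
  ne <- sum(adj) / 2
  with_seed(as.integer(seed), {
    cr <- numeric(n_random)
    lr <- numeric(n_random)
    for (i in seq_len(n_random)) {
      null <- rewire_null(adj, n_swaps = max(1, 10 * ne))
      cr[i] <- clustering_coefficient(null)
      lr[i] <- as.numeric(path_length(null))
    }
  })
  mc <- mean(cr)
  ml <- mean(lr, na.rm = TRUE)
  # triangle-free nulls give mc = 0: gamma is 1 when the original is also
  # triangle-free (null indistinguishable) and undefined otherwise
  gamma <- if (mc > 0) c0 / mc else if (c0 == 0) 1 else NA_real_
  delta <- if (is.finite(ml) && ml > 0) l0 / ml else NA_real_
  gamma / delta
}

#' All synchronization features of one epoch
#'
#' Builds the absolute-correlation graph of the epoch ([connectivity()] then
#' [binarize()]) and returns its mean degree, mean clustering coefficient,
#' characteristic path length, global efficiency and small-worldness.
#'
#' @param epoch Numeric matrix, channels x samples.
#' @param threshold Binarization threshold.
#' @param n_random,seed Null-model settings for [small_worldness()].
#' @return Named numeric vector `c(mean_degree, clustering, path_length,
#'   efficiency, small_worldness)`; entries may be `NA` for degenerate
#'   (edgeless) graphs.
#' @export
network_features <- function(epoch, threshold = 0.7, n_random = 20,
                             seed = 1) {
  adj <- binarize(suppressMessages(connectivity(epoch)), threshold)
  c(mean_degree = mean(rowSums(adj)),
    clustering = clustering_coefficient(adj),
    path_length = as.numeric(path_length(adj)),
    efficiency = global_efficiency(adj),
    small_worldness = small_worldness(adj, n_random, seed))
}
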