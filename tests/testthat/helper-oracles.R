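# Independent reference implementations, written directly from the defining
# formulas.  These deliberately share no code with the package internals:
# entropies use explicit template/distance-matrix constructions, graph
# metrics use literal enumeration.

# Chebyshev distance matrix between all length-m templates of x (first nt).
template_dist <- function(x, m, nt) {
  d <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    v <- x[(1:nt) + k]
    d <- pmax(d, abs(outer(v, v, "-")))
  }
  d
}

oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    d <- template_dist(x, mm, nt)
    cnt <- rowSums(d <= r)          # self-match included
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

oracle_sampen <- function(x, m, r) {
  nt <- length(x) - m               # Richman-Moorman template count
  dm <- template_dist(x, m, nt)
  dm1 <- template_dist(x, m + 1, nt)
  off <- upper.tri(dm)              # unordered pairs, i != j
  bm <- sum(dm[off] <= r)
  bm1 <- sum(dm1[off] <= r)
  if (bm == 0 || bm1 == 0) return(NA_real_)
  -log(bm1 / bm)
}

oracle_permen <- function(x, n) {
  nw <- length(x) - n + 1
  pats <- vapply(seq_len(nw), function(w)
    paste(order(x[w:(w + n - 1)]), collapse = ""), "")
  p <- table(pats) / nw
  -sum(p * log(p))
}

coarse_grain_oracle <- function(x, tau) {
  nb <- length(x) %/% tau
  vapply(seq_len(nb), function(j)
    mean(x[((j - 1) * tau + 1):(j * tau)]), 0)
}

oracle_mse <- function(x, m, r_factor, tau) {
  oracle_sampen(coarse_grain_oracle(x, tau), m, r = r_factor * sd(x))
}

# --- graph metric oracles (literal enumeration) ---

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { ci[i] <- 0; next }
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && adj[nb[a], nb[b]] == 1) e <- e + 1
    }
    ci[i] <- 2 * e / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by explicit breadth-first search
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (!is.finite(d[s, w]) && w != s) { d[s, w] <- depth; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_path_length <- function(adj) {
  if (sum(adj) == 0) return(NA_real_)
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(adj)
  sum(inv) / (n * (n - 1))
}

random_graph <- function(n, p) {
  adj <- matrix(0, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.numeric(runif(sum(up)) < p)
  adj + t(adj)
}
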