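path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))        # a - b - c
complete_graph <- function(n) { a <- matrix(1, n, n); diag(a) <- 0; a }
star_graph <- function(n) {
  a <- matrix(0, n, n); a[1, 2:n] <- 1; a[2:n, 1] <- 1; a
}

test_that("connectivity is |Pearson r| with a zero diagonal", {
  set.seed(3)
  x <- rnorm(500)
  ep <- rbind(x, x, rnorm(500))                  # duplicated channel
  cm <- connectivity(ep)
  expect_equal(cm[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(cm), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(cm))

  # sign flip leaves the matrix unchanged
  ep2 <- ep; ep2[1, ] <- -ep2[1, ]
  expect_equal(connectivity(ep2), cm, tolerance = 1e-12)

  # independent channels: small entries
  set.seed(4)
  big <- matrix(rnorm(4 * 2000), 4, 2000)
  expect_lt(max(connectivity(big)), 0.1)

  # constant channel: correlations defined as 0, with a notice
  ep3 <- rbind(rnorm(100), rep(1, 100))
  expect_message(cm3 <- connectivity(ep3), "constant")
  expect_equal(cm3[1, 2], 0)

  expect_error(connectivity(matrix(rnorm(10), 1, 10)), "2 channels")
})

test_that("binarization uses an inclusive threshold", {
  cm <- matrix(0.9, 4, 4); diag(cm) <- 0
  expect_equal(unclass(binarize(cm, 0.7)), complete_graph(4),
               ignore_attr = TRUE)
  expect_equal(sum(binarize(cm, 0.95)), 0)
  # boundary: entry equal to the threshold is an edge
  cm[1, 2] <- cm[2, 1] <- 0.7
  expect_equal(binarize(cm, 0.7)[1, 2], 1)
  expect_error(binarize(cm, 0), "threshold")
})

test_that("closed-form graph metrics hold", {
  k5 <- complete_graph(5)
  expect_equal(clustering_coefficient(k5), 1)
  expect_equal(as.numeric(path_length(k5)), 1)
  expect_equal(global_efficiency(k5), 1)

  expect_equal(clustering_coefficient(star_graph(6)), 0)

  expect_equal(as.numeric(path_length(path3)), 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)

  empty <- matrix(0, 4, 4)
  expect_true(is.na(path_length(empty)))
  expect_equal(global_efficiency(empty), 0)

  # two disjoint edges: disconnected pairs excluded from L
  two_pairs <- matrix(0, 4, 4)
  two_pairs[1, 2] <- two_pairs[2, 1] <- 1
  two_pairs[3, 4] <- two_pairs[4, 3] <- 1
  L <- path_length(two_pairs)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "connected_fraction"), 4 / 12)
})

test_that("graph metrics match exhaustive enumeration on random graphs", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, runif(1, 0.15, 0.85))
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(adj), oracle_efficiency(adj),
                 tolerance = 1e-12)
    L <- path_length(adj)
    Lo <- oracle_path_length(adj)
    if (is.na(Lo)) expect_true(is.na(L))
    else expect_equal(as.numeric(L), Lo, tolerance = 1e-12)
  }
})

test_that("small-worldness behaves canonically", {
  # complete graph: rewiring cannot change anything
  expect_equal(small_worldness(complete_graph(6), n_random = 5, seed = 1), 1)

  # Erdos-Renyi graphs are their own null in expectation
  set.seed(66)
  sig_er <- vapply(1:20, function(i)
    small_worldness(random_graph(19, 0.3), n_random = 10, seed = i), 0)
  expect_lt(abs(mean(sig_er, na.rm = TRUE) - 1), 0.3)

  # Watts-Strogatz ring (k = 4, light rewiring) is small-world
  ws <- function(seed) {
    set.seed(seed)
    g <- igraph::sample_smallworld(1, 19, 2, 0.1)
    igraph::as_adjacency_matrix(igraph::simplify(g), sparse = FALSE)
  }
  sig_ws <- vapply(1:10, function(i)
    small_worldness(ws(i), n_random = 10, seed = i), 0)
  expect_gt(mean(sig_ws), 1)

  # determinism under a fixed seed
  adj <- random_graph(12, 0.3)
  expect_identical(small_worldness(adj, n_random = 8, seed = 42),
                   small_worldness(adj, n_random = 8, seed = 42))
})

test_that("network features respond monotonically to coupling", {
  mean_deg <- vapply(c(0.3, 0.6, 0.9), function(cp) {
    spec <- group_spec("X", 1, duration_s = 8, fs = 200, coupling = cp,
                       channel_labels = paste0("ch", 1:6))
    mean(vapply(1:5, function(s) {
      rec <- generate_recording(spec, "S", seed = 4000 + s)
      es <- make_epochs(rec)
      mean(vapply(seq_len(dim(es$data)[3]), function(k) {
        adj <- binarize(suppressMessages(connectivity(es$data[, , k])), 0.7)
        mean(rowSums(adj))
      }, 0))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_deg) >= 0))
})

test_that("network_features returns the five named metrics", {
  set.seed(8)
  ep <- matrix(rnorm(19 * 500), 19, 500)
  shared <- rnorm(500)
  ep <- sweep(ep * 0.45, 2, shared, "+")
  nf <- network_features(ep, threshold = 0.7, n_random = 5, seed = 2)
  expect_named(nf, c("mean_degree", "clustering", "path_length",
                     "efficiency", "small_worldness"))
  expect_true(all(is.finite(nf)))
})
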