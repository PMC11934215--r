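test_that("displacement correlation hits its exact limits", {
  # two beads: bead 2 copies bead 1's motion, bead 3 mirrors it
  set.seed(31)
  n <- 500
  z <- rnorm(n)
  co <- array(0, c(n, 3, 3))
  co[, 1, 1] <- z
  co[, 2, 1] <- z
  co[, 3, 1] <- -z
  traj <- trajectory_ensemble(co)
  C <- displacement_correlation(traj, reference = matrix(0, 3, 3),
                                fit = FALSE)
  expect_equal(C$C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C$C[1, 3], -1, tolerance = 1e-12)
  expect_true(isSymmetric(C$C, tol = 1e-12))
  expect_equal(diag(C$C), rep(1, 3))
})

test_that("independent displacements decorrelate at the sampling bound", {
  spec <- gaussian_ensemble_spec(diag(12), mean = chain_coords(4),
                                 n_frames = 1e5, seed = 6L)
  traj <- sample_gaussian_ensemble(spec)
  C <- displacement_correlation(traj, reference = chain_coords(4),
                                fit = FALSE)
  off <- C$C[upper.tri(C$C)]
  expect_lt(max(abs(off)), 3 / sqrt(1e5))
})

test_that("zero-variance residues are flagged and dropped from the graph", {
  set.seed(5)
  n <- 200
  co <- array(rnorm(n * 3 * 3, sd = 0.5), c(n, 3, 3))
  co[, 2, ] <- 1  # frozen bead
  traj <- trajectory_ensemble(co)
  ref <- apply(co, c(2, 3), mean)
  C <- displacement_correlation(traj, reference = ref, fit = FALSE)
  expect_equal(C$excluded, 2L)
  expect_true(all(is.na(C$C[2, ])))
  P <- contact_persistence(traj, cutoff = 100)
  g <- build_graph(C, P)
  deg <- igraph::degree(g$graph)
  expect_equal(unname(deg[2]), 0)
})

test_that("contact persistence counts strict-inequality contacts", {
  co <- array(0, c(4, 2, 3))
  co[, 2, 1] <- c(5, 7, 5, 7)  # oscillating pair
  traj <- trajectory_ensemble(co)
  expect_equal(contact_persistence(traj, cutoff = 6)$P[1, 2], 0.5)
  co[, 2, 1] <- 5
  expect_equal(contact_persistence(trajectory_ensemble(co),
                                   cutoff = 6)$P[1, 2], 1)
  co[, 2, 1] <- 7
  expect_equal(contact_persistence(trajectory_ensemble(co),
                                   cutoff = 6)$P[1, 2], 0)
})

test_that("graph weights follow -log|C| with persistence gating", {
  C <- diag(4)
  C[1, 2] <- C[2, 1] <- 1          # weight 0
  C[2, 3] <- C[3, 2] <- exp(-1)    # weight 1
  C[3, 4] <- C[4, 3] <- -0.5       # anticorrelated, kept with sign
  C[1, 4] <- C[4, 1] <- 0.9        # gated out by persistence below
  P <- matrix(1, 4, 4)
  P[1, 4] <- P[4, 1] <- 0.2
  cm <- structure(list(C = C, excluded = integer(0), selection = 1:4,
                       labels = as.character(1:4), reference_fit = FALSE),
                  class = "correlation_matrix")
  pm <- structure(list(P = P, cutoff = 6, selection = 1:4,
                       labels = as.character(1:4)),
                  class = "persistence_matrix")
  g <- build_graph(cm, pm, fraction = 0.3)
  eattr <- igraph::as_data_frame(g$graph)
  expect_equal(nrow(eattr), 3L)  # pair (1,4) gated out
  w12 <- eattr$weight[eattr$from == "1" & eattr$to == "2"]
  w23 <- eattr$weight[eattr$from == "2" & eattr$to == "3"]
  w34 <- eattr$weight[eattr$from == "3" & eattr$to == "4"]
  expect_equal(w12, 0)
  expect_equal(w23, 1)
  expect_equal(w34, -log(0.5))
  expect_equal(eattr$sign[eattr$from == "3" & eattr$to == "4"], -1)
})

test_that("shortest path agrees with exhaustive enumeration", {
  # the textbook case first
  W <- matrix(NA_real_, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[1, 3] <- W[3, 1] <- 3
  W[3, 4] <- W[4, 3] <- 0.5
  g <- cgraph_from_weights(W)
  sp <- shortest_path(g, 1, 3)
  expect_equal(sp$path, c(1L, 2L, 3L))
  expect_equal(sp$length, 2)
  # random graphs vs the brute-force oracle
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    W <- random_connected_graph(n)
    g <- cgraph_from_weights(W)
    src <- 1L
    snk <- n
    ours <- shortest_path(g, src, snk)
    oracle <- brute_shortest_path(W, src, snk)
    expect_equal(ours$length, oracle$length, tolerance = 1e-9)
    expect_equal(ours$path, oracle$path)
  }
})

test_that("disconnected source/sink is reported as such", {
  W <- matrix(NA_real_, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  g <- cgraph_from_weights(W)
  expect_error(shortest_path(g, 1, 4), "component")
  expect_warning(shortest_path_map(g, source = 1, sink = 2),
                 "components")
})

test_that("path identity is invariant under positive weight rescaling", {
  set.seed(23)
  for (rep in 1:10) {
    W <- random_connected_graph(6)
    alpha <- runif(1, 0.2, 5)
    p1 <- shortest_path(cgraph_from_weights(W), 1, 6)$path
    p2 <- shortest_path(cgraph_from_weights(alpha * W), 1, 6)$path
    expect_equal(p1, p2)
  }
})

test_that("SPM usage concentrates on a bridge between cliques", {
  # two 4-cliques joined by one light bridge edge
  W <- matrix(NA_real_, 8, 8)
  for (i in 1:3) for (j in (i + 1):4) W[i, j] <- W[j, i] <- 1
  for (i in 5:7) for (j in (i + 1):8) W[i, j] <- W[j, i] <- 1
  W[4, 5] <- W[5, 4] <- 0.5
  g <- cgraph_from_weights(W)
  m <- shortest_path_map(g)
  u <- m$node_usage
  expect_true(all(u[c(4, 5)] > max(u[-c(4, 5)])))
  # the bridge edge carries every cross-clique pair: 4 x 4 = 16 paths
  bridge <- m$edge_usage[m$edge_usage$i == 4 & m$edge_usage$j == 5, ]
  expect_equal(bridge$usage, 16)
  # complete graph with equal weights: all nodes tie by symmetry
  Wc <- matrix(1, 5, 5); diag(Wc) <- NA
  mc <- shortest_path_map(cgraph_from_weights(Wc))
  expect_equal(unname(diff(range(mc$node_usage))), 0)
})

test_that("SPM on the opener routes through the gate bead pair", {
  sim <- opener_fixture(n_frames = 2e4, seed = 77L)
  ref <- apply(sim$traj$coords, c(2, 3), mean)
  C <- displacement_correlation(sim$traj, reference = ref, fit = FALSE)
  P <- contact_persistence(sim$traj, cutoff = 40)
  m <- shortest_path_map(build_graph(C, P))
  top2 <- order(m$node_usage, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(3L, 4L))
  # the groove-to-groove communication path passes through the gate
  expect_true(all(c(3L, 4L) %in%
                    shortest_path(build_graph(C, P), 1, 2)$path))
})
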