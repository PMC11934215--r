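test_that("a single oscillating coordinate yields a single mode", {
  n <- 50
  co <- array(0, c(n, 3, 3))
  co[, 1, ] <- matrix(chain_coords(3)[1, ], n, 3, byrow = TRUE)
  co[, 2, ] <- matrix(chain_coords(3)[2, ], n, 3, byrow = TRUE)
  co[, 3, ] <- matrix(chain_coords(3)[3, ], n, 3, byrow = TRUE)
  co[, 2, 1] <- co[, 2, 1] + sin(seq_len(n))  # atom 2 along x only
  traj <- trajectory_ensemble(co)
  m <- fit_ed(traj, fit = FALSE)
  expect_gt(m$eigenvalues[1], 0)
  expect_lt(m$eigenvalues[2] / m$eigenvalues[1], 1e-10)
  # the mode is the x-axis of atom 2 (coordinate 4 in atom-major order)
  expect_equal(abs(m$eigenvectors[4, 1]), 1, tolerance = 1e-8)
  expect_equal(cumulative_variance(m, 1)[1], 1, tolerance = 1e-10)
})

test_that("rigid trajectories are rejected", {
  ref <- chain_coords(4)
  rigid <- trajectory_ensemble(aperm(array(ref, c(4, 3, 5)), c(3, 1, 2)))
  expect_error(fit_ed(rigid, fit = FALSE), "rank-0")
})

test_that("eigenvector orthonormality, variance identities, sign rule", {
  cv <- chain_gnm_covariance(6, contact_cutoff = 8)
  traj <- sample_gaussian_ensemble(gaussian_ensemble_spec(
    cv, n_frames = 5000, seed = 31L))
  m <- fit_ed(traj, fit = FALSE)
  V <- m$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-10))
  expect_equal(sum(m$eigenvalues), m$total_variance, tolerance = 1e-8)
  # deterministic sign: largest-magnitude coordinate positive
  for (j in 1:5) expect_gt(V[which.max(abs(V[, j])), j], 0)
  # projection variance equals the eigenvalue (exact identity)
  p <- project_ed(traj, m, k = 3)
  for (j in 1:3)
    expect_equal(var(p$proj[, j]), m$eigenvalues[j], tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$proj))), 1e-10)
  # Parseval: retained + discarded variance reconstructs the total
  expect_equal(sum(m$eigenvalues[1:3]) +
                 sum(m$eigenvalues[-(1:3)]), m$total_variance,
               tolerance = 1e-8)
})

test_that("recovered spectrum matches the designed covariance", {
  cv <- chain_gnm_covariance(8, contact_cutoff = 8)
  traj <- sample_gaussian_ensemble(gaussian_ensemble_spec(
    cv, n_frames = 4e4, seed = 32L))
  m <- fit_ed(traj, fit = FALSE)
  analytic <- sort(eigen(unclass(cv), symmetric = TRUE,
                         only.values = TRUE)$values, decreasing = TRUE)
  expect_lt(max(abs(m$eigenvalues[1:5] / analytic[1:5] - 1)), 0.08)
  # cumulative variance tracks the analytic partial sums
  cvf <- cumulative_variance(m, 5)
  expect_equal(cvf, cumsum(analytic[1:5]) / sum(analytic),
               tolerance = 0.05)
  expect_true(all(diff(cvf) >= 0) && cvf[5] <= 1)
})

test_that("opener PC1 projections are bimodal and track the state", {
  sim <- opener_fixture(n_frames = 2e4, seed = 33L)
  m <- fit_ed(sim$traj, fit = FALSE)
  p <- project_ed(sim$traj, m, k = 2)
  open_mean <- mean(p$proj[sim$labels == 1L, 1])
  closed_mean <- mean(p$proj[sim$labels == 0L, 1])
  gap <- abs(open_mean - closed_mean)
  expect_gt(gap, 3)  # two well-separated groups along PC1
  assign_open <- (p$proj[, 1] - closed_mean) / (open_mean - closed_mean)
  expect_gt(mean((assign_open > 0.5) == (sim$labels == 1L)), 0.95)
})

test_that("cosine content separates cosines, noise and matching orders", {
  n <- 5000
  tj <- (seq_len(n) - 0.5) / n
  expect_equal(cosine_content(cos(pi * tj), 1), 1, tolerance = 1e-6)
  expect_equal(cosine_content(cos(3 * pi * tj), 3), 1, tolerance = 1e-6)
  # mismatched order: orthogonal, content ~ 0
  expect_lt(cosine_content(cos(2 * pi * tj), 1), 1e-6)
  set.seed(3)
  expect_lt(cosine_content(rnorm(1e5), 1), 0.02)
  expect_error(cosine_content(rep(0, 100)), "zero series")
  expect_error(cosine_content(rnorm(3)), "at least 4")
  # a diffusing (random-walk) projection looks cosine-like: high content
  rw <- cumsum(rnorm(n))
  expect_gt(cosine_content(rw, 1), 0.3)
})

test_that("extreme-conformation interpolation sweeps the groove open", {
  sim <- opener_fixture(n_frames = 1e4, seed = 34L)
  m <- fit_ed(sim$traj, fit = FALSE)
  p <- project_ed(sim$traj, m, k = 2)
  sweep_traj <- interpolate_extremes(m, p, pc = 1, n_frames_out = 9,
                                     topology = sim$traj$topology)
  d <- distance_series(sweep_traj, "resid 1 and name CA",
                       "resid 2 and name CA")
  # monotone between closed-like and open-like groove distances
  expect_true(all(diff(d$values) > 0) || all(diff(d$values) < 0))
  expect_lt(min(d$values), sim$spec$d_closed + 1.5)
  expect_gt(max(d$values), sim$spec$d_open - 1.5)
})

test_that("interpolation endpoints and degenerate modes behave", {
  set.seed(35)
  n <- 200
  co <- array(0, c(n, 3, 3))
  co[, 1, 1] <- rnorm(n)
  base <- trajectory_ensemble(co)
  m <- fit_ed(base, fit = FALSE)
  p <- project_ed(base, m, k = 1)
  s3 <- interpolate_extremes(m, p, pc = 1, n_frames_out = 3)
  # endpoints at observed extreme projections
  pr <- project_ed(s3, m, k = 1)$proj[, 1]
  expect_equal(pr[1], min(p$proj[, 1]), tolerance = 1e-8)
  expect_equal(pr[3], max(p$proj[, 1]), tolerance = 1e-8)
  # a zero-amplitude mode sweeps nowhere: all frames equal the mean
  pz <- p; pz$proj[, 1] <- 0
  sz <- interpolate_extremes(m, pz, pc = 1, n_frames_out = 3)
  expect_equal(sz$coords[1, , ], sz$coords[3, , ], tolerance = 1e-12)
})
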