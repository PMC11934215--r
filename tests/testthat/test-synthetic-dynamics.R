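test_that("chain GNM covariance has the expected structure", {
  cv <- chain_gnm_covariance(5, contact_cutoff = 8)
  expect_true(isSymmetric(cv, tol = 1e-10))
  expect_true(all(eigen(cv, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-10))
  gp <- attr(cv, "gamma_pinv")
  # correlation decays with sequence separation: nearest neighbour
  # beats third neighbour
  corr <- function(i, j) gp[i, j] / sqrt(gp[i, i] * gp[j, j])
  expect_gt(corr(2, 3), corr(2, 5))
  # doubling kT doubles every covariance exactly (linearity)
  cv2 <- chain_gnm_covariance(5, contact_cutoff = 8, kT_scale = 2)
  expect_equal(as.vector(cv2), 2 * as.vector(cv), tolerance = 1e-12)
  # below the 3.8 A bead spacing the contact graph falls apart
  expect_error(chain_gnm_covariance(5, contact_cutoff = 3),
               "disconnected")
})

test_that("gaussian ensemble sampling reproduces the prescribed variance", {
  sigma2 <- 0.49
  spec <- gaussian_ensemble_spec(sigma2 * diag(9), n_frames = 1e5,
                                 seed = 11L)
  traj <- sample_gaussian_ensemble(spec)
  v <- apply(traj$coords, c(2, 3), var)
  # chi-square bound: relative error < 3% at 1e5 frames
  expect_true(all(abs(v / sigma2 - 1) < 0.03))
})

test_that("gaussian ensemble handles degenerate and invalid covariances", {
  spec0 <- gaussian_ensemble_spec(matrix(0, 6, 6),
                                  mean = cbind(1:2, 0, 0),
                                  n_frames = 10L, seed = 1L)
  traj0 <- sample_gaussian_ensemble(spec0)
  for (f in 1:10)
    expect_equal(frame_coords(traj0, f), unname(cbind(c(1, 2), 0, 0)),
                 ignore_attr = TRUE)
  bad <- diag(6); bad[1, 1] <- -1
  expect_error(sample_gaussian_ensemble(
    gaussian_ensemble_spec(bad, n_frames = 5L)), "semi-definite")
})

test_that("generators are pure functions of their seed", {
  s <- gaussian_ensemble_spec(diag(6), n_frames = 50L, seed = 99L)
  expect_identical(sample_gaussian_ensemble(s)$coords,
                   sample_gaussian_ensemble(s)$coords)
  o1 <- opener_fixture(n_frames = 500L, seed = 5L)
  o2 <- opener_fixture(n_frames = 500L, seed = 5L)
  expect_identical(o1$traj$coords, o2$traj$coords)
  expect_identical(o1$labels, o2$labels)
  # the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(opener_fixture(n_frames = 200L, seed = 1L))
  expect_identical(rnorm(1), before)
})

test_that("AR(1) option keeps the marginal variance but adds memory", {
  s <- gaussian_ensemble_spec(diag(3), n_frames = 4e4, seed = 2L,
                              ar_tau = 20)
  x <- sample_gaussian_ensemble(s)$coords[, 1, 1]
  expect_lt(abs(var(x) - 1), 0.1)
  expect_gt(cor(x[-1], x[-length(x)]), 0.9)
})

test_that("two-state opener realizes its designed statistics", {
  sim <- opener_fixture(n_frames = 2e5, seed = 8L)
  p <- sim$spec$p_open
  # stationary open fraction within 3 SE (Markov-chain CLT with the
  # relaxation-time variance inflation 2/k_switch)
  se <- sqrt(p * (1 - p) / (2e5 * sim$spec$k_switch / 2))
  expect_lt(abs(mean(sim$labels) - p), 3 * se)
  # groove series tracks the delayed state
  expect_gt(mean(sim$groove$values[sim$labels == 1]), 24)
  expect_lt(mean(sim$groove$values[sim$labels == 0]), 21.5)
  # bead coordinates realize the groove distance (small transverse
  # contact-noise perturbation allowed)
  d12 <- distance_series(sim$traj, "resid 1 and name CA",
                         "resid 2 and name CA")
  err <- abs(d12$values - sim$groove$values)
  expect_lt(mean(err), 0.1)
  expect_lt(unname(quantile(err, 0.999)), 1)
})

test_that("noise-free opener gives exactly two groove levels", {
  sim <- opener_fixture(n_frames = 5000L, seed = 3L, sigma = 0,
                        gate_sigma = 0, coupling = 0)
  expect_setequal(unique(sim$groove$values), c(20.5, 25.2))
  expect_setequal(unique(sim$gate$values), c(3.8, 8.0))
  # gate switches exactly at state changes
  expect_identical(sim$gate$values == 3.8, sim$gate_state == 1L)
})

test_that("lagged_pair injects the designed lag and correlation", {
  lp <- lagged_pair(2e4, lag = 3, rho = -0.8, seed = 21L)
  cc <- cross_correlation(lp$x, lp$y, max_lag = 30)
  ex <- cc_extremum(cc, "min")
  expect_equal(ex$lead, 3L)
  expect_lt(abs(ex$r - (-0.8)), 3 / sqrt(2e4))
  # rho = 1, lag = 0 gives identical (standardized) series
  lp1 <- lagged_pair(1000, 0, 1, seed = 2L)
  expect_equal(lp1$x, lp1$y, tolerance = 1e-12)
  # rho = 0: no lag survives the white-noise bound
  lp0 <- lagged_pair(2e4, lag = 5, rho = 0, seed = 4L)
  cc0 <- cross_correlation(lp0$x, lp0$y, max_lag = 20)
  expect_lt(max(abs(cc0$r)), 3 / sqrt(2e4))
  expect_error(lagged_pair(10, lag = 10, rho = 0.5), "lag")
})
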