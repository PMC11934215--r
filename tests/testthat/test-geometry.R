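make_frame <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 4), n, 3)
}

test_that("superposition recovers congruent frames exactly", {
  x <- make_frame(10)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotation about z plus a shift is removed completely
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)
  y <- sweep(x %*% Rz, 2, c(5, -2, 1), "+")
  fit2 <- superpose(x, y)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  expect_equal(apply_superposition(x, fit2), y, tolerance = 1e-8)
})

test_that("fitted RMSD matches the independent least-squares oracle", {
  set.seed(77)
  for (rep in 1:5) {
    a <- make_frame(10, seed = rep)
    b <- a
    b[3, ] <- b[3, ] + c(1, 0, 0)      # one atom displaced 1 A
    b <- sweep(b %*% .random_rotation(rep), 2, runif(3, -5, 5), "+")
    ours <- superpose(b, a)$rmsd
    # oracle: bio3d's independent Kabsch implementation
    oracle <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(ours, oracle, tolerance = 5e-3)  # bio3d rounds to 3 dp
  }
})

test_that("degenerate superpositions are rejected", {
  x <- make_frame(10)
  expect_error(superpose(x, x, selection = 1:2), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line + 0, line), "collinear")
})

test_that("rmsd series is zero for copies and tracks opener states", {
  ref <- make_frame(8)
  traj <- trajectory_ensemble(aperm(array(ref, c(8, 3, 4)), c(3, 1, 2)))
  expect_equal(rmsd_series(traj, ref), rep(0, 4), tolerance = 1e-10)

  sim <- opener_fixture(n_frames = 4000L, seed = 12L)
  ref_closed <- frame_coords(sim$traj, which(sim$labels == 0L)[1])
  r <- rmsd_series(sim$traj, ref_closed, fit = FALSE)
  # two plateaus tracking the hidden state labels
  expect_gt(mean(r[sim$labels == 1L]), mean(r[sim$labels == 0L]) + 1)
})

test_that("mean squared deviation matches the isotropic closed form", {
  sigma <- 0.7
  spec <- gaussian_ensemble_spec(sigma^2 * diag(30),
                                 mean = chain_coords(10),
                                 n_frames = 2e4, seed = 3L)
  traj <- sample_gaussian_ensemble(spec)
  r <- rmsd_series(traj, chain_coords(10), fit = FALSE)
  expect_lt(abs(mean(r^2) / (3 * sigma^2) - 1), 0.03)
  # fitting can only reduce the deviation
  rf <- rmsd_series(traj, chain_coords(10), fit = TRUE)
  expect_true(all(rf <= r + 1e-10))
})

test_that("rmsf matches the closed form and the GNM profile shape", {
  sigma <- 0.5
  spec <- gaussian_ensemble_spec(sigma^2 * diag(15),
                                 mean = chain_coords(5),
                                 n_frames = 1e5, seed = 4L)
  traj <- sample_gaussian_ensemble(spec)
  f <- rmsf(traj, fit = FALSE)
  expect_true(all(abs(f / (sqrt(3) * sigma) - 1) < 0.03))
  # rigid trajectory: all zeros
  ref <- chain_coords(5)
  rigid <- trajectory_ensemble(aperm(array(ref, c(5, 3, 3)), c(3, 1, 2)))
  expect_equal(rmsf(rigid, fit = FALSE), rep(0, 5), tolerance = 1e-12)
  expect_error(rmsf(trajectory_ensemble(ref)), "two frames")
  # elastic-network ensemble: chain termini fluctuate the most, and the
  # profile matches the analytic Laplacian pseudo-inverse diagonal
  cv <- chain_gnm_covariance(9, contact_cutoff = 8)
  g <- sample_gaussian_ensemble(gaussian_ensemble_spec(
    cv, n_frames = 5e4, seed = 5L))
  fg <- rmsf(g, fit = FALSE)
  expect_equal(which.max(fg) %in% c(1L, 9L), TRUE)
  analytic <- sqrt(3 * diag(attr(cv, "gamma_pinv")))
  expect_lt(max(abs(fg / analytic - 1)), 0.05)
})

test_that("distance series measures static geometry exactly", {
  co <- array(0, c(3, 2, 3))
  co[, 2, 1] <- 5
  traj <- trajectory_ensemble(co)
  d <- distance_series(traj, 1L, 2L)
  expect_equal(d$values, rep(5, 3))
  co[, 2, ] <- 0
  expect_equal(distance_series(trajectory_ensemble(co), 1L, 2L)$values,
               rep(0, 3))
  top <- topology(data.frame(name = "CA", element = "C", chain = "A",
                             resid = 1:2, resname = "GLY", insert = ""))
  traj2 <- trajectory_ensemble(co, topology = top)
  expect_error(distance_series(traj2, "calpha", 1L), "single-atom")
})

test_that("histogram peaks resolve designed mixtures", {
  set.seed(9)
  # unimodal: one peak near the mean, band = mean +/- 2 sigma
  x <- rnorm(2e4, 20, 1)
  h <- summarize_histogram(x)
  expect_equal(nrow(h$peaks), 1L)
  expect_lt(abs(h$peaks$position - 20), 0.25)
  expect_lt(abs(h$band2sigma[["lower"]] - (mean(x) - 2 * sd(x))), 1e-9)
  # balanced mixture at the two groove-distance peaks
  y <- c(rnorm(2e4, 20.5, 0.8), rnorm(2e4, 25.2, 0.8))
  h2 <- summarize_histogram(y)
  expect_equal(nrow(h2$peaks), 2L)
  expect_lt(abs(h2$peaks$position[1] - 20.5), 0.25)
  expect_lt(abs(h2$peaks$position[2] - 25.2), 0.25)
  # constant series: a single fully loaded bin
  hc <- summarize_histogram(rep(7.25, 500))
  expect_equal(sum(hc$counts), 500L)
  expect_equal(nrow(hc$peaks), 1L)
  expect_error(summarize_histogram(x, bin_width = 0), "positive")
})
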