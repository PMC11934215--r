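## Synthetic trajectory generators with known statistical structure.
## Every generator is a pure function of its seed: the RNG state is
## saved and restored so sampling never perturbs the caller's stream.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## topology for an N-bead chain (one pseudo C-alpha per bead)
.bead_topology <- function(n, resname = "GLY") {
  topology(data.frame(name = "CA", element = "C", chain = "A",
                      resid = seq_len(n), resname = resname, insert = "",
                      stringsAsFactors = FALSE))
}

#' Mean structure of a straight bead chain
#'
#' Beads along x at the canonical 3.8 Angstrom C-alpha spacing; the
#' geometry behind [chain_gnm_covariance()].
#'
#' @param n_residues number of beads
#' @return `n x 3` coordinate matrix (Angstrom)
#' @export
chain_coords <- function(n_residues) {
  cbind(3.8 * (seq_len(n_residues) - 1), 0, 0)
}

#' Elastic-network covariance for a bead chain
#'
#' Builds the Kirchhoff (contact Laplacian) matrix of a straight chain
#' with 3.8 Angstrom spacing, connecting beads closer than
#' `contact_cutoff`, and returns the Gaussian-network fluctuation
#' covariance: the Moore-Penrose pseudo-inverse of the Laplacian
#' (rigid-body null modes removed), applied isotropically to x, y, z and
#' scaled by `kT_scale`. The result is the `3N x 3N` positive
#' semi-definite matrix (Angstrom^2) consumed by
#' [sample_gaussian_ensemble()]; coordinate order is atom-major
#' (x1, y1, z1, x2, ...).
#'
#' @param n_residues number of beads (>= 2)
#' @param contact_cutoff contact distance in Angstrom; below the 3.8
#'   Angstrom spacing the contact graph is disconnected and an error is
#'   raised.
#' @param kT_scale overall variance scale (Angstrom^2); covariances are
#'   linear in it.
#' @return covariance matrix with attributes `mean` (the chain
#'   coordinates) and `gamma_pinv` (the `N x N` pseudo-inverse, whose
#'   diagonal gives per-residue mean-square fluctuations per axis).
#' @export
chain_gnm_covariance <- function(n_residues, contact_cutoff = 8,
                                 kT_scale = 1) {
  stopifnot(n_residues >= 2, contact_cutoff > 0, kT_scale > 0)
  xyz <- chain_coords(n_residues)
  d <- as.matrix(stats::dist(xyz))
  A <- (d < contact_cutoff) & upper.tri(d)
  A <- A | t(A)
  ## connectivity of the contact graph
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  if (igraph::components(g)$no > 1L)
    stop("contact graph is disconnected at cutoff ", contact_cutoff, " A")
  gamma <- diag(rowSums(A)) - A
  gp <- MASS::ginv(gamma)
  gp <- (gp + t(gp)) / 2
  cov3n <- kT_scale * kronecker(gp, diag(3))
  attr(cov3n, "mean") <- xyz
  attr(cov3n, "gamma_pinv") <- kT_scale * gp
  cov3n
}

#' Specification of a Gaussian fluctuation ensemble
#'
#' @param covariance `3N x 3N` symmetric positive semi-definite matrix,
#'   Angstrom^2, atom-major coordinate order.
#' @param mean `N x 3` mean structure (Angstrom). Defaults to the `mean`
#'   attribute of `covariance` when present (as set by
#'   [chain_gnm_covariance()]).
#' @param n_frames number of frames (>= 2)
#' @param dt frame spacing, ns
#' @param seed RNG seed (the generator is a pure function of it)
#' @param ar_tau frame-correlation time (frames). 0 draws frames
#'   independently; > 0 evolves an AR(1) process with autocorrelation
#'   `exp(-1/ar_tau)` per frame while preserving the same marginal
#'   covariance, which is what convergence diagnostics need.
#' @return class `"gaussian_ensemble_spec"`
#' @export
gaussian_ensemble_spec <- function(covariance, mean = NULL,
                                   n_frames = 1000L, dt = 0.001,
                                   seed = 1L, ar_tau = 0) {
  covariance <- as.matrix(covariance)
  p <- nrow(covariance)
  stopifnot(p %% 3L == 0L, ncol(covariance) == p, n_frames >= 2,
            dt > 0, ar_tau >= 0)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  if (is.null(mean)) mean <- attr(covariance, "mean")
  if (is.null(mean)) mean <- matrix(0, p / 3L, 3L)
  mean <- as.matrix(mean)
  stopifnot(nrow(mean) == p / 3L, ncol(mean) == 3L)
  structure(list(covariance = covariance, mean = mean,
                 n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed), ar_tau = ar_tau),
            class = "gaussian_ensemble_spec")
}

#' Sample a multivariate-Gaussian coordinate ensemble
#'
#' Frames are draws `mean + L z` with `L L' = covariance` (eigenvalue
#' square-root factor, so semi-definite covariances are accepted; a
#' meaningfully negative eigenvalue is an error). With `ar_tau > 0` the
#' latent `z` follows a stationary AR(1), keeping the same marginal
#' covariance but adding temporal memory.
#'
#' @param spec a [gaussian_ensemble_spec()]
#' @return a [trajectory_ensemble()] over an N-bead chain topology
#' @export
sample_gaussian_ensemble <- function(spec) {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  p <- nrow(spec$covariance)
  n <- spec$n_frames
  e <- eigen(spec$covariance, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  if (any(e$values < -max(tol, 1e-12)))
    stop("covariance is not positive semi-definite (eigenvalue ",
         format(min(e$values)), ")")
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% (sqrt(lam) * t(e$vectors))  # symmetric square root
  X <- .with_seed(spec$seed, {
    Z <- matrix(rnorm(n * p), n, p)
    if (spec$ar_tau > 0) {
      phi <- exp(-1 / spec$ar_tau)
      w <- sqrt(1 - phi^2)
      for (t in 2:n) Z[t, ] <- phi * Z[t - 1L, ] + w * Z[t, ]
    }
    Z %*% L
  })
  mu <- as.vector(t(spec$mean))          # atom-major flat mean
  X <- sweep(X, 2L, mu, "+")
  co <- aperm(array(t(X), c(3L, p / 3L, n)), c(3L, 2L, 1L))
  trajectory_ensemble(co, dt = spec$dt, topology = .bead_topology(p / 3L))
}

#' Specification of the two-state groove opener
#'
#' A hidden reversible two-state (closed/open) Markov chain drives a
#' 4-bead reporter system emulating the allosteric chain
#' H3 -- gate(H6/H7) -- H9: bead 1 anchors one groove edge, bead 2
#' carries the groove-opening distance along x, and beads 3-4 are the
#' gate pair whose separation drops to a ring--methyl contact in the
#' open state. The gate responds to the state immediately; the groove
#' follows `gate_lead` frames later, so the gate event precedes the
#' opening, and the two series are anti-correlated (small gate distance
#' goes with large groove distance). Groove beads carry no direct
#' correlated motion with each other: each shares a contact-noise
#' component only with its adjacent gate bead (`coupling`), so in the
#' displacement-correlation network all communication between the groove
#' edges is routed through the gate pair -- the designed ground truth
#' for shortest-path-map recovery.
#'
#' Defaults mirror the conditions reported for the flexible paralog:
#' closed/open groove distances at the 20.5 and 25.2 Angstrom
#' distribution peaks, a 3.8 Angstrom gate contact in the open state,
#' and a minority open population.
#'
#' @param d_closed,d_open groove distance means, Angstrom
#'   (`d_open > d_closed`)
#' @param sigma within-state SD of the groove distance, Angstrom
#' @param p_open stationary open fraction, in (0, 1)
#' @param k_switch per-frame switch attempt rate; transition
#'   probabilities are `k_switch * p_open` (closed to open) and
#'   `k_switch * (1 - p_open)` (open to closed), which leaves `p_open`
#'   stationary.
#' @param gate_lead frames by which the gate event precedes the groove
#'   response (>= 0)
#' @param gate_open,gate_closed gate (ring--methyl) distance in the
#'   open / closed state, Angstrom
#' @param gate_sigma within-state SD of the gate distance, Angstrom
#' @param coupling amplitude (Angstrom) of the shared contact-noise
#'   between each groove bead and its adjacent gate bead
#' @param n_frames,dt,seed as in [gaussian_ensemble_spec()]
#' @return class `"two_state_opener_spec"`
#' @export
two_state_opener_spec <- function(d_closed = 20.5, d_open = 25.2,
                                  sigma = 0.8, p_open = 0.3,
                                  k_switch = 0.05, gate_lead = 40L,
                                  gate_open = 3.8, gate_closed = 8.0,
                                  gate_sigma = 0.3, coupling = 1.0,
                                  n_frames = 20000L, dt = 0.001,
                                  seed = 1L) {
  stopifnot(p_open > 0, p_open < 1, d_open > d_closed, gate_lead >= 0,
            sigma >= 0, gate_sigma >= 0, k_switch > 0, k_switch <= 1,
            n_frames >= 2, dt > 0, coupling >= 0,
            gate_closed > gate_open)
  structure(list(d_closed = d_closed, d_open = d_open, sigma = sigma,
                 p_open = p_open, k_switch = k_switch,
                 gate_lead = as.integer(gate_lead),
                 gate_open = gate_open, gate_closed = gate_closed,
                 gate_sigma = gate_sigma, coupling = coupling,
                 n_frames = as.integer(n_frames), dt = dt,
                 seed = as.integer(seed)),
            class = "two_state_opener_spec")
}

#' Simulate the two-state groove opener
#'
#' @param spec a [two_state_opener_spec()]
#' @return a list with
#' \describe{
#'   \item{traj}{4-bead [trajectory_ensemble()] realizing the groove
#'     distance between beads 1-2 and the gate distance between beads
#'     3-4}
#'   \item{labels}{per-frame structural state of the groove (0 closed,
#'     1 open; this is the gate state delayed by `gate_lead`)}
#'   \item{gate_state}{per-frame undelayed hidden state driving the
#'     gate}
#'   \item{gate}{gate [distance series][distance_series] (ground-truth
#'     scalar series, Angstrom)}
#'   \item{groove}{groove distance series (ground truth, Angstrom)}
#'   \item{spec}{the input spec (ground truth for tests)}
#' }
#' @export
simulate_two_state_opener <- function(spec) {
  stopifnot(inherits(spec, "two_state_opener_spec"))
  n <- spec$n_frames
  out <- .with_seed(spec$seed, {
    s <- integer(n)
    s[1] <- rbinom(1L, 1L, spec$p_open)
    p_co <- spec$k_switch * spec$p_open        # closed -> open
    p_oc <- spec$k_switch * (1 - spec$p_open)  # open -> closed
    u <- runif(n)
    for (t in 2:n)
      s[t] <- if (s[t - 1L] == 1L) as.integer(u[t] >= p_oc)
              else as.integer(u[t] < p_co)
    sdel <- c(rep(s[1], spec$gate_lead), s)[seq_len(n)]
    gate <- ifelse(s == 1L, spec$gate_open, spec$gate_closed) +
      rnorm(n, 0, spec$gate_sigma)
    groove <- ifelse(sdel == 1L, spec$d_open, spec$d_closed) +
      rnorm(n, 0, spec$sigma)
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    list(s = s, sdel = sdel, gate = gate, groove = groove,
         e1 = e1, e2 = e2)
  })
  k <- spec$coupling
  X <- array(0, c(n, 4L, 3L))
  X[, 2L, 1L] <- out$groove                 # groove realized along x
  X[, 3L, 2L] <- 15 - out$gate / 2          # gate pair along y
  X[, 4L, 2L] <- 15 + out$gate / 2
  X[, 1L, 3L] <- k * out$e1                 # contact coupling bead1-bead3
  X[, 3L, 3L] <- k * out$e1
  X[, 2L, 3L] <- k * out$e2                 # contact coupling bead2-bead4
  X[, 4L, 3L] <- k * out$e2
  traj <- trajectory_ensemble(X, dt = spec$dt,
                              topology = .bead_topology(4L))
  list(traj = traj,
       labels = out$sdel,
       gate_state = out$s,
       gate = distance_series_from_values(out$gate, spec$dt,
                                          "gate F-ring/Ala contact"),
       groove = distance_series_from_values(out$groove, spec$dt,
                                            "groove H3-H9 opening"),
       spec = spec)
}

#' Generate a standardized pair of series with an injected lead--lag
#'
#' `y(t) = rho * x(t - lag) + sqrt(1 - rho^2) * noise`, both returned
#' standardized. With positive `lag`, `x` leads `y`; the injected
#' coupling is recovered by [cross_correlation()] at a negative extremum
#' lag equal to `-lag` (equivalently `lead = lag`). The null case
#' `rho = 0` calibrates the significance bound.
#'
#' @param n series length
#' @param lag integer frames (`|lag| < n`)
#' @param rho target correlation in `[-1, 1]`
#' @param seed RNG seed
#' @return list of numeric vectors `x`, `y` of length `n`
#' @export
lagged_pair <- function(n, lag, rho, seed = 1L) {
  stopifnot(abs(rho) <= 1, n >= 2)
  lag <- as.integer(lag)
  if (abs(lag) >= n) stop("|lag| must be smaller than n")
  .with_seed(seed, {
    xx <- rnorm(n + abs(lag))
    noise <- rnorm(n)
    if (lag >= 0) {
      x <- xx[(abs(lag) + 1):(n + abs(lag))]
      xl <- xx[1:n]                       # x(t - lag)
    } else {
      x <- xx[1:n]
      xl <- xx[(abs(lag) + 1):(n + abs(lag))]
    }
    y <- rho * xl + sqrt(1 - rho^2) * noise
    list(x = as.vector(scale(x)), y = as.vector(scale(y)))
  })
}
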