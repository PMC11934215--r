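## Essential dynamics: PCA of C-alpha fluctuations, projections,
## convergence diagnostics and extreme-conformation interpolation.

#' Fit an essential-dynamics (PCA) model
#'
#' Frames are least-squares fitted to the reference over the selection
#' (unless `fit = FALSE`), the `3N x 3N` covariance of the selected
#' coordinates about their mean is formed (unweighted -- C-alpha
#' selections are conventionally analyzed with unit masses), and its
#' symmetric eigendecomposition gives the essential modes. Eigenvector
#' signs are fixed by making each vector's largest-magnitude coordinate
#' positive, so refits of resampled data agree.
#'
#' @param traj a [trajectory_ensemble()] (>= 2 frames)
#' @param selection atoms to analyze (default all)
#' @param reference superposition target (`n_atoms x 3`, default
#'   frame 1); by convention the X-ray/start structure, matching the
#'   displacement-correlation reference
#' @param fit superpose frames first (default TRUE); set `FALSE` for
#'   ensembles already in a common frame
#' @param n_components number of modes to retain (default all)
#' @return class `"ed_model"`: `eigenvectors` (`3N x k`, orthonormal,
#'   atom-major), `eigenvalues` (Angstrom^2, descending),
#'   `total_variance` (trace of the covariance), `mean` (length `3N`),
#'   `selection`, `fit`, `reference`.
#' @export
fit_ed <- function(traj, selection = NULL,
                   reference = frame_coords(traj, 1L), fit = TRUE,
                   n_components = NULL) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames for PCA")
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else as.integer(.as_selection(selection, traj$topology))
  co <- if (fit) .fit_frames(traj, reference, sel) else traj$coords
  X <- .flatten_coords(co, sel)
  mu <- colMeans(X)
  Cv <- cov(X)
  tot <- sum(diag(Cv))
  if (tot <= 1e-12) stop("rank-0 trajectory: no coordinate fluctuates")
  e <- eigen(Cv, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  V <- e$vectors
  ## deterministic sign: largest-magnitude coordinate positive
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  k <- if (is.null(n_components)) ncol(V)
       else min(as.integer(n_components), ncol(V))
  structure(list(eigenvectors = V[, seq_len(k), drop = FALSE],
                 eigenvalues = lam[seq_len(k)],
                 total_variance = tot, mean = mu, selection = sel,
                 fit = fit, reference = reference),
            class = "ed_model")
}

## frames x atoms x 3 -> frames x 3N (atom-major: x1,y1,z1,x2,...)
.flatten_coords <- function(co, sel) {
  nf <- dim(co)[1]
  N <- length(sel)
  X <- matrix(0, nf, 3L * N)
  for (d in 1:3) X[, seq(d, 3L * N, by = 3L)] <- co[, sel, d]
  X
}

#' @export
print.ed_model <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("essential-dynamics model:", k, "modes over",
      length(x$mean) / 3, "atoms\n")
  cv <- cumsum(x$eigenvalues) / x$total_variance
  cat("  top eigenvalues (A^2):",
      paste(signif(head(x$eigenvalues, 5L), 4), collapse = ", "), "\n")
  cat("  variance captured by 2 PCs:",
      round(100 * cv[min(2L, k)], 1), "%\n")
  invisible(x)
}

#' Project a trajectory onto essential modes
#'
#' Frames are fitted the same way the model was fitted, then
#' `proj = (frame - mean) . eigenvector` for each of the first `k`
#' modes.
#'
#' @param traj a [trajectory_ensemble()] over the same atoms
#' @param model an [fit_ed()] model
#' @param k number of components (default 2)
#' @return class `"projection_series"`: `proj` (`frames x k` matrix,
#'   Angstrom), `eigenvalues`, `dt`.
#' @export
project_ed <- function(traj, model, k = 2L) {
  stopifnot(inherits(model, "ed_model"))
  k <- as.integer(k)
  if (k > ncol(model$eigenvectors))
    stop("model stores only ", ncol(model$eigenvectors), " components")
  sel <- model$selection
  if (max(sel) > dim(traj$coords)[2])
    stop("selection does not fit this trajectory (atom count mismatch)")
  co <- if (model$fit) .fit_frames(traj, model$reference, sel)
        else traj$coords
  X <- .flatten_coords(co, sel)
  P <- sweep(X, 2L, model$mean) %*%
    model$eigenvectors[, seq_len(k), drop = FALSE]
  colnames(P) <- paste0("PC", seq_len(k))
  structure(list(proj = P, eigenvalues = model$eigenvalues[seq_len(k)],
                 dt = traj$dt),
            class = "projection_series")
}

#' Cumulative variance captured by the top modes
#'
#' @param model an [fit_ed()] model
#' @param k number of leading components
#' @return numeric vector of length `k`: nondecreasing fractions of the
#'   total coordinate variance
#' @export
cumulative_variance <- function(model, k = length(model$eigenvalues)) {
  stopifnot(inherits(model, "ed_model"), k >= 1)
  k <- min(as.integer(k), length(model$eigenvalues))
  cumsum(model$eigenvalues[seq_len(k)]) / model$total_variance
}

#' Cosine content of a principal-component projection
#'
#' Hess's convergence diagnostic: the squared overlap of a projection
#' with a half-period cosine of matching order,
#' `c_i = 2 (sum cos(i*pi*t_j) p_j)^2 / (n * sum p_j^2)` with
#' `t_j = (j - 1/2)/n`, which lies in `[0, 1]`. Values near 1 are the
#' signature of random-diffusion-like sampling -- a trajectory that has
#' not converged; well-sampled multi-state dynamics give values near 0.
#'
#' @param series a [project_ed()] result, a matrix of projections, or a
#'   numeric vector
#' @param order cosine order `i` (matches PC index by convention);
#'   when `series` holds several components the `order`-th column is
#'   used.
#' @return cosine content in `[0, 1]`
#' @export
cosine_content <- function(series, order = 1L) {
  p <- if (inherits(series, "projection_series")) series$proj
       else series
  if (is.matrix(p)) {
    if (ncol(p) < order) stop("series has fewer than ", order,
                              " components")
    p <- p[, order]
  }
  p <- as.numeric(p)
  n <- length(p)
  if (n < 4L) stop("need at least 4 points")
  if (sum(p^2) == 0) stop("zero series has no cosine content")
  tj <- (seq_len(n) - 0.5) / n
  2 * sum(cos(order * pi * tj) * p)^2 / (n * sum(p^2))
}

#' Interpolate between the extreme conformations of a mode
#'
#' Sweeps the mean structure linearly along one eigenvector between the
#' minimum and maximum projections observed in `projections`,
#' reconstructing the "extreme conformation" movie used to read a mode
#' as a motion (for the opener, a monotone groove-opening sweep).
#'
#' @param model an [fit_ed()] model
#' @param projections a [project_ed()] result with at least `pc`
#'   components
#' @param pc mode index (default 1)
#' @param n_frames_out number of interpolation frames (default 11)
#' @param topology optional [topology()] for the selected atoms (e.g.
#'   from [topology_subset()]) to attach to the result
#' @return a [trajectory_ensemble()] of `n_frames_out` frames over the
#'   selected atoms
#' @export
interpolate_extremes <- function(model, projections, pc = 1L,
                                 n_frames_out = 11L, topology = NULL) {
  stopifnot(inherits(model, "ed_model"),
            inherits(projections, "projection_series"))
  if (ncol(projections$proj) < pc)
    stop("projections carry fewer than ", pc, " components")
  a <- seq(min(projections$proj[, pc]), max(projections$proj[, pc]),
           length.out = as.integer(n_frames_out))
  v <- model$eigenvectors[, pc]
  N <- length(model$mean) / 3L
  co <- array(0, c(length(a), N, 3L))
  for (f in seq_along(a)) {
    x <- model$mean + a[f] * v
    co[f, , ] <- matrix(x, N, 3L, byrow = TRUE)
  }
  trajectory_ensemble(co, dt = 1, topology = topology)
}
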