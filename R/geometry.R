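## Superposition, RMSD/RMSF, distance series and histogram summaries.

#' Least-squares (Kabsch) superposition of two frames
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms between a mobile and a reference frame, via the SVD of
#' the covariance of the centered selections with the determinant
#' correction that excludes reflections.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices (Angstrom)
#' @param selection atoms used for the fit (>= 3, non-collinear);
#'   default all atoms
#' @return class `"superposition"`: list with `rotation` (3x3, det +1),
#'   `translation` (length 3), and `rmsd` (Angstrom, over the selection
#'   after fitting). Apply with [apply_superposition()]:
#'   `fitted = mobile %*% rotation + translation`.
#' @export
superpose <- function(mobile, reference,
                      selection = seq_len(nrow(reference))) {
  sel <- as.integer(selection)
  if (length(sel) < 3L) stop("need at least 3 atoms to superpose")
  P <- mobile[sel, , drop = FALSE]
  Q <- reference[sel, , drop = FALSE]
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  ## collinearity: a rank-1 centered selection leaves the rotation free
  if (sum(svd(Pc, nu = 0, nv = 0)$d > 1e-8 * max(1, max(abs(Pc)))) < 2L)
    stop("selected atoms are collinear; rotation is underdetermined")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  structure(list(rotation = R, translation = as.vector(cq - cp %*% R),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords `n x 3` matrix
#' @param fit a [superpose()] result
#' @return transformed `n x 3` matrix
#' @export
apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2L, fit$translation, "+")
}

## fit every frame of a trajectory to a reference on a selection;
## returns the frames x atoms x 3 array of fitted coordinates
.fit_frames <- function(traj, reference, selection) {
  co <- traj$coords
  for (f in seq_len(dim(co)[1])) {
    x <- matrix(co[f, , ], ncol = 3L)
    co[f, , ] <- apply_superposition(x, superpose(x, reference, selection))
  }
  co
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is least-squares fitted to the reference on the selection
#' before the RMSD is taken over the same selection.
#'
#' @param traj a [trajectory_ensemble()]
#' @param reference `n_atoms x 3` matrix (defaults to frame 1)
#' @param selection atoms used for fit and measure (default all)
#' @param fit superpose each frame first? (default TRUE)
#' @return numeric vector, one RMSD in Angstrom per frame
#' @export
rmsd_series <- function(traj, reference = frame_coords(traj, 1L),
                        selection = NULL, fit = TRUE) {
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else as.integer(.as_selection(selection, traj$topology))
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    if (fit) x <- apply_superposition(x, superpose(x, reference, sel))
    sqrt(mean(rowSums((x[sel, , drop = FALSE] -
                         reference[sel, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are optionally fitted to a reference on the selection; the
#' fluctuation of each selected atom is then taken about the
#' *trajectory mean* structure,
#' `rmsf_i = sqrt(mean |r_i - <r_i>|^2)`.
#'
#' @inheritParams rmsd_series
#' @param reference superposition target (default frame 1); the
#'   fluctuation reference is always the post-fit mean.
#' @return numeric vector of RMSF (Angstrom), one per selected atom
#' @export
rmsf <- function(traj, selection = NULL,
                 reference = frame_coords(traj, 1L), fit = TRUE) {
  if (n_frames(traj) < 2L)
    stop("RMSF needs at least two frames")
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else as.integer(.as_selection(selection, traj$topology))
  co <- if (fit) .fit_frames(traj, reference, sel) else traj$coords
  co <- co[, sel, , drop = FALSE]
  mu <- apply(co, c(2L, 3L), mean)
  dev2 <- 0
  for (d in 1:3) dev2 <- dev2 + sweep(co[, , d], 2L, mu[, d])^2
  sqrt(colMeans(dev2))
}

#' Distance series between two atoms
#'
#' The per-frame Euclidean distance between two single-atom selections
#' -- the workhorse observable: groove opening (H3--H9 C-alpha pair),
#' the gate ring--methyl contact, or a hydrogen-bond donor--acceptor
#' pair.
#'
#' @param traj a [trajectory_ensemble()]
#' @param atom_a,atom_b single-atom selections (a selection string, an
#'   [select_atoms()] result, or a bare index)
#' @return class `"distance_series"`: list with `values` (Angstrom per
#'   frame), `dt` (ns) and `label`.
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  a <- .as_selection(atom_a, traj$topology)
  b <- .as_selection(atom_b, traj$topology)
  if (length(a) != 1L || length(b) != 1L)
    stop("distance_series needs single-atom selections (got ",
         length(a), " and ", length(b), ")")
  pa <- matrix(traj$coords[, a, ], ncol = 3L)
  pb <- matrix(traj$coords[, b, ], ncol = 3L)
  d <- sqrt(rowSums((pa - pb)^2))
  distance_series_from_values(
    d, traj$dt,
    paste(attr(a, "provenance"), "-", attr(b, "provenance")))
}

#' Wrap a numeric vector as a distance series
#' @param values distances, Angstrom (>= 0)
#' @param dt frame spacing, ns
#' @param label descriptive label
#' @return class `"distance_series"`
#' @export
distance_series_from_values <- function(values, dt = 1, label = "") {
  stopifnot(all(is.finite(values)), all(values >= 0), dt > 0)
  structure(list(values = as.numeric(values), dt = dt, label = label),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat("distance series '", x$label, "': ", length(x$values),
      " frames, mean ", round(mean(x$values), 2), " A\n", sep = "")
  invisible(x)
}

## topographic prominence of local maxima in a 1D profile: on each side
## walk outwards to the nearest higher ground, tracking the lowest col;
## a side with no higher ground contributes its boundary minimum.
.peak_prominence <- function(y) {
  n <- length(y)
  if (n == 1L) return(list(peaks = 1L, prominence = y))
  up <- c(TRUE, diff(y) > 0)
  down <- c(diff(y) < 0, TRUE)
  peaks <- which(up & down & y > 0)  # plateaus take their first bin
  side_col <- function(p, step) {
    m <- y[p]
    higher <- FALSE
    i <- p + step
    while (i >= 1L && i <= n) {
      if (y[i] > y[p]) { higher <- TRUE; break }
      m <- min(m, y[i])
      i <- i + step
    }
    c(col = m, higher = higher)
  }
  prom <- vapply(peaks, function(p) {
    l <- side_col(p, -1L)
    r <- side_col(p, 1L)
    col <- if (l["higher"] && r["higher"]) max(l["col"], r["col"])
           else if (l["higher"]) l["col"]
           else if (r["higher"]) r["col"]
           else min(l["col"], r["col"])   # global max: base-to-peak
    y[p] - col
  }, numeric(1))
  list(peaks = peaks, prominence = prom)
}

#' Histogram summary of a distance series with peak detection
#'
#' Histograms the series at a fixed bin width, lightly smooths the
#' counts with a centered moving average, and reports local maxima whose
#' topographic prominence exceeds a threshold -- the operation behind
#' "trimodal distribution with peaks at ..." statements. The mean,
#' standard deviation, the conventional `mean +/- 2 sigma` band, and the
#' raw 2.5%/97.5% quantiles (more honest for skewed or multimodal
#' shapes) are all reported.
#'
#' @param series a [distance_series()] (or numeric vector)
#' @param bin_width histogram bin width, Angstrom (default 0.25, which
#'   cleanly separates peaks ~5 Angstrom apart)
#' @param min_prominence minimum peak prominence as a fraction of the
#'   maximum smoothed count (default 0.05)
#' @param smooth_window moving-average window in bins (odd; default 3)
#' @return class `"histogram_summary"`: bin `edges`, `mids`, `counts`,
#'   `mean`, `sd`, `band2sigma`, `quantiles`, and `peaks` (data.frame
#'   `position`, `count`, `prominence`, positions ascending)
#' @export
summarize_histogram <- function(series, bin_width = 0.25,
                                min_prominence = 0.05,
                                smooth_window = 3L) {
  x <- if (inherits(series, "distance_series")) series$values
       else as.numeric(series)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(x) < 100L) stop("need at least 100 values to summarize")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  mids <- edges[-length(edges)] + bin_width / 2
  ## centered moving-average smoothing
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2L == 0L) w <- w + 1L
  if (length(counts) > w) {
    sm <- as.numeric(stats::filter(counts, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- counts[is.na(sm)]
  } else sm <- as.numeric(counts)
  pk <- .peak_prominence(sm)
  keep <- pk$prominence >= min_prominence * max(sm)
  peaks <- data.frame(position = mids[pk$peaks[keep]],
                      count = counts[pk$peaks[keep]],
                      prominence = pk$prominence[keep])
  peaks <- peaks[order(peaks$position), , drop = FALSE]
  m <- mean(x); s <- sd(x)
  structure(list(edges = edges, mids = mids, counts = counts,
                 smoothed = sm, mean = m, sd = s,
                 band2sigma = c(lower = m - 2 * s, upper = m + 2 * s),
                 quantiles = quantile(x, c(0.025, 0.975)),
                 peaks = peaks, n = length(x)),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat("histogram of", x$n, "values: mean", round(x$mean, 2), "A, sd",
      round(x$sd, 2), "A\n")
  cat("  mean +/- 2 sigma: [", round(x$band2sigma[1], 2), ",",
      round(x$band2sigma[2], 2), "] A;  2.5-97.5% quantiles: [",
      round(x$quantiles[1], 2), ",", round(x$quantiles[2], 2), "] A\n")
  if (nrow(x$peaks))
    cat("  peaks at", paste(round(x$peaks$position, 2), collapse = ", "),
        "A\n")
  else cat("  no peaks above prominence threshold\n")
  invisible(x)
}
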