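## Lagged cross-correlation of distance time series and event ordering.

.series_values <- function(x) {
  if (inherits(x, "distance_series")) x$values else as.numeric(x)
}
.series_dt <- function(x, default = 1) {
  if (inherits(x, "distance_series")) x$dt else default
}

#' Lagged cross-correlation of two time series
#'
#' Both series are standardized and the Pearson correlation of the
#' overlapping segments is computed at every lag `k` in
#' `-max_lag..max_lag` as `r(k) = corr(x(t+k), y(t))`.
#'
#' Sign convention (fixed and pinned by the tests): a *negative*
#' extremum lag means `x` leads `y` -- shifting `x` back in time aligns
#' it with `y`, i.e. events in `x` precede their echo in `y`. This is
#' the reading under which the gate contact that triggers groove opening
#' shows its strongest (anti-)correlation at a negative lag time.
#'
#' With `boundaries` set (frame indices of replica starts after the
#' first, as recorded by [replicate_concat()]), frame pairs straddling a
#' replica boundary are excluded, so concatenation introduces no
#' artifactual couplings.
#'
#' @param x,y [distance_series()] objects or numeric vectors of equal
#'   length (and equal `dt` when both carry one)
#' @param max_lag maximum lag in frames (`< length/2`)
#' @param boundaries optional integer vector: first frame index of each
#'   replica after the first
#' @return class `"cross_correlation"`: list with `lags` (frames),
#'   `lag_ns`, `r`, `n`, `dt`.
#' @export
cross_correlation <- function(x, y, max_lag, boundaries = NULL) {
  dtx <- .series_dt(x, NA); dty <- .series_dt(y, NA)
  if (!is.na(dtx) && !is.na(dty) && abs(dtx - dty) > 1e-12)
    stop("series have different time steps")
  dt <- if (!is.na(dtx)) dtx else if (!is.na(dty)) dty else 1
  xv <- .series_values(x); yv <- .series_values(y)
  n <- length(xv)
  if (length(yv) != n) stop("series have different lengths")
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= n / 2) stop("need 0 <= max_lag < n/2")
  if (sd(xv) == 0 || sd(yv) == 0) stop("zero-variance series")
  xs <- as.vector(scale(xv)); ys <- as.vector(scale(yv))
  seg <- if (is.null(boundaries)) rep(1L, n)
         else findInterval(seq_len(n), sort(unique(as.integer(boundaries)))) + 1L
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    a <- abs(k)
    if (k >= 0) { xi <- (1 + a):n; yi <- 1:(n - a) }
    else        { xi <- 1:(n - a); yi <- (1 + a):n }
    ok <- seg[xi] == seg[yi]
    if (sum(ok) < 3L) return(NA_real_)
    cor(xs[xi][ok], ys[yi][ok])
  }, numeric(1))
  structure(list(lags = lags, lag_ns = lags * dt, r = r, n = n, dt = dt),
            class = "cross_correlation")
}

#' @export
print.cross_correlation <- function(x, ...) {
  ex <- cc_extremum(x, "abs")
  cat("cross-correlation over lags [", -max(x$lags), ",", max(x$lags),
      "] frames: strongest r =", round(ex$r, 3), "at lag", ex$lag,
      "frames (", round(ex$lag_ns, 4), "ns )\n")
  invisible(x)
}

#' @export
plot.cross_correlation <- function(x, ...) {
  plot(x$lags, x$r, type = "l", xlab = "lag (frames)",
       ylab = "r", ...)
  ex <- cc_extremum(x, "abs")
  points(ex$lag, ex$r, pch = 19)
  invisible(x)
}

#' Extremum of a cross-correlation function
#'
#' Ties are broken toward lag 0 first, then toward negative lag.
#'
#' @param cc a [cross_correlation()] result
#' @param sense `"abs"` (largest magnitude, the default), `"max"` or
#'   `"min"`
#' @return list with `lag` (frames), `lag_ns`, `r`, and `lead`
#'   (`-lag`: positive when the first series leads)
#' @export
cc_extremum <- function(cc, sense = c("abs", "max", "min")) {
  sense <- match.arg(sense)
  score <- switch(sense, abs = abs(cc$r), max = cc$r, min = -cc$r)
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-15)
  ## tie-break: toward lag 0, then negative lag
  lag <- cc$lags[cand]
  pick <- cand[order(abs(lag), lag)][1L]
  list(lag = cc$lags[pick], lag_ns = cc$lag_ns[pick], r = cc$r[pick],
       lead = -cc$lags[pick])
}

#' Order coupled events against a reference series
#'
#' For each named series the cross-correlation with the reference is
#' computed, the strongest-magnitude extremum located, and events are
#' ordered by their lead on the reference (largest lead = earliest
#' trigger first). Events within `simultaneity_tol` frames of each other
#' are grouped as simultaneous, and a coupling whose extremum magnitude
#' stays below the `3/sqrt(n)` white-noise bound is flagged
#' insignificant.
#'
#' @param pairs named list of [distance_series()] (or numeric vectors)
#' @param reference the reference series (e.g. the groove opening)
#' @param max_lag maximum lag in frames
#' @param simultaneity_tol events closer than this many frames are
#'   reported simultaneous (default 1)
#' @param boundaries passed to [cross_correlation()]
#' @return class `"event_order"`: data.frame with `name`, `lag`,
#'   `lag_ns`, `lead`, `r`, `significant`, `group` (events sharing a
#'   group number are simultaneous), ordered by decreasing lead.
#' @export
event_order <- function(pairs, reference, max_lag,
                        simultaneity_tol = 1L, boundaries = NULL) {
  stopifnot(length(pairs) >= 1L)
  nm <- names(pairs)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("series", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    cc <- cross_correlation(pairs[[i]], reference, max_lag,
                            boundaries = boundaries)
    ex <- cc_extremum(cc, "abs")
    data.frame(name = nm[i], lag = ex$lag, lag_ns = ex$lag_ns,
               lead = ex$lead, r = ex$r,
               significant = abs(ex$r) >= 3 / sqrt(cc$n))
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$lead, df$name), , drop = FALSE]
  ## group events whose leads differ by <= tol (chain rule)
  grp <- integer(nrow(df))
  gi <- 0L
  for (i in seq_len(nrow(df))) {
    if (i == 1L || df$lead[i - 1L] - df$lead[i] > simultaneity_tol)
      gi <- gi + 1L
    grp[i] <- gi
  }
  df$group <- grp
  rownames(df) <- NULL
  structure(df, class = c("event_order", "data.frame"))
}

#' @export
print.event_order <- function(x, ...) {
  cat("event ordering vs reference (lead in frames; same group =",
      "simultaneous):\n")
  print.data.frame(x, digits = 3)
  insig <- x$name[!x$significant]
  if (length(insig))
    cat("  no significant coupling:", paste(insig, collapse = ", "),
        "\n")
  invisible(x)
}
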