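## Free-energy landscapes by Boltzmann inversion of 2D PC histograms.

#' Boltzmann constant in kJ/(mol K)
#' @export
kB_kJmol <- 0.0083145

#' Free-energy landscape from two principal-component projections
#'
#' Bins the (PC1, PC2) samples on a regular grid spanning the observed
#' range padded by `pad` on each side, then Boltzmann-inverts the
#' occupancy: `dE_i = -kB * T * ln(n_i / n_max)` in kJ/mol, so the most
#' populated bin sits at exactly zero and every populated bin is
#' non-negative. Empty bins are masked (`NA`), not given pseudo-counts.
#'
#' @param projections a [project_ed()] result with >= 2 components, or
#'   a 2-column matrix / list of two equal-length numeric vectors
#' @param bins bins per axis (>= 4; default 64)
#' @param temperature simulation temperature in K (default 300)
#' @param pad fractional padding of the observed range (default 0.05)
#' @return class `"free_energy_surface"`: `xedges`, `yedges`, `xmids`,
#'   `ymids`, `counts` (`bins x bins`), `energy` (kJ/mol, `NA` where
#'   unpopulated), `temperature`, `n`.
#' @export
fel <- function(projections, bins = 64L, temperature = 300, pad = 0.05) {
  if (inherits(projections, "projection_series")) {
    stopifnot(ncol(projections$proj) >= 2L)
    p1 <- projections$proj[, 1L]; p2 <- projections$proj[, 2L]
  } else if (is.matrix(projections)) {
    stopifnot(ncol(projections) >= 2L)
    p1 <- projections[, 1L]; p2 <- projections[, 2L]
  } else {
    stopifnot(is.list(projections), length(projections) >= 2L)
    p1 <- as.numeric(projections[[1L]])
    p2 <- as.numeric(projections[[2L]])
  }
  if (!length(p1) || length(p1) != length(p2))
    stop("need two equal-length, non-empty projection series")
  bins <- as.integer(bins)
  if (bins < 4L) stop("need at least 4 bins per axis")
  stopifnot(temperature > 0)
  rng <- function(v) {
    r <- range(v)
    w <- diff(r)
    if (w == 0) w <- max(abs(r[1L]), 1)   # degenerate axis
    r + c(-1, 1) * pad * w
  }
  r1 <- rng(p1); r2 <- rng(p2)
  xe <- seq(r1[1L], r1[2L], length.out = bins + 1L)
  ye <- seq(r2[1L], r2[2L], length.out = bins + 1L)
  i1 <- pmin(pmax(findInterval(p1, xe, rightmost.closed = TRUE), 1L), bins)
  i2 <- pmin(pmax(findInterval(p2, ye, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(tabulate((i2 - 1L) * bins + i1, nbins = bins * bins),
                   bins, bins)
  energy <- -kB_kJmol * temperature * log(counts / max(counts))
  energy[counts == 0L] <- NA_real_
  structure(list(xedges = xe, yedges = ye,
                 xmids = xe[-length(xe)] + diff(xe) / 2,
                 ymids = ye[-length(ye)] + diff(ye) / 2,
                 counts = counts, energy = energy,
                 temperature = temperature, n = length(p1)),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("free-energy surface:", nrow(x$counts), "x", ncol(x$counts),
      "bins,", sum(x$counts > 0), "populated, T =", x$temperature,
      "K\n")
  cat("  energy range of populated bins: 0 -",
      round(max(x$energy, na.rm = TRUE), 2), "kJ/mol\n")
  invisible(x)
}

#' @export
plot.free_energy_surface <- function(x, minima = NULL, ...) {
  image(x$xmids, x$ymids, x$energy, col = hcl.colors(64, "viridis"),
        xlab = "PC1 (A)", ylab = "PC2 (A)", ...)
  if (!is.null(minima) && nrow(minima))
    points(minima$pc1, minima$pc2, pch = 4, cex = 1.4, lwd = 2)
  invisible(x)
}

#' Detect free-energy minima with a persistence merge
#'
#' Local minima over the 8-neighborhood of populated bins are found,
#' then shallow ones are merged watershed-style: basins are grown in
#' order of increasing energy, and when two basins meet, the younger
#' (shallower) minimum survives only if the barrier separating it from
#' the deeper basin is at least `depth_threshold` -- otherwise it is
#' absorbed. The global minimum always survives.
#'
#' Two guards keep sampling noise out of the report. Unpopulated
#' (masked) bins take part in the connectivity pass at a ceiling energy
#' corresponding to half a count, `kB T ln(2 n_max)` -- the histogram's
#' resolution floor -- so rim islands are connected to the landscape
#' rather than counted as separate basins. And only a bin whose full
#' 8-neighborhood is populated can seed a minimum: a genuine basin
#' floor is locally well sampled, whereas sparse rim bins may join
#' basins but not found one.
#'
#' @param surface a [fel()] result
#' @param depth_threshold minimum barrier in kJ/mol for a separate
#'   minimum (default `kB * T`, ~2.49 kJ/mol at 300 K)
#' @return data.frame, one row per retained minimum, ordered by energy:
#'   `pc1`, `pc2` (bin centers), `ix`, `iy` (bin indices), `energy`
#'   (kJ/mol), `barrier` (merge barrier; `Inf` for the global minimum)
#' @export
find_minima <- function(surface,
                        depth_threshold = kB_kJmol *
                          surface$temperature) {
  stopifnot(inherits(surface, "free_energy_surface"))
  E <- surface$energy
  nb <- nrow(E)
  pop <- which(!is.na(E))
  if (!length(pop)) stop("surface has no populated bins")
  ## masked bins join the connectivity pass at the resolution floor
  ceiling_E <- kB_kJmol * surface$temperature * log(2 * max(surface$counts))
  E2 <- E
  E2[is.na(E2)] <- ceiling_E
  ord <- order(E2)
  comp <- integer(length(E))            # 0 = unprocessed
  parent <- integer(0)                  # union-find link (0 = root)
  min_bin <- integer(0)                 # component -> its minimum bin
  birth <- numeric(0)                   # component -> minimum energy
  alive <- logical(0)                   # survives the persistence merge
  barrier <- numeric(0)
  find_root <- function(c0) {
    while (parent[c0] != 0L) c0 <- parent[c0]
    c0
  }
  neigh_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1))
  neigh_offsets <- neigh_offsets[rowSums(abs(neigh_offsets)) > 0L, ]
  for (b in ord) {
    ix <- (b - 1L) %% nb + 1L
    iy <- (b - 1L) %/% nb + 1L
    nx <- ix + neigh_offsets[, 1L]
    ny <- iy + neigh_offsets[, 2L]
    okn <- nx >= 1L & nx <= nb & ny >= 1L & ny <= ncol(E)
    nbins <- (ny[okn] - 1L) * nb + nx[okn]
    ncomp <- unique(vapply(nbins[comp[nbins] != 0L],
                           function(v) find_root(comp[v]), integer(1)))
    if (!length(ncomp)) {               # fresh local minimum
      ## only a fully sampled neighborhood can seed a reported minimum:
      ## sparse rim bins may join basins but not found one
      eligible <- !is.na(E[b]) &&
        (length(parent) == 0L ||          # the global minimum always counts
           (all(okn) && !anyNA(E[nbins])))
      parent <- c(parent, 0L)
      min_bin <- c(min_bin, b)
      birth <- c(birth, E2[b])
      alive <- c(alive, eligible)
      barrier <- c(barrier, Inf)
      comp[b] <- length(parent)
    } else if (length(ncomp) == 1L) {
      comp[b] <- ncomp
    } else {
      ## saddle: merge all meeting components into the deepest
      deepest <- ncomp[which.min(birth[ncomp])]
      for (c2 in setdiff(ncomp, deepest)) {
        pers <- E2[b] - birth[c2]
        if (alive[c2] && pers < depth_threshold) {
          alive[c2] <- FALSE
        } else if (alive[c2]) {
          barrier[c2] <- min(barrier[c2], pers)
        }
        parent[c2] <- deepest           # union
      }
      comp[b] <- deepest
    }
  }
  keep <- which(alive & !is.na(E[min_bin]))
  bins_ <- min_bin[keep]
  ix <- (bins_ - 1L) %% nb + 1L
  iy <- (bins_ - 1L) %/% nb + 1L
  out <- data.frame(pc1 = surface$xmids[ix], pc2 = surface$ymids[iy],
                    ix = ix, iy = iy, energy = E[bins_],
                    barrier = barrier[keep])
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Representative frame for each free-energy minimum
#'
#' For every minimum, the frame whose (PC1, PC2) coordinates lie closest
#' (Euclidean) to the minimum's bin center; ties resolve to the earliest
#' frame.
#'
#' @param projections the [project_ed()] result (or 2-column matrix)
#'   the surface was built from
#' @param minima a [find_minima()] data.frame
#' @return integer vector of frame indices, one per minimum
#' @export
representative_frames <- function(projections, minima) {
  P <- if (inherits(projections, "projection_series")) projections$proj
       else as.matrix(projections)
  stopifnot(nrow(minima) >= 1L, ncol(P) >= 2L)
  vapply(seq_len(nrow(minima)), function(i) {
    d2 <- (P[, 1L] - minima$pc1[i])^2 + (P[, 2L] - minima$pc2[i])^2
    which.min(d2)                      # which.min takes the earliest tie
  }, integer(1))
}
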