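## Displacement-correlation residue networks and shortest-path maps.

#' Displacement correlation matrix between C-alpha atoms
#'
#' The normalized inner product of per-residue displacement vectors
#' taken relative to a reference structure (typically the X-ray
#' coordinates):
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' with `dr_i(t) = r_i(t) - r_i(ref)` after optional least-squares
#' superposition of every frame onto the reference over the selection.
#'
#' Residues whose displacement variance vanishes leave the correlation
#' undefined; their rows and columns are set to `NA`, they are listed in
#' the `excluded` field, and [build_graph()] drops them.
#'
#' @param traj a [trajectory_ensemble()]
#' @param selection atoms to correlate (typically `"calpha"`); default
#'   all atoms
#' @param reference `n_atoms x 3` reference coordinates (default
#'   frame 1)
#' @param fit superpose each frame onto the reference first (default
#'   TRUE). Use `FALSE` when frames are already expressed in a common
#'   lab frame, e.g. ensembles drawn by [sample_gaussian_ensemble()].
#' @return class `"correlation_matrix"`: list with `C` (`N x N`,
#'   symmetric, unit diagonal), `excluded` (indices into the selection),
#'   `selection`, `labels`.
#' @export
displacement_correlation <- function(traj, selection = NULL,
                                     reference = frame_coords(traj, 1L),
                                     fit = TRUE) {
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else as.integer(.as_selection(selection, traj$topology))
  co <- if (fit) .fit_frames(traj, reference, sel) else traj$coords
  nf <- dim(co)[1]
  N <- length(sel)
  num <- matrix(0, N, N)
  for (d in 1:3) {
    D <- co[, sel, d, drop = TRUE] -
      matrix(reference[sel, d], nf, N, byrow = TRUE)
    num <- num + crossprod(D) / nf
  }
  msf <- diag(num)
  tol <- max(msf) * 1e-12
  excluded <- which(msf <= tol)
  dn <- sqrt(msf)
  C <- num / outer(dn, dn)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  if (length(excluded)) {
    C[excluded, ] <- NA_real_
    C[, excluded] <- NA_real_
  }
  labels <- if (!is.null(traj$topology))
    traj$topology$residues$label[traj$topology$atoms$res_index[sel]]
  else as.character(seq_len(N))
  structure(list(C = C, excluded = excluded, selection = sel,
                 labels = labels, reference_fit = fit),
            class = "correlation_matrix")
}

#' Contact persistence matrix
#'
#' `P_ij` is the fraction of frames in which atoms i and j of the
#' selection are closer than `cutoff` (strict inequality) -- the
#' "distance below a threshold for a fraction of the trajectory" gate
#' that decides which residue pairs may carry a network edge.
#'
#' @inheritParams displacement_correlation
#' @param cutoff contact distance, Angstrom (> 0); 6 by default, with 8
#'   the conventional looser alternative
#' @return class `"persistence_matrix"`: list with `P` (`N x N`, unit
#'   diagonal), `cutoff`, `selection`, `labels`.
#' @export
contact_persistence <- function(traj, selection = NULL, cutoff = 6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- if (is.null(selection)) seq_len(dim(traj$coords)[2])
         else as.integer(.as_selection(selection, traj$topology))
  N <- length(sel)
  nf <- n_frames(traj)
  P <- matrix(0, N, N)
  for (f in seq_len(nf)) {
    x <- matrix(traj$coords[f, sel, ], ncol = 3L)
    P <- P + (as.matrix(stats::dist(x)) < cutoff)
  }
  P <- P / nf
  diag(P) <- 1
  labels <- if (!is.null(traj$topology))
    traj$topology$residues$label[traj$topology$atoms$res_index[sel]]
  else as.character(seq_len(N))
  structure(list(P = P, cutoff = cutoff, selection = sel,
                 labels = labels),
            class = "persistence_matrix")
}

#' Build the persistence-gated correlation graph
#'
#' Nodes are the selected residues; an undirected edge joins i and j iff
#' the pair is in contact for at least `fraction` of the trajectory and
#' its displacement correlation is nonzero. Edge weights are
#' `l_ij = -log |C_ij|` (natural log), so strongly correlated pairs are
#' "close"; the sign of `C_ij` is kept as an edge attribute because
#' anti-correlated couplings carry mechanism too. Residues excluded from
#' the correlation matrix (zero variance) carry no edges.
#'
#' @param C a [displacement_correlation()] result
#' @param P a [contact_persistence()] result of matching dimension
#' @param fraction minimum persistence for an edge (default 0.3)
#' @return class `"correlation_graph"`: list with `graph` (igraph,
#'   vertices named by internal index with residue `label` attribute),
#'   `fraction`, `cutoff`.
#' @export
build_graph <- function(C, P, fraction = 0.3) {
  stopifnot(inherits(C, "correlation_matrix"),
            inherits(P, "persistence_matrix"))
  if (!identical(dim(C$C), dim(P$P)))
    stop("correlation and persistence matrices have different dimensions")
  N <- nrow(C$C)
  cm <- C$C
  keep <- P$P >= fraction & upper.tri(cm) & !is.na(cm) & abs(cm) > 0
  ij <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(N, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(N))
  igraph::V(g)$label <- C$labels
  if (nrow(ij)) {
    g <- igraph::add_edges(g, t(ij))
    cij <- cm[ij]
    igraph::E(g)$weight <- -log(abs(cij))
    igraph::E(g)$sign <- sign(cij)
    igraph::E(g)$cij <- cij
    igraph::E(g)$persistence <- P$P[ij]
  }
  structure(list(graph = g, fraction = fraction, cutoff = P$cutoff,
                 labels = C$labels),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("correlation graph:", igraph::vcount(x$graph), "residues,",
      igraph::ecount(x$graph), "edges (cutoff", x$cutoff,
      "A, persistence >=", x$fraction, ")\n")
  invisible(x)
}

## lexicographically smallest vertex sequence among equal-weight paths
.lex_min_path <- function(paths) {
  if (length(paths) == 1L) return(as.integer(paths[[1L]]))
  seqs <- lapply(paths, as.integer)
  best <- seqs[[1L]]
  for (s in seqs[-1L]) {
    n <- min(length(s), length(best))
    cmp <- which(s[seq_len(n)] != best[seq_len(n)])
    if (length(cmp)) {
      if (s[cmp[1L]] < best[cmp[1L]]) best <- s
    } else if (length(s) < length(best)) best <- s
  }
  best
}

#' Dijkstra shortest path between two residues
#'
#' Minimal total `-log|C|` weight path; among ties the lexicographically
#' smallest vertex sequence is returned, making the result
#' deterministic.
#'
#' @param cg a [build_graph()] result
#' @param source,sink internal residue indices (or vertex names)
#' @return list with `path` (integer residue indices), `labels`,
#'   `length` (total weight)
#' @export
shortest_path <- function(cg, source, sink) {
  stopifnot(inherits(cg, "correlation_graph"))
  g <- cg$graph
  source <- as.integer(source); sink <- as.integer(sink)
  if (source == sink) stop("source and sink must differ")
  comp <- igraph::components(g)
  if (comp$membership[source] != comp$membership[sink])
    stop("no path: source is in component ", comp$membership[source],
         ", sink in component ", comp$membership[sink])
  asp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = source, to = sink,
                               weights = igraph::E(g)$weight))
  path <- .lex_min_path(asp$res)
  w <- igraph::distances(g, v = source, to = sink,
                         weights = igraph::E(g)$weight)[1, 1]
  list(path = path, labels = cg$labels[path], length = unname(w))
}

#' Shortest path map (SPM)
#'
#' Accumulates Dijkstra shortest paths over all residue pairs of the
#' (largest) connected component: each edge's usage is the number of
#' source--sink pairs whose shortest path traverses it, and each node's
#' usage is the sum of its incident edge usages -- the score that sizes
#' the SPM spheres. The single path connecting the first and last
#' residue (the published map's backbone) is reported alongside.
#'
#' @param cg a [build_graph()] result
#' @param source,sink endpoints of the reported backbone path; default
#'   first and last residue of the component
#' @return class `"spm"`: list with `edge_usage` (data.frame `i`, `j`,
#'   `weight`, `sign`, `usage`, sorted by decreasing usage),
#'   `node_usage` (named numeric, all residues), `path` (the
#'   source-sink [shortest_path()]), `source`, `sink`.
#' @export
shortest_path_map <- function(cg, source = NULL, sink = NULL) {
  stopifnot(inherits(cg, "correlation_graph"))
  g <- cg$graph
  comp <- igraph::components(g)
  vs <- seq_len(igraph::vcount(g))
  if (comp$no > 1L) {
    big <- which.max(comp$csize)
    warning("graph has ", comp$no,
            " components; using the largest (",
            comp$csize[big], " residues)")
    vs <- which(comp$membership == big)
  }
  if (is.null(source)) source <- vs[1L]
  if (is.null(sink)) sink <- vs[length(vs)]
  w <- igraph::E(g)$weight
  e_usage <- numeric(igraph::ecount(g))
  for (a in vs) {
    targets <- vs[vs > a]
    if (!length(targets)) next
    for (b in targets) {
      asp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = a, to = b, weights = w))
      p <- .lex_min_path(asp$res)
      eid <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1L]))
      e_usage[eid] <- e_usage[eid] + 1
    }
  }
  ends_ <- igraph::ends(g, igraph::E(g), names = FALSE)
  node_usage <- vapply(seq_len(igraph::vcount(g)), function(v)
    sum(e_usage[ends_[, 1L] == v | ends_[, 2L] == v]), numeric(1))
  names(node_usage) <- cg$labels
  eu <- data.frame(i = ends_[, 1L], j = ends_[, 2L],
                   label_i = cg$labels[ends_[, 1L]],
                   label_j = cg$labels[ends_[, 2L]],
                   weight = w, sign = igraph::E(g)$sign,
                   usage = e_usage)
  eu <- eu[order(-eu$usage, eu$i, eu$j), , drop = FALSE]
  rownames(eu) <- NULL
  structure(list(edge_usage = eu, node_usage = node_usage,
                 path = shortest_path(cg, source, sink),
                 source = source, sink = sink),
            class = "spm")
}

#' @export
print.spm <- function(x, ...) {
  cat("shortest path map:", nrow(x$edge_usage), "edges\n")
  top <- head(order(-x$node_usage), 10L)
  cat("  top-usage residues:",
      paste0(names(x$node_usage)[top], " (", x$node_usage[top], ")",
             collapse = ", "), "\n")
  cat("  backbone path (", length(x$path$path), " residues, length ",
      round(x$path$length, 3), "): ",
      paste(x$path$labels, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Export an SPM edge list as TSV
#' @param spm a [shortest_path_map()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_spm_tsv <- function(spm, path) {
  write.table(spm$edge_usage, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
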