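# Independent oracles and fixture builders used across the suite.

# exhaustive simple-path enumeration oracle for weighted shortest paths;
# W: symmetric weight matrix with NA where no edge exists
brute_shortest_path <- function(W, source, sink) {
  n <- nrow(W)
  best <- list(length = Inf, path = NULL)
  visit <- function(v, seen, w, path) {
    if (v == sink) {
      if (w < best$length - 1e-12 ||
          (abs(w - best$length) <= 1e-12 &&
           lex_less(path, best$path))) {
        best$length <<- w
        best$path <<- path
      }
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!seen[u] && !is.na(W[v, u]))
        visit(u, `[<-`(seen, u, TRUE), w + W[v, u], c(path, u))
    }
  }
  visit(source, `[<-`(logical(n), source, TRUE), 0, source)
  best
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) a[d[1]] < b[d[1]] else length(a) < length(b)
}

# wrap a raw weight matrix (NA = no edge) as a correlation graph with
# persistence 1 everywhere, so graph construction is exercised end to end
cgraph_from_weights <- function(W) {
  n <- nrow(W)
  C <- exp(-W)
  C[is.na(C)] <- 0
  diag(C) <- 1
  P <- matrix(1, n, n)
  cm <- structure(list(C = C, excluded = integer(0), selection = 1:n,
                       labels = as.character(1:n), reference_fit = FALSE),
                  class = "correlation_matrix")
  pm <- structure(list(P = P, cutoff = Inf, selection = 1:n,
                       labels = as.character(1:n)),
                  class = "persistence_matrix")
  build_graph(cm, pm, fraction = 0.3)
}

# random connected weighted graph on n nodes (weights in (0.1, 3))
random_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    W <- matrix(NA_real_, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.1, 3)
    }
    A <- !is.na(W)
    reach <- logical(n); reach[1] <- TRUE
    repeat {
      new <- reach | apply(A & matrix(reach, n, n, byrow = FALSE), 2, any)
      if (identical(new, reach)) break
      reach <- new
    }
    if (all(reach)) return(W)
  }
}

# direct brute-force lagged correlation r(k) = corr(x(t+k), y(t))
# over the overlapping segment, written independently of the package
brute_ccf <- function(x, y, k) {
  n <- length(x)
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  pairs_x <- c(); pairs_y <- c()
  for (t in seq_len(n)) {
    if (t + k >= 1 && t + k <= n) {
      pairs_x <- c(pairs_x, xs[t + k])
      pairs_y <- c(pairs_y, ys[t])
    }
  }
  cor(pairs_x, pairs_y)
}

# minimal 3-residue peptide-like PDB fixture written by the test
write_tiny_pdb <- function(path, altloc = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    if (altloc) c(
      "ATOM      5  CA AGLY A   2       4.800   1.500   0.000  0.40  0.00           C",
      "ATOM      6  CA BGLY A   2       4.900   1.600   0.000  0.60  0.00           C")
    else
      "ATOM      5  CA  GLY A   2       4.800   1.500   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.400   2.900   0.000  1.00  0.00           C",
    "ATOM      8  N   LEU A   3       6.700   3.000   0.000  1.00  0.00           N",
    "ATOM      9  CA  LEU A   3       8.200   3.000   0.000  1.00  0.00           C",
    "ATOM     10  C   LEU A   3       8.800   4.400   0.000  1.00  0.00           C",
    "HETATM   11  O   HOH A 101      12.000  12.000  12.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# small opener run shared by several tests
opener_fixture <- function(n_frames = 20000L, seed = 42L, ...) {
  simulate_two_state_opener(
    two_state_opener_spec(n_frames = n_frames, seed = seed, ...))
}

# uniform-ish random proper rotation (QR with sign fix)
.random_rotation <- function(seed) {
  set.seed(seed + 1000)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
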