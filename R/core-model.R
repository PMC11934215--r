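#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov rnorm runif rbinom sd var quantile setNames
#' @importFrom utils head tail write.table packageVersion
#' @importFrom graphics image points axis hist lines
#' @importFrom grDevices hcl.colors
NULL

## three-letter codes accepted as protein residues
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
          "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
          "MSE","HID","HIE","HIP","CYX","ASH","GLH","LYN")

#' Construct a topology from an atom table
#'
#' A `topology` holds the residue and atom bookkeeping shared by all
#' analysis stages: an atom table, a residue table with one row per
#' protein residue (contiguous internal indices), and the map from each
#' residue to its C-alpha atom. Internal residue indices are contiguous
#' and 1-based; all user-facing labels combine chain and PDB residue
#' number (plus any insertion code) so that residues can be named the way
#' structural papers name them (e.g. `"A:G53"`).
#'
#' @param atoms data.frame with columns `name` (atom name, e.g. `"CA"`),
#'   `element`, `chain`, `resid` (PDB residue number), `resname`
#'   (three-letter code) and `insert` (insertion code, `""` if none).
#' @return An object of class `"topology"` with elements `atoms`
#'   (the atom table plus a `res_index` column), `residues` (per-residue
#'   table with `label` and `ca_atom`, `NA` when the residue has no
#'   C-alpha) and counts `n_atoms`, `n_res`.
#' @examples
#' at <- data.frame(name = c("N", "CA", "C"), element = c("N", "C", "C"),
#'                  chain = "A", resid = 1L, resname = "GLY", insert = "")
#' topology(at)
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "chain", "resid", "resname") %in% names(atoms)))
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$element)) atoms$element <- substr(trimws(atoms$name), 1, 1)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$name <- trimws(atoms$name)
  ## residue key in file order; indices contiguous over first appearance
  key <- paste(atoms$chain, atoms$resid, atoms$insert, sep = "|")
  atoms$res_index <- match(key, unique(key))
  first <- !duplicated(atoms$res_index)
  residues <- data.frame(chain   = atoms$chain[first],
                         resid   = atoms$resid[first],
                         resname = atoms$resname[first],
                         insert  = atoms$insert[first],
                         stringsAsFactors = FALSE)
  residues$label <- paste0(residues$chain, ":",
                           bio3d::aa321(residues$resname), residues$resid,
                           residues$insert)
  ca <- integer(nrow(residues)) * NA_integer_
  is_ca <- atoms$name == "CA" & atoms$element != "CA"  # exclude calcium ions
  dup_ca <- duplicated(atoms$res_index[is_ca])
  idx <- which(is_ca)[!dup_ca]
  ca[atoms$res_index[idx]] <- idx
  residues$ca_atom <- ca
  if (anyNA(ca))
    warning(sum(is.na(ca)), " residue(s) without a C-alpha atom; ",
            "flagged unusable in C-alpha selections: ",
            paste(residues$label[is.na(ca)], collapse = ", "))
  structure(list(atoms = atoms, residues = residues,
                 n_atoms = nrow(atoms), n_res = nrow(residues)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_res, "residues,", x$n_atoms, "atoms,",
      length(unique(x$residues$chain)), "chain(s)\n")
  cat("  C-alpha present for", sum(!is.na(x$residues$ca_atom)),
      "residues\n")
  invisible(x)
}

#' Residue labels of a topology
#'
#' @param top a [topology()]
#' @param res_index internal residue indices (default all)
#' @return character vector of `chain:one-letter+number` labels
#' @export
residue_labels <- function(top, res_index = seq_len(top$n_res)) {
  top$residues$label[res_index]
}

#' Restrict a topology to a set of atoms
#'
#' @param top a [topology()]
#' @param sel an [select()]ion (or integer atom indices)
#' @return a new `topology` containing only the selected atoms
#' @export
topology_subset <- function(top, sel) {
  idx <- as.integer(sel)
  topology(top$atoms[idx, c("name", "element", "chain", "resid",
                            "resname", "insert")])
}

#' Construct a trajectory ensemble
#'
#' The coordinate container used throughout: a `frames x atoms x 3` array
#' in Angstrom with a per-frame time step in ns and an attached
#' [topology()].
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom); a
#'   single `n_atoms x 3` matrix is promoted to one frame.
#' @param dt time per frame in ns (> 0).
#' @param topology a [topology()] whose atom count matches `coords`.
#' @return An object of class `"traj_ensemble"`.
#' @export
trajectory_ensemble <- function(coords, dt = 1, topology = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (ns)")
  if (!is.null(topology) && topology$n_atoms != dim(coords)[2])
    stop("atom count mismatch: topology has ", topology$n_atoms,
         " atoms, coords have ", dim(coords)[2])
  structure(list(coords = coords, dt = dt, topology = topology),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory ensemble:", d[1], "frames x", d[2], "atoms, dt =",
      x$dt, "ns (", round(d[1] * x$dt, 3), "ns total )\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory_ensemble()]
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as an atoms x 3 matrix
#' @param traj a [trajectory_ensemble()]
#' @param i frame index
#' @return numeric matrix `n_atoms x 3`
#' @export
frame_coords <- function(traj, i = 1L) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

## altloc rule: keep highest occupancy, ties -> first record
.resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(i) i[which.max(occ[i])]),
                 use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Read a protein structure from a PDB file
#'
#' Parses the file (via bio3d), keeps standard-residue `ATOM` records
#' only (waters and hetero groups are dropped), resolves alternate
#' locations by highest occupancy (ties broken by file order) and builds
#' the shared [topology()]. Residues lacking a C-alpha trigger a warning
#' and are flagged unusable in C-alpha selections.
#'
#' @param path PDB file.
#' @return list with elements `topology` and `traj` (a single-frame
#'   [trajectory_ensemble()] in Angstrom).
#' @export
read_structure <- function(path) {
  ## rm.alt = FALSE: alternate locations are resolved here by occupancy,
  ## not by bio3d's keep-A rule
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% .aa3, , drop = FALSE]
  if (nrow(at) == 0L) stop("no protein residues in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at <- .resolve_altloc(at)
  top <- topology(data.frame(name = at$elety, element = at$elesy,
                             chain = at$chain, resid = at$resno,
                             resname = at$resid, insert = at$insert,
                             stringsAsFactors = FALSE))
  xyz <- cbind(at$x, at$y, at$z)
  list(topology = top,
       traj = trajectory_ensemble(xyz, dt = 1, topology = top))
}

#' Read a coordinate trajectory
#'
#' Multi-model PDB (each `MODEL` is a frame) and DCD are supported
#' through bio3d's readers. Frames are returned in file order.
#'
#' @param path trajectory file (`.pdb` with MODEL records, or `.dcd`).
#' @param topology the [topology()] the frames must match.
#' @param dt time per frame in ns; overrides any file metadata
#'   (multi-model PDB carries none). Default 1 ns.
#' @return a [trajectory_ensemble()].
#' @export
read_trajectory <- function(path, topology, dt = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e) stop("unreadable trajectory '",
                                             path, "': ",
                                             conditionMessage(e)))
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * topology$n_atoms)
    stop("atom-count mismatch: file has ", ncol(xyz) / 3,
         " atoms per frame, topology has ", topology$n_atoms)
  bad <- which(!apply(is.finite(xyz), 1L, all))
  if (length(bad))
    stop("corrupt frame(s): ", paste(bad, collapse = ", "))
  nf <- nrow(xyz)
  co <- aperm(array(t(xyz), c(3L, topology$n_atoms, nf)), c(3L, 2L, 1L))
  trajectory_ensemble(co, dt = dt, topology = topology)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One `MODEL`/`ENDMDL` block per frame, fixed-width ATOM records with
#' three-decimal coordinates (standard PDB precision).
#'
#' @param traj a [trajectory_ensemble()] with a topology attached.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  top <- traj$topology
  if (is.null(top)) stop("trajectory has no topology; cannot write PDB")
  a <- top$atoms
  nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    x <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, nm, "", a$resname, a$chain,
      a$resid %% 10000L, a$insert, x[, 1], x[, 2], x[, 3], 1, 0,
      a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
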