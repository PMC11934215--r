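## Synthetic stand-in for the open/closed apo-dimer worked example.

#' Synthetic open/closed dimer structure (stand-in)
#'
#' Builds a coarse two-chain structure that emulates the geometry of an
#' apo dimer crystallized with one monomer closed and one open: chain A
#' (closed) has its groove reporter C-alpha pair (residues 53 and 220)
#' at 19.2 Angstrom with the gate ring--methyl pair apart, chain B
#' (open) has the groove pair at 25.0 Angstrom with the ring--methyl
#' contact formed at 3.8 Angstrom. Each chain carries a C-alpha
#' backbone plus side-chain reporter atoms on the mechanism residues:
#' PHE 153 (`CZ`), ALA 171 (`CB`), ASP 124 (`CG`), ASN 173 (`ND2`).
#'
#' This object is *synthetic*: it is generated from the target
#' distances, not taken from any deposited structure, and exists so the
#' measurement pipeline (structure reading, atom selection, distance
#' measurement) can be exercised end-to-end without downloads. Distances
#' measured from it therefore validate the machinery, not the crystal
#' structure it imitates.
#'
#' @param path optional file path; when given, the structure is written
#'   there as PDB and the path returned invisibly.
#' @param groove_closed,groove_open groove C-alpha distances, Angstrom
#' @param gate_open ring--methyl contact distance in the open monomer,
#'   Angstrom
#' @param gate_closed ring--methyl distance in the closed monomer,
#'   Angstrom
#' @return list with `topology` and `traj` (as [read_structure()]), or
#'   the path when `path` is given.
#' @export
synthetic_open_closed_structure <- function(path = NULL,
                                            groove_closed = 19.2,
                                            groove_open = 25.0,
                                            gate_open = 3.8,
                                            gate_closed = 5.5) {
  build_chain <- function(chain, groove, gate, zoff) {
    ## C-alpha backbone: residues 50..60 (helix H3 stretch), 120..125,
    ## 150..175 (gate cavity region), 215..225 (helix H9 stretch)
    resid <- c(50:60, 120:126, 150:175, 215:225)
    n <- length(resid)
    ## lay the backbone on an arc; then pin the reporter atoms
    ang <- seq(0, pi, length.out = n)
    xyz <- cbind(12 * cos(ang), 12 * sin(ang), zoff + 0.3 * seq_len(n))
    at <- data.frame(name = "CA", element = "C", chain = chain,
                     resid = resid, resname = "GLY", insert = "",
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     stringsAsFactors = FALSE)
    at$resname[at$resid == 53] <- "GLY"
    at$resname[at$resid == 124] <- "ASP"
    at$resname[at$resid == 153] <- "PHE"
    at$resname[at$resid == 171] <- "ALA"
    at$resname[at$resid == 173] <- "ASN"
    at$resname[at$resid == 220] <- "LEU"
    ## groove pair: place the two reporter C-alphas exactly groove apart
    at[at$resid == 53, c("x", "y", "z")] <- c(0, 0, zoff)
    at[at$resid == 220, c("x", "y", "z")] <- c(groove, 0, zoff)
    ## gate side-chain atoms: PHE153 CZ and ALA171 CB exactly gate apart
    side <- data.frame(
      name = c("CZ", "CB", "CG", "ND2"),
      element = c("C", "C", "C", "N"),
      chain = chain,
      resid = c(153L, 171L, 124L, 173L),
      resname = c("PHE", "ALA", "ASP", "ASN"),
      insert = "",
      x = c(5, 5 + gate, 8, 8 + if (gate <= 4) 6.5 else 3.3),
      y = c(-8, -8, -12, -12),
      z = zoff,
      stringsAsFactors = FALSE)
    rbind(at, side)
  }
  atoms <- rbind(build_chain("A", groove_closed, gate_closed, 0),
                 build_chain("B", groove_open, gate_open, 40))
  ## order by chain / residue / atom record as a PDB would
  atoms <- atoms[order(atoms$chain, atoms$resid,
                       atoms$name != "CA", atoms$name), ]
  top <- topology(atoms[, c("name", "element", "chain", "resid",
                            "resname", "insert")])
  traj <- trajectory_ensemble(as.matrix(atoms[, c("x", "y", "z")]),
                              dt = 1, topology = top)
  if (!is.null(path)) {
    write_trajectory_pdb(traj, path)
    return(invisible(path))
  }
  list(topology = top, traj = traj)
}
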