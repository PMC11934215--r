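#' Select atoms with a small expression grammar
#'
#' Expressions are conjunctions of clauses joined by `and`; within a
#' clause multiple values are alternatives. Supported clauses:
#' \describe{
#'   \item{`calpha`}{the C-alpha atom of every residue that has one}
#'   \item{`protein` / `all`}{every atom in the topology}
#'   \item{`resid N ...`}{PDB residue numbers; ranges as `a:b`}
#'   \item{`resname XXX ...`}{three-letter residue names}
#'   \item{`name XX ...`}{atom names (e.g. `CA`, `CZ`, `ND2`)}
#'   \item{`chain X ...`}{chain identifiers}
#' }
#' So `"resid 53 and name CA"` picks the C-alpha of residue 53, the
#' groove-opening reporter atom of helix H3, and
#' `"resid 173 and name ND2"` the amide nitrogen used for the
#' H5--H7 hydrogen-bond distance.
#'
#' @param top a [topology()]
#' @param expression selection string (case-insensitive keywords).
#' @return class `"atom_selection"`: an integer vector of atom indices
#'   in topology order, with the expression kept as the `provenance`
#'   attribute.
#' @examples
#' at <- data.frame(name = "CA", element = "C", chain = "A",
#'                  resid = 1:3, resname = "GLY", insert = "")
#' select_atoms(topology(at), "calpha")
#' @export
select_atoms <- function(top, expression) {
  stopifnot(inherits(top, "topology"), is.character(expression),
            length(expression) == 1L)
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (!length(clauses)) stop("empty selection expression")
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    kw <- tolower(tok[1])
    args <- tok[-1]
    m <- switch(kw,
      calpha = {
        ca <- top$residues$ca_atom
        seq_len(nrow(a)) %in% ca[!is.na(ca)]
      },
      protein = ,
      all = rep(TRUE, nrow(a)),
      resid = {
        if (!length(args)) stop("'resid' needs at least one number")
        nums <- unlist(lapply(args, function(s) {
          if (grepl("^-?[0-9]+[:-][0-9]+$", s)) {
            ab <- as.integer(strsplit(s, "[:-]")[[1]])
            seq(ab[1], ab[2])
          } else if (grepl("^-?[0-9]+$", s)) as.integer(s)
          else stop("unknown token in selection: '", s, "'")
        }))
        a$resid %in% nums
      },
      resname = {
        if (!length(args)) stop("'resname' needs at least one name")
        a$resname %in% toupper(args)
      },
      name = {
        if (!length(args)) stop("'name' needs at least one atom name")
        a$name %in% toupper(args)
      },
      chain = {
        if (!length(args)) stop("'chain' needs at least one id")
        a$chain %in% args
      },
      stop("unknown token in selection: '", tok[1], "'")
    )
    keep <- keep & m
  }
  idx <- which(keep)
  if (!length(idx)) stop("empty selection: '", expression, "'")
  structure(idx, provenance = expression, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom selection '", attr(x, "provenance"), "': ", length(x),
      " atom(s)\n", sep = "")
  invisible(x)
}

## accept a bare integer vector anywhere a selection is expected
.as_selection <- function(sel, top = NULL, default = "indices") {
  if (inherits(sel, "atom_selection")) return(sel)
  if (is.character(sel)) {
    if (is.null(top)) stop("a topology is required to resolve '", sel, "'")
    return(select_atoms(top, sel))
  }
  idx <- as.integer(sel)
  if (anyDuplicated(idx)) stop("selection has duplicate atom indices")
  if (!is.null(top) && length(idx) && max(idx) > top$n_atoms)
    stop("selection index out of topology bounds")
  structure(idx, provenance = default, class = "atom_selection")
}
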