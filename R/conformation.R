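#' All-atom conformation container
#'
#' A `Conformation` holds an atom table (residue number, residue name, PDB v3
#' atom name, element, partial charge, coordinates in Angstrom), the covalent
#' bond list as pairs of atom indices, and free-form provenance labels
#' (starting state, seed, pipeline stage).
#'
#' @param atoms data.frame with columns `resno`, `resid`, `elety`, `element`,
#'   `charge`, `x`, `y`, `z`.
#' @param bonds two-column integer matrix of 1-based atom indices.
#' @param labels named list of provenance tags.
#' @param spec optional [peptideSpec()] the conformation was built from.
#' @param offset residue-number offset of sequence position 1 (1 when an ACE
#'   cap occupies residue 1, else 0).
#' @return an object of class `Conformation`.
#' @export
conformation <- function(atoms, bonds, labels = list(), spec = NULL,
                         offset = 0L) {
  need <- c("resno", "resid", "elety", "element", "charge", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms table lacks columns: ",
         paste(setdiff(need, names(atoms)), collapse = ", "))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && max(bonds) > nrow(atoms))
    stop("bond index outside atom table")
  structure(list(atoms = atoms, bonds = bonds, labels = labels,
                 spec = spec, offset = as.integer(offset)),
            class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d atoms, %d residues, %d bonds\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), nrow(x$bonds)))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), unlist(x$labels),
                           sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Coordinate matrix of a conformation
#' @param conf a `Conformation`.
#' @return numeric matrix with one xyz row per atom.
#' @export
coords <- function(conf) {
  as.matrix(conf$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a conformation
#' @param conf a `Conformation`.
#' @param xyz numeric matrix, one row per atom.
#' @return the updated `Conformation`.
#' @export
setCoords <- function(conf, xyz) {
  stopifnot(nrow(xyz) == nrow(conf$atoms), ncol(xyz) == 3)
  conf$atoms$x <- xyz[, 1]
  conf$atoms$y <- xyz[, 2]
  conf$atoms$z <- xyz[, 3]
  conf
}

# Index of one atom identified by residue number and atom name.
.atom_index <- function(conf, resno, elety, required = TRUE) {
  i <- which(conf$atoms$resno == resno & conf$atoms$elety == elety)
  if (!length(i)) {
    if (required)
      stop(sprintf("missing atom %s in residue %d", elety, resno))
    return(NA_integer_)
  }
  i[1]
}

# Residue numbers of the peptide sequence positions (skipping cap residues).
.seq_resno <- function(conf, seqpos) seqpos + conf$offset

#' Logical mask for a set of atom names
#' @param conf a `Conformation`.
#' @param names atom names to select (default backbone N, CA, C, O).
#' @param resno optional residue numbers to restrict to.
#' @return logical vector over atoms.
#' @export
atomMask <- function(conf, names = c("N", "CA", "C", "O"), resno = NULL) {
  m <- conf$atoms$elety %in% names
  if (!is.null(resno)) m <- m & conf$atoms$resno %in% resno
  m
}

# Smallest heavy-atom distance between non-bonded atom pairs (1-2 pairs
# excluded); used by builder quality checks.
.min_nonbonded_dist <- function(conf) {
  heavy <- which(conf$atoms$element != "H")
  xyz <- coords(conf)
  bonded <- paste(pmin(conf$bonds[, 1], conf$bonds[, 2]),
                  pmax(conf$bonds[, 1], conf$bonds[, 2]))
  best <- Inf
  for (a in seq_along(heavy)) {
    for (b in seq_len(a - 1L)) {
      i <- heavy[a]; j <- heavy[b]
      if (paste(min(i, j), max(i, j)) %in% bonded) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

#' Backbone dihedral angles
#'
#' @param conf a `Conformation`.
#' @return data.frame with `resno`, `phi`, `psi`, `omega` (degrees; `NA`
#'   where the flanking residue does not exist).  `omega[i]` is the peptide
#'   bond torsion CA(i)-C(i)-N(i+1)-CA(i+1).
#' @export
backboneDihedrals <- function(conf) {
  xyz <- coords(conf)
  res <- sort(unique(conf$atoms$resno))
  g <- function(r, a) {
    i <- .atom_index(conf, r, a, required = FALSE)
    if (is.na(i)) NULL else xyz[i, ]
  }
  out <- data.frame(resno = res, phi = NA_real_, psi = NA_real_,
                    omega = NA_real_)
  for (k in seq_along(res)) {
    r <- res[k]
    N <- g(r, "N"); CA <- g(r, "CA"); C <- g(r, "C")
    if (is.null(CA)) CA <- g(r, "CH3")
    Cp <- if (k > 1) g(res[k - 1], "C") else NULL
    Nn <- if (k < length(res)) g(res[k + 1], "N") else NULL
    CAn <- if (k < length(res)) g(res[k + 1], "CA") else NULL
    if (is.null(CAn) && k < length(res)) CAn <- g(res[k + 1], "CH3")
    if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C))
      out$phi[k] <- .torsion4(Cp, N, CA, C)
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn))
      out$psi[k] <- .torsion4(N, CA, C, Nn)
    if (!is.null(CA) && !is.null(C) && !is.null(Nn) && !is.null(CAn))
      out$omega[k] <- .torsion4(CA, C, Nn, CAn)
  }
  out
}
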