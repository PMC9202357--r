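#' Read a PDB file into one or more Conformations
#'
#' Parsing is delegated to [bio3d::read.pdb()]; this wrapper validates ATOM
#' records up front (rejecting malformed lines with their line number),
#' resolves altloc duplicates by keeping the highest-occupancy copy (with a
#' warning), and converts the atom table into the package's
#' [conformation()] container.  Multi-model files (MODEL/ENDMDL) return a
#' list of Conformations sharing one atom table.
#'
#' @param path PDB file path.
#' @return a `Conformation`, or a list of them for multi-model files.
#' @export
readPDB <- function(path) {
  lines <- readLines(path)
  is_at <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(is_at & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d of %s", bad[1], path))
  multi <- any(grepl("^MODEL ", lines))
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  # altloc resolution: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    keep <- rep(TRUE, nrow(at))
    for (k in unique(key[duplicated(key)])) {
      i <- which(key == k)
      if (length(i) > 1) {
        keep[i] <- FALSE
        keep[i[which.max(at$o[i])]] <- TRUE
      }
    }
    if (any(!keep)) {
      warning("altloc duplicates resolved by highest occupancy")
      at <- at[keep, ]
      cols <- as.vector(vapply(which(keep), function(i)
        3L * (i - 1L) + 1:3, integer(3)))
      if (multi) {
        pdb$xyz <- pdb$xyz[, cols, drop = FALSE]
      } else {
        pdb$xyz <- pdb$xyz[cols]
      }
    }
  }
  mk <- function(xyz) {
    atoms <- data.frame(
      resno = at$resno, resid = at$resid, elety = at$elety,
      element = ifelse(!is.na(at$elesy) & at$elesy != "",
                       trimws(at$elesy), .element_of(trimws(at$elety))),
      charge = 0, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chain = ifelse(is.na(at$chain), "", at$chain),
      insert = ifelse(is.na(at$insert), "", at$insert),
      o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
      type = at$type, stringsAsFactors = FALSE)
    conformation(atoms, matrix(integer(0), ncol = 2),
                 labels = list(source = basename(path)))
  }
  if (multi) {
    lapply(seq_len(nrow(pdb$xyz)), function(m)
      mk(matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)))
  } else {
    mk(matrix(pdb$xyz, ncol = 3, byrow = TRUE))
  }
}

.pdb_atom_line <- function(i, at) {
  name <- at$elety[i]
  name_fmt <- if (nchar(name) >= 4) substr(name, 1, 4)
              else sprintf(" %-3s", name)
  type <- if (!is.null(at$type)) at$type[i] else "ATOM"
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, i, name_fmt, "", substr(at$resid[i], 1, 3),
          if (!is.null(at$chain)) at$chain[i] else "",
          at$resno[i],
          if (!is.null(at$insert)) at$insert[i] else "",
          at$x[i], at$y[i], at$z[i],
          if (!is.null(at$o)) at$o[i] else 1,
          if (!is.null(at$b)) at$b[i] else 0,
          at$element[i])
}

#' Write Conformations to a PDB file
#'
#' Emits standard fixed-width ATOM records (residues keep their numbers, no
#' chain ID unless the atom table carries one).  A list of conformations is
#' written as a MODEL/ENDMDL ensemble.  Files written by this function
#' re-read and re-write byte-identically.
#'
#' @param conf a `Conformation` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(conf, path) {
  one <- function(cf) {
    at <- cf$atoms
    vapply(seq_len(nrow(at)), .pdb_atom_line, character(1), at = at)
  }
  if (inherits(conf, "Conformation")) {
    out <- c(one(conf), "END")
  } else {
    out <- unlist(lapply(seq_along(conf), function(m)
      c(sprintf("MODEL %8d", m), one(conf[[m]]), "ENDMDL")))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}
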