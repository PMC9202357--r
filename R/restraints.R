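#' Atom/residue selector for distance restraints
#'
#' @param resno residue number (may be `NULL` for a pure atom-name selector).
#' @param name atom name (may be `NULL` for a residue-level selector, as in
#'   ambiguous interaction restraints).
#' @param segid optional segment identifier.
#' @return a `RestraintSelector`.
#' @export
restraintSelector <- function(resno = NULL, name = NULL, segid = NULL) {
  if (is.null(resno) && is.null(name))
    stop("selector needs at least a residue number or an atom name")
  structure(list(resno = if (is.null(resno)) NULL else as.integer(resno),
                 name = name, segid = segid),
            class = "RestraintSelector")
}

#' Single distance restraint
#'
#' A flat-bottomed distance bound: satisfied iff the measured distance lies
#' in `[d - dminus, d + dplus]`.  Ambiguous restraints pair `sel_i` with
#' several alternative `sel_j` selectors and are evaluated on the effective
#' distance `(sum r^-6)^(-1/6)` over all branch atom pairs.
#'
#' @param sel_i a [restraintSelector()].
#' @param sel_j a [restraintSelector()] or list of them (ambiguous).
#' @param d target distance (Angstrom), > 0.
#' @param dminus,dplus lower/upper corrections (Angstrom), >= 0.
#' @param ambiguous logical.
#' @return a `DistanceRestraint`.
#' @export
distanceRestraint <- function(sel_i, sel_j, d, dminus = 0, dplus = 0,
                              ambiguous = FALSE) {
  if (d <= 0) stop("restraint target must be positive")
  if (dminus < 0 || dplus < 0) stop("corrections must be non-negative")
  if (inherits(sel_j, "RestraintSelector")) sel_j <- list(sel_j)
  structure(list(sel_i = sel_i, sel_j = sel_j, d = d,
                 dminus = dminus, dplus = dplus,
                 ambiguous = isTRUE(ambiguous)),
            class = "DistanceRestraint")
}

#' Ordered collection of distance restraints
#'
#' @param restraints list of [distanceRestraint()]s.
#' @param kind one of `"backbone_cycle"`, `"disulfide_cycle"`,
#'   `"combined_cycle"`, `"air"`, `"body"`.
#' @return a `RestraintSet`.
#' @export
restraintSet <- function(restraints, kind = c("backbone_cycle",
                         "disulfide_cycle", "combined_cycle", "air", "body")) {
  kind <- match.arg(kind)
  stopifnot(all(vapply(restraints, inherits, logical(1), "DistanceRestraint")))
  structure(list(restraints = restraints, kind = kind),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet (%s): %d restraints\n", x$kind,
              length(x$restraints)))
  invisible(x)
}

#' @export
length.RestraintSet <- function(x) length(x$restraints)

.cycl_correction <- 0.1

#' Head-to-tail cyclization restraints
#'
#' Two bond-forming restraints between the chain termini: C-terminal C to
#' N-terminal N at 1.3 A and C-terminal O to N-terminal N at 2.3 A (the O-N
#' restraint shapes the O-C-N angle), each with 0.1 A lower and upper
#' corrections.
#'
#' @param spec a [peptideSpec()] with `backbone` or `combined` cyclization.
#' @return a `RestraintSet` of kind `backbone_cycle`.
#' @export
backboneCyclizationRestraints <- function(spec) {
  stopifnot(inherits(spec, "PeptideSpec"))
  if (!spec$cyclization %in% c("backbone", "combined"))
    stop("spec does not request head-to-tail cyclization")
  if (spec$caps != "charged_termini")
    stop("capped termini cannot form a head-to-tail bond")
  n <- length(spec$aa)
  restraintSet(list(
    distanceRestraint(restraintSelector(n, "C"), restraintSelector(1L, "N"),
                      1.3, .cycl_correction, .cycl_correction),
    distanceRestraint(restraintSelector(n, "O"), restraintSelector(1L, "N"),
                      2.3, .cycl_correction, .cycl_correction)),
    kind = "backbone_cycle")
}

#' Disulfide cyclization restraints
#'
#' Three restraints between the two bridge cysteines: CA-CA at 4 A, CB-CB at
#' 3.5 A, SG-SG at 2 A (mean distances observed in disulfide-cyclized
#' peptides), each with 0.1 A corrections.
#'
#' @param spec a [peptideSpec()] with a declared `disulfide_pair`.
#' @return a `RestraintSet` of kind `disulfide_cycle`.
#' @export
disulfideCyclizationRestraints <- function(spec) {
  stopifnot(inherits(spec, "PeptideSpec"))
  if (is.null(spec$disulfide_pair))
    stop("spec declares no disulfide pair")
  p <- spec$disulfide_pair
  mk <- function(name, d) {
    distanceRestraint(restraintSelector(p[1], name),
                      restraintSelector(p[2], name),
                      d, .cycl_correction, .cycl_correction)
  }
  restraintSet(list(mk("CA", 4), mk("CB", 3.5), mk("SG", 2)),
               kind = "disulfide_cycle")
}

#' Combined head-to-tail plus disulfide cyclization restraints
#'
#' The union of the backbone and disulfide restraints minus the CB-CB
#' restraint (not required when the termini are also restrained): C-N 1.3,
#' O-N 2.3, CA-CA 4, SG-SG 2, each with 0.1 A corrections.
#'
#' @param spec a [peptideSpec()] with `combined` cyclization.
#' @return a `RestraintSet` of kind `combined_cycle`.
#' @export
combinedCyclizationRestraints <- function(spec) {
  stopifnot(inherits(spec, "PeptideSpec"))
  if (spec$cyclization != "combined")
    stop("spec does not request combined cyclization")
  bb <- backboneCyclizationRestraints(spec)$restraints
  ss <- disulfideCyclizationRestraints(spec)$restraints
  keep <- vapply(ss, function(r) r$sel_i$name != "CB", logical(1))
  restraintSet(c(bb, ss[keep]), kind = "combined_cycle")
}

#' Cyclization restraints appropriate for a spec
#' @param spec a [peptideSpec()].
#' @return a `RestraintSet` matching `spec$cyclization`.
#' @export
cyclizationRestraints <- function(spec) {
  switch(spec$cyclization,
         backbone = backboneCyclizationRestraints(spec),
         disulfide = disulfideCyclizationRestraints(spec),
         combined = combinedCyclizationRestraints(spec))
}

#' Receptor interface residues of a reference complex
#'
#' All receptor residues having any heavy atom within `cutoff` of any
#' peptide heavy atom; used as the active-residue list for docking
#' restraints.
#'
#' @param receptor,peptide `Conformation`s of the two molecules.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return sorted unique receptor residue numbers (integer; empty with a
#'   warning when there is no contact).
#' @export
interfaceFromComplex <- function(receptor, peptide, cutoff = 5) {
  ra <- receptor$atoms[receptor$atoms$element != "H", ]
  pa <- peptide$atoms[peptide$atoms$element != "H", ]
  rx <- as.matrix(ra[, c("x", "y", "z")])
  px <- as.matrix(pa[, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rowSums(px^2), "+") - 2 * rx %*% t(px)
  hit <- rowSums(d2 <= cutoff^2 + 1e-12) > 0
  res <- sort(unique(ra$resno[hit]))
  if (!length(res))
    warning("no receptor residue within cutoff of the peptide; ",
            "empty interface")
  as.integer(res)
}

#' Ambiguous interaction restraints from active/passive residue lists
#'
#' One ambiguous effective-distance restraint per active receptor residue,
#' pairing it with every passive peptide residue, with a 2.0 A target,
#' 2.0 A lower and 0.0 A upper correction (the convention of
#' active/passive restraint generators: effectively "any passive residue
#' within reach").
#'
#' @param active_receptor integer residue numbers asserted to be at the
#'   interface (penalized if absent from it).
#' @param passive_peptide integer residue numbers permitted at the interface
#'   without penalty (the peptide is defined fully passive).
#' @param d target distance (default 2.0).
#' @param segid_active,segid_passive segment ids of the two molecules.
#' @return a `RestraintSet` of kind `air`.
#' @export
ambiguousInteractionRestraints <- function(active_receptor, passive_peptide,
                                           d = 2.0, segid_active = "A",
                                           segid_passive = "B") {
  if (!length(active_receptor)) stop("active residue list is empty")
  if (!length(passive_peptide)) stop("passive residue list is empty")
  if (identical(segid_active, segid_passive) &&
      length(intersect(active_receptor, passive_peptide)))
    stop("active and passive lists overlap on the same molecule")
  restraints <- lapply(sort(as.integer(unique(active_receptor))), function(r) {
    distanceRestraint(
      restraintSelector(r, segid = segid_active),
      lapply(sort(as.integer(unique(passive_peptide))), function(p)
        restraintSelector(p, segid = segid_passive)),
      d, dminus = 2.0, dplus = 0.0, ambiguous = TRUE)
  })
  restraintSet(restraints, kind = "air")
}

# Partition a structure into rigid bodies at chain breaks: a break is a
# C(i)-N(i+1) distance above `break_cutoff` or a gap in residue numbering.
.detect_bodies <- function(conf, break_cutoff = 2.5) {
  res <- unique(conf$atoms$resno)
  if (length(res) < 2) stop("structure with fewer than 2 residues")
  body <- integer(length(res))
  body[1] <- 1L
  xyz <- coords(conf)
  for (k in 2:length(res)) {
    broke <- res[k] != res[k - 1] + 1L
    if (!broke) {
      i <- .atom_index(conf, res[k - 1], "C", required = FALSE)
      j <- .atom_index(conf, res[k], "N", required = FALSE)
      broke <- is.na(i) || is.na(j) ||
        .dist3(xyz[i, ], xyz[j, ]) > break_cutoff
    }
    body[k] <- body[k - 1] + broke
  }
  split(res, body)
}

#' Multibody restraints for a broken or multichain structure
#'
#' Partitions the structure into rigid bodies at chain breaks and emits, for
#' every pair of bodies, two CA-CA distance restraints fixing the measured
#' distance (zero corrections): the first CA of one body to the last CA of
#' the other, and vice versa.  These keep former chains and loop-flanked
#' segments together through high-temperature flexible refinement.
#'
#' @param structure a `Conformation` (typically a prepared receptor).
#' @param break_cutoff C-N distance (Angstrom) above which consecutive
#'   residues are considered disconnected (default 2.5).
#' @return a `RestraintSet` of kind `body` (empty for a single-body input).
#' @export
bodyRestraints <- function(structure, break_cutoff = 2.5) {
  bodies <- .detect_bodies(structure, break_cutoff)
  if (length(bodies) < 2) return(restraintSet(list(), kind = "body"))
  xyz <- coords(structure)
  ca_of <- function(r) .atom_index(structure, r, "CA")
  restraints <- list()
  for (a in seq_along(bodies)) {
    for (b in seq_len(a - 1L)) {
      ends_a <- c(bodies[[a]][1], bodies[[a]][length(bodies[[a]])])
      ends_b <- c(bodies[[b]][1], bodies[[b]][length(bodies[[b]])])
      for (pair in list(c(ends_a[1], ends_b[2]), c(ends_a[2], ends_b[1]))) {
        dd <- .dist3(xyz[ca_of(pair[1]), ], xyz[ca_of(pair[2]), ])
        restraints[[length(restraints) + 1L]] <-
          distanceRestraint(restraintSelector(pair[1], "CA"),
                            restraintSelector(pair[2], "CA"),
                            dd, 0, 0)
      }
    }
  }
  restraintSet(restraints, kind = "body")
}

#' Effective distance of an ambiguous restraint
#'
#' The soft-minimum `(sum r^-6)^(-1/6)` over all candidate atom-pair
#' distances; always less than or equal to the smallest pairwise distance.
#'
#' @param d numeric vector of pairwise distances.
#' @return effective distance (Angstrom).
#' @export
effectiveDistance <- function(d) {
  stopifnot(length(d) > 0, all(d > 0))
  sum(d^-6)^(-1 / 6)
}

# ---- tbl serialization ------------------------------------------------

.sel_to_cns <- function(s) {
  parts <- c(
    if (!is.null(s$segid)) sprintf("segid %s", s$segid),
    if (!is.null(s$resno)) sprintf("resid %d", s$resno),
    if (!is.null(s$name)) sprintf("name %s", s$name))
  if (!length(parts))
    stop("selector with no atom-name/residue information")
  paste0("(", paste(parts, collapse = " and "), ")")
}

#' Serialize a restraint set in the CNS tbl dialect
#'
#' One `assign (sel_i) (sel_j) d dminus dplus` statement per restraint;
#' ambiguous restraints expand the second selection into parenthesized
#' `or` alternatives.  The output round-trips losslessly through
#' [readTbl()].
#'
#' @param set a `RestraintSet`.
#' @param path optional file to write to.
#' @return the tbl text as a character vector of lines.
#' @export
writeTbl <- function(set, path = NULL) {
  stopifnot(inherits(set, "RestraintSet"))
  if (!length(set$restraints) && set$kind != "body")
    stop("refusing to write an empty ", set$kind, " restraint set")
  lines <- vapply(set$restraints, function(r) {
    sj <- if (length(r$sel_j) > 1L)
      paste0("(", paste(vapply(r$sel_j, .sel_to_cns, character(1)),
                        collapse = " or "), ")")
    else .sel_to_cns(r$sel_j[[1]])
    sprintf("assign %s %s %.3f %.3f %.3f",
            .sel_to_cns(r$sel_i), sj, r$d, r$dminus, r$dplus)
  }, character(1))
  if (!is.null(path)) writeLines(lines, path)
  lines
}

.parse_sel <- function(txt) {
  segid <- if (grepl("segid", txt))
    sub(".*segid +([^ )]+).*", "\\1", txt) else NULL
  resno <- if (grepl("resid", txt))
    as.integer(sub(".*resid +(\\d+).*", "\\1", txt)) else NULL
  name <- if (grepl("name", txt))
    sub(".*name +([^ )]+).*", "\\1", txt) else NULL
  restraintSelector(resno, name, segid)
}

#' Parse a CNS tbl restraint file
#'
#' Companion parser to [writeTbl()]; supports the subset of the dialect the
#' package emits (single-level `or` ambiguity).
#'
#' @param x path to a tbl file, or its lines as a character vector.
#' @param kind the `RestraintSet` kind to stamp on the result.
#' @return a `RestraintSet`.
#' @export
readTbl <- function(x, kind = "air") {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  restraints <- lapply(lines, function(ln) {
    if (!startsWith(ln, "assign")) stop("unparseable tbl line: ", ln)
    body <- trimws(sub("^assign", "", ln))
    # split top-level parenthesized groups
    depth <- 0L; start <- NA_integer_; groups <- character(0)
    chars <- strsplit(body, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") {
        if (depth == 0L) start <- i
        depth <- depth + 1L
      } else if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L)
          groups <- c(groups, substr(body, start, i))
      }
    }
    nums <- as.numeric(strsplit(trimws(
      substr(body, max(gregexpr("\\)", body)[[1]]) + 1L, nchar(body))),
      " +")[[1]])
    sel_i <- .parse_sel(groups[1])
    amb <- grepl(" or ", groups[2])
    sel_j <- if (amb) {
      inner <- regmatches(groups[2],
                          gregexpr("\\([^()]*\\)", groups[2]))[[1]]
      lapply(inner, .parse_sel)
    } else list(.parse_sel(groups[2]))
    distanceRestraint(sel_i, sel_j, nums[1], nums[2], nums[3],
                      ambiguous = amb)
  })
  restraintSet(restraints, kind = kind)
}

# Resolve a selector to atom indices on a conformation (sequence-position
# offset applied for capped peptides when the selector carries a resno).
.resolve_selector <- function(sel, conf) {
  at <- conf$atoms
  m <- rep(TRUE, nrow(at))
  if (!is.null(sel$resno)) m <- m & at$resno == sel$resno + conf$offset
  if (!is.null(sel$name)) m <- m & at$elety == sel$name
  which(m)
}

#' Measured distances of a restraint set on a conformation
#'
#' @param conf a `Conformation` (single molecule; selectors resolved by
#'   residue number and atom name).
#' @param set a `RestraintSet`.
#' @return data.frame with target, bounds, measured distance and a
#'   `satisfied` flag per restraint.
#' @export
restraintDistances <- function(conf, set) {
  xyz <- coords(conf)
  rows <- lapply(set$restraints, function(r) {
    ii <- .resolve_selector(r$sel_i, conf)
    jj <- unlist(lapply(r$sel_j, .resolve_selector, conf = conf))
    if (!length(ii) || !length(jj))
      stop("restraint selector matches no atom")
    d <- sqrt(outer(rowSums(xyz[ii, , drop = FALSE]^2),
                    rowSums(xyz[jj, , drop = FALSE]^2), "+") -
              2 * xyz[ii, , drop = FALSE] %*% t(xyz[jj, , drop = FALSE]))
    meas <- effectiveDistance(as.vector(d))
    data.frame(d = r$d, dminus = r$dminus, dplus = r$dplus,
               measured = meas,
               satisfied = meas >= r$d - r$dminus - 1e-9 &
                 meas <= r$d + r$dplus + 1e-9)
  })
  do.call(rbind, rows)
}

#' Read an active/passive residue list
#'
#' Two whitespace-separated lines: active residues first, passive second.
#'
#' @param path file path.
#' @return list with integer vectors `active` and `passive`.
#' @export
readActPass <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("active/passive file needs two lines (active, passive)")
  parse1 <- function(ln) as.integer(strsplit(trimws(ln), "\\s+")[[1]])
  list(active = parse1(lines[1]), passive = parse1(lines[2]))
}

#' Write an active/passive residue list
#' @param active,passive integer residue vectors.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeActPass <- function(active, passive, path) {
  writeLines(c(paste(active, collapse = " "),
               paste(passive, collapse = " ")), path)
  invisible(path)
}
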