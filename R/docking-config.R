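#' Prepare a receptor structure for docking
#'
#' Reproduces the dataset-preparation pipeline: chains are isolated and
#' merged into a single unnamed chain, HETATM records (waters, ligands,
#' ions) are removed, and residue numbering is made non-overlapping --
#' either renumbered continuously from 1 (`reres`) or with later chains
#' shifted by a constant so internal gaps are preserved (`shiftres`).
#' If the merged structure still contains several rigid bodies (former
#' chains or missing loops), body restraints are generated to hold them
#' together during flexible refinement.
#'
#' @param pdb path to a PDB file or a `Conformation`.
#' @param renumber `"reres"`, `"shiftres"` or `"none"` (`none` fails on a
#'   residue-number collision after the merge).
#' @param hbonds_file file name recorded (and written, if `dir` given) for
#'   the body restraints (the docking engine consumes them through its
#'   hydrogen-bond restraint slot).
#' @param dir optional output directory for the prepared PDB and restraint
#'   file.
#' @return list with `conformation` (prepared receptor) and `report`
#'   (a `ReceptorPrepReport`).
#' @export
prepareReceptor <- function(pdb, renumber = c("reres", "shiftres", "none"),
                            hbonds_file = "hbonds.tbl", dir = NULL) {
  renumber <- match.arg(renumber)
  conf <- if (inherits(pdb, "Conformation")) pdb else readPDB(pdb)
  at <- conf$atoms
  if (is.null(at$chain)) at$chain <- ""
  if (is.null(at$type)) at$type <- "ATOM"
  n_het <- sum(at$type == "HETATM")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records left after HETATM removal")
  chains <- unique(at$chain)

  # merge chains into one unnamed chain with non-overlapping numbering
  renum_map <- list()
  if (renumber == "reres") {
    key <- paste(at$chain, at$resno, at$insert %||% "")
    uk <- unique(key)
    new <- match(key, uk)
    renum_map <- stats::setNames(new[!duplicated(key)], uk)
    at$resno <- new
  } else if (renumber == "shiftres") {
    offsetv <- 0L
    prev_max <- NULL
    for (ch in chains) {
      i <- which(at$chain == ch)
      if (!is.null(prev_max) && min(at$resno[i]) + offsetv <= prev_max)
        offsetv <- prev_max - min(at$resno[i]) + 1L
      at$resno[i] <- at$resno[i] + offsetv
      renum_map[[ch]] <- offsetv
      prev_max <- max(at$resno[i])
    }
    renum_map <- unlist(renum_map)
  } else {
    key <- paste(at$chain, at$resno)
    tab <- unique(data.frame(ch = at$chain, r = at$resno))
    if (anyDuplicated(tab$r))
      stop("residue-number collision after chain merge; ",
           "renumbering (reres/shiftres) is required for multichain input")
  }
  at$chain <- ""
  if (!is.null(at$insert)) at$insert <- ""
  conf$atoms <- at
  conf$bonds <- matrix(integer(0), ncol = 2)

  bodies <- tryCatch(.detect_bodies(conf), error = function(e) list(1))
  body_set <- if (length(bodies) > 1) bodyRestraints(conf) else NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writePDB(conf, file.path(dir, "receptor.pdb"))
    if (!is.null(body_set) && length(body_set$restraints))
      writeTbl(body_set, file.path(dir, hbonds_file))
  }
  report <- structure(
    list(chains = chains, n_hetatm_removed = n_het,
         renumber = renumber, renumber_map = renum_map,
         n_bodies = length(bodies),
         hbonds_file = if (!is.null(body_set)) hbonds_file else NA_character_),
    class = "ReceptorPrepReport")
  list(conformation = conf, report = report, body_restraints = body_set)
}

#' @export
print.ReceptorPrepReport <- function(x, ...) {
  cat("ReceptorPrepReport:\n")
  cat("  chains merged:", paste(x$chains, collapse = ","),
      " HETATM removed:", x$n_hetatm_removed, "\n")
  cat("  renumbering:", x$renumber, " bodies:", x$n_bodies, "\n")
  if (!is.na(x$hbonds_file))
    cat("  body restraints:", x$hbonds_file, "\n")
  invisible(x)
}

.PROTOCOLS <- data.frame(
  protocol_id = c("5STR", "30STR", "40STR", "50STR", "60STR", "50STR_FLEX",
                  "50STR_SOLVSHELL", "50STR_FLEX_SOLVSHELL", "50STR_COMB"),
  ensemble_max = c(5, 30, 40, 50, 60, 50, 50, 50, 50),
  flexibility = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, NA),
  solvent_shell = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, NA),
  stringsAsFactors = FALSE)

#' Docking protocol configuration
#'
#' Returns the run configuration of one of the nine benchmarked docking
#' protocols.  All protocols share the base setup: 5000/400/400 models in
#' the three docking stages, semiflexible annealing steps multiplied by 4,
#' the cyclic-peptide topology flag on, and interface-ligand-RMSD
#' clustering at 5 A.  They differ in the maximum peptide-ensemble size
#' and in the extra-flexibility / explicit-solvent-shell switches; the
#' length-adaptive `50STR_COMB` protocol switches both on for long
#' peptides (more than 10 residues) and off for short ones.
#'
#' @param protocol_id one of 5STR, 30STR, 40STR, 50STR, 60STR, 50STR_FLEX,
#'   50STR_SOLVSHELL, 50STR_FLEX_SOLVSHELL, 50STR_COMB.
#' @param peptide_length residue count; required for 50STR_COMB (and used
#'   to emit the flexible-segment bounds).
#' @return a `RunConfig`.
#' @export
protocolConfig <- function(protocol_id, peptide_length = NULL) {
  row <- .PROTOCOLS[.PROTOCOLS$protocol_id == protocol_id, ]
  if (!nrow(row)) stop("unknown protocol id: ", protocol_id)
  flex <- row$flexibility
  solv <- row$solvent_shell
  if (protocol_id == "50STR_COMB") {
    if (is.null(peptide_length))
      stop("50STR_COMB requires the peptide length")
    flex <- peptide_length > 10
    solv <- peptide_length > 10
  }
  structure(list(
    protocol_id = protocol_id,
    models_it0 = 5000L, models_it1 = 400L, models_itw = 400L,
    it1_step_multiplier = 4L,
    cyclic_peptide = TRUE,
    peptide_fully_flexible = flex,
    solvent_shell = solv,
    clustering = list(method = "interface_ligand_rmsd", cutoff = 5),
    ensemble_max = as.integer(row$ensemble_max),
    peptide_length = if (is.null(peptide_length)) NA_integer_
                     else as.integer(peptide_length)),
    class = "RunConfig")
}

#' @export
print.RunConfig <- function(x, ...) {
  cat(sprintf("RunConfig %s: ensemble<=%d models %d/%d/%d flex=%s solv=%s\n",
              x$protocol_id, x$ensemble_max, x$models_it0, x$models_it1,
              x$models_itw, x$peptide_fully_flexible, x$solvent_shell))
  invisible(x)
}

#' Serialize a run configuration as a flat parameter file
#'
#' Emits only the deviations from engine defaults named by the protocol:
#' sampling counts, the step multiplier, the cyclic-peptide flag, the
#' clustering settings, input file paths, and -- when flexibility is on --
#' the flexible-segment fields for the peptide (molecule 2) spanning its
#' full residue range, plus the solvent-shell flag.  Round-trips through
#' [readRunParams()].
#'
#' @param config a `RunConfig`.
#' @param files named list of input paths (`ensemble`, `receptor`,
#'   `restraints`); all must be non-`NULL`.
#' @param path optional output file.
#' @return the parameter lines, invisibly if `path` is given.
#' @export
writeRunParams <- function(config, files, path = NULL) {
  need <- c("ensemble", "receptor", "restraints")
  miss <- setdiff(need, names(files))
  if (length(miss) || any(vapply(files[need], is.null, logical(1))))
    stop("missing input file path(s): ",
         paste(c(miss, need[vapply(files[need], is.null, logical(1))]),
               collapse = ", "))
  kv <- c(
    protocol = config$protocol_id,
    structures_0 = config$models_it0,
    structures_1 = config$models_it1,
    waterrefine = config$models_itw,
    it1_step_multiplier = config$it1_step_multiplier,
    cyclicpept_2 = tolower(config$cyclic_peptide),
    clust_meth = config$clustering$method,
    clust_cutoff = config$clustering$cutoff,
    ensemble_max = config$ensemble_max,
    ensemble_file = files$ensemble,
    receptor_file = files$receptor,
    restraints_file = files$restraints)
  if (isTRUE(config$peptide_fully_flexible)) {
    if (is.na(config$peptide_length))
      stop("flexible-segment fields need the peptide length")
    kv <- c(kv, nfle_2 = 1L, start_fle_2_1 = 1L,
            end_fle_2_1 = config$peptide_length)
  }
  kv <- c(kv, solvshell = tolower(isTRUE(config$solvent_shell)))
  lines <- paste0(names(kv), "=", unname(kv))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a flat run-parameter file
#' @param x path or character vector of `key=value` lines.
#' @return named character vector.
#' @export
readRunParams <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(p)
    paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1))
}
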