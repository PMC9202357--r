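#' Declare a peptide and its cyclization chemistry
#'
#' A `PeptideSpec` couples a one-letter amino-acid sequence with the intended
#' macrocycle chemistry: head-to-tail (`backbone`), a single disulfide bridge
#' (`disulfide`), or both (`combined`).  Head-to-tail closure requires free,
#' charged termini, so capping is only available for disulfide-only peptides.
#'
#' @param sequence one-letter amino-acid string, length >= 3 (typical
#'   macrocycles span 6-14 residues).
#' @param cyclization one of `"backbone"`, `"disulfide"`, `"combined"`.
#' @param caps terminal chemistry: `"charged_termini"` (NH3+ / COO-) or
#'   `"ACE_NME"` (acetyl / N-methyl amide caps).
#' @param disulfide_pair integer pair of sequence positions (1-based) of the
#'   two cysteines forming the bridge; required for `disulfide`/`combined`.
#' @return an object of class `PeptideSpec`.
#' @examples
#' peptideSpec("ACGGGCA", "disulfide", disulfide_pair = c(2, 6))
#' @export
peptideSpec <- function(sequence,
                        cyclization = c("backbone", "disulfide", "combined"),
                        caps = c("charged_termini", "ACE_NME"),
                        disulfide_pair = NULL) {
  cyclization <- match.arg(cyclization)
  caps <- match.arg(caps)
  stopifnot(is.character(sequence), length(sequence) == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 3)
    stop("sequence must contain at least 3 residues")
  bad <- which(!aa %in% names(.AA3))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d", aa[bad[1]], bad[1]))
  if (cyclization %in% c("backbone", "combined") && caps != "charged_termini")
    stop("head-to-tail cyclization requires charged termini, not caps")
  if (cyclization %in% c("disulfide", "combined")) {
    if (is.null(disulfide_pair) || length(disulfide_pair) != 2)
      stop("disulfide_pair must name two residue positions")
    disulfide_pair <- as.integer(disulfide_pair)
    if (disulfide_pair[1] == disulfide_pair[2])
      stop("disulfide_pair must name two distinct positions")
    if (any(disulfide_pair < 1 | disulfide_pair > length(aa)))
      stop("disulfide_pair positions outside the sequence")
    notc <- disulfide_pair[aa[disulfide_pair] != "C"]
    if (length(notc))
      stop(sprintf("disulfide_pair points at non-cysteine residue at position %d",
                   notc[1]))
  } else {
    disulfide_pair <- NULL
  }
  structure(
    list(sequence = paste(aa, collapse = ""), aa = aa,
         cyclization = cyclization, caps = caps,
         disulfide_pair = disulfide_pair),
    class = "PeptideSpec")
}

#' @export
print.PeptideSpec <- function(x, ...) {
  cat("PeptideSpec:", x$sequence, sprintf("(%d residues)\n", length(x$aa)))
  cat("  cyclization:", x$cyclization, " caps:", x$caps, "\n")
  if (!is.null(x$disulfide_pair))
    cat("  disulfide pair:", paste(x$disulfide_pair, collapse = "-"), "\n")
  invisible(x)
}
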