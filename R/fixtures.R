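# Synthetic fixtures: seed-deterministic toy complexes and ranked quality
# tables with known ground truth, so the assessment machinery can be
# exercised without any experimental structures.

# Single-atom residue helper for toy structures.
.toy_conf <- function(resno, xyz, resid = "GLY", elety = "CA") {
  atoms <- data.frame(resno = resno, resid = resid, elety = elety,
                      element = "C", charge = 0,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  conformation(atoms, matrix(integer(0), ncol = 2))
}

#' Toy receptor-peptide complex with planted native contacts
#'
#' Builds a rigid mini-receptor (one atom per residue, 4 A spacing) and a
#' peptide sitting 4.5 A above it, so that peptide residue k contacts
#' exactly receptor residue k (neighboring residues are > 5 A away).
#' Perturbed copies break a chosen number of contacts by translating the
#' corresponding peptide residues 10 A upward, so the surviving-contact
#' count -- and hence fnat -- is known by construction.
#'
#' @param seed RNG seed (adds small deterministic jitter < 0.2 A).
#' @param n_native_contacts number of planted contacts (>= 1).
#' @param break_counts integer vector; one perturbed model is produced per
#'   entry, breaking that many contacts.
#' @return list with `reference` (a `ComplexModel`), `models` (list of
#'   perturbed `ComplexModel`s) and `expected_fnat`.
#' @export
makeToyComplex <- function(seed = 1, n_native_contacts = 4,
                           break_counts = seq_len(n_native_contacts)) {
  stopifnot(n_native_contacts >= 1)
  set.seed(seed)
  n <- n_native_contacts
  jitter <- function(k) matrix(stats::runif(3 * k, -0.1, 0.1), ncol = 3)
  rx <- cbind(4 * (seq_len(n + 2) - 1), 0, 0) + jitter(n + 2)
  receptor <- .toy_conf(seq_len(n + 2), rx)
  px <- cbind(4 * (seq_len(n) - 1), 4.5, 0) + jitter(n)
  peptide <- .toy_conf(seq_len(n), px)
  reference <- complexModel(receptor, peptide)
  models <- lapply(break_counts, function(k) {
    py <- px
    if (k > 0) {
      broken <- seq_len(n) > n - k   # break the last k contacts
      py[broken, 2] <- py[broken, 2] + 10
    }
    complexModel(receptor, .toy_conf(seq_len(n), py))
  })
  list(reference = reference, models = models,
       expected_fnat = (n - break_counts) / n)
}

#' Ranked quality table with planted successes
#'
#' Generates, per complex, `n_models` ranked records that are all
#' `incorrect` except for explicitly planted (rank, class) events, so
#' success rates are computable by hand.
#'
#' @param seed RNG seed (controls nothing but is recorded, keeping the
#'   fixture interface uniform).
#' @param n_complexes number of complexes.
#' @param planted list of per-complex plantings; each element is `NULL` or
#'   a data.frame with columns `rank` and `class`.  Recycled if shorter
#'   than `n_complexes`.
#' @param n_models ranked records per complex (default 200).
#' @return named list of data.frames with `rank` and `capri_class`,
#'   suitable for [singleStructureSuccess()].
#' @export
makeQualityTable <- function(seed = 1, n_complexes = 10, planted = list(),
                             n_models = 200) {
  planted <- rep_len(if (length(planted)) planted else list(NULL),
                     n_complexes)
  out <- lapply(seq_len(n_complexes), function(i) {
    df <- data.frame(rank = seq_len(n_models),
                     capri_class = factor("incorrect",
                                          levels = .CAPRI_LEVELS,
                                          ordered = TRUE))
    p <- planted[[i]]
    if (!is.null(p)) {
      for (r in seq_len(nrow(p))) {
        stopifnot(p$rank[r] <= n_models)
        df$capri_class[p$rank[r]] <- p$class[r]
      }
    }
    df
  })
  names(out) <- sprintf("complex%02d", seq_len(n_complexes))
  attr(out, "seed") <- seed
  out
}
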