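#' Pair a receptor and peptide conformation into a complex
#'
#' @param receptor,peptide `Conformation`s; residue correspondence between
#'   models of the same complex is by residue number.
#' @return a `ComplexModel`.
#' @export
complexModel <- function(receptor, peptide) {
  structure(list(receptor = receptor, peptide = peptide),
            class = "ComplexModel")
}

# Residue-residue contact set across the interface: pairs with any
# heavy-atom pair within cutoff, encoded as "rres|pres".
.contact_set <- function(cx, cutoff) {
  ra <- cx$receptor$atoms[cx$receptor$atoms$element != "H", ]
  pa <- cx$peptide$atoms[cx$peptide$atoms$element != "H", ]
  rx <- as.matrix(ra[, c("x", "y", "z")])
  px <- as.matrix(pa[, c("x", "y", "z")])
  d2 <- outer(rowSums(rx^2), rowSums(px^2), "+") - 2 * rx %*% t(px)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  unique(paste(ra$resno[hit[, 1]], pa$resno[hit[, 2]], sep = "|"))
}

#' Fraction of native contacts
#'
#' Native contacts are reference residue pairs (one receptor residue, one
#' peptide residue) with any heavy-atom pair within `cutoff`; fnat is the
#' fraction of them reproduced in the model.
#'
#' @param model,reference `ComplexModel`s with shared residue numbering.
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fnat in `[0, 1]`.
#' @export
fnat <- function(model, reference, cutoff = 5) {
  native <- .contact_set(reference, cutoff)
  if (!length(native))
    stop("reference complex has no interface contacts; fnat undefined")
  found <- .contact_set(model, cutoff)
  length(intersect(native, found)) / length(native)
}

# Backbone atom rows of the given residues, ordered by (molecule, resno,
# atom name) so model and reference line up.
.interface_backbone <- function(cx, r_res, p_res) {
  pick <- function(conf, res) {
    at <- conf$atoms
    sel <- at$resno %in% res & at$elety %in% c("N", "CA", "C", "O")
    idx <- which(sel)
    idx[order(at$resno[idx], at$elety[idx])]
  }
  ri <- pick(cx$receptor, r_res)
  pi_ <- pick(cx$peptide, p_res)
  rbind(coords(cx$receptor)[ri, , drop = FALSE],
        coords(cx$peptide)[pi_, , drop = FALSE])
}

#' Interface RMSD
#'
#' Backbone RMSD over the reference interface (all residues of either
#' molecule with a heavy atom within `interface_cutoff` of the other
#' molecule in the reference) after optimal superposition on those same
#' atoms.  The 10 A interface definition follows the CAPRI convention.
#'
#' @param model,reference `ComplexModel`s.
#' @param interface_cutoff interface residue cutoff in Angstrom
#'   (default 10).
#' @return i-rmsd in Angstrom.
#' @export
iRmsd <- function(model, reference, interface_cutoff = 10) {
  r_res <- interfaceFromComplex(reference$receptor, reference$peptide,
                                cutoff = interface_cutoff)
  p_res <- interfaceFromComplex(reference$peptide, reference$receptor,
                                cutoff = interface_cutoff)
  if (!length(r_res) || !length(p_res))
    stop("empty reference interface at ", interface_cutoff, " A")
  xr <- .interface_backbone(reference, r_res, p_res)
  xm <- .interface_backbone(model, r_res, p_res)
  if (nrow(xr) != nrow(xm))
    stop("model and reference interface atom counts differ")
  .pair_rmsd(as.vector(t(xr)), as.vector(t(xm)))
}

#' Peptide backbone RMSD with optional cyclic-region mask
#'
#' @param model_peptide,reference_peptide peptide `Conformation`s.
#' @param cyclic_region_only if `TRUE`, restrict to `region` (residues
#'   inside the macrocycle; flexible termini outside the cyclic region are
#'   excluded).
#' @param region integer residue numbers of the cyclic region (required
#'   when `cyclic_region_only`).
#' @return backbone RMSD in Angstrom after superposition.
#' @export
peptideRmsd <- function(model_peptide, reference_peptide,
                        cyclic_region_only = FALSE, region = NULL) {
  res <- sort(unique(reference_peptide$atoms$resno))
  if (cyclic_region_only) {
    if (is.null(region) || !length(intersect(res, region)))
      stop("cyclic_region_only requires a non-empty region mask")
    res <- intersect(res, region)
  }
  sel_r <- which(reference_peptide$atoms$resno %in% res &
                 reference_peptide$atoms$elety %in% c("N", "CA", "C", "O"))
  sel_m <- which(model_peptide$atoms$resno %in% res &
                 model_peptide$atoms$elety %in% c("N", "CA", "C", "O"))
  if (length(sel_r) != length(sel_m))
    stop("model and reference peptide selections differ")
  .pair_rmsd(as.vector(t(coords(reference_peptide)[sel_r, ])),
             as.vector(t(coords(model_peptide)[sel_m, ])))
}

.CAPRI_LEVELS <- c("incorrect", "acceptable", "medium", "high")

#' CAPRI quality class from fnat
#'
#' Peptide-complex criteria: fnat above 0.8 is high, above 0.5 medium,
#' above 0.2 acceptable, otherwise incorrect (strict inequalities: a model
#' at exactly 0.5 is acceptable, not medium).
#'
#' @param f fnat value(s) in `[0, 1]`.
#' @return factor with ordered levels incorrect < acceptable < medium <
#'   high.
#' @export
capriClassify <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  cls <- ifelse(f > 0.8, "high",
         ifelse(f > 0.5, "medium",
         ifelse(f > 0.2, "acceptable", "incorrect")))
  factor(cls, levels = .CAPRI_LEVELS, ordered = TRUE)
}

#' CAPRI quality class from interface RMSD
#'
#' i-rmsd below 0.5 A is high, below 1.0 medium, below 2.0 acceptable,
#' otherwise incorrect.  Reported separately from the fnat class, never
#' merged with it.
#'
#' @param i i-rmsd value(s) in Angstrom.
#' @return ordered factor as in [capriClassify()].
#' @export
capriClassifyIRmsd <- function(i) {
  stopifnot(all(i >= 0))
  cls <- ifelse(i < 0.5, "high",
         ifelse(i < 1.0, "medium",
         ifelse(i < 2.0, "acceptable", "incorrect")))
  factor(cls, levels = .CAPRI_LEVELS, ordered = TRUE)
}

.level_value <- function(level) {
  match(match.arg(as.character(level), .CAPRI_LEVELS), .CAPRI_LEVELS)
}

#' Single-structure success rates over top-N cutoffs
#'
#' For each N, the percentage of complexes whose top-N ranked models
#' contain at least one model of the requested quality level or better.
#'
#' @param per_complex_records named list (one entry per complex) of
#'   data.frames with columns `rank` and `capri_class` (values from
#'   [capriClassify()] or the corresponding strings).
#' @param N_list single-structure cutoffs (default 1, 5, 10, 20, 50, 100,
#'   200).
#' @param level minimum quality level: "acceptable", "medium" or "high".
#' @return a `SuccessCurve` data.frame with columns `N` and `rate` (%).
#' @export
singleStructureSuccess <- function(per_complex_records,
                                   N_list = c(1, 5, 10, 20, 50, 100, 200),
                                   level = "acceptable") {
  if (!length(per_complex_records)) stop("no complexes supplied")
  lv <- .level_value(level)
  rate <- vapply(N_list, function(N) {
    hit <- vapply(per_complex_records, function(df) {
      any(df$rank <= N &
            match(as.character(df$capri_class), .CAPRI_LEVELS) >= lv)
    }, logical(1))
    100 * mean(hit)
  }, numeric(1))
  structure(data.frame(N = N_list, rate = rate, level = level),
            class = c("SuccessCurve", "data.frame"))
}

#' Cluster-based success rates
#'
#' Success for a complex at N clusters: any model of the requested level or
#' better among the top four members of any of the best N clusters.
#' Clusters with fewer than four members contribute their available
#' members.
#'
#' @param clustered_records named list (per complex) of data.frames with
#'   columns `cluster_rank`, `member_rank` and `capri_class`.
#' @param N_list cluster cutoffs (default 1:4).
#' @param level minimum quality level.
#' @param members_per_cluster how many top members of each cluster count
#'   (default 4).
#' @return a `SuccessCurve` data.frame.
#' @export
clusterSuccess <- function(clustered_records, N_list = 1:4,
                           level = "acceptable", members_per_cluster = 4) {
  if (!length(clustered_records)) stop("no complexes supplied")
  lv <- .level_value(level)
  rate <- vapply(N_list, function(N) {
    hit <- vapply(clustered_records, function(df) {
      any(df$cluster_rank <= N &
            df$member_rank <= members_per_cluster &
            match(as.character(df$capri_class), .CAPRI_LEVELS) >= lv)
    }, logical(1))
    100 * mean(hit)
  }, numeric(1))
  structure(data.frame(N = N_list, rate = rate, level = level),
            class = c("SuccessCurve", "data.frame"))
}

#' Assess a set of docked models against a reference complex
#'
#' @param models list of `ComplexModel`s, ranked by an external score (list
#'   order = rank; ties in a supplied `scores` vector are broken by model
#'   id).
#' @param reference the reference `ComplexModel`.
#' @param scores optional numeric vector; lower is better.
#' @param contact_cutoff fnat contact cutoff (default 5).
#' @return data.frame of `QualityRecord`s: model, rank, fnat, i_rmsd,
#'   capri_class (from fnat) and irmsd_class (reported separately).
#' @export
assessModels <- function(models, reference, scores = NULL,
                         contact_cutoff = 5) {
  n <- length(models)
  ord <- if (is.null(scores)) seq_len(n) else order(scores, seq_len(n))
  rank <- integer(n); rank[ord] <- seq_len(n)
  f <- vapply(models, fnat, numeric(1), reference = reference,
              cutoff = contact_cutoff)
  ir <- vapply(models, iRmsd, numeric(1), reference = reference)
  out <- data.frame(model = seq_len(n), rank = rank, fnat = f, i_rmsd = ir,
                    capri_class = capriClassify(f),
                    irmsd_class = capriClassifyIRmsd(ir))
  out[order(out$rank), ]
}
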