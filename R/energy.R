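#' Molecular-mechanics surrogate energy model
#'
#' Term weights for the desk-scale force field used by the cyclization
#' engine.  Equilibrium bond lengths, angles and impropers are taken from
#' the template-built geometry of the conformation itself, so a freshly
#' built peptide is strain-free; the model's job is to preserve covalent
#' geometry and chirality while annealing pulls the macrocycle closed.
#' Energies are in arbitrary thermal units; `kB` converts schedule
#' temperatures into those units.
#'
#' @param k_bond,k_angle,k_improper,k_omega force constants (per A^2 or
#'   rad^2).
#' @param eps_rep repulsive well depth; the purely repulsive nonbonded term
#'   is `eps_rep * ((s/r)^12 - 1)` for `r < s` (capped below `0.7 s`).
#' @param coul_const Coulomb prefactor of the optional electrostatic term
#'   with distance-dependent dielectric (`E = coul_const q_i q_j / r^2`).
#' @param k_restraint flat-bottom restraint force constant.
#' @param switch_offset violation (A) beyond which the restraint penalty
#'   becomes linear (soft-square form).
#' @param kB thermal-unit conversion for the Langevin integrator.
#' @param radii per-element repulsive radii (A).
#' @return an `EnergyModel`.
#' @export
energyModel <- function(k_bond = 1000, k_angle = 150, k_improper = 40,
                        k_omega = 20, eps_rep = 1, coul_const = 10,
                        k_restraint = 50, switch_offset = 0.5, kB = 0.001,
                        radii = c(C = 1.35, N = 1.25, O = 1.2,
                                  S = 1.5, H = 0.75)) {
  structure(list(k_bond = k_bond, k_angle = k_angle,
                 k_improper = k_improper, k_omega = k_omega,
                 eps_rep = eps_rep, coul_const = coul_const,
                 k_restraint = k_restraint, switch_offset = switch_offset,
                 kB = kB, radii = radii),
            class = "EnergyModel")
}

# Full bonded topology (with equilibrium values measured from the current
# coordinates) plus nonbonded exclusions and resolved restraint pairs.
.build_topology <- function(conf, model, restraints = NULL) {
  xyz <- coords(conf)
  n <- nrow(xyz)
  nb <- vector("list", n)
  for (k in seq_len(nrow(conf$bonds))) {
    i <- conf$bonds[k, 1]; j <- conf$bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb <- lapply(nb, sort)

  bonds <- cbind(conf$bonds,
                 sqrt(rowSums((xyz[conf$bonds[, 1], , drop = FALSE] -
                               xyz[conf$bonds[, 2], , drop = FALSE])^2)),
                 model$k_bond)

  angles <- list()
  for (j in seq_len(n)) {
    ns <- nb[[j]]
    if (length(ns) < 2) next
    for (a in seq_along(ns)) for (b in seq_len(a - 1L)) {
      i <- ns[b]; k <- ns[a]
      angles[[length(angles) + 1L]] <-
        c(i, j, k, .angle3(xyz[i, ], xyz[j, ], xyz[k, ]) * .deg,
          model$k_angle)
    }
  }
  angles <- do.call(rbind, angles)

  tors <- list()
  # impropers: pyramidalization/planarity/chirality guards with the built
  # geometry as the reference
  for (x in seq_len(n)) {
    ns <- nb[[x]]
    hs <- ns[conf$atoms$element[ns] != "H"]
    trip <- if (length(ns) == 3L) ns else if (length(hs) >= 3L) hs[1:3]
            else next
    tors[[length(tors) + 1L]] <-
      c(trip[1], trip[2], x, trip[3],
        .torsion4(xyz[trip[1], ], xyz[trip[2], ], xyz[x, ],
                  xyz[trip[3], ]) * .deg,
        model$k_improper)
  }
  # peptide-bond omega torsions (all inter-residue C-N bonds, including a
  # closure bond): CA-C-N-CA' held trans
  for (k in seq_len(nrow(conf$bonds))) {
    i <- conf$bonds[k, 1]; j <- conf$bonds[k, 2]
    nm <- conf$atoms$elety[c(i, j)]
    if (setequal(nm, c("C", "N")) &&
        conf$atoms$resno[i] != conf$atoms$resno[j]) {
      ci <- if (nm[1] == "C") i else j
      nj <- if (nm[1] == "C") j else i
      cai <- .atom_index(conf, conf$atoms$resno[ci], "CA", required = FALSE)
      if (is.na(cai))
        cai <- .atom_index(conf, conf$atoms$resno[ci], "CH3", required = FALSE)
      caj <- .atom_index(conf, conf$atoms$resno[nj], "CA", required = FALSE)
      if (is.na(caj))
        caj <- .atom_index(conf, conf$atoms$resno[nj], "CH3", required = FALSE)
      if (!is.na(cai) && !is.na(caj))
        tors[[length(tors) + 1L]] <- c(cai, ci, nj, caj, pi, model$k_omega)
    }
  }
  tors <- do.call(rbind, tors)

  # ideal-geometry overrides registered by topology edits (cycle closure):
  # measured equilibria are meaningless for a bond that does not yet have
  # its ideal geometry, so the junction terms get canonical values
  if (!is.null(conf$overrides)) {
    ov <- conf$overrides
    for (r in seq_len(NROW(ov$bonds))) {
      o <- ov$bonds[r, ]
      hit <- which((bonds[, 1] == o[1] & bonds[, 2] == o[2]) |
                   (bonds[, 1] == o[2] & bonds[, 2] == o[1]))
      bonds[hit, 3] <- o[3]
    }
    for (r in seq_len(NROW(ov$angles))) {
      o <- ov$angles[r, ]
      hit <- which(angles[, 2] == o[2] &
                   ((angles[, 1] == o[1] & angles[, 3] == o[3]) |
                    (angles[, 1] == o[3] & angles[, 3] == o[1])))
      angles[hit, 4] <- o[4] * .deg
    }
    for (r in seq_len(NROW(ov$impropers))) {
      o <- ov$impropers[r, ]
      hit <- which(tors[, 3] == o[1] & tors[, 6] == model$k_improper)
      tors[hit, 5] <- o[2] * .deg
    }
  }

  # nonbonded exclusions: 1-2, 1-3, 1-4
  ex <- new.env()
  addx <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = ex)
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      addx(i, j)
      for (k in nb[[j]]) {
        if (k == i) next
        addx(i, k)
        for (l in nb[[k]]) if (l != i && l != j) addx(i, l)
      }
    }
  }
  keys <- ls(ex)
  excl <- do.call(rbind, strsplit(keys, " "))
  storage.mode(excl) <- "integer"

  sigma <- unname(model$radii[conf$atoms$element])
  sigma[is.na(sigma)] <- 1.2

  r_i <- integer(0); r_j <- integer(0); r_group <- integer(0)
  r_lo <- numeric(0); r_hi <- numeric(0)
  if (!is.null(restraints) && length(restraints$restraints)) {
    for (g in seq_along(restraints$restraints)) {
      r <- restraints$restraints[[g]]
      ii <- .resolve_selector(r$sel_i, conf)
      jj <- unlist(lapply(r$sel_j, .resolve_selector, conf = conf))
      if (!length(ii) || !length(jj))
        stop("restraint selector matches no atom in the conformation")
      pairs <- expand.grid(ii, jj)
      r_i <- c(r_i, pairs[, 1]); r_j <- c(r_j, pairs[, 2])
      r_group <- c(r_group, rep(g, nrow(pairs)))
      r_lo <- c(r_lo, r$d - r$dminus); r_hi <- c(r_hi, r$d + r$dplus)
    }
  }

  list(bonds = bonds, angles = angles, torsions = tors,
       excl_i = excl[, 1], excl_j = excl[, 2],
       sigma = sigma, q = conf$atoms$charge,
       r_i = as.integer(r_i), r_j = as.integer(r_j),
       r_group = as.integer(r_group), r_lo = r_lo, r_hi = r_hi)
}

#' Energy and analytic gradient of a conformation
#'
#' @param conf a `Conformation` with bond topology.
#' @param model an [energyModel()].
#' @param restraints optional `RestraintSet` resolved on `conf`.
#' @param electrostatics logical; the Coulomb term (off during annealing per
#'   the cyclization protocol).
#' @param restraint_scale multiplier on the restraint penalty.
#' @param topology optional precomputed result of the internal topology
#'   builder (for repeated evaluation).
#' @return list with `energy` (scalar), `gradient` (n x 3 matrix) and
#'   `terms` (named breakdown).
#' @export
energyAndGradient <- function(conf, model = energyModel(), restraints = NULL,
                              electrostatics = FALSE, restraint_scale = 1,
                              topology = NULL) {
  if (any(!is.finite(coords(conf)))) stop("non-finite coordinates")
  if (is.null(topology)) topology <- .build_topology(conf, model, restraints)
  .energy_gradient_cpp(coords(conf), topology, unclass(model),
                       electrostatics, restraint_scale)
}
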