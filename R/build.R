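#' Build a linear all-atom peptide in a defined backbone state
#'
#' Constructs an extended conformation of the peptide from internal
#' coordinates, with every backbone phi/psi set to the preset of the chosen
#' state (beta sheet: phi = -140, psi = 135; polyproline II: phi = -78,
#' psi = 149; omega = 180 throughout), side chains in the extended rotamer,
#' terminal chemistry per the spec (NH3+/COO- or ACE/NME caps), and
#' hydrogens placed according to physiological-pH protonation (Asp/Glu
#' deprotonated, Lys/Arg protonated, His neutral with the proton on NE2,
#' Cys thiols protonated unless named in the declared disulfide pair).
#'
#' The builder is deterministic: the same spec and state always yield
#' bit-identical coordinates.
#'
#' @param spec a [peptideSpec()].
#' @param state `"beta"` or `"polypro"` starting backbone state.
#' @param dihedrals optional named vector `c(phi=, psi=, omega=)` overriding
#'   the state presets (degrees).
#' @return a [conformation()] labelled with the state.
#' @examples
#' conf <- buildLinearPeptide(peptideSpec("AAAAAA", "backbone"), "beta")
#' @export
buildLinearPeptide <- function(spec, state = c("beta", "polypro"),
                               dihedrals = NULL) {
  stopifnot(inherits(spec, "PeptideSpec"))
  state <- match.arg(state)
  dih <- .STATE_DIHEDRALS[[state]]
  if (!is.null(dihedrals)) dih[names(dihedrals)] <- dihedrals
  phi <- dih[["phi"]]; psi <- dih[["psi"]]; omg <- dih[["omega"]]

  capped <- spec$caps == "ACE_NME"
  res3 <- unname(.AA3[spec$aa])
  plan <- data.frame(resid = if (capped) c("ACE", res3, "NME") else res3,
                     stringsAsFactors = FALSE)
  n <- nrow(plan)
  offset <- if (capped) 1L else 0L

  pos <- list()      # "resno|name" -> xyz
  virt <- list()     # virtual reference atoms (ACE pseudo-N)
  rec <- list()      # atom records in emission order
  bonds_nm <- list() # bonds as c(resno_i, name_i, resno_j, name_j)
  put <- function(i, name, xyz, emit = TRUE) {
    pos[[paste0(i, "|", name)]] <<- xyz
    if (emit) rec[[length(rec) + 1L]] <<- list(resno = i, name = name)
  }
  gp <- function(i, name) {
    p <- pos[[paste0(i, "|", name)]]
    if (is.null(p)) stop(sprintf("internal: missing %s %d", name, i))
    p
  }
  addb <- function(i, ni, j, nj) {
    bonds_nm[[length(bonds_nm) + 1L]] <<- list(i, ni, j, nj)
  }

  for (i in seq_len(n)) {
    rn <- plan$resid[i]
    # proline's pyrrolidine ring restricts phi to ~-75; forcing the state
    # preset would drive the ring through the preceding carbonyl
    phi_i <- if (rn == "PRO") -78 else phi
    is_ace <- rn == "ACE"; is_nme <- rn == "NME"
    ca_name <- if (is_ace || is_nme) "CH3" else "CA"
    if (i == 1L) {
      put(i, "N", c(0, 0, 0), emit = !is_ace)
      put(i, ca_name, c(.BB$b_n_ca, 0, 0))
      if (!is_nme)
        put(i, "C", .nerf(c(0, 0, 1), gp(i, "N"), gp(i, ca_name),
                          .BB$b_ca_c, .BB$a_n_ca_c, 0))
    } else {
      Np <- gp(i - 1L, if (plan$resid[i - 1L] == "ACE") "N" else "N")
      CAp <- gp(i - 1L, if (plan$resid[i - 1L] == "ACE") "CH3" else "CA")
      Cp <- gp(i - 1L, "C")
      put(i, "N", .nerf(Np, CAp, Cp, .BB$b_c_n, .BB$a_ca_c_n, psi))
      put(i, ca_name, .nerf(CAp, Cp, gp(i, "N"),
                            .BB$b_n_ca, .BB$a_c_n_ca, omg))
      if (!is_nme)
        put(i, "C", .nerf(Cp, gp(i, "N"), gp(i, ca_name),
                          .BB$b_ca_c, .BB$a_n_ca_c, phi_i))
    }
    if (!is_nme) {
      put(i, "O", .nerf(gp(i, "N"), gp(i, ca_name), gp(i, "C"),
                        .BB$b_c_o, .BB$a_ca_c_o, psi + 180))
      addb(i, ca_name, i, "C"); addb(i, "C", i, "O")
    }
    if (!is_ace) addb(i, "N", i, ca_name)
    if (i > 1L) addb(i - 1L, "C", i, "N")
    # carboxylate on the free C-terminus
    if (i == n && !capped) {
      put(i, "OXT", .nerf(gp(i, "N"), gp(i, "CA"), gp(i, "C"),
                          .BB$b_c_oxt, .BB$a_ca_c_oxt, psi))
      addb(i, "C", i, "OXT")
    }
    # side chain
    sc <- .SIDECHAIN[[rn]]
    if (!is.null(sc)) {
      for (k in seq_len(nrow(sc))) {
        z <- sc[k, ]
        put(i, z$atom, .nerf(gp(i, z$dp), gp(i, z$ap), gp(i, z$p),
                             z$b, z$a, z$d))
        addb(i, z$p, i, z$atom)
      }
    }
    for (cl in .RING_CLOSURES[[rn]] %||% list()) addb(i, cl[1], i, cl[2])
  }

  # assemble heavy-atom table
  atoms <- do.call(rbind, lapply(rec, function(r) {
    xyz <- gp(r$resno, r$name)
    data.frame(resno = r$resno, resid = plan$resid[r$resno], elety = r$name,
               element = .element_of(r$name), charge = 0,
               x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }))
  idx_of <- function(resno, name) {
    i <- which(atoms$resno == resno & atoms$elety == name)
    if (!length(i)) NA_integer_ else i[1]
  }
  bonds <- do.call(rbind, lapply(bonds_nm, function(b) {
    c(idx_of(b[[1]], b[[2]]), idx_of(b[[3]], b[[4]]))
  }))
  bonds <- bonds[stats::complete.cases(bonds), , drop = FALSE]

  conf <- conformation(atoms, bonds,
                       labels = list(state = state, stage = "built"),
                       spec = spec, offset = offset)
  conf <- .add_hydrogens(conf)
  conf <- .assign_charges(conf)
  conf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Number of hydrogens carried by each heavy atom.
.h_count <- function(conf, i) {
  at <- conf$atoms[i, ]
  spec <- conf$spec
  nres <- max(conf$atoms$resno)
  first_pep <- 1L + conf$offset
  last_pep <- nres - conf$offset
  if (at$resid == "ACE") return(if (at$elety == "CH3") 3L else 0L)
  if (at$resid == "NME")
    return(switch(at$elety, CH3 = 3L, N = 1L, 0L))
  if (at$elety == "N") {
    if (at$resid == "PRO")
      return(if (at$resno == first_pep && conf$offset == 0L) 2L else 0L)
    if (at$resno == first_pep && conf$offset == 0L) return(3L)
    return(1L)
  }
  if (at$elety == "CA") return(if (at$resid == "GLY") 2L else 1L)
  if (at$elety %in% c("C", "O", "OXT")) return(0L)
  hs <- .H_SIDE[[at$resid]]
  m <- unname(hs[at$elety])
  if (is.na(m) || is.null(m)) return(0L)
  if (at$elety == "SG" && !is.null(spec) && !is.null(spec$disulfide_pair)) {
    seqpos <- at$resno - conf$offset
    if (seqpos %in% spec$disulfide_pair) return(0L)
  }
  as.integer(m)
}

.h_names <- function(elety, m) {
  if (elety == "N") return(if (m == 1L) "H" else paste0("H", seq_len(m)))
  if (elety == "CA") return(if (m == 1L) "HA" else c("HA2", "HA3"))
  if (elety == "CH3") return(paste0("HH3", seq_len(m)))
  g <- substr(elety, 2, nchar(elety))
  if (m == 1L) return(paste0("H", g))
  if (m == 3L) return(paste0("H", g, 1:3))
  if (.element_of(elety) == "N") paste0("H", g, 1:2) else paste0("H", g, 2:3)
}

# Geometric hydrogen completion from the heavy-atom frame.
.add_hydrogens <- function(conf) {
  xyz <- coords(conf)
  nb <- vector("list", nrow(conf$atoms))
  for (k in seq_len(nrow(conf$bonds))) {
    i <- conf$bonds[k, 1]; j <- conf$bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  newat <- list(); newb <- list()
  for (i in seq_len(nrow(conf$atoms))) {
    m <- .h_count(conf, i)
    if (m == 0L) next
    el <- conf$atoms$element[i]
    hl <- .H_BOND_LENGTH[[el]]
    X <- xyz[i, ]
    nbs <- sort(nb[[i]])
    k <- length(nbs)
    hpos <- list()
    if (k >= 2L && m == 1L) {
      u <- lapply(nbs, function(j) .unit(xyz[j, ] - X))
      hpos[[1]] <- X + hl * .unit(-Reduce(`+`, u))
    } else if (k == 2L && m == 2L) {
      u1 <- .unit(xyz[nbs[1], ] - X); u2 <- .unit(xyz[nbs[2], ] - X)
      d <- .unit(-(u1 + u2)); pn <- .unit(.cross3(u1, u2))
      half <- 54.25 * .deg
      hpos[[1]] <- X + hl * .unit(d * cos(half) + pn * sin(half))
      hpos[[2]] <- X + hl * .unit(d * cos(half) - pn * sin(half))
    } else if (k == 1L) {
      p <- nbs[1]
      ref <- setdiff(sort(nb[[p]]), i)[1]
      if (is.na(ref)) stop("internal: no reference atom for hydrogen placement")
      ang <- if (el == "S") 96 else if (el == "O") 109.5 else
        if (m == 2L) 120 else 109.5
      tors <- switch(as.character(m), "1" = 180, "2" = c(0, 180),
                     "3" = c(60, 180, 300))
      for (t in seq_len(m))
        hpos[[t]] <- .nerf(xyz[ref, ], xyz[p, ], X, hl, ang, tors[t])
    } else stop("internal: unhandled hydrogen geometry")
    nm <- .h_names(conf$atoms$elety[i], m)
    for (t in seq_len(m)) {
      newat[[length(newat) + 1L]] <-
        data.frame(resno = conf$atoms$resno[i], resid = conf$atoms$resid[i],
                   elety = nm[t], element = "H", charge = 0,
                   x = hpos[[t]][1], y = hpos[[t]][2], z = hpos[[t]][3],
                   stringsAsFactors = FALSE)
      newb[[length(newb) + 1L]] <- c(i, nrow(conf$atoms) + length(newat))
    }
  }
  if (length(newat)) {
    conf$atoms <- rbind(conf$atoms, do.call(rbind, newat))
    conf$bonds <- rbind(conf$bonds, do.call(rbind, newb))
  }
  conf
}

.assign_charges <- function(conf) {
  q <- numeric(nrow(conf$atoms))
  for (i in seq_len(nrow(conf$atoms))) {
    at <- conf$atoms[i, ]
    qs <- .Q_SIDE[[at$resid]]
    if (!is.null(qs) && at$elety %in% names(qs)) q[i] <- unname(qs[at$elety])
  }
  if (is.null(conf$spec) || conf$spec$caps == "charged_termini") {
    nres <- max(conf$atoms$resno)
    iN <- .atom_index(conf, 1L, "N", required = FALSE)
    if (!is.na(iN)) q[iN] <- q[iN] + 1
    for (nm in c("O", "OXT")) {
      i <- .atom_index(conf, nres, nm, required = FALSE)
      if (!is.na(i)) q[i] <- q[i] - 0.5
    }
  }
  conf$atoms$charge <- q
  conf
}

#' Distance between the bond-forming atoms of a macrocycle
#'
#' Monitors the gap the cyclization protocol closes: the C-terminal carbonyl
#' carbon to N-terminal nitrogen distance for head-to-tail closure, or the
#' SG-SG distance of the declared cysteine pair for a disulfide bridge.
#'
#' @param conf a `Conformation`.
#' @param mode `"backbone"` or `"disulfide"`.
#' @return distance in Angstrom.
#' @export
endToEndDistance <- function(conf, mode = c("backbone", "disulfide")) {
  mode <- match.arg(mode)
  xyz <- coords(conf)
  if (mode == "backbone") {
    pep <- setdiff(sort(unique(conf$atoms$resno)),
                   conf$atoms$resno[conf$atoms$resid %in% c("ACE", "NME")])
    i <- .atom_index(conf, min(pep), "N")
    j <- .atom_index(conf, max(pep), "C")
  } else {
    sg <- which(conf$atoms$elety == "SG")
    if (!is.null(conf$spec) && !is.null(conf$spec$disulfide_pair)) {
      rs <- conf$spec$disulfide_pair + conf$offset
      sg <- vapply(rs, function(r) .atom_index(conf, r, "SG"), integer(1))
    }
    if (length(sg) != 2) stop("missing atom SG: need exactly two SG atoms")
    i <- sg[1]; j <- sg[2]
  }
  .dist3(xyz[i, ], xyz[j, ])
}
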