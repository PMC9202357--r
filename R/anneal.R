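#' Simulated-annealing schedule for cyclization runs
#'
#' Four cooling phases analogous to the semiflexible refinement stages of a
#' docking run, with the default per-phase step counts (500, 500, 1000,
#' 1000) multiplied by 4 for cyclization, i.e. (2000, 2000, 4000, 4000).
#' Temperatures cool geometrically from `t_start` to `t_end` (arbitrary
#' thermal units).  The peptide is fully flexible in every phase and the
#' electrostatic term is off by default, matching the cyclization protocol.
#'
#' @param base_steps per-phase step counts before multiplication.
#' @param step_multiplier multiplier applied to every phase (default 4).
#' @param t_start,t_end temperature ramp end points (thermal units).
#' @param flexibility `"all"`, `"side_chains"` or `"none"` per phase
#'   (recycled).
#' @param restraint_scale restraint-energy multiplier per phase (recycled).
#' @param electrostatics logical per phase (recycled).
#' @return an `AnnealingSchedule` data.frame, one row per phase.
#' @export
annealingSchedule <- function(base_steps = c(500, 500, 1000, 1000),
                              step_multiplier = 4,
                              t_start = 1000, t_end = 50,
                              flexibility = "all",
                              restraint_scale = 1,
                              electrostatics = FALSE) {
  np <- length(base_steps)
  tb <- t_start * (t_end / t_start)^(seq(0, np) / np)
  sched <- data.frame(
    steps = as.integer(base_steps * step_multiplier),
    t_start = tb[seq_len(np)],
    t_end = tb[seq_len(np) + 1L],
    flexibility = rep_len(flexibility, np),
    restraint_scale = rep_len(restraint_scale, np),
    electrostatics = rep_len(electrostatics, np),
    stringsAsFactors = FALSE)
  class(sched) <- c("AnnealingSchedule", "data.frame")
  sched
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                     "HA", "HA2", "HA3", "CH3")

.mobility_mask <- function(conf, flexibility) {
  switch(flexibility,
         all = rep(TRUE, nrow(conf$atoms)),
         side_chains = !(conf$atoms$elety %in% .BACKBONE_NAMES),
         none = rep(FALSE, nrow(conf$atoms)),
         stop("unknown flexibility mode: ", flexibility))
}

# Integrator parameters: chosen for stability with the default force
# constants (bond k = 1000 per A^2 -> period ~ 0.2 time units).
.MD_DT <- 0.004
.MD_GAMMA <- 2

# Run a schedule (plus final minimization) on one conformation.
.run_schedule <- function(conf, topo, model, schedule,
                          final_minimize = 200, final_restraint_scale = 1,
                          final_elec = TRUE) {
  xyz <- coords(conf)
  for (p in seq_len(nrow(schedule))) {
    mobile <- .mobility_mask(conf, schedule$flexibility[p])
    xyz <- .run_langevin_cpp(xyz, topo, unclass(model),
                             schedule$steps[p],
                             schedule$t_start[p], schedule$t_end[p],
                             .MD_DT, .MD_GAMMA, mobile,
                             schedule$electrostatics[p],
                             schedule$restraint_scale[p],
                             init_velocities = (p == 1L))
  }
  if (final_minimize > 0)
    xyz <- .minimize_cpp(xyz, topo, unclass(model), final_minimize,
                         rep(TRUE, nrow(xyz)), final_elec,
                         final_restraint_scale)
  setCoords(conf, xyz)
}

.model_seed <- function(seed, m) {
  as.integer((as.numeric(seed) * 1000003 + m * 7919) %% 2147483629)
}

.score_conf <- function(conf, topo, model) {
  eg <- .energy_gradient_cpp(coords(conf), topo, unclass(model),
                             FALSE, 1)
  list(score = eg$energy, terms = eg$terms)
}

.closure_distances <- function(conf, spec) {
  out <- c()
  if (spec$cyclization %in% c("backbone", "combined"))
    out <- c(out, c_n = endToEndDistance(conf, "backbone"))
  if (spec$cyclization %in% c("disulfide", "combined"))
    out <- c(out, sg_sg = endToEndDistance(conf, "disulfide"))
  out
}

.model_set <- function(models, table, spec, stage) {
  structure(list(models = models, table = table, spec = spec,
                 stage = stage), class = "ModelSet")
}

#' @export
print.ModelSet <- function(x, ...) {
  cat(sprintf("ModelSet (%s): %d models of %s\n", x$stage,
              length(x$models), x$spec$sequence))
  cat(sprintf("  score range: %.1f .. %.1f\n",
              min(x$table$score), max(x$table$score)))
  invisible(x)
}

#' Step 2: reduce the distance between the bond-forming atoms
#'
#' Restrained simulated annealing of the linear starting conformations.
#' Each model starts from one of the input conformations (alternating),
#' with freshly randomized velocities, runs the four cooling phases fully
#' flexible with the cyclization restraints active and electrostatics off,
#' and finishes with a restrained minimization (the desk-scale surrogate of
#' a brief solvated refinement).  Models are scored by internal plus
#' restraint energy.
#'
#' @param start_ensemble list of starting `Conformation`s (typically the
#'   beta and polyproline builds).
#' @param spec the [peptideSpec()].
#' @param seed master seed; each model derives its own RNG stream from it.
#' @param n_models number of models to generate (protocol default 400).
#' @param schedule an [annealingSchedule()].
#' @param model an [energyModel()].
#' @param final_minimize minimizer iterations of the final phase.
#' @return a `ModelSet` with models, scores and closure distances.
#' @export
reduceDistanceStep2 <- function(start_ensemble, spec, seed = 1,
                                n_models = 400,
                                schedule = annealingSchedule(),
                                model = energyModel(),
                                final_minimize = 200) {
  stopifnot(length(start_ensemble) >= 1)
  restraints <- cyclizationRestraints(spec)
  for (cf in start_ensemble) {
    if (!identical(nrow(cf$atoms), nrow(start_ensemble[[1]]$atoms)))
      stop("start ensemble members differ in topology")
  }
  topo <- .build_topology(start_ensemble[[1]], model, restraints)
  models <- vector("list", n_models)
  rows <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    set.seed(.model_seed(seed, m))
    start <- start_ensemble[[(m - 1L) %% length(start_ensemble) + 1L]]
    out <- .run_schedule(start, topo, model, schedule,
                         final_minimize = final_minimize)
    out$labels$stage <- "step2"
    out$labels$seed <- seed
    out$labels$model <- m
    sc <- .score_conf(out, topo, model)
    cd <- .closure_distances(out, spec)
    models[[m]] <- out
    rows[[m]] <- data.frame(model = m, score = sc$score,
                            t(sc$terms), t(cd))
  }
  .model_set(models, do.call(rbind, rows), spec, "step2")
}

# Closure thresholds: head-to-tail bonds form when N and C are within
# 3.5 A; disulfides when the two SG are within 4 A.
.CLOSURE_NC <- 3.5
.CLOSURE_SS <- 4.0

.IDEAL_CLOSURE <- list(
  b_c_n = 1.329, b_ss = 2.04,
  a_ca_c_n = 116.2, a_o_c_n = 123.0, a_c_n_ca = 121.7, a_c_n_h = 118.5,
  a_cb_s_s = 103.0)

.drop_atoms <- function(conf, idx) {
  if (!length(idx)) return(conf)
  keep <- setdiff(seq_len(nrow(conf$atoms)), idx)
  remap <- integer(nrow(conf$atoms))
  remap[keep] <- seq_along(keep)
  b <- conf$bonds
  b <- b[!(b[, 1] %in% idx | b[, 2] %in% idx), , drop = FALSE]
  conf$atoms <- conf$atoms[keep, , drop = FALSE]
  rownames(conf$atoms) <- NULL
  conf$bonds <- matrix(remap[b], ncol = 2)
  if (!is.null(conf$overrides)) {
    conf$overrides <- lapply(conf$overrides, function(m) {
      if (is.null(m)) return(NULL)
      m[, -ncol(m)] <- remap[as.matrix(m[, -ncol(m), drop = FALSE])]
      m
    })
  }
  conf
}

.add_override <- function(conf, kind, row) {
  if (is.null(conf$overrides))
    conf$overrides <- list(bonds = NULL, angles = NULL, impropers = NULL)
  conf$overrides[[kind]] <- rbind(conf$overrides[[kind]], row)
  conf
}

# Form the covalent cycle: add the bond(s), fix the terminal chemistry
# (head-to-tail closure condenses out the extra terminal protons and the
# OXT oxygen), and register ideal geometry for the new junction.
.close_topology <- function(conf, spec) {
  g <- .IDEAL_CLOSURE
  if (spec$cyclization %in% c("backbone", "combined")) {
    first <- 1L + conf$offset
    last <- max(conf$atoms$resno) - conf$offset
    drop <- c()
    for (nm in c("OXT"))
      drop <- c(drop, .atom_index(conf, last, nm, required = FALSE))
    for (nm in c("H2", "H3"))
      drop <- c(drop, .atom_index(conf, first, nm, required = FALSE))
    conf <- .drop_atoms(conf, drop[!is.na(drop)])
    h1 <- .atom_index(conf, first, "H1", required = FALSE)
    if (!is.na(h1)) conf$atoms$elety[h1] <- "H"
    iC <- .atom_index(conf, last, "C")
    iN <- .atom_index(conf, first, "N")
    iCA1 <- .atom_index(conf, first, "CA")
    iCAn <- .atom_index(conf, last, "CA")
    iO <- .atom_index(conf, last, "O")
    iH <- .atom_index(conf, first, "H", required = FALSE)
    conf$bonds <- rbind(conf$bonds, c(iC, iN))
    conf <- .add_override(conf, "bonds", c(iC, iN, g$b_c_n))
    conf <- .add_override(conf, "angles", c(iCAn, iC, iN, g$a_ca_c_n))
    conf <- .add_override(conf, "angles", c(iO, iC, iN, g$a_o_c_n))
    conf <- .add_override(conf, "angles", c(iC, iN, iCA1, g$a_c_n_ca))
    if (!is.na(iH))
      conf <- .add_override(conf, "angles", c(iC, iN, iH, g$a_c_n_h))
    conf <- .add_override(conf, "impropers", c(iC, 180))
    conf <- .add_override(conf, "impropers", c(iN, 180))
    # termini are no longer charged once the amide bond is formed
    conf$atoms$charge[iN] <- 0
    conf$atoms$charge[iO] <- 0
  }
  if (spec$cyclization %in% c("disulfide", "combined")) {
    rs <- spec$disulfide_pair + conf$offset
    s1 <- .atom_index(conf, rs[1], "SG")
    s2 <- .atom_index(conf, rs[2], "SG")
    b1 <- .atom_index(conf, rs[1], "CB")
    b2 <- .atom_index(conf, rs[2], "CB")
    conf$bonds <- rbind(conf$bonds, c(s1, s2))
    conf <- .add_override(conf, "bonds", c(s1, s2, g$b_ss))
    conf <- .add_override(conf, "angles", c(b1, s1, s2, g$a_cb_s_s))
    conf <- .add_override(conf, "angles", c(b2, s2, s1, g$a_cb_s_s))
  }
  conf$labels$cyclized <- TRUE
  conf
}

.closure_ok <- function(conf, spec) {
  ok <- TRUE
  if (spec$cyclization %in% c("backbone", "combined"))
    ok <- ok && endToEndDistance(conf, "backbone") <= .CLOSURE_NC
  if (spec$cyclization %in% c("disulfide", "combined"))
    ok <- ok && endToEndDistance(conf, "disulfide") <= .CLOSURE_SS
  ok
}

#' Step 3: form the covalent cycle and relax it
#'
#' For every representative whose bond-forming atoms satisfy the closure
#' criteria (N-C within 3.5 A for head-to-tail, SG-SG within 4 A for a
#' disulfide) the covalent bond(s) are added to the topology.  Models are
#' then annealed with the cyclization restraints active in the cooling
#' phases only, and finish with an unrestrained relaxation with doubled
#' iterations.  Representatives failing the criteria are skipped; if none
#' passes, the run aborts with instructions to rerun step 2.
#'
#' @param representatives list of `Conformation`s (step-2 cluster centers,
#'   at most 10).
#' @inheritParams reduceDistanceStep2
#' @param final_minimize minimizer iterations before doubling.
#' @return a `ModelSet` of cyclized models.
#' @export
closeCycleStep3 <- function(representatives, spec, seed = 1,
                            n_models = 400,
                            schedule = annealingSchedule(),
                            model = energyModel(),
                            final_minimize = 200) {
  ok <- vapply(representatives, .closure_ok, logical(1), spec = spec)
  if (!any(ok))
    stop("no representative satisfies the closure criteria ",
         sprintf("(N-C <= %.1f A, SG-SG <= %.1f A); ", .CLOSURE_NC,
                 .CLOSURE_SS),
         "rerun step 2 with more sampling")
  reps <- lapply(representatives[ok], .close_topology, spec = spec)
  topo <- lapply(reps, .build_topology, model = model,
                 restraints = cyclizationRestraints(spec))
  models <- vector("list", n_models)
  rows <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    set.seed(.model_seed(seed, m))
    k <- (m - 1L) %% length(reps) + 1L
    out <- .run_schedule(reps[[k]], topo[[k]], model, schedule,
                         final_minimize = 2L * final_minimize,
                         final_restraint_scale = 0, final_elec = TRUE)
    out$labels$stage <- "step3"
    out$labels$seed <- seed
    out$labels$model <- m
    sc <- .score_conf(out, topo[[k]], model)
    cd <- .closure_distances(out, spec)
    models[[m]] <- out
    rows[[m]] <- data.frame(model = m, score = sc$score,
                            t(sc$terms), t(cd))
  }
  .model_set(models, do.call(rbind, rows), spec, "step3")
}

#' Full cyclization pipeline: ensemble of cyclic conformers
#'
#' Builds the beta and polyproline starting states, runs step 2, clusters
#' at 2.5 A backbone RMSD, takes up to 10 cluster centers, then repeats
#' step 3 once per seed; each step-3 run is clustered again (2.5 A) and
#' contributes up to 10 representatives, so the ensemble holds at most
#' `10 * n_seeds` conformations, each tagged with its seed and cluster
#' rank.
#'
#' @param spec a [peptideSpec()].
#' @param n_seeds number of independent step-3 repetitions.
#' @param seed master seed.
#' @param n_models models per stage (protocol default 400).
#' @param rmsd_cutoff clustering cutoff in Angstrom (default 2.5).
#' @param max_reps representatives kept per run (default 10).
#' @inheritParams reduceDistanceStep2
#' @return an `Ensemble` (see [selectRepresentatives()]).
#' @export
generateEnsemble <- function(spec, n_seeds = 3, seed = 1, n_models = 400,
                             rmsd_cutoff = 2.5, max_reps = 10,
                             schedule = annealingSchedule(),
                             model = energyModel()) {
  stopifnot(n_seeds >= 1)
  starts <- list(buildLinearPeptide(spec, "beta"),
                 buildLinearPeptide(spec, "polypro"))
  s2 <- reduceDistanceStep2(starts, spec, seed = seed, n_models = n_models,
                            schedule = schedule, model = model)
  cl2 <- clusterByRmsd(s2$models, cutoff = rmsd_cutoff)
  reps2 <- selectRepresentatives(cl2, s2$models, max_n = max_reps)
  members <- list()
  tags <- list()
  for (s in seq_len(n_seeds)) {
    s3 <- closeCycleStep3(reps2$members, spec, seed = .model_seed(seed, s),
                          n_models = n_models, schedule = schedule,
                          model = model)
    cl3 <- clusterByRmsd(s3$models, cutoff = rmsd_cutoff)
    reps3 <- selectRepresentatives(cl3, s3$models, max_n = max_reps)
    for (k in seq_along(reps3$members)) {
      cf <- reps3$members[[k]]
      cf$labels$seed <- s
      cf$labels$cluster_rank <- reps3$table$cluster_rank[k]
      members[[length(members) + 1L]] <- cf
      tags[[length(tags) + 1L]] <-
        data.frame(seed = s, cluster_rank = reps3$table$cluster_rank[k],
                   model = reps3$table$model[k])
    }
  }
  structure(list(members = members, table = do.call(rbind, tags),
                 spec = spec, max_size = 10L * n_seeds),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("Ensemble: %d conformations (max %d) of %s\n",
              length(x$members), x$max_size, x$spec$sequence))
  invisible(x)
}

#' Write a per-model score table
#'
#' @param ms a `ModelSet`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(ms, path) {
  utils::write.table(ms$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
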