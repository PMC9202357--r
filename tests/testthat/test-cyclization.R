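test_that("the cyclization schedule quadruples the semiflexible steps", {
  sched <- annealingSchedule()
  expect_equal(sched$steps, c(2000L, 2000L, 4000L, 4000L))
  expect_false(any(sched$electrostatics))
  expect_equal(sched$t_start[1], 1000)
  expect_equal(sched$t_end[nrow(sched)], 50)
})

test_that("a degenerate zero-step schedule leaves conformations unchanged", {
  spec <- gly6_spec()
  starts <- gly6_starts()
  sched <- annealingSchedule(base_steps = c(0, 0, 0, 0))
  out <- reduceDistanceStep2(starts, spec, seed = 1, n_models = 2,
                             schedule = sched, final_minimize = 0)
  for (m in 1:2)
    expect_equal(endToEndDistance(out$models[[m]], "backbone"),
                 endToEndDistance(starts[[m]], "backbone"))
})

test_that("step 2 pulls the restrained distance toward its target", {
  s2 <- gly6_step2_small()
  expect_length(s2$models, 6)
  input_median <- median(vapply(gly6_starts(), endToEndDistance,
                                numeric(1), mode = "backbone"))
  best <- order(s2$table$score)[seq_len(ceiling(6 / 10) * 2)]
  out_median <- median(s2$table$c_n[best])
  expect_lt(out_median, input_median)
  # all models come back with intact topology and chirality is moot for
  # glycine; check bond-topology conservation instead
  expect_identical(s2$models[[1]]$bonds, gly6_starts()[[1]]$bonds)
})

test_that("annealing conserves chirality and bond topology", {
  spec <- peptideSpec("AGAGA", "backbone")
  starts <- list(buildLinearPeptide(spec, "beta"),
                 buildLinearPeptide(spec, "polypro"))
  before <- ca_chirality_torsions(starts[[1]])
  s2 <- reduceDistanceStep2(starts, spec, seed = 5, n_models = 2)
  for (m in s2$models) {
    after <- ca_chirality_torsions(m)
    expect_equal(sign(after), sign(before))
    expect_true(all(abs(after) > 90 & abs(after) < 150))
    expect_identical(m$bonds, starts[[1]]$bonds)
  }
})

test_that("cyclization runs are deterministic in (spec, seed)", {
  spec <- gly6_spec()
  starts <- gly6_starts()
  a <- reduceDistanceStep2(starts, spec, seed = 7, n_models = 2)
  b <- reduceDistanceStep2(starts, spec, seed = 7, n_models = 2)
  expect_identical(coords(a$models[[1]]), coords(b$models[[1]]))
  expect_identical(coords(a$models[[2]]), coords(b$models[[2]]))
  c_ <- reduceDistanceStep2(starts, spec, seed = 8, n_models = 1)
  expect_false(identical(coords(a$models[[1]]), coords(c_$models[[1]])))
})

test_that("step 3 applies the closure criteria thresholds", {
  spec <- gly6_spec()
  s2 <- gly6_step2_small()
  rep_ok <- s2$models[[which.min(s2$table$score)]]
  # engineer exact N-C distances by moving residue 1 along the C->N axis
  set_nc <- function(conf, target) {
    iN <- which(conf$atoms$resno == 1 & conf$atoms$elety == "N")
    iC <- which(conf$atoms$resno == 6 & conf$atoms$elety == "C")
    xyz <- coords(conf)
    u <- xyz[iN, ] - xyz[iC, ]
    shift <- (target / sqrt(sum(u^2)) - 1) * u
    sel <- conf$atoms$resno == 1
    xyz[sel, ] <- sweep(xyz[sel, , drop = FALSE], 2, -shift)
    setCoords(conf, xyz)
  }
  too_far <- set_nc(rep_ok, 3.6)
  expect_error(closeCycleStep3(list(too_far), spec, seed = 1, n_models = 1),
               "rerun step 2")
  near <- set_nc(rep_ok, 3.4)
  tiny <- annealingSchedule(base_steps = c(5, 5, 5, 5))
  s3 <- closeCycleStep3(list(near), spec, seed = 1, n_models = 1,
                        schedule = tiny, final_minimize = 10)
  m <- s3$models[[1]]
  iN <- which(m$atoms$resno == 1 & m$atoms$elety == "N")
  iC <- which(m$atoms$resno == 6 & m$atoms$elety == "C")
  expect_true(any(m$bonds[, 1] == iC & m$bonds[, 2] == iN |
                  m$bonds[, 1] == iN & m$bonds[, 2] == iC))
  # the head-to-tail closure removes the extra terminal atoms
  expect_false("OXT" %in% m$atoms$elety)
  expect_false(any(c("H2", "H3") %in%
                     m$atoms$elety[m$atoms$resno == 1]))
})

test_that("closed macrocycles have amide-like closure geometry", {
  spec <- gly6_spec()
  s2 <- gly6_step2_small()
  cl <- clusterByRmsd(s2$models, 2.5)
  reps <- selectRepresentatives(cl, s2$models)
  s3 <- closeCycleStep3(reps$members, spec, seed = 3, n_models = 4)
  for (i in seq_along(s3$models)) {
    m <- s3$models[[i]]
    expect_lt(abs(endToEndDistance(m, "backbone") - 1.33), 0.1)
    # every omega, including the new bond, is trans within 30 degrees
    bd <- backboneDihedrals(m)
    om <- c(bd$omega[!is.na(bd$omega)],
            torsion_deg(conf_xyz(m, 6, "CA"), conf_xyz(m, 6, "C"),
                        conf_xyz(m, 1, "N"), conf_xyz(m, 1, "CA")))
    expect_true(all(abs(abs(om) - 180) < 30))
  }
})

test_that("disulfide closure forms an S-S bond at ideal length", {
  spec <- peptideSpec("CGGGC", "disulfide", disulfide_pair = c(1, 5))
  starts <- list(buildLinearPeptide(spec, "beta"),
                 buildLinearPeptide(spec, "polypro"))
  s2 <- reduceDistanceStep2(starts, spec, seed = 4, n_models = 4)
  cl <- clusterByRmsd(s2$models, 2.5)
  reps <- selectRepresentatives(cl, s2$models)
  s3 <- closeCycleStep3(reps$members, spec, seed = 4, n_models = 2)
  for (m in s3$models)
    expect_lt(abs(endToEndDistance(m, "disulfide") - 2.04), 0.1)
})

test_that("the final relaxation never raises the energy", {
  spec <- gly6_spec()
  conf <- gly6_step2_small()$models[[1]]
  model <- energyModel()
  topo <- cyclopep:::.build_topology(conf, model)
  xyz <- coords(conf) + 0.15   # push off the minimum
  e_before <- cyclopep:::.energy_gradient_cpp(
    xyz, topo, unclass(model), TRUE, 0)$energy
  set.seed(1)
  xyz2 <- xyz + matrix(rnorm(length(xyz), sd = 0.05), ncol = 3)
  e0 <- cyclopep:::.energy_gradient_cpp(
    xyz2, topo, unclass(model), TRUE, 0)$energy
  xmin <- cyclopep:::.minimize_cpp(xyz2, topo, unclass(model), 100,
                                   rep(TRUE, nrow(xyz2)), TRUE, 0)
  e1 <- cyclopep:::.energy_gradient_cpp(
    xmin, topo, unclass(model), TRUE, 0)$energy
  expect_lte(e1, e0)
})

test_that("ensembles stay within the per-seed representative budget", {
  spec <- gly6_spec()
  ens <- generateEnsemble(spec, n_seeds = 2, seed = 9, n_models = 4)
  expect_s3_class(ens, "Ensemble")
  expect_lte(length(ens$members), 20)
  expect_equal(ens$max_size, 20)
  expect_setequal(unique(ens$table$seed), 1:2)
  # each run contributes exactly as many members as it has clusters
  for (s in 1:2) {
    n_s <- sum(ens$table$seed == s)
    expect_lte(n_s, 10)
    expect_gte(n_s, 1)
  }
})
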