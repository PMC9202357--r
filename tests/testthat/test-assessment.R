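test_that("fnat reproduces planted contact fractions exactly", {
  toy <- makeToyComplex(seed = 1, n_native_contacts = 4,
                        break_counts = 0:4)
  ref <- toy$reference
  expect_equal(fnat(ref, ref), 1)
  for (k in seq_along(toy$models))
    expect_equal(fnat(toy$models[[k]], ref), toy$expected_fnat[k])
  # 3 of 4 contacts preserved -> 0.75
  expect_equal(fnat(toy$models[[2]], ref), 0.75)
  # translating the peptide 50 A away zeroes fnat
  gone <- complexModel(ref$receptor,
                       setCoords(ref$peptide, coords(ref$peptide) + 50))
  expect_equal(fnat(gone, ref), 0)
  # a reference without contacts is rejected
  expect_error(fnat(ref, gone), "no interface contacts")
})

test_that("fnat agrees with brute-force contact enumeration", {
  brute_fnat <- function(model, reference, cutoff = 5) {
    pairs <- function(cx) {
      out <- character(0)
      ra <- cx$receptor$atoms; pa <- cx$peptide$atoms
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(pa))) {
        d <- sqrt((ra$x[i] - pa$x[j])^2 + (ra$y[i] - pa$y[j])^2 +
                  (ra$z[i] - pa$z[j])^2)
        if (d <= cutoff) out <- c(out, paste(ra$resno[i], pa$resno[j]))
      }
      unique(out)
    }
    native <- pairs(reference)
    length(intersect(native, pairs(model))) / length(native)
  }
  toy <- makeToyComplex(seed = 6, n_native_contacts = 5, break_counts = 0:5)
  for (m in toy$models)
    expect_equal(fnat(m, toy$reference), brute_fnat(m, toy$reference))
})

test_that("fnat is invariant under rigid transforms of the model", {
  toy <- makeToyComplex(seed = 2, n_native_contacts = 4, break_counts = 2)
  m <- toy$models[[1]]
  moved <- complexModel(transform_conf(m$receptor, 55, c(0, 1, 1)),
                        transform_conf(m$peptide, 55, c(0, 1, 1)))
  expect_equal(fnat(moved, toy$reference), fnat(m, toy$reference))
})

test_that("i-rmsd is zero for the reference and transform-invariant", {
  toy <- makeToyComplex(seed = 4, n_native_contacts = 5, break_counts = 1)
  ref <- toy$reference
  expect_lt(iRmsd(ref, ref), 1e-9)
  moved <- complexModel(transform_conf(ref$receptor, 40, c(1, 0, 2)),
                        transform_conf(ref$peptide, 40, c(1, 0, 2)))
  expect_lt(iRmsd(moved, ref), 1e-6)
  # a perturbed model has positive i-rmsd, growing with the perturbation
  i1 <- iRmsd(toy$models[[1]], ref)
  expect_gt(i1, 0)
  far <- complexModel(ref$receptor,
                      setCoords(ref$peptide, coords(ref$peptide) +
                                  matrix(c(0, 8, 0), nrow(coords(ref$peptide)),
                                         3, byrow = TRUE)))
  expect_gt(iRmsd(far, ref), i1)
})

test_that("quality degrades monotonically as the peptide is pulled away", {
  toy <- makeToyComplex(seed = 9, n_native_contacts = 6, break_counts = 0)
  ref <- toy$reference
  shifts <- c(0, 1.5, 3, 6, 12)
  f <- i <- numeric(length(shifts))
  for (k in seq_along(shifts)) {
    pep <- setCoords(ref$peptide, sweep(coords(ref$peptide), 2,
                                        -c(0, shifts[k], 0)))
    cx <- complexModel(ref$receptor, pep)
    f[k] <- fnat(cx, ref)
    i[k] <- iRmsd(cx, ref)
  }
  expect_true(all(diff(f) <= 0))
  expect_true(all(diff(i) >= -1e-9))
})

test_that("i-rmsd on a tabulated toy matches an independent Kabsch oracle", {
  kabsch_oracle <- function(xa, xb) {
    ca <- colMeans(xa); cb <- colMeans(xb)
    xa <- sweep(xa, 2, ca); xb <- sweep(xb, 2, cb)
    s <- svd(t(xb) %*% xa)
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    sqrt(mean(rowSums((xb %*% R - xa)^2)))
  }
  mk <- function(resno, elety, xyz) {
    conformation(data.frame(resno = resno, resid = "GLY", elety = elety,
                            element = substr(elety, 1, 1), charge = 0,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                 matrix(integer(0), ncol = 2))
  }
  set.seed(21)
  bb <- c("N", "CA", "C", "O")
  rxyz <- matrix(rnorm(24, sd = 2), 8, 3)
  pxyz <- matrix(rnorm(24, sd = 2), 8, 3) +
    matrix(c(3, 0, 0), 8, 3, byrow = TRUE)
  ref <- complexModel(mk(rep(1:2, each = 4), rep(bb, 2), rxyz),
                      mk(rep(1:2, each = 4), rep(bb, 2), pxyz))
  mxyz_r <- rxyz + matrix(rnorm(24, sd = 0.4), 8, 3)
  mxyz_p <- pxyz + matrix(rnorm(24, sd = 0.4), 8, 3)
  model <- complexModel(mk(rep(1:2, each = 4), rep(bb, 2), mxyz_r),
                        mk(rep(1:2, each = 4), rep(bb, 2), mxyz_p))
  got <- iRmsd(model, ref)
  # oracle on the same (full-interface) atom sets, ordered identically
  ord <- order(rep(1:2, each = 4), rep(bb, 2))
  xa <- rbind(rxyz[ord, ], pxyz[ord, ])
  xb <- rbind(mxyz_r[ord, ], mxyz_p[ord, ])
  expect_lt(abs(got - kabsch_oracle(xa, xb)), 1e-6)
})

test_that("peptide RMSD honours the cyclic-region mask", {
  pep <- buildLinearPeptide(peptideSpec("ACGGCA", "disulfide",
                                        disulfide_pair = c(2, 5)), "beta")
  expect_equal(peptideRmsd(pep, pep), 0)
  # perturb only the termini (outside the cyclic region 2..5)
  pert <- pep
  xyz <- coords(pert)
  sel <- pert$atoms$resno %in% c(1, 6)
  set.seed(3)
  xyz[sel, ] <- xyz[sel, ] + matrix(rnorm(sum(sel) * 3, sd = 1.5), ncol = 3)
  pert <- setCoords(pert, xyz)
  expect_lt(peptideRmsd(pert, pep, cyclic_region_only = TRUE,
                        region = 2:5), 1e-9)
  expect_gt(peptideRmsd(pert, pep), 0)
  expect_error(peptideRmsd(pert, pep, cyclic_region_only = TRUE,
                           region = 100:120), "non-empty region")
})

test_that("CAPRI classification uses strict 'above' thresholds", {
  expect_equal(as.character(capriClassify(0.81)), "high")
  expect_equal(as.character(capriClassify(0.8)), "medium")
  expect_equal(as.character(capriClassify(0.51)), "medium")
  expect_equal(as.character(capriClassify(0.5)), "acceptable")
  expect_equal(as.character(capriClassify(0.21)), "acceptable")
  expect_equal(as.character(capriClassify(0.2)), "incorrect")
  expect_equal(as.character(capriClassify(0)), "incorrect")
  expect_error(capriClassify(1.2))
  # i-rmsd classes are computed separately with strict 'below' thresholds
  expect_equal(as.character(capriClassifyIRmsd(c(0.4, 0.5, 0.9, 1.0, 1.9, 2))),
               c("high", "medium", "medium", "acceptable", "acceptable",
                 "incorrect"))
})

test_that("single-structure success rates match a brute-force scan", {
  # worked example: 6 of 10 complexes with a medium-or-better model in the
  # top 10 gives 60%
  planted <- c(
    lapply(1:3, function(i) data.frame(rank = 4, class = "medium")),
    lapply(1:3, function(i) data.frame(rank = 10, class = "high")),
    list(data.frame(rank = 11, class = "medium")),
    lapply(1:2, function(i) data.frame(rank = 1, class = "acceptable")),
    list(NULL))
  tab <- makeQualityTable(seed = 1, n_complexes = 10, planted = planted,
                          n_models = 20)
  curve <- singleStructureSuccess(tab, level = "medium")
  expect_equal(curve$rate[curve$N == 10], 60)
  # brute force on random tables
  set.seed(17)
  classes <- c("incorrect", "acceptable", "medium", "high")
  rnd <- lapply(1:8, function(i)
    data.frame(rank = 1:30,
               capri_class = factor(sample(classes, 30, TRUE,
                                           prob = c(.85, .08, .05, .02)),
                                    levels = classes, ordered = TRUE)))
  names(rnd) <- paste0("c", 1:8)
  for (lv in c("acceptable", "medium", "high")) {
    curve <- singleStructureSuccess(rnd, N_list = c(1, 5, 10, 20), level = lv)
    lvn <- match(lv, classes)
    for (N in c(1, 5, 10, 20)) {
      brute <- 100 * mean(vapply(rnd, function(df)
        any(match(as.character(df$capri_class[df$rank <= N]),
                  classes) >= lvn), logical(1)))
      expect_equal(curve$rate[curve$N == N], brute)
    }
    # monotone in N, and ordered across levels at fixed N
    expect_true(all(diff(curve$rate) >= 0))
  }
  ca <- singleStructureSuccess(rnd, level = "acceptable")$rate
  cm <- singleStructureSuccess(rnd, level = "medium")$rate
  ch <- singleStructureSuccess(rnd, level = "high")$rate
  expect_true(all(ca >= cm & cm >= ch))
  expect_error(singleStructureSuccess(list()), "no complexes")
})

test_that("cluster success rates follow the top-4-members rule", {
  mkrec <- function(cluster_rank, member_rank, cls) {
    data.frame(cluster_rank = cluster_rank, member_rank = member_rank,
               capri_class = factor(cls, levels = cyclopep:::.CAPRI_LEVELS,
                                    ordered = TRUE))
  }
  # medium model as member 5 of cluster 1: never a success
  tab1 <- list(c1 = rbind(mkrec(1, 1:4, "incorrect"),
                          mkrec(1, 5, "medium")))
  expect_true(all(clusterSuccess(tab1, level = "medium")$rate == 0))
  # medium model as member 1 of cluster 4: success only at N = 4
  tab2 <- list(c1 = rbind(mkrec(1:3, 1, "incorrect"),
                          mkrec(4, 1, "medium")))
  curve <- clusterSuccess(tab2, level = "medium")
  expect_equal(curve$rate, c(0, 0, 0, 100))
  # brute force on random clustered tables
  set.seed(23)
  classes <- cyclopep:::.CAPRI_LEVELS
  rnd <- lapply(1:6, function(i) {
    df <- expand.grid(cluster_rank = 1:5, member_rank = 1:6)
    df$capri_class <- factor(sample(classes, nrow(df), TRUE,
                                    prob = c(.8, .1, .07, .03)),
                             levels = classes, ordered = TRUE)
    df
  })
  names(rnd) <- paste0("c", 1:6)
  for (lv in c("acceptable", "medium")) {
    curve <- clusterSuccess(rnd, level = lv)
    lvn <- match(lv, classes)
    for (N in 1:4) {
      brute <- 100 * mean(vapply(rnd, function(df)
        any(df$cluster_rank <= N & df$member_rank <= 4 &
              match(as.character(df$capri_class), classes) >= lvn),
        logical(1)))
      expect_equal(curve$rate[curve$N == N], brute)
    }
  }
})

test_that("quality-table fixtures are permutation-invariant and seeded", {
  planted <- list(data.frame(rank = 2, class = "high"), NULL)
  t1 <- makeQualityTable(seed = 5, n_complexes = 6, planted = planted)
  t2 <- makeQualityTable(seed = 5, n_complexes = 6, planted = planted)
  expect_identical(t1, t2)
  curve <- singleStructureSuccess(t1, level = "high")
  shuffled <- t1[c(4, 2, 6, 1, 3, 5)]
  expect_equal(singleStructureSuccess(shuffled, level = "high")$rate,
               curve$rate)
  none <- makeQualityTable(seed = 1, n_complexes = 4)
  expect_true(all(singleStructureSuccess(none)$rate == 0))
})
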