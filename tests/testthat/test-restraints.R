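bb_spec <- peptideSpec("GGGGGG", "backbone")
ss_spec <- peptideSpec("ACGGGCA", "disulfide", disulfide_pair = c(2, 6))
cb_spec <- peptideSpec("CGGGGC", "combined", disulfide_pair = c(1, 6))

restraint_df <- function(set) {
  do.call(rbind, lapply(set$restraints, function(r)
    data.frame(i = r$sel_i$name %||% "", j = r$sel_j[[1]]$name %||% "",
               d = r$d, dminus = r$dminus, dplus = r$dplus)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("head-to-tail cyclization restraints carry the protocol values", {
  set <- backboneCyclizationRestraints(bb_spec)
  df <- restraint_df(set)
  expect_equal(nrow(df), 2)
  expect_equal(df$d[df$i == "C"], 1.3)
  expect_equal(df$d[df$i == "O"], 2.3)
  expect_true(all(df$dminus == 0.1 & df$dplus == 0.1))
  capped <- peptideSpec("ACGCA", "disulfide", "ACE_NME", c(2, 4))
  expect_error(backboneCyclizationRestraints(capped), "head-to-tail")
})

test_that("disulfide cyclization restraints carry the protocol values", {
  df <- restraint_df(disulfideCyclizationRestraints(ss_spec))
  expect_equal(nrow(df), 3)
  expect_equal(df$d[df$i == "CA"], 4)
  expect_equal(df$d[df$i == "CB"], 3.5)
  expect_equal(df$d[df$i == "SG"], 2)
  expect_true(all(df$dminus == 0.1 & df$dplus == 0.1))
})

test_that("combined restraints are the union minus the CB-CB entry", {
  df <- restraint_df(combinedCyclizationRestraints(cb_spec))
  expect_equal(nrow(df), 4)
  expect_false("CB" %in% df$i)
  # set comparison against the two generators
  bb <- restraint_df(backboneCyclizationRestraints(cb_spec))
  ss <- restraint_df(disulfideCyclizationRestraints(cb_spec))
  expected <- rbind(bb, ss[ss$i != "CB", ])
  expect_equal(df[order(df$i), ], expected[order(expected$i), ],
               ignore_attr = TRUE)
})

test_that("interface extraction obeys the distance cutoff exactly", {
  mk <- function(resno, xyz) {
    conformation(data.frame(resno = resno, resid = "GLY", elety = "CA",
                            element = "C", charge = 0, x = xyz[, 1],
                            y = xyz[, 2], z = xyz[, 3]),
                 matrix(integer(0), ncol = 2))
  }
  rec <- mk(1:2, rbind(c(0, 0, 0), c(20, 0, 0)))
  pep49 <- mk(1, rbind(c(0, 4.9, 0)))
  pep51 <- mk(1, rbind(c(0, 5.1, 0)))
  expect_equal(interfaceFromComplex(rec, pep49), 1L)
  expect_warning(out <- interfaceFromComplex(rec, pep51), "empty")
  expect_length(out, 0)
  far <- mk(1, rbind(c(0, 100, 0)))
  expect_warning(expect_length(interfaceFromComplex(rec, far), 0))
})

test_that("interface extraction matches a brute-force all-pairs scan", {
  set.seed(42)
  mk <- function(resno, xyz) {
    conformation(data.frame(resno = resno, resid = "GLY", elety = "CA",
                            element = "C", charge = 0, x = xyz[, 1],
                            y = xyz[, 2], z = xyz[, 3]),
                 matrix(integer(0), ncol = 2))
  }
  for (rep in 1:5) {
    rres <- rep(1:3, each = 2)
    rxyz <- matrix(runif(18, 0, 12), ncol = 3)
    pres <- rep(1:2, each = 2)
    pxyz <- matrix(runif(12, 0, 12), ncol = 3)
    rec <- mk(rres, rxyz); pep <- mk(pres, pxyz)
    brute <- sort(unique(unlist(lapply(seq_len(6), function(i)
      if (any(sqrt(colSums((t(pxyz) - rxyz[i, ])^2)) <= 5)) rres[i]))))
    got <- suppressWarnings(interfaceFromComplex(rec, pep))
    expect_equal(got, as.integer(brute))
  }
  # invariance under rigid transforms of the whole complex
  toy <- makeToyComplex(seed = 3, n_native_contacts = 5)
  ref <- toy$reference
  before <- interfaceFromComplex(ref$receptor, ref$peptide)
  after <- interfaceFromComplex(transform_conf(ref$receptor, 70, c(1, 1, 0)),
                                transform_conf(ref$peptide, 70, c(1, 1, 0)))
  expect_equal(before, after)
})

test_that("AIRs pair every active residue with all passive residues", {
  set <- ambiguousInteractionRestraints(1:7, 1:9)
  expect_equal(length(set), 7)
  expect_true(all(vapply(set$restraints, function(r)
    r$ambiguous && length(r$sel_j) == 9, logical(1))))
  expect_true(all(vapply(set$restraints, function(r)
    r$d == 2 && r$dminus == 2 && r$dplus == 0, logical(1))))
  expect_error(ambiguousInteractionRestraints(integer(0), 1:9), "empty")
  expect_error(
    ambiguousInteractionRestraints(1:3, 3:5, segid_active = "A",
                                   segid_passive = "A"), "overlap")
  # emitted tbl: one line per active residue, 9 "or" branches each
  lines <- writeTbl(set)
  expect_length(lines, 7)
  or_counts <- vapply(lines, function(l)
    lengths(regmatches(l, gregexpr(" or ", l))), integer(1))
  expect_true(all(or_counts == 8))
})

# connected components of the body-restraint graph without extra deps
igraph_free_components <- function(set) {
  res <- unique(unlist(lapply(set$restraints, function(r)
    c(r$sel_i$resno, r$sel_j[[1]]$resno))))
  parent <- seq_along(res)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in set$restraints) {
    a <- find(match(r$sel_i$resno, res))
    b <- find(match(r$sel_j[[1]]$resno, res))
    parent[a] <- b
  }
  length(unique(vapply(seq_along(res), find, integer(1))))
}

test_that("body restraints connect detected rigid bodies", {
  single <- buildLinearPeptide(peptideSpec("GGGGGG", "backbone"), "beta")
  expect_length(bodyRestraints(single), 0)
  # two bodies: translate the second half far away
  broken <- single
  xyz <- coords(broken)
  sel <- broken$atoms$resno >= 4
  xyz[sel, 1] <- xyz[sel, 1] + 30
  broken <- setCoords(broken, xyz)
  set <- bodyRestraints(broken)
  expect_equal(length(set), 2)
  expect_true(all(vapply(set$restraints, function(r)
    r$dminus == 0 && r$dplus == 0, logical(1))))
  # targets equal the measured CA-CA distances
  for (r in set$restraints) {
    d <- sqrt(sum((conf_xyz(broken, r$sel_i$resno, "CA") -
                   conf_xyz(broken, r$sel_j[[1]]$resno, "CA"))^2))
    expect_equal(r$d, d)
  }
  # three bodies (via a numbering gap) form one connected component
  three <- single
  three$atoms$resno[three$atoms$resno >= 5] <-
    three$atoms$resno[three$atoms$resno >= 5] + 5L
  xyz <- coords(three)
  xyz[three$atoms$resno >= 10, 2] <- xyz[three$atoms$resno >= 10, 2] + 40
  sel <- three$atoms$resno %in% 3:4
  xyz[sel, 1] <- xyz[sel, 1] + 30
  three <- setCoords(three, xyz)
  # force a second break between residues 2 and 3
  set3 <- bodyRestraints(three)
  g <- igraph_free_components(set3)
  expect_equal(g, 1L)
  one_res <- conformation(single$atoms[single$atoms$resno == 1, ],
                          matrix(integer(0), ncol = 2))
  expect_error(bodyRestraints(one_res), "fewer than 2")
})

test_that("tbl serialization round-trips byte-identically", {
  set <- backboneCyclizationRestraints(bb_spec)
  lines <- writeTbl(set)
  expect_true(any(grepl("1.300 0.100 0.100", lines, fixed = TRUE)))
  rt <- writeTbl(readTbl(lines, kind = "backbone_cycle"))
  expect_identical(lines, rt)
  air <- ambiguousInteractionRestraints(c(3, 8), 1:4)
  expect_identical(writeTbl(air), writeTbl(readTbl(writeTbl(air))))
  expect_error(writeTbl(restraintSet(list(), kind = "air")), "empty")
  empty_body <- restraintSet(list(), kind = "body")
  expect_length(writeTbl(empty_body), 0)
})

test_that("the AIR effective distance is a soft minimum", {
  set.seed(7)
  for (k in 1:20) {
    d <- runif(sample(1:8, 1), 0.5, 15)
    expect_lte(effectiveDistance(d), min(d) + 1e-12)
  }
  expect_equal(effectiveDistance(3), 3)
})
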