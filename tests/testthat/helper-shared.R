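# Shared fixtures, memoized so expensive annealing runs happen once per
# test session.

.shared <- new.env()

memo <- function(key, expr) {
  if (!exists(key, envir = .shared, inherits = FALSE))
    assign(key, expr, envir = .shared)
  get(key, envir = .shared, inherits = FALSE)
}

gly6_spec <- function() peptideSpec("GGGGGG", "backbone")

gly6_starts <- function() memo("gly6_starts", list(
  buildLinearPeptide(gly6_spec(), "beta"),
  buildLinearPeptide(gly6_spec(), "polypro")))

# a short, cheap step-2 run used by several tests
gly6_step2_small <- function() memo("gly6_step2_small",
  reduceDistanceStep2(gly6_starts(), gly6_spec(), seed = 11, n_models = 6))

# independent torsion measurement (degrees, IUPAC sign)
torsion_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

conf_xyz <- function(conf, resno, elety) {
  i <- which(conf$atoms$resno == resno & conf$atoms$elety == elety)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

# rigid-body transform applied to a Conformation
transform_conf <- function(conf, angle_deg = 30, axis = c(0, 0, 1),
                           shift = c(5, -3, 2)) {
  th <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  setCoords(conf, sweep(coords(conf) %*% t(R), 2, -shift))
}

ca_chirality_torsions <- function(conf) {
  out <- c()
  for (r in sort(unique(conf$atoms$resno))) {
    nm <- conf$atoms$elety[conf$atoms$resno == r]
    if (!all(c("N", "C", "CA", "CB") %in% nm)) next
    out <- c(out, torsion_deg(conf_xyz(conf, r, "N"), conf_xyz(conf, r, "C"),
                              conf_xyz(conf, r, "CA"),
                              conf_xyz(conf, r, "CB")))
  }
  out
}
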