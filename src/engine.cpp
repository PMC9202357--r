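// Molecular-mechanics surrogate used by the cyclization engine: template
// bond/angle terms, harmonic (wrapped) dihedral terms for impropers and
// peptide-bond torsions, a purely repulsive capped r^-12 nonbonded term,
// optional distance-dependent-dielectric Coulomb, and flat-bottomed
// soft-square distance restraints with effective-distance (soft-min)
// semantics for ambiguous restraints.  Energies are in arbitrary thermal
// units with kB = 1 (temperatures passed pre-scaled).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Topology {
  NumericMatrix bonds;     // i j r0 k            (1-based indices)
  NumericMatrix angles;    // i j k th0 kth       (th0 radians)
  NumericMatrix torsions;  // i j k l target k    (target radians)
  IntegerVector excl_i, excl_j;  // excluded nonbonded pairs (1-2,1-3,1-4)
  NumericVector sigma;     // per-atom repulsive radius
  NumericVector q;         // per-atom charge
  // restraints: flattened groups
  IntegerVector r_i, r_j, r_group;
  NumericVector r_lo, r_hi;   // per-group bounds
};

static inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

// pairwise exclusion lookup as flat set
static std::vector<bool> build_excl(int n, const IntegerVector& ei,
                                    const IntegerVector& ej) {
  std::vector<bool> ex((size_t)n * n, false);
  for (int k = 0; k < ei.size(); ++k) {
    int a = ei[k] - 1, b = ej[k] - 1;
    ex[(size_t)a * n + b] = true;
    ex[(size_t)b * n + a] = true;
  }
  return ex;
}

class Energy {
public:
  int n;
  Topology top;
  std::vector<bool> excl;
  double eps_rep, coul_const, k_restraint, sw;
  bool elec_on;
  double restraint_scale;

  Energy(int n_, Topology t, double eps_rep_, double coul_const_,
         double k_restraint_, double sw_)
    : n(n_), top(t), eps_rep(eps_rep_), coul_const(coul_const_),
      k_restraint(k_restraint_), sw(sw_), elec_on(false),
      restraint_scale(1.0) {
    excl = build_excl(n, top.excl_i, top.excl_j);
  }

  // total energy and gradient; terms accumulated into `terms`
  double eval(const std::vector<double>& x, std::vector<double>& g,
              std::vector<double>& terms) {
    std::fill(g.begin(), g.end(), 0.0);
    terms.assign(6, 0.0);
    double e = 0.0;

    // bonds
    for (int b = 0; b < top.bonds.nrow(); ++b) {
      int i = (int)top.bonds(b, 0) - 1, j = (int)top.bonds(b, 1) - 1;
      double r0 = top.bonds(b, 2), kb = top.bonds(b, 3);
      double dx[3], r2 = 0;
      for (int d = 0; d < 3; ++d) { dx[d] = x[3*i+d] - x[3*j+d]; r2 += dx[d]*dx[d]; }
      double r = std::sqrt(r2);
      double dr = r - r0;
      terms[0] += kb * dr * dr;
      double f = 2.0 * kb * dr / std::max(r, 1e-8);
      for (int d = 0; d < 3; ++d) { g[3*i+d] += f * dx[d]; g[3*j+d] -= f * dx[d]; }
    }
    e += terms[0];

    // angles
    for (int a = 0; a < top.angles.nrow(); ++a) {
      int i = (int)top.angles(a, 0) - 1, j = (int)top.angles(a, 1) - 1,
          k = (int)top.angles(a, 2) - 1;
      double th0 = top.angles(a, 3), ka = top.angles(a, 4);
      double u[3], v[3], ru2 = 0, rv2 = 0, uv = 0;
      for (int d = 0; d < 3; ++d) {
        u[d] = x[3*i+d] - x[3*j+d];
        v[d] = x[3*k+d] - x[3*j+d];
        ru2 += u[d]*u[d]; rv2 += v[d]*v[d]; uv += u[d]*v[d];
      }
      double ru = std::sqrt(ru2), rv = std::sqrt(rv2);
      double c = uv / (ru * rv);
      c = std::max(-0.999999, std::min(0.999999, c));
      double th = std::acos(c);
      double dth = th - th0;
      terms[1] += ka * dth * dth;
      double s = std::sqrt(1.0 - c * c);
      double pref = 2.0 * ka * dth * (-1.0 / s);
      for (int d = 0; d < 3; ++d) {
        double dcdi = (v[d] / (ru * rv)) - c * u[d] / ru2;
        double dcdk = (u[d] / (ru * rv)) - c * v[d] / rv2;
        g[3*i+d] += pref * dcdi;
        g[3*k+d] += pref * dcdk;
        g[3*j+d] -= pref * (dcdi + dcdk);
      }
    }
    e += terms[1];

    // torsions / impropers: harmonic in wrapped (phi - target)
    for (int t = 0; t < top.torsions.nrow(); ++t) {
      int i = (int)top.torsions(t, 0) - 1, j = (int)top.torsions(t, 1) - 1,
          k = (int)top.torsions(t, 2) - 1, l = (int)top.torsions(t, 3) - 1;
      double tgt = top.torsions(t, 4), kt = top.torsions(t, 5);
      double b1[3], b2[3], b3[3];
      for (int d = 0; d < 3; ++d) {
        b1[d] = x[3*j+d] - x[3*i+d];
        b2[d] = x[3*k+d] - x[3*j+d];
        b3[d] = x[3*l+d] - x[3*k+d];
      }
      double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                       b1[0]*b2[1]-b1[1]*b2[0] };
      double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                       b2[0]*b3[1]-b2[1]*b3[0] };
      double n1s = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
      double n2s = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
      double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
      if (n1s < 1e-12 || n2s < 1e-12 || b2n < 1e-8) continue;
      double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                       n1[0]*b2[1]-n1[1]*b2[0] };
      double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
      double yy = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / b2n;
      double phi = -std::atan2(yy, xx);   // IUPAC sign
      double dphi = wrap_angle(phi - tgt);
      terms[2] += kt * dphi * dphi;
      double dedphi = 2.0 * kt * dphi;
      // analytic dihedral gradient (sign matches the IUPAC convention)
      double gi[3], gl[3];
      for (int d = 0; d < 3; ++d) {
        gi[d] = -b2n / n1s * n1[d];
        gl[d] =  b2n / n2s * n2[d];
      }
      double c12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (b2n*b2n);
      double c32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (b2n*b2n);
      for (int d = 0; d < 3; ++d) {
        double gj = (-c12 - 1.0) * gi[d] + c32 * gl[d];
        double gk = c12 * gi[d] + (-c32 - 1.0) * gl[d];
        g[3*i+d] += dedphi * gi[d];
        g[3*j+d] += dedphi * gj;
        g[3*k+d] += dedphi * gk;
        g[3*l+d] += dedphi * gl[d];
      }
    }
    e += terms[2];

    // nonbonded: capped purely repulsive r^-12 (+ optional Coulomb with
    // distance-dependent dielectric)
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excl[(size_t)i * n + j]) continue;
        double dx[3], r2 = 0;
        for (int d = 0; d < 3; ++d) { dx[d] = x[3*i+d] - x[3*j+d]; r2 += dx[d]*dx[d]; }
        double s = top.sigma[i] + top.sigma[j];
        double qq = top.q[i] * top.q[j];
        bool do_rep = r2 < s * s;
        bool do_el = elec_on && qq != 0.0 && r2 < 144.0;
        if (!do_rep && !do_el) continue;
        double r = std::sqrt(r2);
        double dedr = 0.0;
        if (do_rep) {
          double rcap = 0.7 * s;
          if (r >= rcap) {
            double sr = s / r;
            double sr12 = std::pow(sr, 12.0);
            terms[3] += eps_rep * (sr12 - 1.0);   // shifted to 0 at r = s
            dedr += -12.0 * eps_rep * sr12 / r;
          } else {
            double src = s / rcap;
            double src12 = std::pow(src, 12.0);
            double f0 = -12.0 * eps_rep * src12 / rcap;
            terms[3] += eps_rep * (src12 - 1.0) + f0 * (r - rcap);
            dedr += f0;
          }
        }
        if (do_el) {
          terms[4] += coul_const * qq / r2;
          dedr += -2.0 * coul_const * qq / (r2 * r);
        }
        double f = dedr / std::max(r, 1e-8);
        for (int d = 0; d < 3; ++d) { g[3*i+d] += f * dx[d]; g[3*j+d] -= f * dx[d]; }
      }
    }
    e += terms[3] + terms[4];

    // restraints: per group, effective distance (sum r^-6)^(-1/6), then
    // flat-bottom harmonic with linear asymptote beyond switch offset
    int ngroup = top.r_lo.size();
    if (ngroup > 0 && restraint_scale > 0.0) {
      std::vector<double> S(ngroup, 0.0);
      int npair = top.r_i.size();
      std::vector<double> rr(npair);
      for (int p = 0; p < npair; ++p) {
        int i = top.r_i[p] - 1, j = top.r_j[p] - 1;
        double dx0 = x[3*i]-x[3*j], dx1 = x[3*i+1]-x[3*j+1], dx2 = x[3*i+2]-x[3*j+2];
        double r = std::sqrt(dx0*dx0 + dx1*dx1 + dx2*dx2);
        rr[p] = std::max(r, 1e-6);
        S[top.r_group[p] - 1] += std::pow(rr[p], -6.0);
      }
      std::vector<double> deff(ngroup), dEdeff(ngroup, 0.0);
      for (int gI = 0; gI < ngroup; ++gI) {
        deff[gI] = std::pow(S[gI], -1.0 / 6.0);
        double viol = 0.0, sgn = 0.0;
        if (deff[gI] > top.r_hi[gI]) { viol = deff[gI] - top.r_hi[gI]; sgn = 1.0; }
        else if (deff[gI] < top.r_lo[gI]) { viol = top.r_lo[gI] - deff[gI]; sgn = -1.0; }
        if (viol > 0.0) {
          double kw = k_restraint * restraint_scale;
          if (viol <= sw) {
            terms[5] += kw * viol * viol;
            dEdeff[gI] = sgn * 2.0 * kw * viol;
          } else {
            terms[5] += kw * sw * sw + 2.0 * kw * sw * (viol - sw);
            dEdeff[gI] = sgn * 2.0 * kw * sw;
          }
        }
      }
      for (int p = 0; p < npair; ++p) {
        int gI = top.r_group[p] - 1;
        if (dEdeff[gI] == 0.0) continue;
        int i = top.r_i[p] - 1, j = top.r_j[p] - 1;
        // d deff / d r_p = deff^7 * r_p^-7
        double dd = std::pow(deff[gI], 7.0) * std::pow(rr[p], -7.0);
        double f = dEdeff[gI] * dd / rr[p];
        for (int d = 0; d < 3; ++d) {
          double dxd = x[3*i+d] - x[3*j+d];
          g[3*i+d] += f * dxd;
          g[3*j+d] -= f * dxd;
        }
      }
      e += terms[5];
    }
    return e;
  }
};

static Topology unpack(List topo) {
  Topology t;
  t.bonds = as<NumericMatrix>(topo["bonds"]);
  t.angles = as<NumericMatrix>(topo["angles"]);
  t.torsions = as<NumericMatrix>(topo["torsions"]);
  t.excl_i = as<IntegerVector>(topo["excl_i"]);
  t.excl_j = as<IntegerVector>(topo["excl_j"]);
  t.sigma = as<NumericVector>(topo["sigma"]);
  t.q = as<NumericVector>(topo["q"]);
  t.r_i = as<IntegerVector>(topo["r_i"]);
  t.r_j = as<IntegerVector>(topo["r_j"]);
  t.r_group = as<IntegerVector>(topo["r_group"]);
  t.r_lo = as<NumericVector>(topo["r_lo"]);
  t.r_hi = as<NumericVector>(topo["r_hi"]);
  return t;
}

// [[Rcpp::export(name = ".energy_gradient_cpp")]]
List energy_gradient_cpp(NumericMatrix xyz, List topo, List model,
                         bool elec_on, double restraint_scale) {
  int n = xyz.nrow();
  Energy en(n, unpack(topo), as<double>(model["eps_rep"]),
            as<double>(model["coul_const"]), as<double>(model["k_restraint"]),
            as<double>(model["switch_offset"]));
  en.elec_on = elec_on;
  en.restraint_scale = restraint_scale;
  std::vector<double> x(3 * n), g(3 * n), terms;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = xyz(i, d);
  for (double v : x) if (!std::isfinite(v)) stop("non-finite coordinates");
  double e = en.eval(x, g, terms);
  NumericMatrix grad(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) grad(i, d) = g[3*i+d];
  NumericVector tv = NumericVector::create(
    _["bond"] = terms[0], _["angle"] = terms[1], _["torsion"] = terms[2],
    _["repulsion"] = terms[3], _["elec"] = terms[4], _["restraint"] = terms[5]);
  return List::create(_["energy"] = e, _["gradient"] = grad,
                      _["terms"] = tv);
}

// Langevin dynamics with a linear temperature ramp; frozen atoms get zero
// force and velocity.  Uses R's RNG for reproducibility.
// [[Rcpp::export(name = ".run_langevin_cpp")]]
NumericMatrix run_langevin_cpp(NumericMatrix xyz, List topo, List model,
                               int nsteps, double t_start, double t_end,
                               double dt, double gamma, LogicalVector mobile,
                               bool elec_on, double restraint_scale,
                               bool init_velocities) {
  int n = xyz.nrow();
  Energy en(n, unpack(topo), as<double>(model["eps_rep"]),
            as<double>(model["coul_const"]), as<double>(model["k_restraint"]),
            as<double>(model["switch_offset"]));
  en.elec_on = elec_on;
  en.restraint_scale = restraint_scale;
  double kB = as<double>(model["kB"]);
  std::vector<double> x(3 * n), v(3 * n, 0.0), g(3 * n), terms;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = xyz(i, d);
  RNGScope scope;
  if (init_velocities) {
    double kT0 = kB * t_start;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[3*i+d] = mobile[i] ? R::norm_rand() * std::sqrt(kT0) : 0.0;
  }
  for (int s = 0; s < nsteps; ++s) {
    double T = t_start + (t_end - t_start) * ((double)s / std::max(1, nsteps - 1));
    double kT = kB * T;
    en.eval(x, g, terms);
    double noise = std::sqrt(2.0 * gamma * kT * dt);
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) { v[3*i] = v[3*i+1] = v[3*i+2] = 0.0; continue; }
      for (int d = 0; d < 3; ++d) {
        double& vi = v[3*i+d];
        vi += -g[3*i+d] * dt;
        vi *= (1.0 - gamma * dt);
        vi += noise * R::norm_rand();
        // velocity guard keeps the integrator stable on steep contacts
        if (vi > 5.0) vi = 5.0;
        if (vi < -5.0) vi = -5.0;
        x[3*i+d] += vi * dt;
      }
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3*i+d];
  return out;
}

// Steepest-descent minimization with backtracking line search; the
// returned configuration never has higher energy than the input.
// [[Rcpp::export(name = ".minimize_cpp")]]
NumericMatrix minimize_cpp(NumericMatrix xyz, List topo, List model,
                           int maxiter, LogicalVector mobile, bool elec_on,
                           double restraint_scale) {
  int n = xyz.nrow();
  Energy en(n, unpack(topo), as<double>(model["eps_rep"]),
            as<double>(model["coul_const"]), as<double>(model["k_restraint"]),
            as<double>(model["switch_offset"]));
  en.elec_on = elec_on;
  en.restraint_scale = restraint_scale;
  std::vector<double> x(3 * n), g(3 * n), xt(3 * n), gt(3 * n), terms;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3*i+d] = xyz(i, d);
  double e = en.eval(x, g, terms);
  double step = 1e-3;
  for (int it = 0; it < maxiter; ++it) {
    double gmax = 0.0;
    for (int i = 0; i < n; ++i)
      if (mobile[i])
        for (int d = 0; d < 3; ++d)
          gmax = std::max(gmax, std::fabs(g[3*i+d]));
    if (gmax < 1e-4) break;
    bool accepted = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          xt[3*i+d] = x[3*i+d] - (mobile[i] ? step * g[3*i+d] : 0.0);
      double et = en.eval(xt, gt, terms);
      if (et < e) {
        x = xt; g = gt; e = et;
        step *= 1.2;
        accepted = true;
        break;
      }
      step *= 0.5;
    }
    if (!accepted) break;
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3*i+d];
  return out;
}
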