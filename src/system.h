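#ifndef DNADYN_SYSTEM_H
#define DNADYN_SYSTEM_H

#include "geometry.h"
#include <unordered_set>

// Element kinds (kept in sync with the R side)
enum ElKind { EL_STEP = 0, EL_CROSSOVER = 1, EL_SSDNA = 2, EL_STACKING = 3 };

struct DnaSys {
  int N;
  arma::vec mass6;     // 6N diagonal mass matrix (m,m,m,I1,I2,I3 per node)
  arma::vec radius;    // hydrodynamic radii, nm
  arma::vec charge;    // effective charge per node, units of e
  arma::ivec el_kind;
  arma::imat el_nodes;     // m x 2, 0-based
  arma::mat  el_intrinsic; // m x 6, nm / radians
  arma::cube el_stiff;     // 6 x 6 x m, pN/nm and pN*nm/rad^2
  arma::mat  el_morse;     // m x 3 (eps, a, r0)
  arma::uvec el_flip;      // flip node-b frame by pi about its x axis
  std::unordered_set<long long> excl; // electrostatic exclusions, key i*N+j (i<j)
  double lB;               // Bjerrum length, nm
};

inline DnaSys parse_sys(const Rcpp::List &s) {
  DnaSys sys;
  sys.mass6 = Rcpp::as<arma::vec>(s["mass6"]);
  sys.N = (int)(sys.mass6.n_elem/6);
  sys.radius = Rcpp::as<arma::vec>(s["radius"]);
  sys.charge = Rcpp::as<arma::vec>(s["charge"]);
  sys.el_kind = Rcpp::as<arma::ivec>(s["el_kind"]);
  sys.el_nodes = Rcpp::as<arma::imat>(s["el_nodes"]);
  sys.el_intrinsic = Rcpp::as<arma::mat>(s["el_intrinsic"]);
  sys.el_stiff = Rcpp::as<arma::cube>(s["el_stiff"]);
  sys.el_morse = Rcpp::as<arma::mat>(s["el_morse"]);
  sys.el_flip = Rcpp::as<arma::uvec>(s["el_flip"]);
  sys.lB = Rcpp::as<double>(s["lB"]);
  arma::imat ex = Rcpp::as<arma::imat>(s["exclusions"]);
  for (arma::uword r = 0; r < ex.n_rows; ++r) {
    int i = ex(r,0), j = ex(r,1);
    if (i > j) std::swap(i, j);
    sys.excl.insert((long long)i*sys.N + j);
  }
  return sys;
}

// Evaluate internal generalized forces (3 force + 3 torque per node, node-major
// 6-blocks) and the energy decomposition. kappa <= 0 disables electrostatics.
// When nbr is non-null it supplies a precomputed electrostatic pair list
// (exclusions already removed, built with a skin).
inline void eval_forces(const DnaSys &sys, const arma::mat &pos, const arma::mat &quat,
                        double kappa, bool use_elec, bool use_stack, double kBT,
                        arma::vec &f, double E[3], arma::vec &stack_d,
                        const std::vector<std::pair<int,int>> *nbr = nullptr) {
  const int N = sys.N;
  f.zeros(6*N);
  E[0] = E[1] = E[2] = 0.0;
  const arma::uword m = sys.el_kind.n_elem;
  static const arma::mat33 FLIP = arma::diagmat(arma::vec3{1.0, -1.0, -1.0});

  // node triads, computed once
  std::vector<arma::mat33> Tn(N);
  for (int i = 0; i < N; ++i) Tn[i] = quat_to_mat(quat.row(i).t());

  int istack = 0;
  for (arma::uword e = 0; e < m; ++e) {
    const int a = sys.el_nodes(e,0), b = sys.el_nodes(e,1);
    const arma::vec3 ra = pos.row(a).t(), rb = pos.row(b).t();
    const int kind = sys.el_kind(e);
    if (kind == EL_STEP || kind == EL_CROSSOVER) {
      const arma::mat33 &Ta = Tn[a];
      arma::mat33 Tb = Tn[b];
      if (sys.el_flip(e)) Tb = Tb*FLIP;
      bool ok = true;
      arma::mat33 Tm;
      arma::vec::fixed<6> p = step_params_tm(Ta, ra, Tb, rb, ok, &Tm);
      if (!ok)
        Rcpp::stop("element %d: step decomposition degenerate (anti-parallel frames)", (int)e + 1);
      arma::vec::fixed<6> dq;
      for (int i = 0; i < 6; ++i) {
        double d = p(i) - sys.el_intrinsic(e,i);
        if (i >= 3) d = wrap_pi(d);
        dq(i) = d;
      }
      const arma::vec::fixed<6> Kdq = sys.el_stiff.slice(e)*dq;
      E[0] += 0.5*arma::dot(dq, Kdq);
      const arma::mat::fixed<6,12> J = step_jacobian_fast(Ta, ra, Tb, rb, Tm, ok);
      if (!ok)
        Rcpp::stop("element %d: step decomposition degenerate (anti-parallel frames)", (int)e + 1);
      const arma::vec::fixed<12> g = J.t()*Kdq; // gradient wrt (dra, dtheta_a, drb, dtheta_b)
      for (int i = 0; i < 6; ++i) {
        f(6*a + i) -= g(i);
        f(6*b + i) -= g(6 + i);
      }
    } else if (kind == EL_SSDNA) {
      const arma::vec3 d = rb - ra;
      const double s = arma::norm(d);
      const double k = sys.el_stiff(0,0,e), L0 = sys.el_intrinsic(e,2);
      E[0] += 0.5*k*(s - L0)*(s - L0);
      if (s > 1e-12) {
        const arma::vec3 fa = k*(s - L0)*(d/s);
        for (int i = 0; i < 3; ++i) { f(6*a + i) += fa(i); f(6*b + i) -= fa(i); }
      }
    } else { // stacking
      const arma::vec3 d = rb - ra;
      const double s = arma::norm(d);
      stack_d(istack++) = s;
      if (use_stack) {
        const double eps = sys.el_morse(e,0), aa = sys.el_morse(e,1), r0 = sys.el_morse(e,2);
        const double ex = std::exp(-aa*(s - r0));
        E[2] += eps*(1.0 - ex)*(1.0 - ex) - eps;
        const double dPi = 2.0*eps*aa*ex*(1.0 - ex); // dPi/dr
        if (s > 1e-12) {
          const arma::vec3 fa = dPi*(d/s); // force on a toward b when attractive
          for (int i = 0; i < 3; ++i) { f(6*a + i) += fa(i); f(6*b + i) -= fa(i); }
        }
      }
    }
  }

  if (use_elec && kappa > 0.0) {
    const double rc = 3.0/kappa, rc2 = rc*rc;
    auto pair_term = [&](int i, int j) {
      arma::vec3 d = pos.row(j).t() - pos.row(i).t();
      const double s2 = arma::dot(d, d);
      if (s2 > rc2) return;
      const double s = std::sqrt(s2);
      if (s < 0.1)
        Rcpp::stop("electrostatics: nodes %d and %d overlap (r = %.3g nm)", i + 1, j + 1, s);
      const double pref = sys.charge(i)*sys.charge(j)*sys.lB*kBT;
      const double ee = pref*std::exp(-kappa*s)/s;
      E[1] += ee;
      const double fmag = ee*(kappa + 1.0/s); // repulsive magnitude
      const arma::vec3 fj = fmag*(d/s);       // pushes j away from i
      for (int k2 = 0; k2 < 3; ++k2) { f(6*j + k2) += fj(k2); f(6*i + k2) -= fj(k2); }
    };
    if (nbr) {
      for (const auto &pr : *nbr) pair_term(pr.first, pr.second);
    } else {
      for (int i = 0; i < N; ++i)
        for (int j = i + 1; j < N; ++j) {
          if (sys.excl.count((long long)i*N + j)) continue;
          pair_term(i, j);
        }
    }
  }
}

// Verlet-style electrostatic pair list: all non-excluded pairs within
// cutoff + skin of the reference configuration.
inline void build_pair_list(const DnaSys &sys, const arma::mat &pos,
                            double cutoff, double skin,
                            std::vector<std::pair<int,int>> &out) {
  out.clear();
  const int N = sys.N;
  const double rl2 = (cutoff + skin)*(cutoff + skin);
  for (int i = 0; i < N; ++i) {
    const arma::vec3 ri = pos.row(i).t();
    for (int j = i + 1; j < N; ++j) {
      arma::vec3 d = pos.row(j).t() - ri;
      if (arma::dot(d, d) > rl2) continue;
      if (sys.excl.count((long long)i*N + j)) continue;
      out.emplace_back(i, j);
    }
  }
}

// Generalized Rotne-Prager-Yamakawa mobility with translation-rotation
// coupling (lab frame), regularized for overlapping spheres; equal radii.
inline arma::mat rpy_pair_blocks(const arma::vec3 &rv, double a, double eta) {
  // returns 9x9-free layout: [tt (3x3); rr (3x3); W (3x3)] stacked 9x3? use mat(9,3)
  arma::mat out(9, 3);
  const double r = arma::norm(rv);
  const arma::vec3 rh = rv/r;
  const arma::mat33 P = rh*rh.t();
  const arma::mat33 I = arma::eye(3,3);
  arma::mat33 tt, rr, W;
  const double pe = M_PI*eta;
  if (r >= 2.0*a) {
    tt = (1.0/(8.0*pe*r))*((1.0 + 2.0*a*a/(3.0*r*r))*I + (1.0 - 2.0*a*a/(r*r))*P);
    rr = (1.0/(16.0*pe*r*r*r))*(3.0*P - I);
  } else {
    tt = (1.0/(6.0*pe*a))*((1.0 - 9.0*r/(32.0*a))*I + (3.0*r/(32.0*a))*P);
    const double x = r/a;
    rr = (1.0/(8.0*pe*a*a*a))*((1.0 - 27.0*x/32.0 + 5.0*x*x*x/64.0)*I
                               + (9.0*x/32.0 - 3.0*x*x*x/64.0)*P);
  }
  // rotation-translation coupling: omega_i = W * F_j with rh pointing i -> j
  double g;
  if (r >= 2.0*a) g = 1.0/(8.0*pe*r*r);
  else            g = (1.0/(16.0*pe*a*a))*(r/a)*(1.0 - 3.0*r/(8.0*a));
  arma::mat33 epsr = { {0.0, rh(2), -rh(1)}, {-rh(2), 0.0, rh(0)}, {rh(1), -rh(0), 0.0} };
  W = -g*epsr; // W*F = g * (rh x F)
  out.rows(0,2) = tt; out.rows(3,5) = rr; out.rows(6,8) = W;
  return out;
}

inline arma::mat rpy_mobility(const arma::mat &pos, double a, double eta) {
  const int N = pos.n_rows;
  arma::mat Xi(6*N, 6*N, arma::fill::zeros);
  const double pe = M_PI*eta;
  const double mt = 1.0/(6.0*pe*a), mr = 1.0/(8.0*pe*a*a*a);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 3; ++k) {
      Xi(6*i + k, 6*i + k) = mt;
      Xi(6*i + 3 + k, 6*i + 3 + k) = mr;
    }
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const arma::vec3 rv = pos.row(j).t() - pos.row(i).t();
      if (arma::norm(rv) < 1e-12)
        Rcpp::stop("mobility: nodes %d and %d coincide", i + 1, j + 1);
      const arma::mat B = rpy_pair_blocks(rv, a, eta);
      const arma::mat33 tt = B.rows(0,2), rr = B.rows(3,5), W = B.rows(6,8);
      Xi.submat(6*i, 6*j, 6*i + 2, 6*j + 2) = tt;
      Xi.submat(6*j, 6*i, 6*j + 2, 6*i + 2) = tt.t();
      Xi.submat(6*i + 3, 6*j + 3, 6*i + 5, 6*j + 5) = rr;
      Xi.submat(6*j + 3, 6*i + 3, 6*j + 5, 6*i + 5) = rr.t();
      // omega_i from F_j and, by symmetry, U_j from T_i
      Xi.submat(6*i + 3, 6*j, 6*i + 5, 6*j + 2) = W;
      Xi.submat(6*j, 6*i + 3, 6*j + 2, 6*i + 5) = W.t();
      // omega_j from F_i: flip rh -> -rh gives -W
      Xi.submat(6*j + 3, 6*i, 6*j + 5, 6*i + 2) = -W;
      Xi.submat(6*i, 6*j + 3, 6*i + 2, 6*j + 5) = -W.t();
    }
  }
  return Xi;
}

#endif
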