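#ifndef DNADYN_GEOMETRY_H
#define DNADYN_GEOMETRY_H

#include <RcppArmadillo.h>

// Quaternion convention: (w, x, y, z), unit norm, acting as v' = R(q) v.
inline arma::mat33 quat_to_mat(const arma::vec &q) {
  const double w = q(0), x = q(1), y = q(2), z = q(3);
  arma::mat33 R;
  R(0,0) = 1 - 2*(y*y + z*z); R(0,1) = 2*(x*y - w*z);     R(0,2) = 2*(x*z + w*y);
  R(1,0) = 2*(x*y + w*z);     R(1,1) = 1 - 2*(x*x + z*z); R(1,2) = 2*(y*z - w*x);
  R(2,0) = 2*(x*z - w*y);     R(2,1) = 2*(y*z + w*x);     R(2,2) = 1 - 2*(x*x + y*y);
  return R;
}

inline arma::vec4 quat_mul(const arma::vec &a, const arma::vec &b) {
  arma::vec4 q;
  q(0) = a(0)*b(0) - a(1)*b(1) - a(2)*b(2) - a(3)*b(3);
  q(1) = a(0)*b(1) + a(1)*b(0) + a(2)*b(3) - a(3)*b(2);
  q(2) = a(0)*b(2) - a(1)*b(3) + a(2)*b(0) + a(3)*b(1);
  q(3) = a(0)*b(3) + a(1)*b(2) - a(2)*b(1) + a(3)*b(0);
  return q;
}

inline arma::vec4 quat_from_rotvec(const arma::vec3 &v) {
  const double th = arma::norm(v);
  arma::vec4 q;
  if (th < 1e-14) {
    q(0) = 1.0; q(1) = 0.5*v(0); q(2) = 0.5*v(1); q(3) = 0.5*v(2);
  } else {
    const double s = std::sin(0.5*th)/th;
    q(0) = std::cos(0.5*th); q(1) = s*v(0); q(2) = s*v(1); q(3) = s*v(2);
  }
  return q / arma::norm(q);
}

// Rodrigues rotation with precomputed cosine/sine.
inline arma::vec3 rotate_cs(const arma::vec3 &v, const arma::vec3 &u,
                            double c, double s) {
  return v*c + arma::cross(u, v)*s + u*(arma::dot(u, v)*(1.0 - c));
}

inline arma::vec3 rotate_about(const arma::vec3 &v, const arma::vec3 &u, double th) {
  return rotate_cs(v, u, std::cos(th), std::sin(th));
}

inline double wrap_pi(double a) {
  // wrap to (-pi, pi]
  const double twopi = 2.0*M_PI;
  a -= twopi*std::floor((a + M_PI)/twopi);
  if (a <= -M_PI) a += twopi;
  if (a > M_PI) a -= twopi;
  return a;
}

// Scalar 3-vector helpers for the hot kernel (plain doubles, no temporaries).
namespace sk {
inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1]*b[2] - a[2]*b[1];
  o[1] = a[2]*b[0] - a[0]*b[2];
  o[2] = a[0]*b[1] - a[1]*b[0];
}
inline double dot3(const double *a, const double *b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
// Rodrigues rotation with precomputed cosine/sine: o = c v + s (u x v) + (1-c)(u.v) u
inline void rot_cs3(const double *v, const double *u, double c, double s, double *o) {
  double cx[3];
  cross3(u, v, cx);
  const double k = (1.0 - c)*dot3(u, v);
  o[0] = c*v[0] + s*cx[0] + k*u[0];
  o[1] = c*v[1] + s*cx[1] + k*u[1];
  o[2] = c*v[2] + s*cx[2] + k*u[2];
}
// Core CEHS decomposition on scalar arrays. Columns of the 3x3 triads are
// the frame axes; matrices are column-major 9-arrays (arma layout).
// Returns false for anti-parallel z axes. Tm (column-major) optional.
inline bool step_params_raw(const double *Ta, const double *ra,
                            const double *Tb, const double *rb,
                            double *p, double *Tm) {
  const double *xa0 = Ta, *za0 = Ta + 6;
  const double *xb0 = Tb, *zb0 = Tb + 6;
  double c = dot3(za0, zb0);
  if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
  double hinge[3];
  cross3(za0, zb0, hinge);
  const double hn = std::sqrt(dot3(hinge, hinge));
  const bool bent = hn >= 1e-12;
  double xa[3], xb[3], zm[3];
  double gamma = 0.0;
  if (!bent) {
    if (c < 0.0) return false;
    for (int i = 0; i < 3; ++i) { xa[i] = xa0[i]; xb[i] = xb0[i]; zm[i] = za0[i]; }
  } else {
    gamma = std::acos(c);
    const double inv = 1.0/hn;
    hinge[0] *= inv; hinge[1] *= inv; hinge[2] *= inv;
    const double ch = std::sqrt(0.5*(1.0 + c));   // cos(gamma/2)
    const double sh = std::sqrt(0.5*(1.0 - c));   // sin(gamma/2)
    rot_cs3(xa0, hinge, ch, sh, xa);
    rot_cs3(xb0, hinge, ch, -sh, xb);
    rot_cs3(za0, hinge, ch, sh, zm);
  }
  double cx[3];
  cross3(xa, xb, cx);
  const double ctw = dot3(xa, xb);
  const double stw = dot3(cx, zm);
  const double twist = std::atan2(stw, ctw);
  const double chw = std::sqrt(std::max(0.0, 0.5*(1.0 + ctw)));
  const double shw = (stw >= 0.0 ? 1.0 : -1.0)
    *std::sqrt(std::max(0.0, 0.5*(1.0 - ctw)));
  double xm[3];
  rot_cs3(xa, zm, chw, shw, xm);
  const double pz = dot3(zm, xm);
  xm[0] -= pz*zm[0]; xm[1] -= pz*zm[1]; xm[2] -= pz*zm[2];
  const double nx = 1.0/std::sqrt(dot3(xm, xm));
  xm[0] *= nx; xm[1] *= nx; xm[2] *= nx;
  double ym[3];
  cross3(zm, xm, ym);
  double tilt = 0.0, roll = 0.0;
  if (bent) {
    double hy[3];
    cross3(hinge, ym, hy);
    roll = gamma*dot3(hinge, ym);
    tilt = gamma*dot3(hy, zm);
  }
  const double d[3] = { rb[0] - ra[0], rb[1] - ra[1], rb[2] - ra[2] };
  p[0] = dot3(d, xm); p[1] = dot3(d, ym); p[2] = dot3(d, zm);
  p[3] = tilt; p[4] = roll; p[5] = twist;
  if (Tm) {
    Tm[0] = xm[0]; Tm[1] = xm[1]; Tm[2] = xm[2];
    Tm[3] = ym[0]; Tm[4] = ym[1]; Tm[5] = ym[2];
    Tm[6] = zm[0]; Tm[7] = zm[1]; Tm[8] = zm[2];
  }
  return true;
}
// o (3x3 col-major) = R * T with R a small rotation given col-major.
inline void matmul33(const double *R, const double *T, double *o) {
  for (int c2 = 0; c2 < 3; ++c2)
    for (int r = 0; r < 3; ++r)
      o[3*c2 + r] = R[r]*T[3*c2] + R[3 + r]*T[3*c2 + 1] + R[6 + r]*T[3*c2 + 2];
}
} // namespace sk

inline arma::vec::fixed<6> step_params_tm(const arma::mat33 &Ta, const arma::vec3 &ra,
                                          const arma::mat33 &Tb, const arma::vec3 &rb,
                                          bool &ok, arma::mat33 *Tm_out = nullptr) {
  arma::vec::fixed<6> p;
  double Tm[9];
  ok = sk::step_params_raw(Ta.memptr(), ra.memptr(), Tb.memptr(), rb.memptr(),
                           p.memptr(), Tm_out ? Tm : nullptr);
  if (!ok) { p.zeros(); return p; }
  if (Tm_out) std::copy(Tm, Tm + 9, Tm_out->memptr());
  return p;
}

inline arma::vec::fixed<6> step_params_core(const arma::mat33 &Ta, const arma::vec3 &ra,
                                            const arma::mat33 &Tb, const arma::vec3 &rb,
                                            bool &ok) {
  return step_params_tm(Ta, ra, Tb, rb, ok, nullptr);
}

// Jacobian of the six step parameters with respect to the 12 nodal DOFs
// (translation a, lab-frame rotation increment a, translation b, rotation
// increment b). Translational columns are analytic (displacement rows are the
// mid triad, angle rows vanish); rotational columns use central differences
// with angle rows wrapped across +-pi.
inline arma::mat::fixed<6,12> step_jacobian_fast(const arma::mat33 &Ta, const arma::vec3 &ra,
                                                 const arma::mat33 &Tb, const arma::vec3 &rb,
                                                 const arma::mat33 &Tm, bool &ok) {
  static const double h = 1e-6;
  // small rotations about +x,+y,+z by +-h (column-major), built once
  struct Perts {
    double Rp[3][9], Rm[3][9];
    Perts() {
      const double c = std::cos(h), s = std::sin(h);
      for (int ax = 0; ax < 3; ++ax) {
        arma::mat33 R(arma::fill::eye);
        const int i1 = (ax + 1) % 3, i2 = (ax + 2) % 3;
        R(i1,i1) = c; R(i2,i2) = c; R(i2,i1) = s; R(i1,i2) = -s;
        std::copy(R.memptr(), R.memptr() + 9, Rp[ax]);
        arma::mat33 Rt = R.t();
        std::copy(Rt.memptr(), Rt.memptr() + 9, Rm[ax]);
      }
    }
  };
  static const Perts P;
  arma::mat::fixed<6,12> J;
  J.zeros();
  for (int r = 0; r < 3; ++r)
    for (int cidx = 0; cidx < 3; ++cidx) {
      J(r, cidx) = -Tm(cidx, r);     // d t / d ra = -Tm^T
      J(r, 6 + cidx) = Tm(cidx, r);  // d t / d rb = +Tm^T
    }
  const double *pta = Ta.memptr(), *ptb = Tb.memptr();
  const double *pra = ra.memptr(), *prb = rb.memptr();
  double Tp[9], pp[6], pm[6];
  for (int blk = 0; blk < 2; ++blk) {        // rotations of node a, then b
    for (int ax = 0; ax < 3; ++ax) {
      bool ok1, ok2;
      if (blk == 0) {
        sk::matmul33(P.Rp[ax], pta, Tp);
        ok1 = sk::step_params_raw(Tp, pra, ptb, prb, pp, nullptr);
        sk::matmul33(P.Rm[ax], pta, Tp);
        ok2 = sk::step_params_raw(Tp, pra, ptb, prb, pm, nullptr);
      } else {
        sk::matmul33(P.Rp[ax], ptb, Tp);
        ok1 = sk::step_params_raw(pta, pra, Tp, prb, pp, nullptr);
        sk::matmul33(P.Rm[ax], ptb, Tp);
        ok2 = sk::step_params_raw(pta, pra, Tp, prb, pm, nullptr);
      }
      if (!ok1 || !ok2) { ok = false; return J; }
      const int col = (blk == 0) ? 3 + ax : 9 + ax;
      for (int i = 0; i < 6; ++i) {
        double d = pp[i] - pm[i];
        if (i >= 3) d = wrap_pi(d);
        J(i, col) = d/(2.0*h);
      }
    }
  }
  ok = true;
  return J;
}

// Full finite-difference Jacobian over all 12 DOFs (reference version, used
// by the exported single-pair helper).
inline arma::mat step_jacobian_core(const arma::mat33 &Ta, const arma::vec3 &ra,
                                    const arma::mat33 &Tb, const arma::vec3 &rb,
                                    bool &ok) {
  const double h = 1e-6;
  arma::mat J(6, 12);
  for (int k = 0; k < 12; ++k) {
    arma::mat33 Tap = Ta, Tam = Ta, Tbp = Tb, Tbm = Tb;
    arma::vec3 rap = ra, ram = ra, rbp = rb, rbm = rb;
    arma::vec3 e(arma::fill::zeros);
    e(k % 3) = h;
    if (k < 3)        { rap += e; ram -= e; }
    else if (k < 6)   { Tap = quat_to_mat(quat_from_rotvec(e))*Ta;
                        Tam = quat_to_mat(quat_from_rotvec(-e))*Ta; }
    else if (k < 9)   { rbp += e; rbm -= e; }
    else              { Tbp = quat_to_mat(quat_from_rotvec(e))*Tb;
                        Tbm = quat_to_mat(quat_from_rotvec(-e))*Tb; }
    bool ok1 = true, ok2 = true;
    arma::vec::fixed<6> pp = step_params_core(Tap, rap, Tbp, rbp, ok1);
    arma::vec::fixed<6> pm = step_params_core(Tam, ram, Tbm, rbm, ok2);
    if (!ok1 || !ok2) { ok = false; return J; }
    for (int i = 0; i < 6; ++i) {
      double d = pp(i) - pm(i);
      if (i >= 3) d = wrap_pi(d);
      J(i, k) = d/(2.0*h);
    }
  }
  ok = true;
  return J;
}

#endif
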