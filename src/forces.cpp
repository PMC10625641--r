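// [[Rcpp::depends(RcppArmadillo)]]
#include "system.h"
using namespace Rcpp;

// Internal force vector and energy decomposition at a configuration.
// [[Rcpp::export(name = ".cpp_eval_forces")]]
List cpp_eval_forces(const List &sys_r, const arma::mat &pos, const arma::mat &quat,
                     double kappa, bool use_elec, bool use_stack, double kBT) {
  DnaSys sys = parse_sys(sys_r);
  const int nstack = (int)arma::sum(sys.el_kind == EL_STACKING);
  arma::vec f;
  arma::vec stack_d(std::max(nstack, 1), arma::fill::zeros);
  double E[3];
  eval_forces(sys, pos, quat, kappa, use_elec, use_stack, kBT, f, E, stack_d);
  return List::create(_["force"] = f,
                      _["elastic"] = E[0],
                      _["electrostatic"] = E[1],
                      _["stacking"] = E[2],
                      _["stack_dist"] = (nstack > 0) ? stack_d : arma::vec());
}

// [[Rcpp::export(name = ".cpp_assemble_mobility")]]
arma::mat cpp_assemble_mobility(const arma::mat &pos, double radius, double eta) {
  return rpy_mobility(pos, radius, eta);
}

// Single RPY pair coupling: returns the 6x6 block coupling node i's motion to
// forces/torques on node j, rh pointing i -> j.
// [[Rcpp::export(name = ".cpp_pair_mobility")]]
arma::mat cpp_pair_mobility(const arma::vec &r_vec, double radius, double eta) {
  arma::vec3 rv = r_vec;
  const arma::mat B = rpy_pair_blocks(rv, radius, eta);
  arma::mat out(6, 6, arma::fill::zeros);
  out.submat(0, 0, 2, 2) = B.rows(0, 2);          // tt
  out.submat(3, 3, 5, 5) = B.rows(3, 5);          // rr
  out.submat(3, 0, 5, 2) = B.rows(6, 8);          // omega_i from F_j
  out.submat(0, 3, 2, 5) = -B.rows(6, 8).t();     // U_i from T_j
  return out;
}
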