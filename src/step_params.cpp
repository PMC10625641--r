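// [[Rcpp::depends(RcppArmadillo)]]
#include "geometry.h"
using namespace Rcpp;

// Base-pair step parameters for a single pair of frames.
// Returns radians; the R wrapper converts to the 3DNA degree convention.
// [[Rcpp::export(name = ".cpp_step_parameters")]]
arma::vec cpp_step_parameters(const arma::mat &Ta, const arma::vec &ra,
                              const arma::mat &Tb, const arma::vec &rb) {
  bool ok = true;
  arma::vec::fixed<6> p = step_params_core(Ta, ra, Tb, rb, ok);
  if (!ok) stop("step decomposition is degenerate: frames are anti-parallel");
  return arma::vec(p);
}

// [[Rcpp::export(name = ".cpp_step_jacobian")]]
arma::mat cpp_step_jacobian(const arma::mat &Ta, const arma::vec &ra,
                            const arma::mat &Tb, const arma::vec &rb) {
  bool ok = true;
  arma::mat J = step_jacobian_core(Ta, ra, Tb, rb, ok);
  if (!ok) stop("step decomposition is degenerate: frames are anti-parallel");
  return J;
}
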