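// Matrix-exponential propagation of continuous-time Markov occupancy.
//
// The generator can be very stiff (calcium binding rates of order 1e6-1e7
// s^-1 next to desensitization rates below 1 s^-1), so explicit ODE stepping
// at the working grid would be unstable.  For a piecewise-constant ligand
// time course the generator is constant within each segment and the exact
// propagator over one grid step is expm(Q * dt); stepping with it is
// unconditionally stable and exact at the grid points.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Row-vector convention: occupancy evolves as p(t + dt) = p(t) %*% expm(Q dt).

// [[Rcpp::export]]
arma::mat cpp_propagate(const arma::mat& Q, const arma::rowvec& occ0,
                        const int nsteps, const double dt) {
  if (!Q.is_finite()) stop("non-finite entries in generator matrix");
  arma::mat P = arma::expmat(Q * dt);
  arma::mat out(nsteps + 1, Q.n_rows);
  arma::rowvec p = occ0;
  out.row(0) = p;
  for (int i = 1; i <= nsteps; ++i) {
    p = p * P;
    p /= arma::accu(p);   // re-project onto the simplex (exact flow conserves mass)
    out.row(i) = p;
  }
  return out;
}

// Piecewise-constant protocol: one generator per segment, shared grid step.
// Returns the open probability (sum of occupancies over `conducting`,
// 1-based indices) on the full concatenated grid, plus the final occupancy
// and, optionally, the full occupancy matrix.

// [[Rcpp::export]]
List cpp_simulate_segments(const List& Qs, const IntegerVector& nsteps,
                           const double dt, const arma::rowvec& occ0,
                           const IntegerVector& conducting,
                           const bool keep_occupancy) {
  const int nseg = Qs.size();
  int ntot = 1;
  for (int s = 0; s < nseg; ++s) ntot += nsteps[s];

  arma::uvec cond(conducting.size());
  for (int i = 0; i < conducting.size(); ++i) cond[i] = conducting[i] - 1;

  arma::vec po(ntot);
  arma::mat occ;
  if (keep_occupancy) occ.set_size(ntot, occ0.n_elem);

  arma::rowvec p = occ0;
  po[0] = arma::accu(p.cols(cond));
  if (keep_occupancy) occ.row(0) = p;

  int at = 1;
  for (int s = 0; s < nseg; ++s) {
    arma::mat Q = as<arma::mat>(Qs[s]);
    if (!Q.is_finite()) stop("non-finite entries in generator matrix");
    arma::mat P = arma::expmat(Q * dt);
    for (int i = 0; i < nsteps[s]; ++i) {
      p = p * P;
      p /= arma::accu(p);
      po[at] = arma::accu(p.cols(cond));
      if (keep_occupancy) occ.row(at) = p;
      ++at;
    }
  }

  List out = List::create(_["po"] = po, _["final"] = p);
  if (keep_occupancy) out["occupancy"] = occ;
  return out;
}
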