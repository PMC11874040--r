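// Per-spatial-frequency Tikhonov-regularized least-squares solves for the
// spatio-angular reconstruction: for each frequency, estimate the 15
// spherical-harmonic coefficients from the n_meas measured Fourier
// coefficients via W = (H^H H + eta I)^{-1} H^H.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Factored transfer function: row p of H(nu) is b_{view(p)}(nu) * a_p,
// so H^H H = bA^2 G_A + bB^2 G_B with G_v = A_v^T A_v fixed across
// frequencies.  G: nfreq x nmeas complex data spectra; returns nfreq x 15.
// [[Rcpp::export]]
Rcpp::List cpp_solve_factored(const arma::cx_mat& G,
                              const arma::mat& A,
                              const arma::uvec& isViewA,
                              const arma::vec& bA,
                              const arma::vec& bB,
                              double eta,
                              double pinvTol) {
  const uword nfreq = G.n_rows;
  const uword nmeas = A.n_rows;
  const uword nc = A.n_cols;

  mat GA(nc, nc, fill::zeros), GB(nc, nc, fill::zeros);
  for (uword p = 0; p < nmeas; ++p) {
    const rowvec ap = A.row(p);
    if (isViewA[p]) GA += ap.t() * ap; else GB += ap.t() * ap;
  }

  cx_mat out(nfreq, nc, fill::zeros);
  mat M(nc, nc);
  cx_vec rhs(nc);
  bool warned = false;

  for (uword f = 0; f < nfreq; ++f) {
    const double ba = bA[f], bb = bB[f];
    if (ba == 0.0 && bb == 0.0) continue;   // outside all views' supports
    M = ba * ba * GA + bb * bb * GB;
    M.diag() += eta;
    rhs.zeros();
    for (uword p = 0; p < nmeas; ++p) {
      const double b = isViewA[p] ? ba : bb;
      if (b == 0.0) continue;               // row invalid outside support
      rhs += (b * G(f, p)) * conv_to<cx_vec>::from(A.row(p).t());
    }
    cx_vec x;
    if (eta > 0.0) {
      // M is real sympd: solve once against [Re(rhs), Im(rhs)]
      mat X = solve(M, join_rows(real(rhs), imag(rhs)),
                    solve_opts::likely_sympd);
      x = cx_vec(X.col(0), X.col(1));
    } else {
      mat Mp = pinv(M, pinvTol);
      vec xr = Mp * real(rhs), xi = Mp * imag(rhs);
      x = cx_vec(xr, xi);
      warned = true;
    }
    out.row(f) = x.st();
  }
  return Rcpp::List::create(Rcpp::Named("coef") = out,
                            Rcpp::Named("pinvUsed") = warned);
}

// Generic (coupled-mode) solver: H is an nmeas x 15 x nfreq complex cube.
// [[Rcpp::export]]
arma::cx_mat cpp_solve_generic(const arma::cx_mat& G,
                               const arma::cx_cube& H,
                               double eta,
                               double pinvTol) {
  const uword nfreq = G.n_rows;
  const uword nc = H.n_cols;
  cx_mat out(nfreq, nc, fill::zeros);
  for (uword f = 0; f < nfreq; ++f) {
    const cx_mat Hf = H.slice(f);
    if (norm(Hf, "fro") == 0.0) continue;
    cx_mat M = Hf.t() * Hf;     // .t() is conjugate transpose for cx_mat
    M.diag() += eta;
    cx_vec rhs = Hf.t() * G.row(f).st();
    cx_vec x;
    if (eta > 0.0) {
      x = solve(M, rhs, solve_opts::likely_sympd);
    } else {
      x = pinv(M, pinvTol) * rhs;
    }
    out.row(f) = x.st();
  }
  return out;
}
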