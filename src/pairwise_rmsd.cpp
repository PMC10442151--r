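#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Minimized (proper-rotation Kabsch) RMSD between every pair of frames.
// coords: n_atoms x 3 x n_frames cube, one slice per frame.
// Uses per-pair 3x3 SVD; the reflection case is handled by flipping the
// sign of the smallest singular value when det(H) < 0.
// [[Rcpp::export]]
arma::mat cpp_pairwise_rmsd(const arma::cube& coords) {
  const arma::uword m  = coords.n_rows;
  const arma::uword nf = coords.n_slices;
  std::vector<arma::mat> centered(nf);
  arma::vec G(nf);
  for (arma::uword f = 0; f < nf; ++f) {
    arma::mat A = coords.slice(f);
    arma::rowvec c = arma::mean(A, 0);
    A.each_row() -= c;
    centered[f] = A;
    G(f) = arma::accu(A % A);
  }
  arma::mat out(nf, nf, arma::fill::zeros);
  arma::mat U, V;
  arma::vec s;
  for (arma::uword i = 0; i + 1 < nf; ++i) {
    for (arma::uword j = i + 1; j < nf; ++j) {
      arma::mat H = centered[i].t() * centered[j];
      arma::svd(U, s, V, H);
      const double d  = (arma::det(H) < 0.0) ? -1.0 : 1.0;
      const double tr = s(0) + s(1) + d * s(2);
      double msd = (G(i) + G(j) - 2.0 * tr) / static_cast<double>(m);
      if (msd < 0.0) msd = 0.0;
      out(i, j) = out(j, i) = std::sqrt(msd);
    }
  }
  return out;
}

// RMSD of every frame against one reference coordinate set (after optimal
// proper-rotation superposition).  ref: m x 3 matrix.
// [[Rcpp::export]]
arma::vec cpp_rmsd_to_ref(const arma::cube& coords, const arma::mat& ref) {
  const arma::uword m  = coords.n_rows;
  const arma::uword nf = coords.n_slices;
  arma::mat R = ref;
  arma::rowvec cr = arma::mean(R, 0);
  R.each_row() -= cr;
  const double Gr = arma::accu(R % R);
  arma::vec out(nf);
  arma::mat U, V;
  arma::vec s;
  for (arma::uword f = 0; f < nf; ++f) {
    arma::mat A = coords.slice(f);
    arma::rowvec c = arma::mean(A, 0);
    A.each_row() -= c;
    arma::mat H = A.t() * R;
    arma::svd(U, s, V, H);
    const double d  = (arma::det(H) < 0.0) ? -1.0 : 1.0;
    const double tr = s(0) + s(1) + d * s(2);
    double msd = (arma::accu(A % A) + Gr - 2.0 * tr) / static_cast<double>(m);
    if (msd < 0.0) msd = 0.0;
    out(f) = std::sqrt(msd);
  }
  return out;
}
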