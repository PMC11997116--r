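// Block-diagonal batched matrix products for multi-head attention.
// Activations are stored sample-major: row (b-1)*L + l holds position l of
// sample b. Each sample contributes one L-row block; the three modes cover
// the products needed by scaled dot-product attention and its gradients:
//   nt: C_b = A_b * B_b'   (A, B: L x p blocks  -> C: L x L blocks)
//   nn: C_b = A_b * B_b    (A: L x L, B: L x p  -> C: L x p blocks)
//   tn: C_b = A_b' * B_b   (A: L x L, B: L x p  -> C: L x p blocks)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
arma::mat blockmm(const arma::mat& A, const arma::mat& B, int L,
                  std::string mode) {
  const int N = A.n_rows;
  if (N % L != 0) Rcpp::stop("blockmm: nrow(A) not a multiple of L");
  const int nb = N / L;
  arma::mat C;
  if (mode == "nt") {
    if ((int)B.n_rows != N || B.n_cols != A.n_cols)
      Rcpp::stop("blockmm nt: shape mismatch");
    C.set_size(N, L);
    for (int b = 0; b < nb; ++b) {
      const arma::span r(b * L, (b + 1) * L - 1);
      C(r, arma::span::all) = A(r, arma::span::all) * B(r, arma::span::all).t();
    }
  } else if (mode == "nn" || mode == "tn") {
    if ((int)A.n_cols != L || (int)B.n_rows != N)
      Rcpp::stop("blockmm nn/tn: shape mismatch");
    C.set_size(N, B.n_cols);
    for (int b = 0; b < nb; ++b) {
      const arma::span r(b * L, (b + 1) * L - 1);
      if (mode == "nn")
        C(r, arma::span::all) = A(r, arma::span::all) * B(r, arma::span::all);
      else
        C(r, arma::span::all) = A(r, arma::span::all).t() * B(r, arma::span::all);
    }
  } else {
    Rcpp::stop("blockmm: unknown mode");
  }
  return C;
}
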