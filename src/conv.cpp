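// 3x3 same-size convolution with zero padding and tanh non-linearity,
// forward and backward. Filters arrive as an R array of dim (3, 3, kin, kout)
// flattened column-major; images as (h, w, k) cubes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::cube conv3x3_forward_cpp(const arma::cube& X,      // h x w x kin
                               const arma::vec& Wf,      // 3*3*kin*kout
                               const arma::vec& bias) {  // kout
  const int h = X.n_rows, w = X.n_cols, kin = X.n_slices;
  const int kout = (int)bias.n_elem;
  if ((int)Wf.n_elem != 9 * kin * kout) Rcpp::stop("filter size mismatch");
  cube Y(h, w, kout);
  for (int co = 0; co < kout; ++co) {
    mat acc(h, w); acc.fill(bias(co));
    for (int ci = 0; ci < kin; ++ci) {
      const mat& x = X.slice(ci);
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const double wgt = Wf(di + 3 * dj + 9 * (ci + kin * co));
          // output (i,j) reads input (i+di-1, j+dj-1); zero outside
          const int ri0 = std::max(0, 1 - di), ri1 = std::min(h - 1, h - di);
          const int rj0 = std::max(0, 1 - dj), rj1 = std::min(w - 1, w - dj);
          if (ri0 > ri1 || rj0 > rj1) continue;
          acc.submat(ri0, rj0, ri1, rj1) +=
              wgt * x.submat(ri0 + di - 1, rj0 + dj - 1,
                             ri1 + di - 1, rj1 + dj - 1);
        }
      }
    }
    Y.slice(co) = tanh(acc);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward_cpp(const arma::cube& dY,  // h x w x kout
                                const arma::cube& Y,   // tanh outputs
                                const arma::cube& X,
                                const arma::vec& Wf) {
  const int h = X.n_rows, w = X.n_cols, kin = X.n_slices;
  const int kout = dY.n_slices;
  cube dA = dY % (1.0 - Y % Y);
  cube dX(h, w, kin, fill::zeros);
  vec dW(9 * kin * kout, fill::zeros), db(kout);
  for (int co = 0; co < kout; ++co) {
    db(co) = accu(dA.slice(co));
    const mat& da = dA.slice(co);
    for (int ci = 0; ci < kin; ++ci) {
      const mat& x = X.slice(ci);
      mat& dx = dX.slice(ci);
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int ri0 = std::max(0, 1 - di), ri1 = std::min(h - 1, h - di);
          const int rj0 = std::max(0, 1 - dj), rj1 = std::min(w - 1, w - dj);
          if (ri0 > ri1 || rj0 > rj1) continue;
          const mat xs = x.submat(ri0 + di - 1, rj0 + dj - 1,
                                  ri1 + di - 1, rj1 + dj - 1);
          const mat das = da.submat(ri0, rj0, ri1, rj1);
          dW(di + 3 * dj + 9 * (ci + kin * co)) += accu(xs % das);
          dx.submat(ri0 + di - 1, rj0 + dj - 1, ri1 + di - 1, rj1 + dj - 1) +=
              Wf(di + 3 * dj + 9 * (ci + kin * co)) * das;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
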