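// Core 2D MDLSTM block scan (canonical direction: top-to-bottom,
// left-to-right) with an anti-diagonal wavefront schedule, plus the matching
// reverse-mode backward pass. Rotation to the other three scan directions is
// handled by the R wrappers; these kernels only ever see the canonical order.
//
// Gate layout within stacked (5u)-row matrices: [i; f1; f2; o; g].
// Cell update (bounded): c = i*g + 0.5*f1*c_up + 0.5*f2*c_left
// Output:                h = o * tanh(c)
// Missing neighbours (first row / first column) contribute zero h and c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Gather image columns lying on anti-diagonal d (i + j == d) of an h x w
// grid. Returns pixel (column) indices p = i + j*h in increasing i.
static uvec diag_pixels(const int h, const int w, const int d) {
  const int i0 = std::max(0, d - (w - 1));
  const int i1 = std::min(h - 1, d);
  uvec idx(i1 - i0 + 1);
  for (int i = i0; i <= i1; ++i) idx(i - i0) = (uword)(i + (d - i) * h);
  return idx;
}

// [[Rcpp::export]]
Rcpp::List mdlstm_forward_cpp(const arma::mat& X,  // k x (h*w), pixel-major
                              const int h, const int w,
                              const arma::mat& Win,    // 5u x k
                              const arma::mat& Rup,    // 5u x u
                              const arma::mat& Rleft,  // 5u x u
                              const arma::vec& bias,   // 5u
                              const bool keep_cache) {
  const int u = (int)Rup.n_cols;
  const int hw = h * w;
  if ((int)X.n_cols != hw)
    Rcpp::stop("input has %d pixels, expected %d", (int)X.n_cols, hw);

  mat A = Win * X;          // input projections for every pixel at once
  A.each_col() += bias;
  mat G(5 * u, hw);         // activated gates
  mat C(u, hw), Tc(u, hw), H(u, hw);

  for (int d = 0; d <= h + w - 2; ++d) {
    const uvec idx = diag_pixels(h, w, d);
    const int m = (int)idx.n_elem;
    mat Hup(u, m, fill::zeros), Hleft(u, m, fill::zeros);
    mat Cup(u, m, fill::zeros), Cleft(u, m, fill::zeros);
    for (int t = 0; t < m; ++t) {
      const int p = (int)idx(t), i = p % h, j = p / h;
      if (i > 0) { Hup.col(t)   = H.col(p - 1); Cup.col(t)   = C.col(p - 1); }
      if (j > 0) { Hleft.col(t) = H.col(p - h); Cleft.col(t) = C.col(p - h); }
    }
    mat Ad = A.cols(idx) + Rup * Hup + Rleft * Hleft;
    mat gi = sigmoid(Ad.rows(0, u - 1));
    mat f1 = sigmoid(Ad.rows(u, 2 * u - 1));
    mat f2 = sigmoid(Ad.rows(2 * u, 3 * u - 1));
    mat go = sigmoid(Ad.rows(3 * u, 4 * u - 1));
    mat gg = tanh(Ad.rows(4 * u, 5 * u - 1));
    mat cd = gi % gg + 0.5 * (f1 % Cup) + 0.5 * (f2 % Cleft);
    mat tc = tanh(cd);
    mat hd = go % tc;
    for (int t = 0; t < m; ++t) {
      const uword p = idx(t);
      G.col(p) = join_cols(join_cols(gi.col(t), f1.col(t)),
                           join_cols(join_cols(f2.col(t), go.col(t)), gg.col(t)));
      C.col(p) = cd.col(t); Tc.col(p) = tc.col(t); H.col(p) = hd.col(t);
    }
  }
  if (!H.is_finite())
    Rcpp::stop("non-finite MDLSTM activations (weights too large or bad input)");

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("H") = H,
                                      Rcpp::Named("Cmax") = abs(C).max());
  if (keep_cache)
    out["cache"] = Rcpp::List::create(Rcpp::Named("G") = G,
                                      Rcpp::Named("C") = C,
                                      Rcpp::Named("Tc") = Tc);
  return out;
}

// [[Rcpp::export]]
Rcpp::List mdlstm_backward_cpp(const arma::mat& dH,  // u x (h*w)
                               const int h, const int w,
                               const arma::mat& X,
                               const arma::mat& Win,
                               const arma::mat& Rup,
                               const arma::mat& Rleft,
                               const arma::mat& G,
                               const arma::mat& C,
                               const arma::mat& Tc,
                               const arma::mat& Hout) {
  const int u = (int)Rup.n_cols;
  const int hw = h * w;
  mat dA(5 * u, hw, fill::zeros);
  mat dC(u, hw, fill::zeros);

  const mat RupT = Rup.t(), RleftT = Rleft.t();

  for (int d = h + w - 2; d >= 0; --d) {
    const uvec idx = diag_pixels(h, w, d);
    const int m = (int)idx.n_elem;

    // gradient flowing in from the two downstream neighbours (diagonal d+1)
    mat dh(u, m), dcin(u, m, fill::zeros);
    for (int t = 0; t < m; ++t) {
      const int p = (int)idx(t), i = p % h, j = p / h;
      vec acc = dH.col(p);
      if (i + 1 < h) {  // neighbour below consumed h,c via Rup / f1
        const uword q = p + 1;
        acc += RupT * dA.col(q);
        dcin.col(t) += 0.5 * (G.col(q).rows(u, 2 * u - 1) % dC.col(q));
      }
      if (j + 1 < w) {  // neighbour to the right via Rleft / f2
        const uword q = p + h;
        acc += RleftT * dA.col(q);
        dcin.col(t) += 0.5 * (G.col(q).rows(2 * u, 3 * u - 1) % dC.col(q));
      }
      dh.col(t) = acc;
    }

    mat gi(u, m), f1(u, m), f2(u, m), go(u, m), gg(u, m), tc(u, m);
    mat Cup(u, m, fill::zeros), Cleft(u, m, fill::zeros);
    for (int t = 0; t < m; ++t) {
      const int p = (int)idx(t), i = p % h, j = p / h;
      gi.col(t) = G.col(p).rows(0, u - 1);
      f1.col(t) = G.col(p).rows(u, 2 * u - 1);
      f2.col(t) = G.col(p).rows(2 * u, 3 * u - 1);
      go.col(t) = G.col(p).rows(3 * u, 4 * u - 1);
      gg.col(t) = G.col(p).rows(4 * u, 5 * u - 1);
      tc.col(t) = Tc.col(p);
      if (i > 0) Cup.col(t)   = C.col(p - 1);
      if (j > 0) Cleft.col(t) = C.col(p - h);
    }

    mat dc  = dcin + dh % go % (1.0 - tc % tc);
    mat dgi = dc % gg, dgg = dc % gi;
    mat df1 = 0.5 * (dc % Cup), df2 = 0.5 * (dc % Cleft);
    mat dgo = dh % tc;

    mat dAd = join_cols(
        join_cols(dgi % gi % (1.0 - gi), df1 % f1 % (1.0 - f1)),
        join_cols(join_cols(df2 % f2 % (1.0 - f2), dgo % go % (1.0 - go)),
                  dgg % (1.0 - gg % gg)));
    for (int t = 0; t < m; ++t) {
      const uword p = idx(t);
      dA.col(p) = dAd.col(t);
      dC.col(p) = dc.col(t);
    }
  }

  // shifted activation images for the recurrent weight gradients
  mat HupF(u, hw, fill::zeros), HleftF(u, hw, fill::zeros);
  for (int p = 0; p < hw; ++p) {
    const int i = p % h, j = p / h;
    if (i > 0) HupF.col(p)   = Hout.col(p - 1);
    if (j > 0) HleftF.col(p) = Hout.col(p - h);
  }

  return Rcpp::List::create(
      Rcpp::Named("dWin")   = dA * X.t(),
      Rcpp::Named("dRup")   = dA * HupF.t(),
      Rcpp::Named("dRleft") = dA * HleftF.t(),
      Rcpp::Named("dbias")  = sum(dA, 1),
      Rcpp::Named("dX")     = Win.t() * dA);
}
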