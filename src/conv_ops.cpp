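// Compiled kernels for the CNN engine: valid 3x3 convolution forward /
// backward and 2x2 max pooling on the engine's row-major activation
// layout (rows ordered sample-major, then y, then x with x fastest;
// one column per channel). Armadillo supplies the GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for a valid 3x3 convolution: input (B*s*s) x C, output
// (B*so*so) x (9*C) with column blocks ordered by kernel offset
// (dy-major, dx fastest).
// [[Rcpp::export(name = ".cpp_im2col3")]]
arma::mat cpp_im2col3(const arma::mat& X, int B, int s) {
  const int so = s - 2;
  const int C = X.n_cols;
  const int n_out = B * so * so;
  arma::mat G(n_out, 9 * C);
  for (int dy = 0; dy < 3; ++dy) {
    for (int dx = 0; dx < 3; ++dx) {
      const int k = 3 * dy + dx;
      for (int c = 0; c < C; ++c) {
        const double* src = X.colptr(c);
        double* dst = G.colptr(k * C + c);
        for (int b = 0; b < B; ++b) {
          const int in_base = b * s * s;
          int out_base = b * so * so;
          for (int y = 0; y < so; ++y) {
            const double* row = src + in_base + (y + dy) * s + dx;
            double* out = dst + out_base + y * so;
            for (int x = 0; x < so; ++x) out[x] = row[x];
          }
        }
      }
    }
  }
  return G;
}

// Forward convolution: returns (B*so*so) x F output, optionally exposing
// the im2col matrix for the backward pass via `keep`.
// [[Rcpp::export(name = ".cpp_conv3_forward")]]
List cpp_conv3_forward(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b, int B, int s, bool keep) {
  arma::mat G = cpp_im2col3(X, B, s);
  arma::mat out = G * W;
  out.each_row() += b.t();
  if (keep) return List::create(Named("out") = out, Named("G") = G);
  return List::create(Named("out") = out);
}

// Backward convolution: given dOut (B*so*so) x F, the cached im2col G and
// the kernel W, returns dW, db and dX.
// [[Rcpp::export(name = ".cpp_conv3_backward")]]
List cpp_conv3_backward(const arma::mat& dOut, const arma::mat& G,
                        const arma::mat& W, int B, int s) {
  const int so = s - 2;
  const int C = W.n_rows / 9;
  arma::mat dW = G.t() * dOut;
  arma::vec db = arma::sum(dOut, 0).t();
  arma::mat dG = dOut * W.t();
  arma::mat dX(B * s * s, C, arma::fill::zeros);
  for (int dy = 0; dy < 3; ++dy) {
    for (int dx = 0; dx < 3; ++dx) {
      const int k = 3 * dy + dx;
      for (int c = 0; c < C; ++c) {
        const double* src = dG.colptr(k * C + c);
        double* dst = dX.colptr(c);
        for (int b2 = 0; b2 < B; ++b2) {
          const int in_base = b2 * s * s;
          const int out_base = b2 * so * so;
          for (int y = 0; y < so; ++y) {
            double* row = dst + in_base + (y + dy) * s + dx;
            const double* out = src + out_base + y * so;
            for (int x = 0; x < so; ++x) row[x] += out[x];
          }
        }
      }
    }
  }
  return List::create(Named("dW") = dW, Named("db") = db, Named("dX") = dX);
}

// 2x2/stride-2 max pooling; records the winning offset (1..4, dy-major)
// per output element for the backward pass.
// [[Rcpp::export(name = ".cpp_pool2_forward")]]
List cpp_pool2_forward(const arma::mat& X, int B, int s) {
  const int so = s / 2;
  const int C = X.n_cols;
  arma::mat out(B * so * so, C);
  arma::imat winner(B * so * so, C);
  for (int c = 0; c < C; ++c) {
    const double* src = X.colptr(c);
    double* dst = out.colptr(c);
    arma::sword* win = winner.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int in_base = b * s * s;
      const int out_base = b * so * so;
      for (int y = 0; y < so; ++y) {
        for (int x = 0; x < so; ++x) {
          double best = src[in_base + 2 * y * s + 2 * x];
          int bk = 1;
          const int cand_off[4] = {0, 1, s, s + 1};
          for (int k = 1; k < 4; ++k) {
            double v = src[in_base + 2 * y * s + 2 * x + cand_off[k]];
            if (v > best) { best = v; bk = k + 1; }
          }
          dst[out_base + y * so + x] = best;
          win[out_base + y * so + x] = bk;
        }
      }
    }
  }
  return List::create(Named("out") = out, Named("winner") = winner);
}

// [[Rcpp::export(name = ".cpp_pool2_backward")]]
arma::mat cpp_pool2_backward(const arma::mat& dOut, const arma::imat& winner,
                             int B, int s) {
  const int so = s / 2;
  const int C = dOut.n_cols;
  arma::mat dX(B * s * s, C, arma::fill::zeros);
  const int cand_off[4] = {0, 1, s, s + 1};
  for (int c = 0; c < C; ++c) {
    const double* src = dOut.colptr(c);
    const arma::sword* win = winner.colptr(c);
    double* dst = dX.colptr(c);
    for (int b = 0; b < B; ++b) {
      const int in_base = b * s * s;
      const int out_base = b * so * so;
      for (int y = 0; y < so; ++y) {
        for (int x = 0; x < so; ++x) {
          const int o = out_base + y * so + x;
          dst[in_base + 2 * y * s + 2 * x + cand_off[win[o] - 1]] += src[o];
        }
      }
    }
  }
  return dX;
}
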