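// Low-level numerical kernels: 2-D convolution (cross-correlation) with
// replicate (edge) padding, its adjoint, and a small byte hash.
//
// Tensor layout: images are arma::cube of shape (H, W, C).  Convolution
// weights are a (C_out x C_in*k*k) matrix; within a row the ordering is
// channel-major, then kernel column, then kernel row (row fastest), i.e.
// for a single channel the row is as.vector(K) of the 3x3 matrix K in R
// (column-major: K[1,1], K[2,1], K[3,1], K[1,2], ...).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col with replicate padding; output column index = r + c*H.
static arma::mat im2col_rep(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = k / 2;
  arma::mat cols(C * k * k, (arma::uword)H * W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const arma::uword colidx = (arma::uword)r + (arma::uword)c * H;
      int idx = 0;
      for (int ch = 0; ch < C; ++ch)
        for (int dc = -p; dc <= p; ++dc)
          for (int dr = -p; dr <= p; ++dr)
            cols(idx++, colidx) =
              x(clampi(r + dr, 0, H - 1), clampi(c + dc, 0, W - 1), ch);
    }
  }
  return cols;
}

// Same-size convolution with replicate padding.
// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k = (int)std::lround(std::sqrt((double)w.n_cols / C));
  if ((arma::uword)(C * k * k) != w.n_cols)
    stop("weight matrix width does not match input channels / kernel size");
  if (w.n_rows != b.n_elem)
    stop("bias length does not match output channels");
  arma::mat cols = im2col_rep(x, k);
  arma::mat out = w * cols;
  out.each_col() += b;
  arma::cube res(H, W, w.n_rows);
  for (arma::uword ch = 0; ch < w.n_rows; ++ch)
    res.slice(ch) = arma::reshape(out.row(ch), H, W);
  return res;
}

// Gradients of the same-size replicate-padded convolution.
// Returns grad wrt input, weights and bias given upstream grad_out.
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& w,
                  const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int k = (int)std::lround(std::sqrt((double)w.n_cols / C));
  const int p = k / 2;
  if ((int)gout.n_slices != (int)w.n_rows ||
      (int)gout.n_rows != H || (int)gout.n_cols != W)
    stop("grad_out shape does not match layer geometry");
  arma::mat G(w.n_rows, (arma::uword)H * W);
  for (arma::uword ch = 0; ch < w.n_rows; ++ch)
    G.row(ch) = arma::vectorise(gout.slice(ch)).t();
  arma::mat cols = im2col_rep(x, k);
  arma::mat gw = G * cols.t();
  arma::vec gb = arma::sum(G, 1);
  arma::mat colsg = w.t() * G;  // (C*k*k) x (H*W)
  arma::cube gin(H, W, C, arma::fill::zeros);
  // Adjoint of replicate-padded im2col: each padded tap accumulates into
  // its clamped source pixel.
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const arma::uword colidx = (arma::uword)r + (arma::uword)c * H;
      int idx = 0;
      for (int ch = 0; ch < C; ++ch)
        for (int dc = -p; dc <= p; ++dc)
          for (int dr = -p; dr <= p; ++dr)
            gin(clampi(r + dr, 0, H - 1), clampi(c + dc, 0, W - 1), ch) +=
              colsg(idx++, colidx);
    }
  }
  return List::create(_["grad_input"] = gin, _["grad_w"] = gw,
                      _["grad_b"] = gb);
}

// FNV-1a 32-bit hash of a raw vector, as 8 hex characters.
// [[Rcpp::export]]
std::string cpp_fnv1a32(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint8_t)bytes[i];
    h *= 16777619u;
  }
  char buf[9];
  std::snprintf(buf, sizeof(buf), "%08x", h);
  return std::string(buf);
}
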