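// Compiled kernels for the hot layers: 1x1 and 3x3 convolutions (im2col +
// GEMM, blocked per image so the im2col buffer stays cache-resident) and
// non-overlapping max pooling, all on the package's batched map layout -- a
// (B*S) x C matrix with S = H*W, spatial index s = y + x*H (0-based), image
// b in rows [b*S, (b+1)*S).  3x3 kernels are column-major length-9 blocks
// per input channel: weight row j + 9*c with j = (dy+1) + 3*(dx+1).  Bias
// add and ReLU are fused; the backward pass recovers the ReLU mask from the
// stored activations (out > 0).  All R matrices are wrapped as zero-copy
// Armadillo views; results are computed directly into R-allocated output
// matrices.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerMatrix;

static inline mat view(NumericMatrix m) {
  return mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// im2col for one image: fills col (S x 9C) from X rows [b*S, (b+1)*S).
static void im2col3_one(const mat& Xb, int H, int W, int b, mat& col) {
  const int S = H * W;
  const int C = Xb.n_cols;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xp = Xb.colptr(c) + (size_t)b * S;
    for (int j = 0; j < 9; ++j) {
      const int dy = j % 3 - 1;
      const int dx = j / 3 - 1;
      double* cp = col.colptr(9 * c + j);
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      for (int x = x0; x < x1; ++x) {
        const double* src = xp + (size_t)(x + dx) * H + dy;
        double* dst = cp + (size_t)x * H;
        std::copy(src + y0, src + y1, dst + y0);
      }
    }
  }
}

// Scatter-add transpose of im2col3_one into dX rows [b*S, (b+1)*S).
static void col2im3_one(const mat& dcol, int H, int W, int b, mat& dX) {
  const int S = H * W;
  const int C = dX.n_cols;
  for (int c = 0; c < C; ++c) {
    double* xp = dX.colptr(c) + (size_t)b * S;
    for (int j = 0; j < 9; ++j) {
      const int dy = j % 3 - 1;
      const int dx = j / 3 - 1;
      const double* cp = dcol.colptr(9 * c + j);
      const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
      const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
      for (int x = x0; x < x1; ++x) {
        double* dst = xp + (size_t)(x + dx) * H + dy;
        const double* src = cp + (size_t)x * H;
        for (int y = y0; y < y1; ++y) dst[y] += src[y];
      }
    }
  }
}

static inline void bias_relu(mat& out, const double* bv, bool relu) {
  const size_t n = out.n_rows;
  for (uword c = 0; c < out.n_cols; ++c) {
    double* p = out.colptr(c);
    const double b = bv[c];
    if (relu) {
      for (size_t i = 0; i < n; ++i) {
        const double v = p[i] + b;
        p[i] = v > 0 ? v : 0;
      }
    } else {
      for (size_t i = 0; i < n; ++i) p[i] += b;
    }
  }
}

// d := dout masked by (act > 0).
static void masked_copy(const mat& dout, const mat& act, mat& d, bool relu) {
  if (!relu) { d = dout; return; }
  d.set_size(dout.n_rows, dout.n_cols);
  const size_t n = d.n_elem;
  const double* a = act.memptr();
  const double* s = dout.memptr();
  double* p = d.memptr();
  for (size_t i = 0; i < n; ++i) p[i] = a[i] > 0 ? s[i] : 0;
}

// [[Rcpp::export]]
NumericMatrix conv1_fwd_cpp(NumericMatrix Xb_, NumericMatrix Wm_,
                            NumericVector bv, bool relu) {
  const mat Xb = view(Xb_), Wm = view(Wm_);
  NumericMatrix out_(Xb_.nrow(), Wm_.ncol());
  mat out = view(out_);
  out = Xb * Wm;
  bias_relu(out, bv.begin(), relu);
  return out_;
}

// [[Rcpp::export]]
Rcpp::List conv1_bwd_cpp(NumericMatrix Xb_, NumericMatrix Wm_,
                         NumericMatrix dout_, NumericMatrix act_,
                         bool relu) {
  const mat Xb = view(Xb_), Wm = view(Wm_), dout = view(dout_),
    act = view(act_);
  mat d;
  masked_copy(dout, act, d, relu);
  NumericMatrix dX_(Xb_.nrow(), Xb_.ncol());
  NumericMatrix dW_(Wm_.nrow(), Wm_.ncol());
  NumericVector db_(Wm_.ncol());
  mat dX = view(dX_), dW = view(dW_);
  dX = d * Wm.t();
  dW = Xb.t() * d;
  vec db(db_.begin(), db_.size(), false, true);
  db = sum(d, 0).t();
  return Rcpp::List::create(Rcpp::Named("dX") = dX_,
                            Rcpp::Named("dW") = dW_,
                            Rcpp::Named("db") = db_);
}

// [[Rcpp::export]]
NumericMatrix conv3_fwd_cpp(NumericMatrix Xb_, NumericMatrix Wm_,
                            NumericVector bv, int H, int W, int B,
                            bool relu) {
  const mat Xb = view(Xb_), Wm = view(Wm_);
  const int S = H * W;
  const int C = Xb.n_cols;
  NumericMatrix out_(Xb_.nrow(), Wm_.ncol());
  mat out = view(out_);
  mat col(S, 9 * C);
  for (int b = 0; b < B; ++b) {
    im2col3_one(Xb, H, W, b, col);
    out.rows((size_t)b * S, (size_t)(b + 1) * S - 1) = col * Wm;
  }
  bias_relu(out, bv.begin(), relu);
  return out_;
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd_cpp(NumericMatrix Xb_, NumericMatrix Wm_,
                         NumericMatrix dout_, NumericMatrix act_,
                         int H, int W, int B, bool relu) {
  const mat Xb = view(Xb_), Wm = view(Wm_), dout = view(dout_),
    act = view(act_);
  const int S = H * W;
  const int C = Xb.n_cols;
  mat d;
  masked_copy(dout, act, d, relu);
  NumericMatrix dX_(Xb_.nrow(), Xb_.ncol());
  NumericMatrix dW_(Wm_.nrow(), Wm_.ncol());
  NumericVector db_(Wm_.ncol());
  mat dX = view(dX_), dW = view(dW_);
  mat col(S, 9 * C);
  for (int b = 0; b < B; ++b) {
    im2col3_one(Xb, H, W, b, col);
    const mat db2 = d.rows((size_t)b * S, (size_t)(b + 1) * S - 1);
    dW += col.t() * db2;
    mat dcol = db2 * Wm.t();
    col2im3_one(dcol, H, W, b, dX);
  }
  vec db(db_.begin(), db_.size(), false, true);
  db = sum(d, 0).t();
  return Rcpp::List::create(Rcpp::Named("dX") = dX_,
                            Rcpp::Named("dW") = dW_,
                            Rcpp::Named("db") = db_);
}

// [[Rcpp::export]]
Rcpp::List maxpool_fwd_cpp(NumericMatrix Xb_, int H, int W, int B, int p) {
  const mat Xb = view(Xb_);
  const int S = H * W;
  const int Ho = H / p, Wo = W / p, So = Ho * Wo;
  const int C = Xb.n_cols;
  NumericMatrix out_(B * So, C);
  IntegerMatrix arg_(B * So, C);   // 0-based row index into Xb of the max
  mat out = view(out_);
  for (int c = 0; c < C; ++c) {
    const double* xp = Xb.colptr(c);
    double* op = out.colptr(c);
    int* ap = &arg_(0, c);
    for (int b = 0; b < B; ++b) {
      for (int xo = 0; xo < Wo; ++xo) {
        for (int yo = 0; yo < Ho; ++yo) {
          double best = -datum::inf;
          size_t besti = 0;
          for (int dx = 0; dx < p; ++dx) {
            for (int dy = 0; dy < p; ++dy) {
              const size_t idx = (size_t)b * S +
                (size_t)(xo * p + dx) * H + (yo * p + dy);
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          const size_t o = (size_t)b * So + (size_t)xo * Ho + yo;
          op[o] = best;
          ap[o] = (int)besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out_,
                            Rcpp::Named("arg") = arg_);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cpp(NumericMatrix dout_, IntegerMatrix arg_,
                              int n_in) {
  const int C = dout_.ncol();
  const int n = dout_.nrow();
  NumericMatrix dX_(n_in, C);
  for (int c = 0; c < C; ++c) {
    const double* dp = &dout_(0, c);
    const int* ap = &arg_(0, c);
    double* xp = &dX_(0, c);
    for (int i = 0; i < n; ++i) xp[ap[i]] += dp[i];
  }
  return dX_;
}
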