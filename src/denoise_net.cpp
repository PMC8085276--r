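// Core numerical kernels for the residual spatiotemporal denoising network.
//
// Layout conventions (shared with the R side):
//  * An activation block is a (B*H*W) x C float matrix; global row index
//    g = s*H*W + x*H + y (column-major pixels, matching R matrices).
//  * A conv layer's weights are a (9*C_in) x C_out matrix. Row j = r*C_in + c
//    holds the tap for kernel offset r and input channel c, with
//    r = (kx)*3 + ky, ky/kx in {0,1,2} corresponding to dy/dx = ky-1 / kx-1.
//    Convolution is cross-correlation: output (y,x) reads input (y+dy, x+dx).
//  * Same (zero) padding; 3x3 kernels only.
//
// All arithmetic is single precision on top of BLAS GEMM; results are
// deterministic for a fixed thread count.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col3(const fmat& X, int H, int W, int B, fmat& out) {
  const int C = X.n_cols, HW = H * W;
  out.set_size(X.n_rows, 9 * C);
  int r = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++r) {
      const int x0 = std::max(0, -dx), x1 = W - std::max(0, dx);
      const int y0 = std::max(0, -dy), y1 = H - std::max(0, dy);
      for (int c = 0; c < C; ++c) {
        float* po = out.colptr(r * C + c);
        const float* px = X.colptr(c);
        for (int s = 0; s < B; ++s) {
          const int base = s * HW;
          for (int x = 0; x < W; ++x) {
            float* d = po + base + x * H;
            if (x < x0 || x >= x1) {
              std::fill(d, d + H, 0.0f);
              continue;
            }
            const float* src = px + base + (x + dx) * H + dy;
            if (y0 > 0) std::fill(d, d + y0, 0.0f);
            std::memcpy(d + y0, src + y0, sizeof(float) * (y1 - y0));
            if (y1 < H) std::fill(d + y1, d + H, 0.0f);
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dXcol, int H, int W, int B, fmat& dX) {
  const int C = dX.n_cols, HW = H * W;
  dX.zeros();
  int r = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy, ++r) {
      const int x0 = std::max(0, -dx), x1 = W - std::max(0, dx);
      const int y0 = std::max(0, -dy), y1 = H - std::max(0, dy);
      if (x1 <= x0 || y1 <= y0) continue;
      for (int c = 0; c < C; ++c) {
        const float* ps = dXcol.colptr(r * C + c);
        float* pd = dX.colptr(c);
        for (int s = 0; s < B; ++s) {
          const int base = s * HW;
          for (int x = x0; x < x1; ++x) {
            const float* src = ps + base + x * H + y0;
            float* dst = pd + base + (x + dx) * H + y0 + dy;
            const int len = y1 - y0;
            for (int y = 0; y < len; ++y) dst[y] += src[y];
          }
        }
      }
    }
  }
}

static inline void lrelu_inplace(fmat& Z, float slope) {
  Z.for_each([slope](float& v) { if (v < 0) v *= slope; });
}

struct Net {
  std::vector<fmat> W;
  std::vector<frowvec> b;
  float slope;
};

static Net net_from_r(Rcpp::List W_, Rcpp::List b_, double slope) {
  Net net;
  net.slope = (float)slope;
  for (int l = 0; l < W_.size(); ++l) {
    net.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(W_[l])));
    net.b.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(b_[l])));
  }
  return net;
}

// forward pass; if acts != nullptr store all activations (input first)
static fmat net_forward(const Net& net, const fmat& X, int H, int W, int B,
                        std::vector<fmat>* acts) {
  const int L = net.W.size();
  fmat A = X, Xcol;
  if (acts) { acts->clear(); acts->push_back(A); }
  for (int l = 0; l < L; ++l) {
    im2col3(A, H, W, B, Xcol);
    A = Xcol * net.W[l];
    A.each_row() += net.b[l];
    if (l < L - 1) lrelu_inplace(A, net.slope);
    if (acts) acts->push_back(A);
  }
  return A;
}

// backprop of mean squared error between prediction and desired residual;
// returns the batch loss and fills gradients
static double net_backward(const Net& net, const std::vector<fmat>& acts,
                           const fmat& desired, int H, int W, int B,
                           std::vector<fmat>& gW, std::vector<frowvec>& gb) {
  const int L = net.W.size();
  const double numel = (double)desired.n_rows * desired.n_cols;
  fmat diff = acts[L] - desired;
  const double loss = accu(conv_to<mat>::from(square(diff))) / numel;
  fmat dZ = diff * (float)(2.0 / numel);
  fmat Xcol, dA;
  for (int l = L - 1; l >= 0; --l) {
    im2col3(acts[l], H, W, B, Xcol);
    gW[l] = Xcol.t() * dZ;
    gb[l] = sum(dZ, 0);
    if (l > 0) {
      fmat dXcol = dZ * net.W[l].t();
      dA.set_size(acts[l].n_rows, acts[l].n_cols);
      col2im3(dXcol, H, W, B, dA);
      // lrelu derivative read off the (sign-preserving) stored activation
      const float slope = net.slope;
      dZ = std::move(dA);
      const float* a = acts[l].memptr();
      float* z = dZ.memptr();
      const uword n = dZ.n_elem;
      for (uword i = 0; i < n; ++i)
        if (a[i] <= 0) z[i] *= slope;
    }
  }
  return loss;
}

// gather samples idx (0-based) from an (H,W,3,N) R array into a (B*HW) x 3 block
static fmat gather(const fvec& data, const std::vector<int>& idx,
                   int HW, int C) {
  const int B = idx.size();
  fmat out(B * HW, C);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      std::copy(data.memptr() + ((size_t)idx[s] * C + c) * HW,
                data.memptr() + ((size_t)idx[s] * C + c) * HW + HW,
                out.colptr(c) + (size_t)s * HW);
  return out;
}

static double eval_loss(const Net& net, const fvec& in, const fvec& tg,
                        int H, int W, int n, int batch) {
  const int HW = H * W;
  double sse = 0.0, numel = 0.0;
  for (int start = 0; start < n; start += batch) {
    const int B = std::min(batch, n - start);
    std::vector<int> idx(B);
    for (int s = 0; s < B; ++s) idx[s] = start + s;
    fmat X = gather(in, idx, HW, 3), T = gather(tg, idx, HW, 3);
    fmat pred = net_forward(net, X, H, W, B, nullptr);
    fmat diff = pred - (X - T);
    sse += accu(conv_to<mat>::from(square(diff)));
    numel += (double)diff.n_elem;
  }
  return sse / numel;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List W_, Rcpp::List b_,
                     Rcpp::NumericVector train_in, Rcpp::NumericVector train_tg,
                     Rcpp::NumericVector val_in, Rcpp::NumericVector val_tg,
                     Rcpp::IntegerMatrix order, int H, int Wd, int batch,
                     double lr, double beta1, double beta2, double eps,
                     double slope, bool track_best, bool verbose) {
  Net net = net_from_r(W_, b_, slope);
  const int L = net.W.size(), HW = H * Wd;
  const int n_train = order.nrow(), n_epochs = order.ncol();
  const int n_val = val_in.size() / (HW * 3);
  fvec tin = conv_to<fvec>::from(Rcpp::as<vec>(train_in));
  fvec ttg = conv_to<fvec>::from(Rcpp::as<vec>(train_tg));
  fvec vin, vtg;
  if (n_val > 0) {
    vin = conv_to<fvec>::from(Rcpp::as<vec>(val_in));
    vtg = conv_to<fvec>::from(Rcpp::as<vec>(val_tg));
  }

  std::vector<fmat> gW(L), mW(L), vW(L);
  std::vector<frowvec> gb(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    mW[l].zeros(size(net.W[l])); vW[l].zeros(size(net.W[l]));
    mb[l].zeros(size(net.b[l])); vb[l].zeros(size(net.b[l]));
  }
  long t = 0;
  vec train_loss(n_epochs), val_loss(n_epochs, fill::value(datum::nan));
  std::vector<fmat> bestW; std::vector<frowvec> bestb;
  double best_val = datum::inf; int best_epoch = NA_INTEGER;
  std::vector<fmat> acts;

  for (int e = 0; e < n_epochs; ++e) {
    double sse_w = 0.0, n_seen = 0.0;
    for (int start = 0; start < n_train; start += batch) {
      const int B = std::min(batch, n_train - start);
      std::vector<int> idx(B);
      for (int s = 0; s < B; ++s) idx[s] = order(start + s, e) - 1;
      fmat X = gather(tin, idx, HW, 3), T = gather(ttg, idx, HW, 3);
      net_forward(net, X, H, Wd, B, &acts);
      double loss = net_backward(net, acts, X - T, H, Wd, B, gW, gb);
      sse_w += loss * B; n_seen += B;
      ++t;
      const float c1 = 1.0f - (float)std::pow(beta1, (double)t);
      const float c2 = 1.0f - (float)std::pow(beta2, (double)t);
      for (int l = 0; l < L; ++l) {
        mW[l] = (float)beta1 * mW[l] + (float)(1 - beta1) * gW[l];
        vW[l] = (float)beta2 * vW[l] + (float)(1 - beta2) * square(gW[l]);
        net.W[l] -= (float)lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + (float)eps);
        mb[l] = (float)beta1 * mb[l] + (float)(1 - beta1) * gb[l];
        vb[l] = (float)beta2 * vb[l] + (float)(1 - beta2) * square(gb[l]);
        net.b[l] -= (float)lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + (float)eps);
      }
    }
    train_loss(e) = sse_w / n_seen;
    if (n_val > 0) {
      val_loss(e) = eval_loss(net, vin, vtg, H, Wd, n_val, batch);
      if (track_best && val_loss(e) < best_val) {
        best_val = val_loss(e); best_epoch = e + 1;
        bestW = net.W; bestb = net.b;
      }
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << e + 1 << "/" << n_epochs
                  << " train_loss " << train_loss(e)
                  << " val_loss " << val_loss(e) << std::endl;
    Rcpp::checkUserInterrupt();
  }

  if (track_best && !bestW.empty()) { net.W = bestW; net.b = bestb; }
  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = Rcpp::wrap(conv_to<mat>::from(net.W[l]));
    bout[l] = Rcpp::wrap(conv_to<vec>::from(net.b[l].t()));
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = Wout, Rcpp::Named("b") = bout,
      Rcpp::Named("train_loss") = train_loss,
      Rcpp::Named("val_loss") = val_loss,
      Rcpp::Named("best_epoch") = best_epoch);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_forward(Rcpp::List W_, Rcpp::List b_,
                                Rcpp::NumericVector input, int H, int Wd,
                                double slope) {
  Net net = net_from_r(W_, b_, slope);
  const int HW = H * Wd;
  const int N = input.size() / (HW * 3);
  fvec in = conv_to<fvec>::from(Rcpp::as<vec>(input));
  Rcpp::NumericVector out(input.size());
  for (int s = 0; s < N; ++s) {
    std::vector<int> idx(1, s);
    fmat X = gather(in, idx, HW, 3);
    fmat pred = net_forward(net, X, H, Wd, 1, nullptr);
    for (int c = 0; c < 3; ++c)
      for (int p = 0; p < HW; ++p)
        out[((size_t)s * 3 + c) * HW + p] = pred(p, c);
  }
  out.attr("dim") = input.attr("dim");
  return out;
}

// [[Rcpp::export]]
double cpp_dataset_loss(Rcpp::List W_, Rcpp::List b_,
                        Rcpp::NumericVector input, Rcpp::NumericVector target,
                        int H, int Wd, double slope, int batch) {
  Net net = net_from_r(W_, b_, slope);
  const int n = input.size() / (H * Wd * 3);
  fvec fin = conv_to<fvec>::from(Rcpp::as<vec>(input));
  fvec ftg = conv_to<fvec>::from(Rcpp::as<vec>(target));
  return eval_loss(net, fin, ftg, H, Wd, n, batch);
}

// backward-warp a frame by a per-pixel displacement of the image content:
// out(y, x) = bilinear sample of img at (y - dy(y,x), x - dx(y,x)),
// out-of-frame samples take `fill`
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_warp(Rcpp::NumericMatrix img, Rcpp::NumericMatrix dy,
                             Rcpp::NumericMatrix dx, double fill) {
  const int H = img.nrow(), W = img.ncol();
  Rcpp::NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double sy = y - dy(y, x), sx = x - dx(y, x);
      if (sy < 0 || sx < 0 || sy > H - 1 || sx > W - 1) {
        out(y, x) = fill;
        continue;
      }
      const int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      const int y1 = std::min(y0 + 1, H - 1), x1 = std::min(x0 + 1, W - 1);
      const double fy = sy - y0, fx = sx - x0;
      out(y, x) = (1 - fy) * (1 - fx) * img(y0, x0) +
                  fy * (1 - fx) * img(y1, x0) +
                  (1 - fy) * fx * img(y0, x1) +
                  fy * fx * img(y1, x1);
    }
  }
  return out;
}
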