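// Compact U-Net encoder-decoder for proximity-map regression.
//
// Forward and backward passes are implemented with im2col + BLAS gemm in
// single precision; the optimiser lives in R. Feature maps are
// arma::fcube (H x W x C); convolution weights arrive from R as
// (kh, kw, cin, cout) arrays whose column-major flattening matches the
// row order of the im2col patch matrix, so reshapes are plain copies.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;

static fcube as_fcube(const NumericVector& v) {
  Rcpp::IntegerVector d = v.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected an H x W x C array");
  fcube out(d[0], d[1], d[2]);
  std::copy(v.begin(), v.end(), out.memptr());
  return out;
}

static NumericVector as_rarray(const fcube& x) {
  NumericVector out(x.n_elem);
  std::copy(x.begin(), x.end(), out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols,
                                                x.n_slices);
  return out;
}

// ---- layers ---------------------------------------------------------------

struct ConvW {            // k x k convolution, same padding (k = 1 or 3)
  int k, cin, cout;
  fmat W;                 // (k*k*cin, cout)
  fvec b;
  fmat gW;                // gradient accumulators
  fvec gb;
};

struct UpW {              // 2 x 2 stride-2 transposed convolution
  int cin, cout;
  fmat W[4];              // per (di, dj): (cin, cout)
  fvec b;
  fmat gW[4];
  fvec gb;
};

static ConvW parse_conv(const List& weights, const std::string& name,
                        bool with_grad) {
  List layer = weights[name];
  NumericVector w = layer["W"];
  NumericVector b = layer["b"];
  Rcpp::IntegerVector d = w.attr("dim");
  ConvW out;
  out.k = d[0];
  out.cin = d[2];
  out.cout = d[3];
  out.W.set_size(d[0] * d[1] * d[2], d[3]);
  std::copy(w.begin(), w.end(), out.W.memptr());
  out.b = conv_to<fvec>::from(
      std::vector<double>(b.begin(), b.end()));
  if (with_grad) {
    out.gW.zeros(out.W.n_rows, out.W.n_cols);
    out.gb.zeros(out.b.n_elem);
  }
  return out;
}

static UpW parse_up(const List& weights, const std::string& name,
                    bool with_grad) {
  List layer = weights[name];
  NumericVector w = layer["W"];
  NumericVector b = layer["b"];
  Rcpp::IntegerVector d = w.attr("dim");  // (2, 2, cin, cout)
  UpW out;
  out.cin = d[2];
  out.cout = d[3];
  for (int j = 0; j < 4; ++j) out.W[j].set_size(out.cin, out.cout);
  // flat index: di + 2*dj + 4*ci + 4*cin*co
  for (int co = 0; co < out.cout; ++co)
    for (int ci = 0; ci < out.cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          out.W[di + 2 * dj](ci, co) =
              (float)w[di + 2 * dj + 4 * ci + 4 * (size_t)out.cin * co];
  out.b = conv_to<fvec>::from(std::vector<double>(b.begin(), b.end()));
  if (with_grad) {
    for (int j = 0; j < 4; ++j) out.gW[j].zeros(out.cin, out.cout);
    out.gb.zeros(out.b.n_elem);
  }
  return out;
}

// im2col for 3x3 same-padded convolution: (H*W, 9*C), column
// q = kh + 3*kw + 9*ci, row p = r + H*c.
static fmat im2col3(const fcube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  fmat out(H * (size_t)W, 9 * (size_t)C, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const fmat& S = X.slice(ci);
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh) {
        float* dst = out.colptr((kh + 1) + 3 * (kw + 1) + 9 * ci);
        int r0 = std::max(0, -kh), r1 = std::min(H, H - kh);
        if (r1 <= r0) continue;
        for (int c = 0; c < W; ++c) {
          int sc = c + kw;
          if (sc < 0 || sc >= W) continue;
          std::memcpy(dst + (size_t)c * H + r0, S.colptr(sc) + r0 + kh,
                      sizeof(float) * (r1 - r0));
        }
      }
  }
  return out;
}

// Scatter-add of the im2col gradient back to image space.
static void col2im3(const fmat& dcol, fcube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int ci = 0; ci < C; ++ci) {
    fmat& S = dX.slice(ci);
    for (int kw = -1; kw <= 1; ++kw)
      for (int kh = -1; kh <= 1; ++kh) {
        const float* src = dcol.colptr((kh + 1) + 3 * (kw + 1) + 9 * ci);
        int r0 = std::max(0, -kh), r1 = std::min(H, H - kh);
        if (r1 <= r0) continue;
        for (int c = 0; c < W; ++c) {
          int sc = c + kw;
          if (sc < 0 || sc >= W) continue;
          float* d = S.colptr(sc) + r0 + kh;
          const float* s = src + (size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) d[r] += s[r];
        }
      }
  }
}

static fcube mat_to_cube(const fmat& m, int H, int W) {
  return fcube(const_cast<float*>(m.memptr()), H, W, m.n_cols);
}

static fmat cube_to_mat(const fcube& x) {
  return fmat(const_cast<float*>(x.memptr()), x.n_rows * x.n_cols,
              x.n_slices);
}

static fcube conv_forward(const ConvW& L, const fcube& X, bool relu) {
  const int H = X.n_rows, W = X.n_cols;
  fmat xm = (L.k == 3) ? im2col3(X) : cube_to_mat(X);
  fmat ym = xm * L.W;
  ym.each_row() += L.b.t();
  if (relu) ym.transform([](float v) { return v > 0 ? v : 0.f; });
  return mat_to_cube(ym, H, W);
}

// Backward through (conv + optional ReLU). Y is the layer output
// (post-ReLU), X its input. Returns dX and accumulates gW/gb.
static fcube conv_backward(ConvW& L, const fcube& X, const fcube& Y,
                           fcube dY, bool relu) {
  const int H = X.n_rows, W = X.n_cols;
  if (relu) dY %= conv_to<fcube>::from(Y > 0);
  fmat dym = cube_to_mat(dY);
  fmat xm = (L.k == 3) ? im2col3(X) : cube_to_mat(X);
  L.gW += xm.t() * dym;
  L.gb += sum(dym, 0).t();
  fmat dxm = dym * L.W.t();
  fcube dX(H, W, L.cin, fill::zeros);
  if (L.k == 3) {
    col2im3(dxm, dX);
  } else {
    std::copy(dxm.begin(), dxm.end(), dX.memptr());
  }
  return dX;
}

static fcube up_forward(const UpW& L, const fcube& X) {
  const int H = X.n_rows, W = X.n_cols;
  fcube Y(2 * H, 2 * W, L.cout);
  fmat xm = cube_to_mat(X);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      fmat p = xm * L.W[di + 2 * dj];       // (H*W, cout)
      p.each_row() += L.b.t();
      for (int co = 0; co < L.cout; ++co) {
        const float* src = p.colptr(co);
        fmat& S = Y.slice(co);
        for (int c = 0; c < W; ++c) {
          float* d = S.colptr(2 * c + dj) + di;
          const float* s = src + (size_t)c * H;
          for (int r = 0; r < H; ++r) d[2 * r] = s[r];
        }
      }
    }
  return Y;
}

static fcube up_backward(UpW& L, const fcube& X, const fcube& dY) {
  const int H = X.n_rows, W = X.n_cols;
  fmat xm = cube_to_mat(X);
  fcube dX(H, W, L.cin, fill::zeros);
  fmat dxm = cube_to_mat(dX);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      fmat dp(H * (size_t)W, L.cout);
      for (int co = 0; co < L.cout; ++co) {
        float* d = dp.colptr(co);
        const fmat& S = dY.slice(co);
        for (int c = 0; c < W; ++c) {
          const float* s = S.colptr(2 * c + dj) + di;
          float* dd = d + (size_t)c * H;
          for (int r = 0; r < H; ++r) dd[r] = s[2 * r];
        }
      }
      L.gW[di + 2 * dj] += xm.t() * dp;
      L.gb += sum(dp, 0).t();
      dxm += dp * L.W[di + 2 * dj].t();
    }
  std::copy(dxm.begin(), dxm.end(), dX.memptr());
  return dX;
}

static fcube maxpool_forward(const fcube& X, ucube& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  fcube Y(H, W, C);
  idx.set_size(H, W, C);
  for (int ci = 0; ci < C; ++ci) {
    const fmat& S = X.slice(ci);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        uword best = 0;
        float bv = S(2 * r, 2 * c);
        const int rr[4] = {0, 1, 0, 1}, cc[4] = {0, 0, 1, 1};
        for (int j = 1; j < 4; ++j) {
          float v = S(2 * r + rr[j], 2 * c + cc[j]);
          if (v > bv) { bv = v; best = j; }
        }
        Y(r, c, ci) = bv;
        idx(r, c, ci) = best;
      }
  }
  return Y;
}

static fcube maxpool_backward(const fcube& dY, const ucube& idx,
                              int H0, int W0) {
  const int H = dY.n_rows, W = dY.n_cols, C = dY.n_slices;
  fcube dX(H0, W0, C, fill::zeros);
  const int rr[4] = {0, 1, 0, 1}, cc[4] = {0, 0, 1, 1};
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        uword j = idx(r, c, ci);
        dX(2 * r + rr[j], 2 * c + cc[j], ci) = dY(r, c, ci);
      }
  return dX;
}

// ---- network --------------------------------------------------------------

struct Net {
  int depth;
  std::vector<ConvW> enc1, enc2;   // levels 1..depth (depth = bottleneck)
  std::vector<UpW> up;             // levels depth-1..1 (stored deep->shallow)
  std::vector<ConvW> dec1, dec2;
  ConvW fin;
};

static Net parse_net(const List& weights, int depth, bool with_grad) {
  Net n;
  n.depth = depth;
  char buf[32];
  for (int l = 1; l <= depth; ++l) {
    snprintf(buf, sizeof(buf), "enc_%d_conv1", l);
    n.enc1.push_back(parse_conv(weights, buf, with_grad));
    snprintf(buf, sizeof(buf), "enc_%d_conv2", l);
    n.enc2.push_back(parse_conv(weights, buf, with_grad));
  }
  for (int l = depth - 1; l >= 1; --l) {
    snprintf(buf, sizeof(buf), "up_%d", l);
    n.up.push_back(parse_up(weights, buf, with_grad));
    snprintf(buf, sizeof(buf), "dec_%d_conv1", l);
    n.dec1.push_back(parse_conv(weights, buf, with_grad));
    snprintf(buf, sizeof(buf), "dec_%d_conv2", l);
    n.dec2.push_back(parse_conv(weights, buf, with_grad));
  }
  n.fin = parse_conv(weights, "final", with_grad);
  return n;
}

struct Ctx {                        // per-image forward intermediates
  std::vector<fcube> enc_in, enc_mid, enc_out;   // per level 1..depth
  std::vector<fcube> pooled;
  std::vector<ucube> pool_idx;
  std::vector<fcube> up_in, up_out, cat, dec_mid, dec_out;  // deep->shallow
  fcube fin_in, out;
};

static void net_forward(const Net& n, const fcube& x, Ctx& ctx) {
  fcube cur = x;
  for (int l = 0; l < n.depth; ++l) {
    ctx.enc_in.push_back(cur);
    ctx.enc_mid.push_back(conv_forward(n.enc1[l], ctx.enc_in[l], true));
    ctx.enc_out.push_back(conv_forward(n.enc2[l], ctx.enc_mid[l], true));
    if (l < n.depth - 1) {
      ucube idx;
      ctx.pooled.push_back(maxpool_forward(ctx.enc_out[l], idx));
      ctx.pool_idx.push_back(idx);
      cur = ctx.pooled[l];
    }
  }
  fcube deep = ctx.enc_out[n.depth - 1];
  for (int j = 0; j < n.depth - 1; ++j) {     // j: deep -> shallow
    int l = n.depth - 2 - j;                  // encoder level index of skip
    ctx.up_in.push_back(deep);
    ctx.up_out.push_back(up_forward(n.up[j], ctx.up_in[j]));
    ctx.cat.push_back(join_slices(ctx.enc_out[l], ctx.up_out[j]));
    ctx.dec_mid.push_back(conv_forward(n.dec1[j], ctx.cat[j], true));
    ctx.dec_out.push_back(conv_forward(n.dec2[j], ctx.dec_mid[j], true));
    deep = ctx.dec_out[j];
  }
  ctx.fin_in = deep;
  ctx.out = conv_forward(n.fin, ctx.fin_in, true);
}

static void net_backward(Net& n, Ctx& ctx, const fcube& dOut) {
  fcube d = conv_backward(n.fin, ctx.fin_in, ctx.out, dOut, true);
  for (int j = n.depth - 2; j >= 0; --j) {
    int l = n.depth - 2 - j;
    d = conv_backward(n.dec2[j], ctx.dec_mid[j], ctx.dec_out[j], d, true);
    d = conv_backward(n.dec1[j], ctx.cat[j], ctx.dec_mid[j], d, true);
    int nskip = ctx.enc_out[l].n_slices;
    fcube d_skip = d.slices(0, nskip - 1);
    fcube d_up = d.slices(nskip, d.n_slices - 1);
    fcube d_deep = up_backward(n.up[j], ctx.up_in[j], d_up);
    // the skip-connection gradient joins the pooled path at encoder level
    // l; stash it (up_in[j] is no longer needed, reuse the slot)
    (void)l;
    ctx.up_in[j] = d_skip;
    d = d_deep;
  }
  // d now reaches the bottleneck output; walk the encoder upwards
  for (int l = n.depth - 1; l >= 0; --l) {
    fcube dout;
    if (l == n.depth - 1) {
      dout = d;
    } else {
      int j = n.depth - 2 - l;
      dout = maxpool_backward(d, ctx.pool_idx[l], ctx.enc_out[l].n_rows,
                              ctx.enc_out[l].n_cols);
      dout += ctx.up_in[j];                // add skip gradient
    }
    fcube dmid = conv_backward(n.enc2[l], ctx.enc_mid[l], ctx.enc_out[l],
                               dout, true);
    d = conv_backward(n.enc1[l], ctx.enc_in[l], ctx.enc_mid[l], dmid, true);
  }
}

// ---- loss -----------------------------------------------------------------

enum LossKind { L_MSE, L_RMSE, L_HUBER, L_LOGCOSH };

static LossKind loss_kind(const std::string& s) {
  if (s == "mse") return L_MSE;
  if (s == "rmse") return L_RMSE;
  if (s == "huber") return L_HUBER;
  if (s == "logcosh") return L_LOGCOSH;
  Rcpp::stop("unknown loss kind '" + s + "'");
}

// ---- exported entry points ------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_unet_forward(List weights, NumericVector image,
                               int depth) {
  fcube x = as_fcube(image);
  int div = 1 << (depth - 1);
  if (x.n_rows % div || x.n_cols % div)
    Rcpp::stop("input dimensions must be divisible by 2^(depth-1)");
  Net n = parse_net(weights, depth, false);
  Ctx ctx;
  net_forward(n, x, ctx);
  return as_rarray(ctx.out);
}

// Forward + loss (+ gradients) over a batch of images. Loss reduction is
// the mean over all pixels, channels and batch items; RMSE takes the
// square root over the whole batch.
// [[Rcpp::export]]
List cpp_unet_batch(List weights, List images, List targets, int depth,
                    std::string loss, double delta, bool grad) {
  const int B = images.size();
  if (targets.size() != B) Rcpp::stop("images/targets length mismatch");
  Net n = parse_net(weights, depth, grad);
  LossKind kind = loss_kind(loss);
  const float del = (float)delta;

  std::vector<Ctx> ctxs(B);
  std::vector<fcube> ys(B);
  double total = 0.0;
  size_t nelem = 0;
  for (int i = 0; i < B; ++i) {
    fcube x = as_fcube(images[i]);
    ys[i] = as_fcube(targets[i]);
    net_forward(n, x, ctxs[i]);
    const fcube& p = ctxs[i].out;
    nelem += p.n_elem;
    const float* pp = p.memptr();
    const float* tt = ys[i].memptr();
    double acc = 0;
    for (size_t j = 0; j < p.n_elem; ++j) {
      double r = (double)pp[j] - tt[j];
      switch (kind) {
        case L_MSE:
        case L_RMSE: acc += r * r; break;
        case L_HUBER: {
          double a = std::fabs(r);
          acc += a <= del ? 0.5 * r * r : del * a - 0.5 * del * del;
          break;
        }
        case L_LOGCOSH: {
          double a = std::fabs(r);
          acc += a + std::log1p(std::exp(-2 * a)) - std::log(2.0);
          break;
        }
      }
    }
    total += acc;
  }
  double mean_val = total / (double)nelem;
  double loss_val = (kind == L_RMSE) ? std::sqrt(mean_val) : mean_val;

  List out;
  out["loss"] = loss_val;
  if (!grad) return out;

  const double inv_n = 1.0 / (double)nelem;
  for (int i = 0; i < B; ++i) {
    fcube dOut(ctxs[i].out.n_rows, ctxs[i].out.n_cols,
               ctxs[i].out.n_slices);
    const float* pp = ctxs[i].out.memptr();
    const float* tt = ys[i].memptr();
    float* dd = dOut.memptr();
    for (size_t j = 0; j < dOut.n_elem; ++j) {
      double r = (double)pp[j] - tt[j];
      double g;
      switch (kind) {
        case L_MSE: g = 2.0 * r * inv_n; break;
        case L_RMSE:
          g = loss_val > 0 ? r * inv_n / loss_val : 0.0;
          break;
        case L_HUBER:
          g = (std::fabs(r) <= del ? r : (r > 0 ? del : -del)) * inv_n;
          break;
        default: g = std::tanh(r) * inv_n;
      }
      dd[j] = (float)g;
    }
    net_backward(n, ctxs[i], dOut);
  }

  // package gradients mirroring the weight list layout
  List grads;
  char buf[32];
  for (int l = 1; l <= depth; ++l) {
    for (int which = 0; which < 2; ++which) {
      ConvW& L = which ? n.enc2[l - 1] : n.enc1[l - 1];
      snprintf(buf, sizeof(buf), "enc_%d_conv%d", l, which + 1);
      NumericVector gw(L.gW.n_elem);
      std::copy(L.gW.begin(), L.gW.end(), gw.begin());
      gw.attr("dim") = Rcpp::IntegerVector::create(L.k, L.k, L.cin, L.cout);
      grads[std::string(buf)] =
          List::create(Rcpp::Named("W") = gw,
                       Rcpp::Named("b") = NumericVector(L.gb.begin(),
                                                        L.gb.end()));
    }
  }
  for (int j = 0; j < depth - 1; ++j) {
    int l = depth - 1 - j;
    UpW& U = n.up[j];
    NumericVector gw(4 * (size_t)U.cin * U.cout);
    for (int co = 0; co < U.cout; ++co)
      for (int ci = 0; ci < U.cin; ++ci)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di)
            gw[di + 2 * dj + 4 * ci + 4 * (size_t)U.cin * co] =
                U.gW[di + 2 * dj](ci, co);
    gw.attr("dim") = Rcpp::IntegerVector::create(2, 2, U.cin, U.cout);
    snprintf(buf, sizeof(buf), "up_%d", l);
    grads[std::string(buf)] =
        List::create(Rcpp::Named("W") = gw,
                     Rcpp::Named("b") = NumericVector(U.gb.begin(),
                                                      U.gb.end()));
    for (int which = 0; which < 2; ++which) {
      ConvW& L = which ? n.dec2[j] : n.dec1[j];
      snprintf(buf, sizeof(buf), "dec_%d_conv%d", l, which + 1);
      NumericVector gw2(L.gW.n_elem);
      std::copy(L.gW.begin(), L.gW.end(), gw2.begin());
      gw2.attr("dim") = Rcpp::IntegerVector::create(L.k, L.k, L.cin,
                                                    L.cout);
      grads[std::string(buf)] =
          List::create(Rcpp::Named("W") = gw2,
                       Rcpp::Named("b") = NumericVector(L.gb.begin(),
                                                        L.gb.end()));
    }
  }
  {
    ConvW& L = n.fin;
    NumericVector gw(L.gW.n_elem);
    std::copy(L.gW.begin(), L.gW.end(), gw.begin());
    gw.attr("dim") = Rcpp::IntegerVector::create(L.k, L.k, L.cin, L.cout);
    grads["final"] =
        List::create(Rcpp::Named("W") = gw,
                     Rcpp::Named("b") = NumericVector(L.gb.begin(),
                                                      L.gb.end()));
  }
  out["grads"] = grads;
  return out;
}
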