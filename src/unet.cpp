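// Small two-level encoder-decoder segmenter with skip connections,
// trained with Adam on a soft-Dice loss. The whole mini-batch is pushed
// through each layer as one im2col + GEMM so BLAS does the heavy
// lifting; patch extraction is written as contiguous block copies and
// arithmetic runs in single precision, keeping a full training run in
// CPU-minutes on one core. All randomness (weight init, batch order,
// augmentation) lives on the R side; these routines are deterministic.
//
// Layout: a C-channel feature map over an H x W grid for a batch of B
// images is a (C x H*W*B) matrix; image i occupies columns
// [i*H*W, (i+1)*H*W), pixels column-major within the grid (px = r + H*c).
// im2col rows are ordered (kernel offset, channel): row = krow*C + ch.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 3x3 kernel offsets in krow order
static const int KDR[9] = {-1, 0, 1, -1, 0, 1, -1, 0, 1};
static const int KDC[9] = {-1, -1, -1, 0, 0, 0, 1, 1, 1};

// For each kernel offset and each image column, the valid pixel run is
// contiguous in both source and destination, so patch extraction reduces
// to dense submatrix copies; out-of-frame taps stay at the zero fill.
static fmat im2col_batch(const fmat& F, int H, int W, int B) {
  const int C = F.n_rows, HW = H * W;
  fmat col(C * 9, (size_t)HW * B, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dr = KDR[k], dc = KDC[k];
    const int cmin = std::max(0, -dc), cmax = W - 1 - std::max(0, dc);
    const int rlo = std::max(0, -dr), rhi = H - 1 - std::max(0, dr);
    const uword r0 = (uword)k * C, r1 = r0 + C - 1;
    for (int i = 0; i < B; ++i) {
      const size_t off = (size_t)i * HW;
      for (int c = cmin; c <= cmax; ++c) {
        const size_t dst = off + (size_t)H * c + rlo;
        const size_t src = off + (size_t)H * (c + dc) + rlo + dr;
        col.submat(r0, dst, r1, dst + (rhi - rlo)) =
            F.cols(src, src + (rhi - rlo));
      }
    }
  }
  return col;
}

static fmat col2im_batch(const fmat& dcol, int C, int H, int W, int B) {
  const int HW = H * W;
  fmat dF(C, (size_t)HW * B, fill::zeros);
  for (int k = 0; k < 9; ++k) {
    const int dr = KDR[k], dc = KDC[k];
    const int cmin = std::max(0, -dc), cmax = W - 1 - std::max(0, dc);
    const int rlo = std::max(0, -dr), rhi = H - 1 - std::max(0, dr);
    const uword r0 = (uword)k * C, r1 = r0 + C - 1;
    for (int i = 0; i < B; ++i) {
      const size_t off = (size_t)i * HW;
      for (int c = cmin; c <= cmax; ++c) {
        const size_t dst = off + (size_t)H * c + rlo;
        const size_t src = off + (size_t)H * (c + dc) + rlo + dr;
        dF.cols(src, src + (rhi - rlo)) +=
            dcol.submat(r0, dst, r1, dst + (rhi - rlo));
      }
    }
  }
  return dF;
}

static fmat maxpool_batch(const fmat& F, int H, int W, int B, umat& argmax) {
  const int C = F.n_rows, Hp = H / 2, Wp = W / 2;
  fmat out(C, (size_t)Hp * Wp * B);
  argmax.set_size(C, (size_t)Hp * Wp * B);
  for (int i = 0; i < B; ++i) {
    const size_t off = (size_t)i * H * W, offp = (size_t)i * Hp * Wp;
    for (int c = 0; c < Wp; ++c) {
      for (int r = 0; r < Hp; ++r) {
        const size_t px = offp + r + Hp * c;
        const size_t cand[4] = {
          off + 2 * r + H * (2 * c),     off + 2 * r + 1 + H * (2 * c),
          off + 2 * r + H * (2 * c + 1), off + 2 * r + 1 + H * (2 * c + 1)};
        for (int ch = 0; ch < C; ++ch) {
          size_t best = cand[0];
          float bv = F(ch, cand[0]);
          for (int k = 1; k < 4; ++k)
            if (F(ch, cand[k]) > bv) { bv = F(ch, cand[k]); best = cand[k]; }
          out(ch, px) = bv;
          argmax(ch, px) = best;
        }
      }
    }
  }
  return out;
}

static fmat unpool_batch(const fmat& dP, const umat& argmax,
                         size_t ncols_full) {
  fmat dF(dP.n_rows, ncols_full, fill::zeros);
  for (uword j = 0; j < dP.n_cols; ++j)
    for (uword ch = 0; ch < dP.n_rows; ++ch)
      dF(ch, argmax(ch, j)) += dP(ch, j);
  return dF;
}

static fmat upsample_batch(const fmat& F, int Hp, int Wp, int B) {
  const int C = F.n_rows, H = 2 * Hp, W = 2 * Wp;
  fmat out(C, (size_t)H * W * B);
  for (int i = 0; i < B; ++i) {
    const size_t off = (size_t)i * H * W, offp = (size_t)i * Hp * Wp;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        out.col(off + r + H * c) = F.col(offp + (r / 2) + Hp * (c / 2));
  }
  return out;
}

static fmat downsum_batch(const fmat& dU, int H, int W, int B) {
  const int C = dU.n_rows, Hp = H / 2, Wp = W / 2;
  fmat out(C, (size_t)Hp * Wp * B, fill::zeros);
  for (int i = 0; i < B; ++i) {
    const size_t off = (size_t)i * H * W, offp = (size_t)i * Hp * Wp;
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r)
        out.col(offp + (r / 2) + Hp * (c / 2)) += dU.col(off + r + H * c);
  }
  return out;
}

struct Weights {
  fmat W1, W2, W3, W4, W5, W6;
  fvec b1, b2, b3, b4, b5, b6;
};

static Weights unpack(const Rcpp::List& w) {
  Weights p;
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  p.b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["b1"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
  p.b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["b2"]));
  p.W3 = conv_to<fmat>::from(Rcpp::as<mat>(w["W3"]));
  p.b3 = conv_to<fvec>::from(Rcpp::as<vec>(w["b3"]));
  p.W4 = conv_to<fmat>::from(Rcpp::as<mat>(w["W4"]));
  p.b4 = conv_to<fvec>::from(Rcpp::as<vec>(w["b4"]));
  p.W5 = conv_to<fmat>::from(Rcpp::as<mat>(w["W5"]));
  p.b5 = conv_to<fvec>::from(Rcpp::as<vec>(w["b5"]));
  p.W6 = conv_to<fmat>::from(Rcpp::as<mat>(w["W6"]));
  p.b6 = conv_to<fvec>::from(Rcpp::as<vec>(w["b6"]));
  return p;
}

static Rcpp::List pack(const Weights& p) {
  auto d = [](const fmat& x) { return conv_to<mat>::from(x); };
  auto dv = [](const fvec& x) { return conv_to<vec>::from(x); };
  return Rcpp::List::create(
      Rcpp::Named("W1") = d(p.W1), Rcpp::Named("b1") = dv(p.b1),
      Rcpp::Named("W2") = d(p.W2), Rcpp::Named("b2") = dv(p.b2),
      Rcpp::Named("W3") = d(p.W3), Rcpp::Named("b3") = dv(p.b3),
      Rcpp::Named("W4") = d(p.W4), Rcpp::Named("b4") = dv(p.b4),
      Rcpp::Named("W5") = d(p.W5), Rcpp::Named("b5") = dv(p.b5),
      Rcpp::Named("W6") = d(p.W6), Rcpp::Named("b6") = dv(p.b6));
}

struct Cache {
  fmat COL1, E1, P1, COL2, E2, P2, COL3, E3, C2, COL4, D2, C1, COL5, D1;
  umat arg1, arg2;
  fmat prob;  // (HW x B)
};

static fmat conv_relu(const fmat& col, const fmat& W, const fvec& b) {
  fmat a = W * col;
  a.each_col() += b;
  a.transform([](float x) { return x > 0.0f ? x : 0.0f; });
  return a;
}

// X: (3*HW x B) batch input; returns probabilities (HW x B)
static fmat forward_batch(const fmat& X, int H, int W, const Weights& w,
                          Cache* cc) {
  const int HW = H * W, B = X.n_cols;
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;

  fmat F0(3, (size_t)HW * B);
  for (int i = 0; i < B; ++i)
    for (int ch = 0; ch < 3; ++ch)
      F0.submat(ch, (size_t)i * HW, ch, (size_t)(i + 1) * HW - 1) =
          X.submat((size_t)ch * HW, i, (size_t)(ch + 1) * HW - 1, i).t();

  fmat COL1 = im2col_batch(F0, H, W, B);
  fmat E1 = conv_relu(COL1, w.W1, w.b1);
  umat arg1;
  fmat P1 = maxpool_batch(E1, H, W, B, arg1);

  fmat COL2 = im2col_batch(P1, H2, W2, B);
  fmat E2 = conv_relu(COL2, w.W2, w.b2);
  umat arg2;
  fmat P2 = maxpool_batch(E2, H2, W2, B, arg2);

  fmat COL3 = im2col_batch(P2, H4, W4, B);
  fmat E3 = conv_relu(COL3, w.W3, w.b3);

  fmat C2 = join_cols(E2, upsample_batch(E3, H4, W4, B));
  fmat COL4 = im2col_batch(C2, H2, W2, B);
  fmat D2 = conv_relu(COL4, w.W4, w.b4);

  fmat C1 = join_cols(E1, upsample_batch(D2, H2, W2, B));
  fmat COL5 = im2col_batch(C1, H, W, B);
  fmat D1 = conv_relu(COL5, w.W5, w.b5);

  fmat Z = w.W6 * D1;
  Z += w.b6(0);
  fmat prob = reshape(1.0f / (1.0f + exp(-Z.row(0).t())), HW, B);

  if (cc) {
    cc->COL1 = std::move(COL1); cc->E1 = std::move(E1);
    cc->P1 = std::move(P1); cc->COL2 = std::move(COL2);
    cc->E2 = std::move(E2); cc->P2 = std::move(P2);
    cc->COL3 = std::move(COL3); cc->E3 = std::move(E3);
    cc->C2 = std::move(C2); cc->COL4 = std::move(COL4);
    cc->D2 = std::move(D2); cc->C1 = std::move(C1);
    cc->COL5 = std::move(COL5); cc->D1 = std::move(D1);
    cc->arg1 = std::move(arg1); cc->arg2 = std::move(arg2);
    cc->prob = prob;
  }
  return prob;
}

// per-image soft Dice; fills dP (HW x B) with the mean-loss gradient
static double soft_dice_batch(const fmat& P, const fmat& T, fmat& dP) {
  const double eps = 1e-6;
  double total = 0.0;
  dP.set_size(size(P));
  for (uword i = 0; i < P.n_cols; ++i) {
    const fvec p = P.col(i), t = T.col(i);
    const double inter = dot(p, t), denom = accu(p) + accu(t) + eps;
    total += 1.0 - (2.0 * inter + eps) / denom;
    dP.col(i) = conv_to<fvec>::from(
        -(2.0 * conv_to<vec>::from(t) * denom - (2.0 * inter + eps)) /
        (denom * denom) / (double)P.n_cols);
  }
  return total / (double)P.n_cols;
}

static void relu_mask(fmat& grad, const fmat& act) {
  for (uword j = 0; j < grad.n_elem; ++j)
    if (act[j] <= 0.0f) grad[j] = 0.0f;
}

static void backward_batch(const Cache& cc, const fmat& dP, int H, int W,
                           const Weights& w, Weights& g) {
  const int B = dP.n_cols;
  const int H2 = H / 2, W2 = W / 2, H4 = H / 4, W4 = W / 4;
  const int c1 = w.W1.n_rows, c2 = w.W2.n_rows;

  fmat dsig = dP % cc.prob % (1.0f - cc.prob);
  frowvec dZ = vectorise(dsig).t();

  g.W6 += dZ * cc.D1.t();
  g.b6(0) += accu(dZ);
  fmat dD1 = w.W6.t() * dZ;
  relu_mask(dD1, cc.D1);

  g.W5 += dD1 * cc.COL5.t();
  g.b5 += sum(dD1, 1);
  fmat dC1 = col2im_batch(w.W5.t() * dD1, cc.C1.n_rows, H, W, B);

  fmat dE1 = dC1.rows(0, c1 - 1);
  fmat dD2 = downsum_batch(dC1.rows(c1, dC1.n_rows - 1), H, W, B);
  relu_mask(dD2, cc.D2);

  g.W4 += dD2 * cc.COL4.t();
  g.b4 += sum(dD2, 1);
  fmat dC2 = col2im_batch(w.W4.t() * dD2, cc.C2.n_rows, H2, W2, B);

  fmat dE2 = dC2.rows(0, c2 - 1);
  fmat dE3 = downsum_batch(dC2.rows(c2, dC2.n_rows - 1), H2, W2, B);
  relu_mask(dE3, cc.E3);

  g.W3 += dE3 * cc.COL3.t();
  g.b3 += sum(dE3, 1);
  fmat dP2 = col2im_batch(w.W3.t() * dE3, c2, H4, W4, B);
  dE2 += unpool_batch(dP2, cc.arg2, cc.E2.n_cols);
  relu_mask(dE2, cc.E2);

  g.W2 += dE2 * cc.COL2.t();
  g.b2 += sum(dE2, 1);
  fmat dP1 = col2im_batch(w.W2.t() * dE2, c1, H2, W2, B);
  dE1 += unpool_batch(dP1, cc.arg1, cc.E1.n_cols);
  relu_mask(dE1, cc.E1);

  g.W1 += dE1 * cc.COL1.t();
  g.b1 += sum(dE1, 1);
}

// [[Rcpp::export]]
arma::mat cpp_unet_predict(const arma::mat& X, int H, int W,
                           const Rcpp::List& weights) {
  Weights w = unpack(weights);
  fmat Xf = conv_to<fmat>::from(X);
  const uword chunk = 32;  // bound the im2col working set
  fmat out(H * W, Xf.n_cols);
  for (uword start = 0; start < Xf.n_cols; start += chunk) {
    const uword stop = std::min<uword>(start + chunk, Xf.n_cols) - 1;
    out.cols(start, stop) =
        forward_batch(Xf.cols(start, stop), H, W, w, nullptr);
  }
  return conv_to<mat>::from(out);
}

static void adam_update(fmat& w, fmat& m, fmat& v, const fmat& g, double lr,
                        double t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  w -= (float)lr * (m / c1) / (sqrt(v / c2) + eps);
}

static void adam_update_vec(fvec& w, fvec& m, fvec& v, const fvec& g,
                            double lr, double t) {
  fmat wm = w, mm = m, vm = v;
  adam_update(wm, mm, vm, fmat(g), lr, t);
  w = wm.col(0); m = mm.col(0); v = vm.col(0);
}

// One epoch of mini-batch Adam on soft-Dice loss. `order` is a 1-based
// permutation of columns (drawn in R); consecutive groups of
// `batch_size` form the mini-batches. Returns the updated optimiser
// state and the mean per-image loss.
// [[Rcpp::export]]
Rcpp::List cpp_unet_train_epoch(const arma::mat& X, const arma::mat& Y,
                                int H, int W, const Rcpp::List& state,
                                double lr, int batch_size,
                                const arma::uvec& order) {
  Weights w = unpack(state["weights"]);
  Weights m = unpack(state["adam_m"]), v = unpack(state["adam_v"]);
  double step = Rcpp::as<double>(state["step"]);

  fmat Xf = conv_to<fmat>::from(X);
  fmat Yf = conv_to<fmat>::from(Y);

  const uword n = order.n_elem;
  double total_loss = 0.0;
  uword n_batches = 0;

  for (uword start = 0; start < n; start += batch_size) {
    const uword stop = std::min<uword>(start + batch_size, n) - 1;
    const uvec idx = order.subvec(start, stop) - 1;
    fmat Xb = Xf.cols(idx), Yb = Yf.cols(idx);

    Cache cc;
    fmat P = forward_batch(Xb, H, W, w, &cc);
    fmat dP;
    total_loss += soft_dice_batch(P, Yb, dP);
    ++n_batches;

    Weights g;
    g.W1 = zeros<fmat>(size(w.W1)); g.b1 = zeros<fvec>(size(w.b1));
    g.W2 = zeros<fmat>(size(w.W2)); g.b2 = zeros<fvec>(size(w.b2));
    g.W3 = zeros<fmat>(size(w.W3)); g.b3 = zeros<fvec>(size(w.b3));
    g.W4 = zeros<fmat>(size(w.W4)); g.b4 = zeros<fvec>(size(w.b4));
    g.W5 = zeros<fmat>(size(w.W5)); g.b5 = zeros<fvec>(size(w.b5));
    g.W6 = zeros<fmat>(size(w.W6)); g.b6 = zeros<fvec>(size(w.b6));
    backward_batch(cc, dP, H, W, w, g);

    step += 1.0;
    adam_update(w.W1, m.W1, v.W1, g.W1, lr, step);
    adam_update(w.W2, m.W2, v.W2, g.W2, lr, step);
    adam_update(w.W3, m.W3, v.W3, g.W3, lr, step);
    adam_update(w.W4, m.W4, v.W4, g.W4, lr, step);
    adam_update(w.W5, m.W5, v.W5, g.W5, lr, step);
    adam_update(w.W6, m.W6, v.W6, g.W6, lr, step);
    adam_update_vec(w.b1, m.b1, v.b1, g.b1, lr, step);
    adam_update_vec(w.b2, m.b2, v.b2, g.b2, lr, step);
    adam_update_vec(w.b3, m.b3, v.b3, g.b3, lr, step);
    adam_update_vec(w.b4, m.b4, v.b4, g.b4, lr, step);
    adam_update_vec(w.b5, m.b5, v.b5, g.b5, lr, step);
    adam_update_vec(w.b6, m.b6, v.b6, g.b6, lr, step);
  }

  return Rcpp::List::create(
      Rcpp::Named("state") = Rcpp::List::create(
          Rcpp::Named("weights") = pack(w), Rcpp::Named("adam_m") = pack(m),
          Rcpp::Named("adam_v") = pack(v), Rcpp::Named("step") = step),
      Rcpp::Named("loss") = total_loss / (double)n_batches);
}
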