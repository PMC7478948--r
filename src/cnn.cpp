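// Residual U-shaped 2D convolutional network for patchwise lesion
// segmentation, with hand-written forward/backward passes.  Convolutions are
// realised as im2col + BLAS gemm; optimisation is Adam on a pixelwise
// binary cross-entropy (with-logits) loss.
//
// Topology for `depth` resolution levels and C base channels
// (C_l = C * 2^l):
//   in  : 3x3 conv 1 -> C_0, ReLU
//   enc : per level, one residual unit  y = relu(x + conv3x3(x))
//   down: 3x3 stride-2 conv C_l -> C_{l+1}, ReLU
//   up  : 1x1 projection C_l -> C_{l-1}, nearest x2 upsample,
//         3x3 conv, + encoder skip, ReLU, then one residual unit
//   out : 1x1 conv C_0 -> 1 (logits)
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Conv {
  mat W;  vec b;
  mat gW; vec gb;
  mat mW, vW; vec mb, vb;
  int Cin, Cout, k, stride;
  void init(int cin, int cout, int kk, int ss, std::mt19937 &rng,
            double bias0 = 0.0) {
    Cin = cin; Cout = cout; k = kk; stride = ss;
    const int fan = cin * kk * kk;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan));
    W.set_size(cout, fan);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b = vec(cout, fill::value(bias0));
    gW = zeros<mat>(cout, fan); gb = zeros<vec>(cout);
    mW = zeros<mat>(cout, fan); vW = zeros<mat>(cout, fan);
    mb = zeros<vec>(cout);      vb = zeros<vec>(cout);
  }
  void zero_grad() { gW.zeros(); gb.zeros(); }
  void adam(double lr, double b1, double b2, double eps, int t) {
    const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    mW = b1 * mW + (1 - b1) * gW;  vW = b2 * vW + (1 - b2) * square(gW);
    W -= lr * (mW / c1) / (sqrt(vW / c2) + eps);
    mb = b1 * mb + (1 - b1) * gb;  vb = b2 * vb + (1 - b2) * square(gb);
    b -= lr * (mb / c1) / (sqrt(vb / c2) + eps);
  }
};

// F is (C x H*W), pixel index p = i + j*H.  3x3 kernel, pad 1, stride s.
// cols is (C*9 x Ho*Wo), row r = c*9 + kj*3 + ki.
static void im2col3(const mat &F, int H, int W, int s, mat &cols) {
  const int C = F.n_rows, Ho = H / s, Wo = W / s;
  cols.zeros(C * 9, (uword)Ho * Wo);
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io) {
      double *cp = cols.colptr(io + (uword)jo * Ho);
      for (int kj = 0; kj < 3; ++kj) {
        const int j = jo * s - 1 + kj;
        if (j < 0 || j >= W) continue;
        for (int ki = 0; ki < 3; ++ki) {
          const int i = io * s - 1 + ki;
          if (i < 0 || i >= H) continue;
          const double *fp = F.colptr(i + (uword)j * H);
          for (int c = 0; c < C; ++c) cp[c * 9 + kj * 3 + ki] = fp[c];
        }
      }
    }
}

// scatter-add transpose of im2col3: cols (C*9 x Ho*Wo) -> F (C x H*W)
static void col2im3(const mat &cols, int H, int W, int s, mat &F) {
  const int C = F.n_rows, Ho = H / s, Wo = W / s;
  F.zeros();
  for (int jo = 0; jo < Wo; ++jo)
    for (int io = 0; io < Ho; ++io) {
      const double *cp = cols.colptr(io + (uword)jo * Ho);
      for (int kj = 0; kj < 3; ++kj) {
        const int j = jo * s - 1 + kj;
        if (j < 0 || j >= W) continue;
        for (int ki = 0; ki < 3; ++ki) {
          const int i = io * s - 1 + ki;
          if (i < 0 || i >= H) continue;
          double *fp = F.colptr(i + (uword)j * H);
          for (int c = 0; c < C; ++c) fp[c] += cp[c * 9 + kj * 3 + ki];
        }
      }
    }
}

static mat upsample2(const mat &P, int H, int W) { // H,W: coarse grid
  const int C = P.n_rows, H2 = 2 * H, W2 = 2 * W;
  mat U(C, (uword)H2 * W2);
  for (int j = 0; j < W2; ++j)
    for (int i = 0; i < H2; ++i)
      U.col(i + (uword)j * H2) = P.col((i / 2) + (uword)(j / 2) * H);
  return U;
}

static mat downsum2(const mat &dU, int H, int W) { // H,W: coarse grid
  const int C = dU.n_rows, H2 = 2 * H;
  mat dP(C, (uword)H * W, fill::zeros);
  const int W2 = 2 * W;
  for (int j = 0; j < W2; ++j)
    for (int i = 0; i < H2; ++i)
      dP.col((i / 2) + (uword)(j / 2) * H) += dU.col(i + (uword)j * H2);
  return dP;
}

struct Net {
  int depth, base;
  Conv in_c, out_c;
  std::vector<Conv> enc, down, proj, up, dec; // down/proj/up/dec sized depth-1
  void build(int d, int c, std::mt19937 &rng) {
    depth = d; base = c;
    in_c.init(1, c, 3, 1, rng);
    enc.resize(d); down.resize(d - 1);
    proj.resize(d - 1); up.resize(d - 1); dec.resize(d - 1);
    for (int l = 0; l < d; ++l) enc[l].init(c << l, c << l, 3, 1, rng);
    for (int l = 0; l < d - 1; ++l) down[l].init(c << l, c << (l + 1), 3, 2, rng);
    for (int l = 1; l < d; ++l) { // stored at index l-1
      proj[l - 1].init(c << l, c << (l - 1), 1, 1, rng);
      up[l - 1].init(c << (l - 1), c << (l - 1), 3, 1, rng);
      dec[l - 1].init(c << (l - 1), c << (l - 1), 3, 1, rng);
    }
    out_c.init(c, 1, 1, 1, rng, -2.0); // bias toward background prior
  }
  std::vector<Conv *> all() {
    std::vector<Conv *> v;
    v.push_back(&in_c);
    for (auto &x : enc) v.push_back(&x);
    for (auto &x : down) v.push_back(&x);
    for (auto &x : proj) v.push_back(&x);
    for (auto &x : up) v.push_back(&x);
    for (auto &x : dec) v.push_back(&x);
    v.push_back(&out_c);
    return v;
  }
};

struct Tape {
  mat x_in;                       // 1 x HW
  mat in_s;                       // pre-relu of input conv
  std::vector<mat> enc_in, enc_s; // residual-unit input / pre-relu sum
  std::vector<mat> down_s;        // pre-relu of down convs
  std::vector<mat> dproj_in, dup_u, dup_s, ddec_in, ddec_s; // decoder tapes
  mat xfinal;                     // C0 x HW, input to out conv
  mat z;                          // logits 1 x HW
};

static mat conv_fwd(Conv &cv, const mat &X, int H, int W, mat &colbuf) {
  if (cv.k == 1) { mat O = cv.W * X; O.each_col() += cv.b; return O; }
  im2col3(X, H, W, cv.stride, colbuf);
  mat O = cv.W * colbuf;
  O.each_col() += cv.b;
  return O;
}

// accumulate gradients; returns gradient wrt input
static mat conv_bwd(Conv &cv, const mat &X, const mat &dOut, int H, int W,
                    mat &colbuf) {
  if (cv.k == 1) {
    cv.gW += dOut * X.t();
    cv.gb += sum(dOut, 1);
    return cv.W.t() * dOut;
  }
  im2col3(X, H, W, cv.stride, colbuf);
  cv.gW += dOut * colbuf.t();
  cv.gb += sum(dOut, 1);
  mat dcols = cv.W.t() * dOut;
  mat dX(X.n_rows, X.n_cols);
  col2im3(dcols, H, W, cv.stride, dX);
  return dX;
}

static void forward(Net &net, const vec &x, int H, int W, Tape &tp) {
  const int L = net.depth;
  mat colbuf;
  tp.x_in = mat(x.t());
  tp.in_s = conv_fwd(net.in_c, tp.x_in, H, W, colbuf);
  tp.enc_in.assign(L, mat()); tp.enc_s.assign(L, mat());
  tp.down_s.assign(L - 1, mat());
  tp.dproj_in.assign(L - 1, mat()); tp.dup_u.assign(L - 1, mat());
  tp.dup_s.assign(L - 1, mat()); tp.ddec_in.assign(L - 1, mat());
  tp.ddec_s.assign(L - 1, mat());
  mat a = clamp(tp.in_s, 0.0, datum::inf);
  int h = H, w = W;
  std::vector<mat> e(L);
  for (int l = 0; l < L; ++l) {
    tp.enc_in[l] = a;
    tp.enc_s[l] = a + conv_fwd(net.enc[l], a, h, w, colbuf);
    e[l] = clamp(tp.enc_s[l], 0.0, datum::inf);
    if (l < L - 1) {
      tp.down_s[l] = conv_fwd(net.down[l], e[l], h, w, colbuf);
      a = clamp(tp.down_s[l], 0.0, datum::inf);
      h /= 2; w /= 2;
    }
  }
  mat xcur = e[L - 1]; // at level L-1, size h x w
  for (int l = L - 1; l >= 1; --l) {
    const int li = l - 1;
    tp.dproj_in[li] = xcur;
    mat p = net.proj[li].W * xcur; p.each_col() += net.proj[li].b;
    tp.dup_u[li] = upsample2(p, h, w);
    h *= 2; w *= 2;
    // encoder skip added after the post-upsample conv, before the ReLU
    tp.dup_s[li] = conv_fwd(net.up[li], tp.dup_u[li], h, w, colbuf) + e[l - 1];
    mat c = clamp(tp.dup_s[li], 0.0, datum::inf);
    tp.ddec_in[li] = c;
    tp.ddec_s[li] = c + conv_fwd(net.dec[li], c, h, w, colbuf);
    xcur = clamp(tp.ddec_s[li], 0.0, datum::inf);
  }
  tp.xfinal = xcur;
  tp.z = net.out_c.W * xcur; tp.z.each_col() += net.out_c.b;
}

// dz: gradient wrt logits (1 x HW); accumulates parameter gradients
static void backward_full(Net &net, Tape &tp, const mat &dz, int H, int W) {
  const int L = net.depth;
  mat colbuf;
  std::vector<mat> dE(L);
  std::vector<int> hh(L), ww(L);
  hh[0] = H; ww[0] = W;
  for (int l = 1; l < L; ++l) { hh[l] = hh[l - 1] / 2; ww[l] = ww[l - 1] / 2; }
  mat dx = conv_bwd(net.out_c, tp.xfinal, dz, H, W, colbuf);
  for (int l = 1; l <= L - 1; ++l) {
    const int li = l - 1;
    const int h = hh[l - 1], w = ww[l - 1];
    mat ds = dx % conv_to<mat>::from(tp.ddec_s[li] > 0);
    mat dc = ds + conv_bwd(net.dec[li], tp.ddec_in[li], ds, h, w, colbuf);
    mat dus = dc % conv_to<mat>::from(tp.dup_s[li] > 0);
    if (dE[l - 1].n_elem == 0) dE[l - 1] = dus; else dE[l - 1] += dus;
    mat du = conv_bwd(net.up[li], tp.dup_u[li], dus, h, w, colbuf);
    mat dp = downsum2(du, hh[l], ww[l]);
    net.proj[li].gW += dp * tp.dproj_in[li].t();
    net.proj[li].gb += sum(dp, 1);
    dx = net.proj[li].W.t() * dp;
  }
  if (dE[L - 1].n_elem == 0) dE[L - 1] = dx; else dE[L - 1] += dx;
  mat dtmp = dE[L - 1];
  for (int l = L - 1; l >= 0; --l) {
    const int h = hh[l], w = ww[l];
    mat ds = dtmp % conv_to<mat>::from(tp.enc_s[l] > 0);
    mat din = ds + conv_bwd(net.enc[l], tp.enc_in[l], ds, h, w, colbuf);
    if (l > 0) {
      mat dd = din % conv_to<mat>::from(tp.down_s[l - 1] > 0);
      mat elm1 = clamp(tp.enc_s[l - 1], 0.0, datum::inf);
      mat dprev = conv_bwd(net.down[l - 1], elm1, dd, hh[l - 1], ww[l - 1], colbuf);
      dtmp = dprev;
      if (dE[l - 1].n_elem) dtmp += dE[l - 1];
    } else {
      mat din0 = din % conv_to<mat>::from(tp.in_s > 0);
      conv_bwd(net.in_c, tp.x_in, din0, h, w, colbuf);
    }
  }
}

static double softplus(double z) {
  return std::max(z, 0.0) + std::log1p(std::exp(-std::fabs(z)));
}

static void pack_conv(Rcpp::List &out, const std::string &name, const Conv &c) {
  out[name + "_W"] = Rcpp::wrap(c.W);
  out[name + "_b"] = Rcpp::wrap(c.b);
}
static void unpack_conv(const Rcpp::List &in, const std::string &name, Conv &c,
                        int cin, int cout, int k, int s) {
  c.W = Rcpp::as<mat>(in[name + "_W"]);
  c.b = Rcpp::as<vec>(in[name + "_b"]);
  c.Cin = cin; c.Cout = cout; c.k = k; c.stride = s;
}

static Rcpp::List pack_net(Net &net) {
  Rcpp::List out;
  pack_conv(out, "in", net.in_c);
  for (int l = 0; l < net.depth; ++l)
    pack_conv(out, "enc" + std::to_string(l), net.enc[l]);
  for (int l = 0; l < net.depth - 1; ++l) {
    pack_conv(out, "down" + std::to_string(l), net.down[l]);
    pack_conv(out, "proj" + std::to_string(l), net.proj[l]);
    pack_conv(out, "up" + std::to_string(l), net.up[l]);
    pack_conv(out, "dec" + std::to_string(l), net.dec[l]);
  }
  pack_conv(out, "out", net.out_c);
  return out;
}

static Net unpack_net(const Rcpp::List &params, int depth, int base) {
  Net net; net.depth = depth; net.base = base;
  net.enc.resize(depth); net.down.resize(depth - 1);
  net.proj.resize(depth - 1); net.up.resize(depth - 1); net.dec.resize(depth - 1);
  unpack_conv(params, "in", net.in_c, 1, base, 3, 1);
  for (int l = 0; l < depth; ++l)
    unpack_conv(params, "enc" + std::to_string(l), net.enc[l],
                base << l, base << l, 3, 1);
  for (int l = 0; l < depth - 1; ++l) {
    unpack_conv(params, "down" + std::to_string(l), net.down[l],
                base << l, base << (l + 1), 3, 2);
    unpack_conv(params, "proj" + std::to_string(l), net.proj[l],
                base << (l + 1), base << l, 1, 1);
    unpack_conv(params, "up" + std::to_string(l), net.up[l],
                base << l, base << l, 3, 1);
    unpack_conv(params, "dec" + std::to_string(l), net.dec[l],
                base << l, base << l, 3, 1);
  }
  unpack_conv(params, "out", net.out_c, base, 1, 1, 1);
  return net;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::cube &X, const arma::cube &Y, int depth,
                         int base_ch, double lr, int epochs, int batch,
                         int seed) {
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  if (H % (1 << (depth - 1)) || W % (1 << (depth - 1)))
    Rcpp::stop("patch size must be divisible by 2^(depth-1)");
  std::mt19937 rng((unsigned)seed);
  Net net; net.build(depth, base_ch, rng);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::vector<double> curve;
  Tape tp;
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0; long ep_pix = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      const int bsz = std::min(batch, N - b0);
      for (auto *c : net.all()) c->zero_grad();
      const double norm = 1.0 / ((double)bsz * H * W);
      for (int bi = 0; bi < bsz; ++bi) {
        const int s = order[b0 + bi];
        vec x = vectorise(X.slice(s));
        vec y = vectorise(Y.slice(s));
        forward(net, x, H, W, tp);
        const rowvec zr = tp.z.row(0);
        double loss = 0.0;
        mat dz(1, zr.n_elem);
        for (uword p = 0; p < zr.n_elem; ++p) {
          loss += softplus(zr(p)) - y(p) * zr(p);
          dz(0, p) = (1.0 / (1.0 + std::exp(-zr(p))) - y(p)) * norm;
        }
        if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
        ep_loss += loss; ep_pix += (long)H * W;
        backward_full(net, tp, dz, H, W);
      }
      ++t;
      for (auto *c : net.all()) c->adam(lr, 0.9, 0.999, 1e-8, t);
    }
    curve.push_back(ep_loss / ep_pix);
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List out = pack_net(net);
  return Rcpp::List::create(Rcpp::Named("params") = out,
                            Rcpp::Named("loss_curve") = curve);
}

// [[Rcpp::export]]
arma::cube cpp_cnn_predict(const Rcpp::List &params, const arma::cube &X,
                           int depth, int base_ch) {
  Net net = unpack_net(params, depth, base_ch);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  cube P(H, W, N);
  Tape tp;
  for (int s = 0; s < N; ++s) {
    vec x = vectorise(X.slice(s));
    forward(net, x, H, W, tp);
    const rowvec zr = tp.z.row(0);
    vec pr(zr.n_elem);
    for (uword p = 0; p < zr.n_elem; ++p)
      pr(p) = 1.0 / (1.0 + std::exp(-zr(p)));
    P.slice(s) = reshape(pr, H, W);
  }
  return P;
}
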