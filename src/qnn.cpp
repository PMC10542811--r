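// Tape-interpreted encoder-decoder segmentation network with binarized /
// quantized variants and custom backpropagation.
//
// The R side builds a linear "tape" of ops (see build_model); this file
// executes it forward (train/eval) and backward.  Three variants share the
// tape vocabulary:
//   fp   : plain conv + BatchNorm + ReLU
//   bfp  : binary convs (RSign inputs, mean-thresholded sign weights),
//          BatchNorm, PReLU with real-valued parameters
//   bq   : as bfp, but every remaining real-valued quantity is fake-quantized
//          in the forward pass (4-bit RSign thresholds, 2/4-bit PReLU
//          parameters, power-of-two shift norm with 4-bit bias, 4-bit first
//          layer, unsigned q-bit skip connections with per-connection shift).
// Backward uses straight-through estimators (clip-aware for clamped codes);
// the sign nonlinearity uses either the clipped pass-through (STE) or the
// tanh(2x) surrogate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double BN_EPS = 1e-5;
constexpr double BN_MOMENTUM = 0.1;

struct OpCache {
  std::vector<arma::cube> in;    // op input (per sample), when needed
  std::vector<arma::cube> aux;   // secondary tensor (xhat, masks, ...)
  arma::vec v1, v2;              // per-channel stats (invstd, ...)
  arma::mat m1;                  // effective (binarized/quantized) pw weight
  arma::mat aux2;                // gathered batch matrix (pw input)
  arma::cube c1;                 // effective dw/stem weight
};

inline arma::cube get_cube(SEXP s) {
  NumericVector a(s);
  IntegerVector d = a.attr("dim");
  return arma::cube(a.begin(), d[0], d[1], d.size() >= 3 ? d[2] : 1, false);
}
inline arma::mat get_mat(SEXP s) {
  NumericVector a(s);
  IntegerVector d = a.attr("dim");
  return arma::mat(a.begin(), d[0], d[1], false);
}
inline arma::vec get_vec(SEXP s) {
  NumericVector a(s);
  return arma::vec(a.begin(), a.size(), false);
}

inline arma::mat flat(arma::cube& c) {  // (H*W) x C view over cube memory
  return arma::mat(c.memptr(), c.n_rows * c.n_cols, c.n_slices, false);
}

// quantization helpers -------------------------------------------------------
inline double qclamp(double code, double lo, double hi, bool* clipped) {
  if (code < lo) { *clipped = true; return lo; }
  if (code > hi) { *clipped = true; return hi; }
  return code;
}

// sign with the printed tie rule: x > t -> +1, x <= t -> -1
inline double rsign1(double x, double t) { return x > t ? 1.0 : -1.0; }

// per-output-channel mean-threshold binarization of a weight column
inline void binarize_col(const double* w, double* out, int n) {
  double mu = 0; for (int i = 0; i < n; ++i) mu += w[i];
  mu /= n;
  for (int i = 0; i < n; ++i) out[i] = w[i] > mu ? 1.0 : -1.0;
}

// dw 3x3 conv, padding 1, one channel
void dw3_forward(const arma::mat& in, arma::mat& out, const double* w9,
                 int stride) {
  const int H = in.n_rows, W = in.n_cols;
  const int Ho = out.n_rows, Wo = out.n_cols;
  if (stride == 1) {              // vectorized: 9 shifted submatrix axpys
    arma::mat P(H + 2, W + 2, arma::fill::zeros);
    P.submat(1, 1, H, W) = in;
    out.zeros();
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di)
        out += w9[di + 3 * dj] * P.submat(di, dj, di + H - 1, dj + W - 1);
    return;
  }
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      double acc = 0;
      const int ib = io * stride - 1, jb = jo * stride - 1;
      for (int dj = 0; dj < 3; ++dj) {
        const int j = jb + dj;
        if (j < 0 || j >= W) continue;
        for (int di = 0; di < 3; ++di) {
          const int i = ib + di;
          if (i < 0 || i >= H) continue;
          acc += in.at(i, j) * w9[di + 3 * dj];
        }
      }
      out.at(io, jo) = acc;
    }
  }
}

void dw3_backward(const arma::mat& in, const arma::mat& g, arma::mat& din,
                  const double* w9, double* gw9, int stride) {
  const int H = in.n_rows, W = in.n_cols;
  const int Ho = g.n_rows, Wo = g.n_cols;
  if (stride == 1) {
    arma::mat P(H + 2, W + 2, arma::fill::zeros);
    P.submat(1, 1, H, W) = in;
    arma::mat DP(H + 2, W + 2, arma::fill::zeros);
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        DP.submat(di, dj, di + H - 1, dj + W - 1) += w9[di + 3 * dj] * g;
        gw9[di + 3 * dj] +=
            arma::accu(g % P.submat(di, dj, di + H - 1, dj + W - 1));
      }
    din += DP.submat(1, 1, H, W);
    return;
  }
  for (int jo = 0; jo < Wo; ++jo) {
    for (int io = 0; io < Ho; ++io) {
      const double go = g.at(io, jo);
      if (go == 0) continue;
      const int ib = io * stride - 1, jb = jo * stride - 1;
      for (int dj = 0; dj < 3; ++dj) {
        const int j = jb + dj;
        if (j < 0 || j >= W) continue;
        for (int di = 0; di < 3; ++di) {
          const int i = ib + di;
          if (i < 0 || i >= H) continue;
          din.at(i, j) += go * w9[di + 3 * dj];
          gw9[di + 3 * dj] += go * in.at(i, j);
        }
      }
    }
  }
}

inline int out_size(int n, int stride) { return (n - 1) / stride + 1; }

struct Engine {
  List params, buffers, tape;
  int surrogate;        // 0 = ste, 1 = tanh(2x)
  bool train;
  std::vector<OpCache> cache;
  std::vector<arma::cube> skip_store;        // quantized/stored skip values
  std::vector<arma::cube> skip_pre;          // pre-quantization skip inputs
  std::vector<int> skip_slot_op;             // op index of skip_save per slot
  List grads;                                // accumulated weight grads
  std::map<std::string, double*> grad_ptr;
  std::map<std::string, int> grad_len;

  Engine(List params_, List buffers_, List tape_, int surrogate_, bool train_)
      : params(params_), buffers(buffers_), tape(tape_),
        surrogate(surrogate_), train(train_) {}

  SEXP par(const std::string& nm) {
    if (!params.containsElementNamed(nm.c_str()))
      stop("missing parameter: %s", nm.c_str());
    return params[nm];
  }
  SEXP buf(const std::string& nm) {
    if (!buffers.containsElementNamed(nm.c_str()))
      stop("missing buffer: %s", nm.c_str());
    return buffers[nm];
  }
  double bufval(const std::string& nm) { return as<double>(buf(nm)); }

  void init_grads() {
    CharacterVector nms = params.names();
    grads = List(params.size());
    grads.names() = nms;
    for (int i = 0; i < params.size(); ++i) {
      NumericVector p = params[i];
      NumericVector g(p.size());
      g.attr("dim") = p.attr("dim");
      grads[i] = g;
      std::string nm = as<std::string>(nms[i]);
      grad_ptr[nm] = REAL(grads[i]);
      grad_len[nm] = p.size();
    }
  }

  // ---- forward -------------------------------------------------------------
  // batch: modified in place layer by layer
  void forward(std::vector<arma::cube>& batch) {
    const int nops = tape.size();
    cache.assign(nops, OpCache());
    int max_slot = 0;
    for (int t = 0; t < nops; ++t) {
      List op = tape[t];
      if (as<std::string>(op["op"]) == "skip_save")
        max_slot = std::max(max_slot, as<int>(op["slot"]));
    }
    skip_store.assign(max_slot, arma::cube());
    skip_pre.assign(max_slot, arma::cube());
    skip_slot_op.assign(max_slot, -1);
    // per-slot per-sample storage
    skip_batch.assign(max_slot, std::vector<arma::cube>());

    for (int t = 0; t < nops; ++t) {
      List op = tape[t];
      std::string kind = as<std::string>(op["op"]);
      if (kind == "quant_input") fwd_quant_input(batch);
      else if (kind == "conv_stem") fwd_stem(t, op, batch);
      else if (kind == "rsign") fwd_rsign(t, op, batch);
      else if (kind == "dw") fwd_dw(t, op, batch);
      else if (kind == "pw") fwd_pw(t, op, batch);
      else if (kind == "bn") fwd_bn(t, op, batch);
      else if (kind == "affine") fwd_affine(t, op, batch);
      else if (kind == "act") fwd_act(t, op, batch);
      else if (kind == "skip_save") fwd_skip_save(t, op, batch);
      else if (kind == "skip_cat") fwd_skip_cat(t, op, batch);
      else if (kind == "upsample") fwd_upsample(batch);
      else if (kind == "sigmoid") fwd_sigmoid(t, batch);
      else stop("unknown op: %s", kind.c_str());
    }
  }

  std::vector<std::vector<arma::cube>> skip_batch;   // slot -> samples
  std::vector<std::vector<arma::cube>> skip_grad;    // slot -> grads

  void fwd_quant_input(std::vector<arma::cube>& batch) {
    for (auto& x : batch)
      x.for_each([](double& v) {
        double c = std::round(v * 16.0);
        if (c < 0) c = 0; if (c > 15) c = 15;
        v = c / 16.0;
      });
  }

  void fwd_stem(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::cube w = get_cube(par(nm + ".w"));   // 3 x 3 x Cout
    const int stride = as<int>(op["stride"]);
    const bool q4 = as<std::string>(op["kind"]) == "q4";
    arma::cube weff = w;                       // deep copy
    OpCache& C = cache[t];
    if (q4) {
      const double step = std::pow(2.0, bufval(nm + ".wshift"));
      weff.for_each([step](double& v) {
        bool cl = false;
        v = qclamp(std::round(v / step), -8, 7, &cl) * step;
      });
    }
    C.c1 = weff;
    C.in = batch;   // cache input (deep copies)
    const int Cout = w.n_slices;
    for (auto& x : batch) {
      const int Ho = out_size(x.n_rows, stride), Wo = out_size(x.n_cols, stride);
      arma::cube y(Ho, Wo, Cout);
      arma::mat tmp(Ho, Wo);
      for (int c = 0; c < Cout; ++c) {
        dw3_forward(x.slice(0), tmp, weff.slice(c).memptr(), stride);
        y.slice(c) = tmp;
      }
      x = std::move(y);
    }
  }

  void fwd_rsign(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::vec alpha = get_vec(par(nm + ".alpha"));
    const bool quant = as<bool>(op["quantized"]);
    arma::vec aeff(alpha.n_elem);
    for (arma::uword c = 0; c < alpha.n_elem; ++c) {
      if (quant) {
        bool cl = false;
        aeff[c] = qclamp(std::round(alpha[c] / 0.25), -8, 7, &cl) * 0.25;
      } else aeff[c] = alpha[c];
    }
    OpCache& C = cache[t];
    C.v1 = aeff;
    C.in.resize(batch.size());
    for (size_t s = 0; s < batch.size(); ++s) {
      arma::cube& x = batch[s];
      arma::cube z = x;                        // z = x - alpha (cached)
      for (arma::uword c = 0; c < x.n_slices; ++c) z.slice(c) -= aeff[c];
      C.in[s] = z;
      x.set_size(z.n_rows, z.n_cols, z.n_slices);
      for (arma::uword i = 0; i < z.n_elem; ++i)
        x[i] = z[i] > 0 ? 1.0 : -1.0;
    }
  }

  void fwd_dw(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::cube w = get_cube(par(nm + ".w"));
    const int stride = as<int>(op["stride"]);
    const bool binary = as<bool>(op["binary"]);
    arma::cube weff = w;
    if (binary)
      for (arma::uword c = 0; c < w.n_slices; ++c)
        binarize_col(w.slice(c).memptr(), weff.slice(c).memptr(), 9);
    OpCache& C = cache[t];
    C.c1 = weff;
    C.in = batch;
    const int Cc = w.n_slices;
    for (auto& x : batch) {
      const int Ho = out_size(x.n_rows, stride), Wo = out_size(x.n_cols, stride);
      arma::cube y(Ho, Wo, Cc);
      arma::mat tmp(Ho, Wo);
      for (int c = 0; c < Cc; ++c) {
        dw3_forward(x.slice(c), tmp, weff.slice(c).memptr(), stride);
        y.slice(c) = tmp;
      }
      x = std::move(y);
    }
  }

  void fwd_pw(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::mat w = get_mat(par(nm + ".w"));     // Cin x Cout
    const bool binary = as<bool>(op["binary"]);
    arma::mat weff = w;
    if (binary)
      for (arma::uword c = 0; c < w.n_cols; ++c)
        binarize_col(w.colptr(c), weff.colptr(c), w.n_rows);
    OpCache& C = cache[t];
    C.m1 = weff;
    // gather the whole batch into one (N*HW x Cin) matrix for a single GEMM
    const arma::uword HW = batch[0].n_rows * batch[0].n_cols;
    arma::mat B(HW * batch.size(), w.n_rows);
    for (size_t s = 0; s < batch.size(); ++s)
      B.rows(s * HW, (s + 1) * HW - 1) = flat(batch[s]);
    arma::mat Y = B * weff;
    C.aux2 = std::move(B);                     // cached for the weight grad
    for (size_t s = 0; s < batch.size(); ++s) {
      arma::cube y(batch[s].n_rows, batch[s].n_cols, w.n_cols);
      flat(y) = Y.rows(s * HW, (s + 1) * HW - 1);
      batch[s] = std::move(y);
    }
  }

  void fwd_bn(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::vec gamma = get_vec(par(nm + ".gamma"));
    arma::vec beta = get_vec(par(nm + ".beta"));
    arma::vec rmean = get_vec(buf(nm + ".mean"));   // views into buffers
    arma::vec rvar = get_vec(buf(nm + ".var"));
    const int Cc = gamma.n_elem;
    arma::vec mu(Cc), var(Cc);
    if (train) {
      mu.zeros(); var.zeros();
      double m = 0;
      for (auto& x : batch) m += x.n_rows * x.n_cols;
      for (int c = 0; c < Cc; ++c) {
        double s = 0, ss = 0;
        for (auto& x : batch) {
          s += arma::accu(x.slice(c));
          ss += arma::accu(arma::square(x.slice(c)));
        }
        mu[c] = s / m;
        var[c] = ss / m - mu[c] * mu[c];
        if (var[c] < 0) var[c] = 0;
        rmean[c] = (1 - BN_MOMENTUM) * rmean[c] + BN_MOMENTUM * mu[c];
        rvar[c] = (1 - BN_MOMENTUM) * rvar[c] + BN_MOMENTUM * var[c];
      }
    } else { mu = rmean; var = rvar; }
    OpCache& C = cache[t];
    C.v1 = 1.0 / arma::sqrt(var + BN_EPS);     // invstd
    C.in.resize(batch.size());                 // xhat cached
    for (size_t s = 0; s < batch.size(); ++s) {
      arma::cube& x = batch[s];
      arma::cube xhat = x;
      for (int c = 0; c < Cc; ++c)
        xhat.slice(c) = (x.slice(c) - mu[c]) * C.v1[c];
      C.in[s] = xhat;
      for (int c = 0; c < Cc; ++c)
        x.slice(c) = gamma[c] * xhat.slice(c) + beta[c];
    }
  }

  void fwd_affine(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    arma::vec w = get_vec(par(nm + ".w"));
    arma::vec b = get_vec(par(nm + ".b"));
    const double bstep = std::pow(2.0, bufval(nm + ".bstep"));
    const int Cc = w.n_elem;
    arma::vec weff(Cc), beff(Cc), bmask(Cc);
    for (int c = 0; c < Cc; ++c) {
      if (w[c] == 0) stop("shift norm: zero scale in %s", nm.c_str());
      bool cl = false;
      double s = qclamp(std::round(std::log2(std::fabs(w[c]))), -8, 7, &cl);
      weff[c] = (w[c] > 0 ? 1.0 : -1.0) * std::pow(2.0, s);
      cl = false;
      beff[c] = qclamp(std::round(b[c] / bstep), -8, 7, &cl) * bstep;
      bmask[c] = cl ? 0.0 : 1.0;
    }
    OpCache& C = cache[t];
    C.v1 = weff; C.v2 = bmask;
    C.in = batch;
    for (auto& x : batch)
      for (int c = 0; c < Cc; ++c)
        x.slice(c) = weff[c] * x.slice(c) + beff[c];
  }

  void fwd_act(int t, List op, std::vector<arma::cube>& batch) {
    std::string nm = as<std::string>(op["name"]);
    std::string kind = as<std::string>(op["kind"]);
    OpCache& C = cache[t];
    if (kind == "relu") {
      C.in = batch;
      for (auto& x : batch) x.transform([](double v) { return v > 0 ? v : 0.0; });
      return;
    }
    arma::vec beta = get_vec(par(nm + ".beta"));
    arma::vec gam = get_vec(par(nm + ".gamma"));
    arma::vec eta = get_vec(par(nm + ".eta"));
    const int Cc = beta.n_elem;
    arma::vec be(Cc), ge(Cc), ee(Cc), bm(Cc), gm(Cc), em(Cc);
    if (kind == "prelu_q") {
      const double gstep = std::pow(2.0, bufval(nm + ".gstep"));
      const double estep = std::pow(2.0, bufval(nm + ".estep"));
      for (int c = 0; c < Cc; ++c) {
        bool cl = false;
        be[c] = qclamp(std::round(beta[c] / 0.25), 0, 3, &cl) * 0.25;
        bm[c] = cl ? 0 : 1;
        cl = false;
        ge[c] = qclamp(std::round(gam[c] / gstep), -8, 7, &cl) * gstep;
        gm[c] = cl ? 0 : 1;
        cl = false;
        ee[c] = qclamp(std::round(eta[c] / estep), -8, 7, &cl) * estep;
        em[c] = cl ? 0 : 1;
      }
    } else {
      be = beta; ge = gam; ee = eta;
      bm.ones(); gm.ones(); em.ones();
    }
    C.v1 = arma::join_cols(arma::join_cols(be, ge), ee);
    C.v2 = arma::join_cols(arma::join_cols(bm, gm), em);
    C.in = batch;
    for (auto& x : batch)
      for (int c = 0; c < Cc; ++c)
        x.slice(c).transform([&](double v) {
          return v > ge[c] ? (v - ge[c]) + ee[c] : be[c] * (v - ge[c]) + ee[c];
        });
  }

  void fwd_skip_save(int t, List op, std::vector<arma::cube>& batch) {
    const int slot = as<int>(op["slot"]) - 1;
    const bool quant = as<bool>(op["quantized"]);
    skip_slot_op[slot] = t;
    OpCache& C = cache[t];
    if (!quant) {
      skip_batch[slot] = batch;                // identity store
      return;
    }
    std::string nm = as<std::string>(op["name"]);
    const int bits = as<int>(op["bits"]);
    const double step = std::pow(2.0, bufval(nm + ".shift"));
    const double cmax = std::pow(2.0, bits) - 1;
    C.in = batch;                              // pre-quant input (STE mask)
    for (auto& x : batch)
      x.for_each([step, cmax](double& v) {
        double c = std::round(v / step);
        if (c < 0) c = 0; if (c > cmax) c = cmax;
        v = c * step;
      });
    skip_batch[slot] = batch;
  }

  void fwd_skip_cat(int t, List op, std::vector<arma::cube>& batch) {
    const int slot = as<int>(op["slot"]) - 1;
    for (size_t s = 0; s < batch.size(); ++s)
      batch[s] = arma::join_slices(batch[s], skip_batch[slot][s]);
    (void)t;
  }

  void fwd_upsample(std::vector<arma::cube>& batch) {
    for (auto& x : batch) {
      arma::cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
      for (arma::uword c = 0; c < x.n_slices; ++c)
        for (arma::uword j = 0; j < x.n_cols; ++j)
          for (arma::uword i = 0; i < x.n_rows; ++i) {
            const double v = x.at(i, j, c);
            y.at(2 * i, 2 * j, c) = v;
            y.at(2 * i + 1, 2 * j, c) = v;
            y.at(2 * i, 2 * j + 1, c) = v;
            y.at(2 * i + 1, 2 * j + 1, c) = v;
          }
      x = std::move(y);
    }
  }

  void fwd_sigmoid(int t, std::vector<arma::cube>& batch) {
    for (auto& x : batch)
      x.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
    cache[t].in = batch;                       // cache p
  }

  // ---- backward ------------------------------------------------------------
  void backward(std::vector<arma::cube>& g) {
    const int nops = tape.size();
    skip_grad.assign(skip_batch.size(), std::vector<arma::cube>());
    for (int t = nops - 1; t >= 0; --t) {
      List op = tape[t];
      std::string kind = as<std::string>(op["op"]);
      if (kind == "quant_input") { /* input needs no gradient */ }
      else if (kind == "conv_stem") bwd_stem(t, op, g);
      else if (kind == "rsign") bwd_rsign(t, op, g);
      else if (kind == "dw") bwd_dw(t, op, g);
      else if (kind == "pw") bwd_pw(t, op, g);
      else if (kind == "bn") bwd_bn(t, op, g);
      else if (kind == "affine") bwd_affine(t, op, g);
      else if (kind == "act") bwd_act(t, op, g);
      else if (kind == "skip_save") bwd_skip_save(t, op, g);
      else if (kind == "skip_cat") bwd_skip_cat(t, op, g);
      else if (kind == "upsample") bwd_upsample(g);
      else if (kind == "sigmoid") bwd_sigmoid(t, g);
    }
  }

  double* gptr(const std::string& nm) {
    auto it = grad_ptr.find(nm);
    if (it == grad_ptr.end()) stop("no gradient slot for %s", nm.c_str());
    return it->second;
  }

  void bwd_sigmoid(int t, std::vector<arma::cube>& g) {
    OpCache& C = cache[t];
    for (size_t s = 0; s < g.size(); ++s)
      g[s] %= C.in[s] % (1.0 - C.in[s]);
  }

  void bwd_upsample(std::vector<arma::cube>& g) {
    for (auto& gy : g) {
      arma::cube gx(gy.n_rows / 2, gy.n_cols / 2, gy.n_slices);
      for (arma::uword c = 0; c < gx.n_slices; ++c)
        for (arma::uword j = 0; j < gx.n_cols; ++j)
          for (arma::uword i = 0; i < gx.n_rows; ++i)
            gx.at(i, j, c) = gy.at(2 * i, 2 * j, c) + gy.at(2 * i + 1, 2 * j, c)
                           + gy.at(2 * i, 2 * j + 1, c) + gy.at(2 * i + 1, 2 * j + 1, c);
      gy = std::move(gx);
    }
  }

  void bwd_skip_cat(int t, List op, std::vector<arma::cube>& g) {
    const int slot = as<int>(op["slot"]) - 1;
    skip_grad[slot].resize(g.size());
    for (size_t s = 0; s < g.size(); ++s) {
      const arma::uword csk = skip_batch[slot][s].n_slices;
      const arma::uword cmain = g[s].n_slices - csk;
      skip_grad[slot][s] = g[s].slices(cmain, g[s].n_slices - 1);
      arma::cube main = g[s].slices(0, cmain - 1);
      g[s] = std::move(main);
    }
    (void)t;
  }

  void bwd_skip_save(int t, List op, std::vector<arma::cube>& g) {
    const int slot = as<int>(op["slot"]) - 1;
    const bool quant = as<bool>(op["quantized"]);
    // add gradient arriving from the decoder's consumption of this skip
    if (!skip_grad[slot].empty())
      for (size_t s = 0; s < g.size(); ++s) g[s] += skip_grad[slot][s];
    if (!quant) return;
    std::string nm = as<std::string>(op["name"]);
    const int bits = as<int>(op["bits"]);
    const double step = std::pow(2.0, bufval(nm + ".shift"));
    const double hi = (std::pow(2.0, bits) - 1) * step;
    OpCache& C = cache[t];
    for (size_t s = 0; s < g.size(); ++s) {
      const arma::cube& x = C.in[s];
      for (arma::uword i = 0; i < x.n_elem; ++i)
        if (x[i] < -0.5 * step || x[i] > hi + 0.5 * step) g[s][i] = 0;
    }
  }

  void bwd_act(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    std::string kind = as<std::string>(op["kind"]);
    OpCache& C = cache[t];
    if (kind == "relu") {
      for (size_t s = 0; s < g.size(); ++s)
        for (arma::uword i = 0; i < g[s].n_elem; ++i)
          if (C.in[s][i] <= 0) g[s][i] = 0;
      return;
    }
    const int Cc = C.in[0].n_slices;
    arma::vec be = C.v1.subvec(0, Cc - 1), ge = C.v1.subvec(Cc, 2 * Cc - 1),
              bm = C.v2.subvec(0, Cc - 1), gm = C.v2.subvec(Cc, 2 * Cc - 1),
              em = C.v2.subvec(2 * Cc, 3 * Cc - 1);
    double *gb = gptr(nm + ".beta"), *gg = gptr(nm + ".gamma"),
           *ge_ = gptr(nm + ".eta");
    for (size_t s = 0; s < g.size(); ++s) {
      const arma::cube& x = C.in[s];
      for (int c = 0; c < Cc; ++c) {
        const arma::mat& xs = x.slice(c);
        arma::mat& gs = g[s].slice(c);
        double db = 0, dg = 0, de = 0;
        for (arma::uword i = 0; i < xs.n_elem; ++i) {
          const double gv = gs[i];
          de += gv;
          if (xs[i] > ge[c]) { dg -= gv; }
          else { db += gv * (xs[i] - ge[c]); dg -= gv * be[c]; gs[i] = gv * be[c]; }
        }
        gb[c] += db * bm[c];
        gg[c] += dg * gm[c];
        ge_[c] += de * em[c];
      }
    }
  }

  void bwd_affine(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    OpCache& C = cache[t];
    const int Cc = C.v1.n_elem;
    double *gw = gptr(nm + ".w"), *gb = gptr(nm + ".b");
    for (size_t s = 0; s < g.size(); ++s) {
      for (int c = 0; c < Cc; ++c) {
        gw[c] += arma::accu(g[s].slice(c) % C.in[s].slice(c));
        gb[c] += arma::accu(g[s].slice(c)) * C.v2[c];
        g[s].slice(c) *= C.v1[c];
      }
    }
  }

  void bwd_bn(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    arma::vec gamma = get_vec(par(nm + ".gamma"));
    OpCache& C = cache[t];
    const int Cc = gamma.n_elem;
    double m = 0;
    for (auto& gs : g) m += gs.n_rows * gs.n_cols;
    double *ggam = gptr(nm + ".gamma"), *gbet = gptr(nm + ".beta");
    for (int c = 0; c < Cc; ++c) {
      double sg = 0, sgx = 0;
      for (size_t s = 0; s < g.size(); ++s) {
        sg += arma::accu(g[s].slice(c));
        sgx += arma::accu(g[s].slice(c) % C.in[s].slice(c));
      }
      ggam[c] += sgx;
      gbet[c] += sg;
      const double mg = sg / m, mgx = sgx / m;
      const double k = gamma[c] * C.v1[c];
      for (size_t s = 0; s < g.size(); ++s)
        g[s].slice(c) = k * (g[s].slice(c) - mg - C.in[s].slice(c) * mgx);
    }
  }

  void bwd_pw(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    OpCache& C = cache[t];
    arma::mat gw(gptr(nm + ".w"), C.m1.n_rows, C.m1.n_cols, false, true);
    const arma::uword HW = g[0].n_rows * g[0].n_cols;
    arma::mat G(HW * g.size(), C.m1.n_cols);
    for (size_t s = 0; s < g.size(); ++s)
      G.rows(s * HW, (s + 1) * HW - 1) = flat(g[s]);
    gw += C.aux2.t() * G;
    arma::mat GX = G * C.m1.t();
    for (size_t s = 0; s < g.size(); ++s) {
      arma::cube gx(g[s].n_rows, g[s].n_cols, C.m1.n_rows);
      flat(gx) = GX.rows(s * HW, (s + 1) * HW - 1);
      g[s] = std::move(gx);
    }
  }

  void bwd_dw(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    const int stride = as<int>(op["stride"]);
    OpCache& C = cache[t];
    const int Cc = C.c1.n_slices;
    double* gw = gptr(nm + ".w");
    for (size_t s = 0; s < g.size(); ++s) {
      arma::cube gx(C.in[s].n_rows, C.in[s].n_cols, Cc, arma::fill::zeros);
      for (int c = 0; c < Cc; ++c) {
        arma::mat din(gx.slice(c).memptr(), gx.n_rows, gx.n_cols, false, true);
        dw3_backward(C.in[s].slice(c), g[s].slice(c), din,
                     C.c1.slice(c).memptr(), gw + 9 * c, stride);
      }
      g[s] = std::move(gx);
    }
  }

  void bwd_rsign(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    OpCache& C = cache[t];
    const int Cc = C.in[0].n_slices;
    double* ga = gptr(nm + ".alpha");
    const bool quant = as<bool>(op["quantized"]);
    arma::vec alpha = get_vec(par(nm + ".alpha"));
    for (size_t s = 0; s < g.size(); ++s) {
      const arma::cube& z = C.in[s];
      for (int c = 0; c < Cc; ++c) {
        arma::mat& gs = g[s].slice(c);
        const arma::mat& zs = z.slice(c);
        double da = 0;
        for (arma::uword i = 0; i < gs.n_elem; ++i) {
          double sur;
          if (surrogate == 0) sur = std::fabs(zs[i]) <= 1.0 ? 1.0 : 0.0;
          else {
            const double th = std::tanh(2.0 * zs[i]);
            sur = 2.0 * (1.0 - th * th);
          }
          gs[i] *= sur;
          da -= gs[i];
        }
        bool clipped = quant &&
          (std::round(alpha[c] / 0.25) < -8 || std::round(alpha[c] / 0.25) > 7);
        ga[c] += clipped ? 0.0 : da;
      }
    }
  }

  void bwd_stem(int t, List op, std::vector<arma::cube>& g) {
    std::string nm = as<std::string>(op["name"]);
    const int stride = as<int>(op["stride"]);
    OpCache& C = cache[t];
    const int Cout = C.c1.n_slices;
    double* gw = gptr(nm + ".w");
    for (size_t s = 0; s < g.size(); ++s) {
      arma::mat din(C.in[s].n_rows, C.in[s].n_cols, arma::fill::zeros);
      for (int c = 0; c < Cout; ++c)
        dw3_backward(C.in[s].slice(0), g[s].slice(c), din,
                     C.c1.slice(c).memptr(), gw + 9 * c, stride);
      // no gradient propagated to the input image
    }
  }
};

}  // namespace

// ---- exported entry points -------------------------------------------------

// Forward + dice loss + backward over one minibatch.
// imgs: list of H x W x 1 arrays; masks: list of H x W x out_channels arrays.
// Returns loss, per-parameter grads and (updated) buffers.
// [[Rcpp::export(name = ".cx_qnn_loss_grad")]]
List cx_qnn_loss_grad(List params, List buffers, List tape,
                      List imgs, List masks, int surrogate) {
  const int N = imgs.size();
  Engine eng(params, buffers, tape, surrogate, true);
  eng.init_grads();
  std::vector<arma::cube> batch(N);
  for (int s = 0; s < N; ++s) batch[s] = get_cube(imgs[s]);
  eng.forward(batch);

  // dice loss (smoothing eps = 1), averaged over samples and channels
  const double eps = 1.0;
  double loss = 0;
  std::vector<arma::cube> g(N);
  const int Cc = batch[0].n_slices;
  for (int s = 0; s < N; ++s) {
    arma::cube tgt = get_cube(masks[s]);
    g[s].set_size(arma::size(batch[s]));
    for (int c = 0; c < Cc; ++c) {
      const arma::mat& p = batch[s].slice(c);
      const arma::mat& tt = tgt.slice(c);
      const double A = 2.0 * arma::accu(p % tt) + eps;
      const double B = arma::accu(p) + arma::accu(tt) + eps;
      loss += (1.0 - A / B) / (N * Cc);
      // d(1 - A/B)/dp = -(2 t B - A) / B^2
      g[s].slice(c) = -(2.0 * tt * B - A) / (B * B) / (N * Cc);
    }
  }
  eng.backward(g);
  return List::create(_["loss"] = loss, _["grads"] = eng.grads,
                      _["buffers"] = buffers);
}

// Forward pass only.  mode: 0 = eval (running stats), 1 = train-mode stats
// (used for BN calibration).  Returns per-sample probability maps and,
// optionally, the stored skip-connection tensors per slot.
// [[Rcpp::export(name = ".cx_qnn_forward")]]
List cx_qnn_forward(List params, List buffers, List tape, List imgs,
                    int mode, bool collect_skips) {
  const int N = imgs.size();
  Engine eng(params, buffers, tape, 0, mode == 1);
  std::vector<arma::cube> batch(N);
  for (int s = 0; s < N; ++s) batch[s] = get_cube(imgs[s]);
  eng.forward(batch);
  List probs(N);
  for (int s = 0; s < N; ++s) {
    NumericVector a(batch[s].n_elem);
    std::copy(batch[s].begin(), batch[s].end(), a.begin());
    a.attr("dim") = IntegerVector::create(batch[s].n_rows, batch[s].n_cols,
                                          batch[s].n_slices);
    probs[s] = a;
  }
  List out = List::create(_["probs"] = probs, _["buffers"] = buffers);
  if (collect_skips) {
    const int nslots = eng.skip_batch.size();
    List skips(nslots);
    for (int k = 0; k < nslots; ++k) {
      List per(N);
      for (int s = 0; s < N; ++s) {
        arma::cube& x = eng.skip_batch[k][s];
        NumericVector a(x.n_elem);
        std::copy(x.begin(), x.end(), a.begin());
        a.attr("dim") = IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
        per[s] = a;
      }
      skips[k] = per;
    }
    out["skips"] = skips;
  }
  return out;
}
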