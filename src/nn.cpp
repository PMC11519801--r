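// Mini neural-network engine for 1-D spectral classifiers.
//
// Supports an optional Conv1D front-end (valid padding, ReLU, inverted
// dropout, max-pooling, flatten) followed by a fully connected stack with
// ReLU hidden units, optional per-layer dropout and L2 penalties, and a
// single sigmoid output unit trained with mini-batch SGD + momentum on
// binary cross-entropy.  Internals run in single precision (the customary
// deep-learning precision); all randomness (initialisation, shuffling,
// dropout masks) is drawn from R's RNG so results are reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::fvec;
using arma::uword;

namespace {

struct ArchSpec {
  bool has_conv;
  int input_len;
  int filters, kernel, stride, pool, pool_stride;
  double conv_dropout;
  std::vector<int> dense_sizes;      // ends with 1 (sigmoid unit)
  std::vector<double> dense_dropout; // applied to each hidden layer's output
  std::vector<double> dense_l2;      // per dense layer weight matrix
  int conv_len, pool_len, dense_input;
};

int out_len(int L, int k, int s) { return (L - k) / s + 1; }

ArchSpec parse_arch(const List& arch) {
  ArchSpec a;
  a.input_len = as<int>(arch["input_len"]);
  a.has_conv = as<bool>(arch["conv"]);
  if (a.has_conv) {
    a.filters = as<int>(arch["filters"]);
    a.kernel = as<int>(arch["kernel"]);
    a.stride = as<int>(arch["stride"]);
    a.pool = as<int>(arch["pool"]);
    a.pool_stride = as<int>(arch["pool_stride"]);
    a.conv_dropout = as<double>(arch["conv_dropout"]);
    if (a.kernel > a.input_len) stop("kernel larger than input length");
    a.conv_len = out_len(a.input_len, a.kernel, a.stride);
    if (a.pool > a.conv_len) stop("pool size larger than conv output");
    a.pool_len = out_len(a.conv_len, a.pool, a.pool_stride);
    a.dense_input = a.pool_len * a.filters;
  } else {
    a.filters = a.kernel = a.stride = a.pool = a.pool_stride = 0;
    a.conv_dropout = 0.0;
    a.conv_len = a.pool_len = 0;
    a.dense_input = a.input_len;
  }
  a.dense_sizes = as<std::vector<int>>(arch["dense_sizes"]);
  a.dense_dropout = as<std::vector<double>>(arch["dense_dropout"]);
  a.dense_l2 = as<std::vector<double>>(arch["dense_l2"]);
  return a;
}

struct Params {
  fmat conv_W;  // kernel x filters
  frowvec conv_b;
  std::vector<fmat> W;
  std::vector<frowvec> b;
};

fmat toF(SEXP x) { return arma::conv_to<fmat>::from(as<arma::mat>(x)); }
frowvec toFR(SEXP x) {
  return arma::conv_to<frowvec>::from(as<arma::rowvec>(x));
}

Params parse_params(const ArchSpec& a, const List& params) {
  Params p;
  if (a.has_conv) {
    p.conv_W = toF(params["conv_W"]);
    p.conv_b = toFR(params["conv_b"]);
  }
  List Ws = params["dense_W"], bs = params["dense_b"];
  for (int l = 0; l < Ws.size(); ++l) {
    p.W.push_back(toF(Ws[l]));
    p.b.push_back(toFR(bs[l]));
  }
  return p;
}

List wrap_params(const ArchSpec& a, const Params& p) {
  List Ws(p.W.size()), bs(p.b.size());
  for (size_t l = 0; l < p.W.size(); ++l) {
    Ws[l] = wrap(arma::conv_to<arma::mat>::from(p.W[l]));
    bs[l] = wrap(arma::conv_to<arma::rowvec>::from(p.b[l]));
  }
  if (a.has_conv)
    return List::create(_["conv_W"] = wrap(arma::conv_to<arma::mat>::from(p.conv_W)),
                        _["conv_b"] = wrap(arma::conv_to<arma::rowvec>::from(p.conv_b)),
                        _["dense_W"] = Ws, _["dense_b"] = bs);
  return List::create(_["conv_W"] = R_NilValue, _["conv_b"] = R_NilValue,
                      _["dense_W"] = Ws, _["dense_b"] = bs);
}

fmat glorot(int rows, int cols, int fan_in, int fan_out) {
  double lim = std::sqrt(6.0 / (double)(fan_in + fan_out));
  fmat W(rows, cols);
  for (int j = 0; j < cols; ++j)
    for (int i = 0; i < rows; ++i)
      W(i, j) = (float)((2.0 * R::unif_rand() - 1.0) * lim);
  return W;
}

// im2col: rows of Xc index (sample i, window p) as r = i + n*p.
fmat im2col(const fmat& X, const ArchSpec& a) {
  int n = X.n_rows, Lc = a.conv_len, k = a.kernel, s = a.stride;
  fmat Xc((uword)n * Lc, k);
  for (int j = 0; j < k; ++j)
    for (int p = 0; p < Lc; ++p)
      Xc.col(j).subvec((uword)n * p, (uword)n * p + n - 1) =
          X.col((uword)(p * s + j));
  return Xc;
}

struct ConvCache {
  fmat Xc;                   // (n*Lc) x k
  fmat mult;                 // combined relu x inverted-dropout multiplier
  fmat D1;                   // post relu+dropout feature map
  arma::Mat<arma::u8> amoff; // argmax offset within each pooling window
};

// Forward through the conv block, writing the flattened output directly:
// column f*pool_len + w of the result holds filter f at pooled position w.
fmat conv_forward(const fmat& X, const ArchSpec& a, const Params& p,
                  bool training, ConvCache* cache) {
  int n = X.n_rows, F = a.filters, Lp = a.pool_len;
  fmat Xc = im2col(X, a);
  fmat Z1 = Xc * p.conv_W;
  Z1.each_row() += p.conv_b;
  // fused ReLU + inverted dropout: D1 = Z1 * mult
  fmat mult;
  if (training) {
    mult.set_size(Z1.n_rows, Z1.n_cols);
    float* m = mult.memptr();
    const float* z = Z1.memptr();
    if (a.conv_dropout > 0) {
      const double keep = 1.0 - a.conv_dropout;
      const float inv = (float)(1.0 / keep);
      for (uword i = 0; i < Z1.n_elem; ++i)
        m[i] = (z[i] > 0 && R::unif_rand() < keep) ? inv : 0.0f;
    } else {
      for (uword i = 0; i < Z1.n_elem; ++i) m[i] = z[i] > 0 ? 1.0f : 0.0f;
    }
    Z1 %= mult; // Z1 now holds D1
  } else {
    Z1.transform([](float v) { return v > 0 ? v : 0.0f; });
  }
  fmat Fl(n, (uword)Lp * F);
  arma::Mat<arma::u8> amoff;
  if (cache) amoff.set_size((uword)n * Lp, F);
  for (int f = 0; f < F; ++f) {
    const float* src = Z1.colptr(f);
    for (int w = 0; w < Lp; ++w) {
      float* dst = Fl.colptr((uword)f * Lp + w);
      int start = w * a.pool_stride;
      if (cache) {
        arma::u8* am = amoff.colptr(f) + (uword)n * w;
        for (int i = 0; i < n; ++i) {
          int best = 0;
          float bv = src[(uword)i + (uword)n * start];
          for (int o = 1; o < a.pool; ++o) {
            float v = src[(uword)i + (uword)n * (start + o)];
            if (v > bv) { bv = v; best = o; }
          }
          dst[i] = bv;
          am[i] = (arma::u8)best;
        }
      } else {
        for (int i = 0; i < n; ++i) {
          float bv = src[(uword)i + (uword)n * start];
          for (int o = 1; o < a.pool; ++o) {
            float v = src[(uword)i + (uword)n * (start + o)];
            if (v > bv) bv = v;
          }
          dst[i] = bv;
        }
      }
    }
  }
  if (cache) {
    cache->Xc = std::move(Xc);
    cache->mult = std::move(mult);
    cache->D1 = std::move(Z1);
    cache->amoff = std::move(amoff);
  }
  return Fl;
}

struct DenseCache {
  std::vector<fmat> A;    // activations, A[0] = input
  std::vector<fmat> mult; // fused relu/dropout multiplier per hidden layer
};

fvec dense_forward(const fmat& H, const ArchSpec& a, const Params& p,
                   bool training, DenseCache* cache) {
  size_t L = p.W.size();
  fmat A = H;
  if (cache) { cache->A.clear(); cache->mult.clear(); cache->A.push_back(A); }
  for (size_t l = 0; l < L; ++l) {
    fmat Z = A * p.W[l];
    Z.each_row() += p.b[l];
    if (l + 1 < L) {
      if (training) {
        fmat mult(Z.n_rows, Z.n_cols);
        float* m = mult.memptr();
        const float* z = Z.memptr();
        if (a.dense_dropout[l] > 0) {
          const double keep = 1.0 - a.dense_dropout[l];
          const float inv = (float)(1.0 / keep);
          for (uword i = 0; i < Z.n_elem; ++i)
            m[i] = (z[i] > 0 && R::unif_rand() < keep) ? inv : 0.0f;
        } else {
          for (uword i = 0; i < Z.n_elem; ++i) m[i] = z[i] > 0 ? 1.0f : 0.0f;
        }
        Z %= mult;
        if (cache) { cache->mult.push_back(std::move(mult)); }
      } else {
        Z.transform([](float v) { return v > 0 ? v : 0.0f; });
      }
      A = std::move(Z);
      if (cache) cache->A.push_back(A);
    } else {
      fvec out = 1.0f / (1.0f + arma::exp(-Z.col(0)));
      return out;
    }
  }
  stop("empty dense stack");
}

double bce(const fvec& p, const fvec& y) {
  double s = 0.0;
  for (uword i = 0; i < p.n_elem; ++i) {
    double pc = std::min(std::max((double)p[i], 1e-12), 1.0 - 1e-12);
    s += y[i] > 0.5f ? std::log(pc) : std::log(1.0 - pc);
  }
  return -s / p.n_elem;
}

struct Grads {
  fmat conv_W;
  frowvec conv_b;
  std::vector<fmat> W;
  std::vector<frowvec> b;
};

// Forward + backward for one batch; returns data loss and fills grads.
double batch_grads(const fmat& X, const fvec& y, const ArchSpec& a,
                   const Params& p, Grads& g, fvec& prob) {
  int n = X.n_rows;
  ConvCache cc;
  DenseCache dc;
  fmat H = a.has_conv ? conv_forward(X, a, p, true, &cc) : X;
  prob = dense_forward(H, a, p, true, &dc);
  double loss = bce(prob, y);

  size_t L = p.W.size();
  g.W.assign(L, fmat());
  g.b.assign(L, frowvec());
  fmat dZ(n, 1);
  dZ.col(0) = (prob - y) / (float)n; // d(bce)/dZ at the sigmoid output
  for (int l = (int)L - 1; l >= 0; --l) {
    const fmat& Ain = dc.A[l];
    g.W[l] = Ain.t() * dZ;
    if (a.dense_l2[l] > 0) g.W[l] += (float)(2.0 * a.dense_l2[l]) * p.W[l];
    g.b[l] = arma::sum(dZ, 0);
    if (l > 0) {
      fmat dA = dZ * p.W[l].t();
      dZ = dA % dc.mult[l - 1];
    } else if (a.has_conv) {
      fmat dFl = dZ * p.W[0].t(); // n x (Lp*F)
      int F = a.filters, Lp = a.pool_len;
      fmat dD1(cc.D1.n_rows, cc.D1.n_cols, arma::fill::zeros);
      for (int f = 0; f < F; ++f) {
        float* dcol = dD1.colptr(f);
        const arma::u8* am = cc.amoff.colptr(f);
        for (int w = 0; w < Lp; ++w) {
          const float* src = dFl.colptr((uword)f * Lp + w);
          int start = w * a.pool_stride;
          const arma::u8* amw = am + (uword)n * w;
          for (int i = 0; i < n; ++i)
            dcol[(uword)i + (uword)n * (start + amw[i])] += src[i];
        }
      }
      dD1 %= cc.mult; // back through relu + dropout in one pass
      g.conv_W = cc.Xc.t() * dD1;
      g.conv_b = arma::sum(dD1, 0);
    }
  }
  return loss;
}

fvec predict_chunked(const fmat& X, const ArchSpec& a, const Params& p,
                     int chunk = 512) {
  int n = X.n_rows;
  fvec out(n);
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk) - 1;
    fmat Xb = X.rows(s, e);
    fmat H = a.has_conv ? conv_forward(Xb, a, p, false, nullptr) : Xb;
    out.subvec(s, e) = dense_forward(H, a, p, false, nullptr);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List cpp_init_params(List arch) {
  ArchSpec a = parse_arch(arch);
  Params p;
  if (a.has_conv) {
    // fan_in = kernel * in_channels (1), fan_out = kernel * filters
    p.conv_W = glorot(a.kernel, a.filters, a.kernel, a.kernel * a.filters);
    p.conv_b = frowvec(a.filters, arma::fill::zeros);
  }
  int in = a.dense_input;
  for (size_t l = 0; l < a.dense_sizes.size(); ++l) {
    int out = a.dense_sizes[l];
    p.W.push_back(glorot(in, out, in, out));
    p.b.push_back(frowvec(out, arma::fill::zeros));
    in = out;
  }
  return wrap_params(a, p);
}

// [[Rcpp::export]]
List cpp_train(SEXP X_, SEXP y_, SEXP Xval_, SEXP yval_, List arch,
               List params, List train_cfg) {
  ArchSpec a = parse_arch(arch);
  Params p = parse_params(a, params);
  fmat X = toF(X_), Xval = toF(Xval_);
  fvec y = arma::conv_to<fvec>::from(as<arma::vec>(y_));
  fvec yval = arma::conv_to<fvec>::from(as<arma::vec>(yval_));
  int epochs = as<int>(train_cfg["epochs"]);
  int batch = as<int>(train_cfg["batch_size"]);
  double lr = as<double>(train_cfg["learning_rate"]);
  double momentum = as<double>(train_cfg["momentum"]);
  double factor = as<double>(train_cfg["sched_factor"]);
  int patience = as<int>(train_cfg["sched_patience"]);
  double min_lr = as<double>(train_cfg["min_learning_rate"]);

  int n = X.n_rows;
  Grads v; // momentum velocities
  if (a.has_conv) {
    v.conv_W = fmat(p.conv_W.n_rows, p.conv_W.n_cols, arma::fill::zeros);
    v.conv_b = frowvec(p.conv_b.n_elem, arma::fill::zeros);
  }
  for (size_t l = 0; l < p.W.size(); ++l) {
    v.W.push_back(fmat(p.W[l].n_rows, p.W[l].n_cols, arma::fill::zeros));
    v.b.push_back(frowvec(p.b[l].n_elem, arma::fill::zeros));
  }

  NumericVector tr_loss(epochs), tr_acc(epochs), va_loss(epochs),
      va_acc(epochs), lrs(epochs);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  double best_val = R_PosInf;
  int wait = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double loss_sum = 0.0;
    int correct = 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(n, s + batch);
      arma::uvec rows(e - s);
      for (int i = s; i < e; ++i) rows[i - s] = idx[i];
      fmat Xb = X.rows(rows);
      fvec yb = y.elem(rows);
      Grads g;
      fvec prob;
      double loss = batch_grads(Xb, yb, a, p, g, prob);
      loss_sum += loss * (e - s);
      for (int i = 0; i < e - s; ++i)
        if ((prob[i] >= 0.5f) == (yb[i] >= 0.5f)) ++correct;
      // SGD + momentum (v = m*v - lr*g; w += v)
      const float flr = (float)lr, fm = (float)momentum;
      if (a.has_conv) {
        v.conv_W = fm * v.conv_W - flr * g.conv_W;
        p.conv_W += v.conv_W;
        v.conv_b = fm * v.conv_b - flr * g.conv_b;
        p.conv_b += v.conv_b;
      }
      for (size_t l = 0; l < p.W.size(); ++l) {
        v.W[l] = fm * v.W[l] - flr * g.W[l];
        p.W[l] += v.W[l];
        v.b[l] = fm * v.b[l] - flr * g.b[l];
        p.b[l] += v.b[l];
      }
    }
    tr_loss[ep] = loss_sum / n;
    tr_acc[ep] = (double)correct / n;
    fvec pv = predict_chunked(Xval, a, p);
    va_loss[ep] = bce(pv, yval);
    int vc = 0;
    for (uword i = 0; i < pv.n_elem; ++i)
      if ((pv[i] >= 0.5f) == (yval[i] >= 0.5f)) ++vc;
    va_acc[ep] = (double)vc / pv.n_elem;
    lrs[ep] = lr;
    // plateau scheduler on validation loss
    if (va_loss[ep] < best_val - 1e-8) {
      best_val = va_loss[ep];
      wait = 0;
    } else if (++wait >= patience) {
      lr = std::max(lr * factor, min_lr);
      wait = 0;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = wrap_params(a, p),
                      _["train_loss"] = tr_loss, _["train_acc"] = tr_acc,
                      _["val_loss"] = va_loss, _["val_acc"] = va_acc,
                      _["lr"] = lrs);
}

// [[Rcpp::export]]
NumericVector cpp_predict(SEXP X_, List arch, List params) {
  ArchSpec a = parse_arch(arch);
  Params p = parse_params(a, params);
  fmat X = toF(X_);
  if ((int)X.n_cols != a.input_len) stop("input length mismatch");
  fvec out = predict_chunked(X, a, p);
  return wrap(arma::conv_to<arma::vec>::from(out));
}
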