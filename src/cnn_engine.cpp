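// Training/prediction engine for the 1-D convolutional classifier.
// Mirrors the reference R implementation in R/cnn_train.R exactly
// (same activation layout: (n, L*C) matrices, column = l + (c-1)*L;
// same im2col convolution, max-pool argmax ties to the first offset,
// inverted dropout, Adam updates). The R path is kept as the slow
// oracle; this is the production path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

enum LayerKind { CONV = 0, POOL = 1, DENSE = 2, SOFTMAX = 3 };

struct Layer {
  int kind;
  int width;   // conv kernel / pool width
  int Lin, Cin, Lout, Cout;
};

struct Cache {
  mat Xcol;    // conv
  umat mask;   // conv relu mask (on (n*L, Cout) view)
  imat arg;    // pool argmax offset (1-based)
  mat flat;    // dense/softmax input
  umat relu_mask;
  mat drop_mask;
  bool has_drop = false;
};

static std::vector<Layer> parse_layers(const Rcpp::IntegerMatrix& ltab) {
  std::vector<Layer> out;
  for (int i = 0; i < ltab.nrow(); ++i) {
    Layer l;
    l.kind = ltab(i, 0);
    l.width = ltab(i, 1);
    l.Lin = ltab(i, 2);
    l.Cin = ltab(i, 3);
    l.Lout = ltab(i, 4);
    l.Cout = ltab(i, 5);
    out.push_back(l);
  }
  return out;
}

// im2col with same padding; Mp channel blocks are contiguous so each
// (offset, channel) column of Xcol is one memcpy
static mat conv_im2col(const mat& X, int L, int C, int width) {
  const int n = X.n_rows, pad = (width - 1) / 2, Lp = L + 2 * pad;
  mat Mp(n, (size_t)Lp * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    Mp.cols((size_t)c * Lp + pad, (size_t)c * Lp + pad + L - 1) =
      X.cols((size_t)c * L, (size_t)c * L + L - 1);
  }
  mat Xcol((size_t)n * L, (size_t)width * C);
  for (int off = 0; off < width; ++off) {
    for (int c = 0; c < C; ++c) {
      std::memcpy(Xcol.colptr((size_t)off * C + c),
                  Mp.colptr((size_t)c * Lp + off),
                  sizeof(double) * (size_t)n * L);
    }
  }
  return Xcol;
}

static mat conv_col2im(const mat& dXcol, int n, int L, int C, int width) {
  const int pad = (width - 1) / 2, Lp = L + 2 * pad;
  mat dMp(n, (size_t)Lp * C, fill::zeros);
  for (int off = 0; off < width; ++off) {
    for (int c = 0; c < C; ++c) {
      double* dst = dMp.colptr((size_t)c * Lp + off);
      const double* src = dXcol.colptr((size_t)off * C + c);
      for (size_t i = 0; i < (size_t)n * L; ++i) dst[i] += src[i];
    }
  }
  mat dX(n, (size_t)L * C);
  for (int c = 0; c < C; ++c) {
    dX.cols((size_t)c * L, (size_t)c * L + L - 1) =
      dMp.cols((size_t)c * Lp + pad, (size_t)c * Lp + pad + L - 1);
  }
  return dX;
}

// forward through all layers; caches filled when train_mode (or when
// caches != nullptr)
static mat forward(const mat& X, const std::vector<Layer>& layers,
                   std::vector<mat>& W, std::vector<vec>& b,
                   double dropout_rate, bool train_mode,
                   std::vector<Cache>* caches) {
  mat A = X;
  const int n = X.n_rows;
  for (size_t k = 0; k < layers.size(); ++k) {
    const Layer& ly = layers[k];
    if (ly.kind == CONV) {
      mat Xcol = conv_im2col(A, ly.Lin, ly.Cin, ly.width);
      mat Z = Xcol * W[k];
      Z.each_row() += b[k].t();
      umat mask = Z > 0;
      Z %= conv_to<mat>::from(mask);
      Z.reshape(n, (size_t)ly.Lin * ly.Cout);
      A = std::move(Z);
      if (caches) {
        (*caches)[k].Xcol = std::move(Xcol);
        (*caches)[k].mask = std::move(mask);
      }
    } else if (ly.kind == POOL) {
      const int L = ly.Lin, C = ly.Cin, w = ly.width, Lo = ly.Lout;
      mat best(n, (size_t)Lo * C);
      imat arg(n, (size_t)Lo * C);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < Lo; ++j) {
      double* bp = best.colptr((size_t)c * Lo + j);
      int* ap = arg.colptr((size_t)c * Lo + j);
      const double* x0 = A.colptr((size_t)c * L + (size_t)j * w);
      for (int i = 0; i < n; ++i) { bp[i] = x0[i]; ap[i] = 1; }
      for (int off = 1; off < w; ++off) {
        const double* xo = A.colptr((size_t)c * L + (size_t)j * w + off);
        for (int i = 0; i < n; ++i) {
          if (xo[i] > bp[i]) { bp[i] = xo[i]; ap[i] = off + 1; }
        }
      }
        }
      }
      A = std::move(best);
      if (caches) (*caches)[k].arg = std::move(arg);
    } else if (ly.kind == DENSE) {
      mat Z = A * W[k];
      Z.each_row() += b[k].t();
      umat relu_mask = Z > 0;
      mat H = Z % conv_to<mat>::from(relu_mask);
      if (caches) {
        (*caches)[k].flat = std::move(A);
        (*caches)[k].relu_mask = std::move(relu_mask);
        (*caches)[k].has_drop = false;
      }
      if (train_mode && dropout_rate > 0) {
        const double keep = 1.0 - dropout_rate;
        mat dm(H.n_rows, H.n_cols);
        // column-major draw matches matrix(runif(length(H)), nrow(H)) in R
        for (size_t i = 0; i < dm.n_elem; ++i) {
          dm[i] = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        }
        H %= dm;
        if (caches) {
          (*caches)[k].drop_mask = std::move(dm);
          (*caches)[k].has_drop = true;
        }
      }
      A = std::move(H);
    } else {  // SOFTMAX
      mat Z = A * W[k];
      Z.each_row() += b[k].t();
      if (caches) (*caches)[k].flat = std::move(A);
      Z.each_col() -= max(Z, 1);
      Z = exp(Z);
      Z.each_col() /= sum(Z, 1);
      A = std::move(Z);
    }
  }
  return A;
}

static void backward(const mat& probs, const mat& Y1hot,
                     const std::vector<Layer>& layers,
                     std::vector<mat>& W, std::vector<Cache>& caches,
                     std::vector<mat>& gW, std::vector<vec>& gb) {
  const int n = probs.n_rows;
  mat dA = (probs - Y1hot) / (double)n;
  for (int k = (int)layers.size() - 1; k >= 0; --k) {
    const Layer& ly = layers[k];
    if (ly.kind == SOFTMAX) {
      gW[k] = caches[k].flat.t() * dA;
      gb[k] = sum(dA, 0).t();
      dA = dA * W[k].t();
    } else if (ly.kind == DENSE) {
      if (caches[k].has_drop) dA %= caches[k].drop_mask;
      dA %= conv_to<mat>::from(caches[k].relu_mask);
      gW[k] = caches[k].flat.t() * dA;
      gb[k] = sum(dA, 0).t();
      dA = dA * W[k].t();
    } else if (ly.kind == POOL) {
      const int L = ly.Lin, C = ly.Cin, w = ly.width, Lo = ly.Lout;
      mat dX(n, (size_t)L * C, fill::zeros);
      for (int c = 0; c < C; ++c) {
        for (int j = 0; j < Lo; ++j) {
          const double* dp = dA.colptr((size_t)c * Lo + j);
          const int* ap = caches[k].arg.colptr((size_t)c * Lo + j);
          for (int i = 0; i < n; ++i) {
            dX((size_t)i + (size_t)n * ((size_t)c * L + (size_t)j * w +
                                        ap[i] - 1)) = dp[i];
          }
        }
      }
      dA = std::move(dX);
    } else {  // CONV
      dA.reshape((size_t)n * ly.Lin, ly.Cout);
      dA %= conv_to<mat>::from(caches[k].mask);
      gW[k] = caches[k].Xcol.t() * dA;
      gb[k] = sum(dA, 0).t();
      mat dXcol = dA * W[k].t();
      dA = conv_col2im(dXcol, n, ly.Lin, ly.Cin, ly.width);
    }
  }
}

static void unpack_params(const Rcpp::List& params, std::vector<mat>& W,
                          std::vector<vec>& b) {
  for (int k = 0; k < params.size(); ++k) {
    Rcpp::List p = params[k];
    if (p.size() == 0) {
      W.push_back(mat());
      b.push_back(vec());
    } else {
      W.push_back(Rcpp::as<mat>(p["W"]));
      b.push_back(Rcpp::as<vec>(p["b"]));
    }
  }
}

static Rcpp::List pack_params(const std::vector<Layer>& layers,
                              const std::vector<mat>& W,
                              const std::vector<vec>& b) {
  Rcpp::List out(layers.size());
  for (size_t k = 0; k < layers.size(); ++k) {
    if (layers[k].kind == POOL) {
      out[k] = Rcpp::List::create();
    } else {
      out[k] = Rcpp::List::create(Rcpp::Named("W") = W[k],
                                  Rcpp::Named("b") = Rcpp::NumericVector(b[k].begin(), b[k].end()));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_forward")]]
arma::mat cpp_forward(const arma::mat& X, const Rcpp::IntegerMatrix& ltab,
                      const Rcpp::List& params) {
  std::vector<Layer> layers = parse_layers(ltab);
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(params, W, b);
  return forward(X, layers, W, b, 0.0, false, nullptr);
}

// [[Rcpp::export(name = ".cpp_train")]]
Rcpp::List cpp_train(const arma::mat& X, const arma::ivec& y,
                     const Rcpp::IntegerMatrix& ltab,
                     const Rcpp::List& params0, int epochs, double alpha,
                     double dropout_rate, int batch_size, double beta1,
                     double beta2, double eps) {
  std::vector<Layer> layers = parse_layers(ltab);
  std::vector<mat> W;
  std::vector<vec> b;
  unpack_params(params0, W, b);
  const size_t nl = layers.size();
  std::vector<mat> mW(nl), vW(nl), gW(nl);
  std::vector<vec> mb(nl), vb(nl), gb(nl);
  for (size_t k = 0; k < nl; ++k) {
    mW[k] = zeros<mat>(W[k].n_rows, W[k].n_cols);
    vW[k] = mW[k];
    mb[k] = zeros<vec>(b[k].n_elem);
    vb[k] = mb[k];
  }
  const int n = X.n_rows;
  const int bs = std::min(batch_size, n);
  vec loss_hist(epochs), acc_hist(epochs);
  std::vector<Cache> caches(nl);
  uvec perm(n);
  long t_step = 0;
  const double CLIP = 1e-12;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    // seeded Fisher-Yates shuffle through R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double loss_sum = 0.0;
    long correct = 0;
    for (int s = 0; s < n; s += bs) {
      const int e = std::min(s + bs, n) - 1;
      uvec idx = perm.subvec(s, e);
      mat xb = X.rows(idx);
      const int nb = xb.n_rows;
      vec yb(nb);
      for (int i = 0; i < nb; ++i) yb[i] = (double)y[idx[i]];
      mat probs = forward(xb, layers, W, b, dropout_rate, true, &caches);
      double ls = 0.0;
      for (int i = 0; i < nb; ++i) {
        double h = std::min(std::max(probs(i, 1), CLIP), 1.0 - CLIP);
        ls -= yb[i] * std::log(h) + (1.0 - yb[i]) * std::log1p(-h);
        if ((probs(i, 1) > probs(i, 0)) == (yb[i] == 1.0)) ++correct;
      }
      if (!std::isfinite(ls)) {
        Rcpp::stop("non-finite loss at epoch %d; try a smaller learning rate",
                   epoch + 1);
      }
      loss_sum += ls;
      mat Y1hot(nb, 2);
      Y1hot.col(0) = 1.0 - yb;
      Y1hot.col(1) = yb;
      backward(probs, Y1hot, layers, W, caches, gW, gb);
      ++t_step;
      const double c1 = 1.0 - std::pow(beta1, (double)t_step);
      const double c2 = 1.0 - std::pow(beta2, (double)t_step);
      for (size_t k = 0; k < nl; ++k) {
        if (layers[k].kind == POOL) continue;
        mW[k] = beta1 * mW[k] + (1.0 - beta1) * gW[k];
        vW[k] = beta2 * vW[k] + (1.0 - beta2) * square(gW[k]);
        W[k] -= alpha * (mW[k] / c1) / (sqrt(vW[k] / c2) + eps);
        mb[k] = beta1 * mb[k] + (1.0 - beta1) * gb[k];
        vb[k] = beta2 * vb[k] + (1.0 - beta2) * square(gb[k]);
        b[k] -= alpha * (mb[k] / c1) / (sqrt(vb[k] / c2) + eps);
      }
    }
    loss_hist[epoch] = loss_sum / n;
    acc_hist[epoch] = (double)correct / n;
    if (epoch % 10 == 9) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = pack_params(layers, W, b),
    Rcpp::Named("loss") = Rcpp::wrap(loss_hist),
    Rcpp::Named("accuracy") = Rcpp::wrap(acc_hist));
}
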