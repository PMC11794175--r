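// Minimal convolution primitives for the desk-scale networks.
//
// Multi-channel frame stacks are arma::cubes of shape H x W x (C*T), slice
// index = c*T + t (all frames of channel 0 first).  Spatial convolutions use
// im2col + BLAS; temporal convolutions are slice-wise weighted sums.  All
// kernels are 3 (spatial 3x3, temporal 3) with zero padding 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int outdim(int n, int stride) { return (n + stride - 1) / stride; }

// im2col for one frame (all input channels), pad 1, kernel 3x3.
// Returns (H2*W2) x (9*Cin); column order: ci-major, then (ky,kx).
static arma::mat im2col3(const arma::cube& x, int T, int Cin, int t, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int H2 = outdim(H, stride), W2 = outdim(W, stride);
  arma::mat M(H2 * (size_t)W2, 9 * (size_t)Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const arma::mat& s = x.slice((size_t)ci * T + t);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int col = ci * 9 + (ky + 1) * 3 + (kx + 1);
        for (int ox = 0; ox < W2; ++ox) {
          const int ix = ox * stride + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < H2; ++oy) {
            const int iy = oy * stride + ky;
            if (iy < 0 || iy >= H) continue;
            M((size_t)ox * H2 + oy, col) = s(iy, ix);
          }
        }
      }
    }
  }
  return M;
}

// scatter-add of col-matrix gradient back to input frame gradient
static void col2im3(arma::cube& dx, const arma::mat& dM, int T, int Cin, int t,
                    int stride) {
  const int H = dx.n_rows, W = dx.n_cols;
  const int H2 = outdim(H, stride), W2 = outdim(W, stride);
  for (int ci = 0; ci < Cin; ++ci) {
    arma::mat& s = dx.slice((size_t)ci * T + t);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int col = ci * 9 + (ky + 1) * 3 + (kx + 1);
        for (int ox = 0; ox < W2; ++ox) {
          const int ix = ox * stride + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < H2; ++oy) {
            const int iy = oy * stride + ky;
            if (iy < 0 || iy >= H) continue;
            s(iy, ix) += dM((size_t)ox * H2 + oy, col);
          }
        }
      }
    }
  }
}

// Spatial 3x3 convolution, weights (9*Cin) x Cout, bias length Cout.
// [[Rcpp::export]]
arma::cube sconv_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int T, int stride) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_cols;
  const int H2 = outdim(x.n_rows, stride), W2 = outdim(x.n_cols, stride);
  arma::cube y(H2, W2, (size_t)Cout * T);
  for (int t = 0; t < T; ++t) {
    arma::mat M = im2col3(x, T, Cin, t, stride);
    arma::mat O = M * W;               // (H2*W2) x Cout
    O.each_row() += b.t();
    for (int co = 0; co < Cout; ++co)
      y.slice((size_t)co * T + t) = arma::reshape(O.col(co), H2, W2);
  }
  return y;
}

// Backward of sconv_fwd. dy has shape H2 x W2 x (Cout*T).
// [[Rcpp::export]]
List sconv_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy,
               int T, int stride) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_cols;
  const int H2 = dy.n_rows, W2 = dy.n_cols;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  arma::mat dO(H2 * (size_t)W2, Cout);
  for (int t = 0; t < T; ++t) {
    for (int co = 0; co < Cout; ++co) {
      dO.col(co) = arma::vectorise(dy.slice((size_t)co * T + t));
      db(co) += arma::accu(dO.col(co));
    }
    arma::mat M = im2col3(x, T, Cin, t, stride);
    dW += M.t() * dO;
    col2im3(dx, dO * W.t(), T, Cin, t, stride);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Temporal convolution, kernel 3, pad 1: weights Cout x (3*Cin), column
// order ci-major then k in {-1,0,1}; bias length Cout.
// [[Rcpp::export]]
arma::cube tconv_fwd(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int T) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_rows;
  arma::cube y(x.n_rows, x.n_cols, (size_t)Cout * T);
  for (int co = 0; co < Cout; ++co) {
    for (int t = 0; t < T; ++t) {
      arma::mat acc(x.n_rows, x.n_cols);
      acc.fill(b(co));
      for (int ci = 0; ci < Cin; ++ci) {
        for (int k = -1; k <= 1; ++k) {
          const int tt = t + k;
          if (tt < 0 || tt >= T) continue;
          acc += W(co, ci * 3 + (k + 1)) * x.slice((size_t)ci * T + tt);
        }
      }
      y.slice((size_t)co * T + t) = acc;
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv_bwd(const arma::cube& x, const arma::mat& W, const arma::cube& dy,
               int T) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_rows;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::cube dx(x.n_rows, x.n_cols, x.n_slices, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    for (int t = 0; t < T; ++t) {
      const arma::mat& g = dy.slice((size_t)co * T + t);
      db(co) += arma::accu(g);
      for (int ci = 0; ci < Cin; ++ci) {
        for (int k = -1; k <= 1; ++k) {
          const int tt = t + k;
          if (tt < 0 || tt >= T) continue;
          dW(co, ci * 3 + (k + 1)) += arma::accu(g % x.slice((size_t)ci * T + tt));
          dx.slice((size_t)ci * T + tt) += W(co, ci * 3 + (k + 1)) * g;
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Nearest-neighbour 2x upsampling of every slice.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& x) {
  arma::cube y(x.n_rows * 2, x.n_cols * 2, x.n_slices);
  for (size_t s = 0; s < x.n_slices; ++s)
    for (size_t j = 0; j < x.n_cols; ++j)
      for (size_t i = 0; i < x.n_rows; ++i) {
        const double v = x(i, j, s);
        y(2 * i, 2 * j, s) = v;
        y(2 * i + 1, 2 * j, s) = v;
        y(2 * i, 2 * j + 1, s) = v;
        y(2 * i + 1, 2 * j + 1, s) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& dy) {
  arma::cube dx(dy.n_rows / 2, dy.n_cols / 2, dy.n_slices);
  for (size_t s = 0; s < dy.n_slices; ++s)
    for (size_t j = 0; j < dx.n_cols; ++j)
      for (size_t i = 0; i < dx.n_rows; ++i)
        dx(i, j, s) = dy(2 * i, 2 * j, s) + dy(2 * i + 1, 2 * j, s) +
                      dy(2 * i, 2 * j + 1, s) + dy(2 * i + 1, 2 * j + 1, s);
  return dx;
}

// ---- fused (2+1)D video network ------------------------------------------
// Blocks: spatial 3x3 stride-2 conv + ReLU, temporal 3-tap conv + ReLU.
// Heads: sigmoid continuum head + 3 linear auxiliary heads on GAP features.

static arma::cube sconv_f(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int T, int stride) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_cols;
  const int H2 = outdim(x.n_rows, stride), W2 = outdim(x.n_cols, stride);
  arma::cube y(H2, W2, (size_t)Cout * T);
  for (int t = 0; t < T; ++t) {
    arma::mat M = im2col3(x, T, Cin, t, stride);
    arma::mat O = M * W;
    O.each_row() += b.t();
    for (int co = 0; co < Cout; ++co)
      y.slice((size_t)co * T + t) = arma::reshape(O.col(co), H2, W2);
  }
  return y;
}

static arma::cube tconv_f(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int T) {
  const int Cin = x.n_slices / T;
  const int Cout = W.n_rows;
  arma::cube y(x.n_rows, x.n_cols, (size_t)Cout * T);
  for (int co = 0; co < Cout; ++co)
    for (int t = 0; t < T; ++t) {
      arma::mat acc(x.n_rows, x.n_cols);
      acc.fill(b(co));
      for (int ci = 0; ci < Cin; ++ci)
        for (int k = -1; k <= 1; ++k) {
          const int tt = t + k;
          if (tt < 0 || tt >= T) continue;
          acc += W(co, ci * 3 + (k + 1)) * x.slice((size_t)ci * T + tt);
        }
      y.slice((size_t)co * T + t) = acc;
    }
  return y;
}

static arma::vec gap_f(const arma::cube& x, int T) {
  const int C = x.n_slices / T;
  arma::vec f(C);
  for (int c = 0; c < C; ++c) {
    double s = 0;
    for (int t = 0; t < T; ++t) s += arma::accu(x.slice((size_t)c * T + t));
    f(c) = s / (x.n_rows * x.n_cols * T);
  }
  return f;
}

// forward only: returns p, aux, features, last activations
// [[Rcpp::export]]
List vnet_forward_cpp(const arma::cube& video, List blocks,
                      const arma::vec& wp, double bp, const arma::mat& Wa,
                      const arma::vec& ba, int T) {
  arma::cube x = video - 0.5;
  for (int bi = 0; bi < blocks.size(); ++bi) {
    List b = blocks[bi];
    x = sconv_f(x, as<arma::mat>(b["Ws"]), as<arma::vec>(b["bs"]), T, 2);
    x.transform([](double v) { return v > 0 ? v : 0; });
    x = tconv_f(x, as<arma::mat>(b["Wt"]), as<arma::vec>(b["bt"]), T);
    x.transform([](double v) { return v > 0 ? v : 0; });
  }
  arma::vec f = gap_f(x, T);
  const double logit = arma::dot(wp, f) + bp;
  const double p = 1.0 / (1.0 + std::exp(-logit));
  arma::vec aux = Wa * f + ba;
  return List::create(_["p"] = p, _["aux"] = aux, _["features"] = f,
                      _["acts"] = x);
}

// fused forward + backward for one video
// [[Rcpp::export]]
List vnet_grad_cpp(const arma::cube& video, List blocks, const arma::vec& wp,
                   double bp, const arma::mat& Wa, const arma::vec& ba,
                   int T, double y, const arma::vec& aux_t,
                   const arma::vec& aux_mask, double lambda) {
  const int nb = blocks.size();
  std::vector<arma::cube> xs(nb + 1), ss(nb), ts(nb);
  xs[0] = video - 0.5;
  for (int bi = 0; bi < nb; ++bi) {
    List b = blocks[bi];
    ss[bi] = sconv_f(xs[bi], as<arma::mat>(b["Ws"]), as<arma::vec>(b["bs"]),
                     T, 2);
    arma::cube sr = ss[bi];
    sr.transform([](double v) { return v > 0 ? v : 0; });
    ts[bi] = tconv_f(sr, as<arma::mat>(b["Wt"]), as<arma::vec>(b["bt"]), T);
    arma::cube tr = ts[bi];
    tr.transform([](double v) { return v > 0 ? v : 0; });
    xs[bi + 1] = tr;
  }
  arma::vec f = gap_f(xs[nb], T);
  const double logit = arma::dot(wp, f) + bp;
  const double p = 1.0 / (1.0 + std::exp(-logit));
  const double pc = std::min(std::max(p, 1e-7), 1.0 - 1e-7);
  arma::vec aux = Wa * f + ba;
  arma::vec res = (aux - aux_t) % aux_mask;
  const double bern = -(y * std::log(pc) + (1 - y) * std::log(1 - pc));
  const double loss = bern + lambda * arma::accu(arma::square(res));

  const double dlogit = p - y;
  arma::vec daux = 2.0 * lambda * res;
  arma::vec df = wp * dlogit + Wa.t() * daux;

  const arma::cube& last = xs[nb];
  const int C = last.n_slices / T;
  arma::cube dx(last.n_rows, last.n_cols, last.n_slices);
  const double denom = (double)last.n_rows * last.n_cols * T;
  for (int c = 0; c < C; ++c)
    for (int t = 0; t < T; ++t)
      dx.slice((size_t)c * T + t).fill(df(c) / denom);

  List gblocks(nb);
  for (int bi = nb - 1; bi >= 0; --bi) {
    List b = blocks[bi];
    arma::mat Wt = as<arma::mat>(b["Wt"]);
    arma::mat Ws = as<arma::mat>(b["Ws"]);
    // ReLU after temporal conv
    for (size_t i = 0; i < dx.n_elem; ++i)
      if (ts[bi](i) < 0) dx(i) = 0;
    // temporal conv backward (input was relu(ss))
    arma::cube sr = ss[bi];
    sr.transform([](double v) { return v > 0 ? v : 0; });
    const int Cin_t = sr.n_slices / T;
    const int Cout_t = Wt.n_rows;
    arma::mat dWt(Wt.n_rows, Wt.n_cols, arma::fill::zeros);
    arma::vec dbt(Cout_t, arma::fill::zeros);
    arma::cube ds(sr.n_rows, sr.n_cols, sr.n_slices, arma::fill::zeros);
    for (int co = 0; co < Cout_t; ++co)
      for (int t = 0; t < T; ++t) {
        const arma::mat& g = dx.slice((size_t)co * T + t);
        dbt(co) += arma::accu(g);
        for (int ci = 0; ci < Cin_t; ++ci)
          for (int k = -1; k <= 1; ++k) {
            const int tt = t + k;
            if (tt < 0 || tt >= T) continue;
            dWt(co, ci * 3 + (k + 1)) += arma::accu(g % sr.slice((size_t)ci * T + tt));
            ds.slice((size_t)ci * T + tt) += Wt(co, ci * 3 + (k + 1)) * g;
          }
      }
    // ReLU after spatial conv
    for (size_t i = 0; i < ds.n_elem; ++i)
      if (ss[bi](i) < 0) ds(i) = 0;
    // spatial conv backward
    const int Cin_s = xs[bi].n_slices / T;
    const int Cout_s = Ws.n_cols;
    arma::mat dWs(Ws.n_rows, Ws.n_cols, arma::fill::zeros);
    arma::vec dbs(Cout_s, arma::fill::zeros);
    arma::cube dxp(xs[bi].n_rows, xs[bi].n_cols, xs[bi].n_slices,
                   arma::fill::zeros);
    arma::mat dO(ds.n_rows * (size_t)ds.n_cols, Cout_s);
    for (int t = 0; t < T; ++t) {
      for (int co = 0; co < Cout_s; ++co) {
        dO.col(co) = arma::vectorise(ds.slice((size_t)co * T + t));
        dbs(co) += arma::accu(dO.col(co));
      }
      arma::mat M = im2col3(xs[bi], T, Cin_s, t, 2);
      dWs += M.t() * dO;
      col2im3(dxp, dO * Ws.t(), T, Cin_s, t, 2);
    }
    gblocks[bi] = List::create(_["Ws"] = dWs, _["bs"] = dbs, _["Wt"] = dWt,
                               _["bt"] = dbt);
    dx = dxp;
  }
  List grads = List::create(
      _["blocks"] = gblocks, _["wp"] = arma::mat(f * dlogit),
      _["bp"] = dlogit, _["Wa"] = arma::mat(daux * f.t()), _["ba"] = daux);
  return List::create(_["loss"] = loss, _["bernoulli"] = bern,
                      _["grads"] = grads, _["p"] = p, _["aux"] = aux);
}
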