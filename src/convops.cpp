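// Low-level numerical kernels for the encoder-decoder networks and mask
// post-processing. Tensors are R arrays with dims (H, W, C), column-major,
// mapped onto arma::cube (n_rows = H, n_cols = W, n_slices = C).
// Convolutions are cross-correlations with zero 'same' padding, stride 1;
// down/up-sampling is done by dedicated 2x2 pool / transpose-conv kernels.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: rows index output pixels p = i + H*j; columns index (ki, kj, c)
// as q = ki + k*kj + k*k*c. Zero padding outside the raster.
static arma::mat im2col(const arma::cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  arma::mat out(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        const int di = ki - pad, dj = kj - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* col = out.colptr(q) + j * H;
          const double* src = xc.colptr(j + dj) + di;
          for (int i = i0; i < i1; ++i) col[i] = src[i];
        }
      }
    }
  }
  return out;
}

// col2im: scatter-add, the adjoint of im2col.
static arma::cube col2im(const arma::mat& m, int H, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  arma::cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& xc = out.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int q = ki + k * kj + k * k * c;
        const int di = ki - pad, dj = kj - pad;
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* col = m.colptr(q) + j * H;
          double* dst = xc.colptr(j + dj) + di;
          for (int i = i0; i < i1; ++i) dst[i] += col[i];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x_, NumericVector w_,
                            NumericVector b_) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat wm(w_.begin(), k * k * C, Cout, false);
  arma::mat y = im2col(x, k) * wm;
  y.each_row() += arma::rowvec(b_.begin(), Cout, false);
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(H, W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x_, NumericVector w_, NumericVector gy_) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int k = wd[0], Cout = wd[3];
  arma::cube x(x_.begin(), H, W, C, false);
  arma::mat wm(w_.begin(), k * k * C, Cout, false);
  arma::mat gy(gy_.begin(), H * W, Cout, false);
  arma::mat xcol = im2col(x, k);
  arma::mat gw = xcol.t() * gy;               // (k2C, Cout)
  arma::rowvec gb = arma::sum(gy, 0);
  arma::cube gx = col2im(gy * wm.t(), H, W, C, k);
  NumericVector gxv(gx.begin(), gx.end());
  gxv.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  return List::create(_["gx"] = gxv, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x_) {
  IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = H / 2, Wo = W / 2;
  arma::cube x(x_.begin(), H, W, C, false);
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector gy_) {
  IntegerVector gd = gy_.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2];
  arma::cube gy(gy_.begin(), Ho, Wo, C, false);
  arma::cube gx(2 * Ho, 2 * Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double v = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = v;
        gx(2 * i + 1, 2 * j, c) = v;
        gx(2 * i, 2 * j + 1, c) = v;
        gx(2 * i + 1, 2 * j + 1, c) = v;
      }
  NumericVector out(gx.begin(), gx.end());
  out.attr("dim") = IntegerVector::create(2 * Ho, 2 * Wo, C);
  return out;
}

// transpose convolution, kernel 2, stride 2 (non-overlapping):
// y[2i+a, 2j+b, co] = sum_ci x[i,j,ci] * w[a,b,ci,co] + b[co]
// [[Rcpp::export]]
NumericVector cpp_tconv2_fw(NumericVector x_, NumericVector w_,
                            NumericVector b_) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], Cout = wd[3];
  arma::mat xm(x_.begin(), H * W, C, false);
  arma::cube y(2 * H, 2 * W, Cout, arma::fill::zeros);
  arma::cube w(w_.begin(), 2 * 2, C, Cout, false); // (a+2b, ci, co)
  for (int co = 0; co < Cout; ++co) {
    arma::mat wab = w.slice(co);                    // (4, C)
    for (int ab = 0; ab < 4; ++ab) {
      const int a = ab % 2, b = ab / 2;
      arma::vec v = xm * wab.row(ab).t() + b_[co];  // (H*W)
      arma::mat vm(v.memptr(), H, W, false);
      arma::mat& ys = y.slice(co);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) ys(2 * i + a, 2 * j + b) = vm(i, j);
    }
  }
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_tconv2_bw(NumericVector x_, NumericVector w_, NumericVector gy_) {
  IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], Cout = wd[3];
  arma::mat xm(x_.begin(), H * W, C, false);
  arma::cube w(w_.begin(), 4, C, Cout, false);
  arma::cube gy(gy_.begin(), 2 * H, 2 * W, Cout, false);
  arma::cube gw(2, 2, C * Cout, arma::fill::zeros); // reshaped later
  arma::mat gx(H * W, C, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const arma::mat& gys = gy.slice(co);
    for (int ab = 0; ab < 4; ++ab) {
      const int a = ab % 2, b = ab / 2;
      arma::mat g(H, W);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) g(i, j) = gys(2 * i + a, 2 * j + b);
      arma::vec gv(g.memptr(), H * W, false);
      gb[co] += arma::accu(gv);
      // gw[a,b,ci,co] = sum_p x[p,ci] * g[p]
      arma::rowvec gwrow = gv.t() * xm;             // (C)
      for (int ci = 0; ci < C; ++ci)
        gw(a, b, ci + C * co) = gwrow[ci];
      // gx[p,ci] += g[p] * w[ab,ci,co]
      gx += gv * w.slice(co).row(ab);
    }
  }
  NumericVector gxv(gx.begin(), gx.end());
  gxv.attr("dim") = IntegerVector::create(H, W, C);
  NumericVector gwv(gw.begin(), gw.end());
  gwv.attr("dim") = IntegerVector::create(2, 2, C, Cout);
  return List::create(_["gx"] = gxv, _["gw"] = gwv,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 8-connected two-pass labelling with union-find; labels contiguous 1..n.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      const int di[4] = {-1, -1, 0, -1}; // N, NW (prev col up), W, SW order below
      // neighbours already visited in column-major scan: (i-1,j), (i-1,j-1),
      // (i,j-1), (i+1,j-1)
      int ni[4] = {i - 1, i - 1, i, i + 1};
      int nj[4] = {j, j - 1, j - 1, j - 1};
      (void)di;
      for (int t = 0; t < 4; ++t) {
        if (ni[t] < 0 || ni[t] >= H || nj[t] < 0) continue;
        int l = lab(ni[t], nj[t]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        best = parent.size();
        parent.push_back(best);
      }
      lab(i, j) = best;
    }
  }
  // second pass: resolve + compact
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++next;
        lab(i, j) = remap[r];
      }
  return lab;
}

// bilinear resampling of an (H,W,C) raster at source coordinates
// (srcy, srcx), 0-based pixel-centre convention; out-of-range clamped.
// [[Rcpp::export]]
NumericVector cpp_remap_bilinear(NumericVector img_, NumericMatrix srcy,
                                 NumericMatrix srcx) {
  IntegerVector xd = img_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int Ho = srcy.nrow(), Wo = srcy.ncol();
  arma::cube img(img_.begin(), H, W, C, false);
  arma::cube out(Ho, Wo, C);
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double sy = std::min(std::max(srcy(i, j), 0.0), H - 1.0);
      double sx = std::min(std::max(srcx(i, j), 0.0), W - 1.0);
      int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
      int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
      double fy = sy - i0, fx = sx - j0;
      for (int c = 0; c < C; ++c) {
        out(i, j, c) =
            (1 - fy) * (1 - fx) * img(i0, j0, c) +
            fy * (1 - fx) * img(i1, j0, c) +
            (1 - fy) * fx * img(i0, j1, c) + fy * fx * img(i1, j1, c);
      }
    }
  }
  NumericVector o(out.begin(), out.end());
  o.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return o;
}
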