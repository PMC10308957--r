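// Convolution and pooling kernels for the graph engine.
// Tensor layout follows R column-major arrays with dim c(H, W, C, N):
// flat index = h + H*(w + W*(c + C*n)).
// Weight layout dim c(kh, kw, Cin/groups, Cout):
// flat index = dh + kh*(dw + kw*(ci + Cg*co)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array [H, W, C, N]");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col buffer (rows = kh*kw*Cg, cols = Ho*Wo with ho fastest)
// for image n, channel group starting at c0.
static void im2col(const double* x, int H, int W, int C, int n,
                   int c0, int Cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& col) {
  for (int ci = 0; ci < Cg; ++ci) {
    const double* xc = x + (size_t)(c0 + ci) * H * W + (size_t)n * H * W * C;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          double* dst = col.colptr(0) + r; // access via col(r, j)
          if (wi < 0 || wi >= W) {
            for (int ho = 0; ho < Ho; ++ho) col(r, ho + Ho * wo) = 0.0;
            continue;
          }
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dh;
            col(r, ho + Ho * wo) =
              (hi < 0 || hi >= H) ? 0.0 : xc[hi + (size_t)H * wi];
          }
          (void)dst;
        }
      }
    }
  }
}

// Scatter-add the column buffer back into the input gradient.
static void col2im(arma::mat& col, double* dx, int H, int W, int C, int n,
                   int c0, int Cg, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  for (int ci = 0; ci < Cg; ++ci) {
    double* xc = dx + (size_t)(c0 + ci) * H * W + (size_t)n * H * W * C;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int r = dh + kh * (dw + kw * ci);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dh;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += col(r, ho + Ho * wo);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad, int groups) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4) stop("expected 4-d weights [kh, kw, Cin/groups, Cout]");
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  if (Cg * groups != C) stop("channel mismatch: input has " +
    std::to_string(C) + " channels, weights expect " + std::to_string(Cg * groups));
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("output would be empty");
  int Cout_g = Cout / groups;

  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat col(kh * kw * Cg, Ho * Wo);
  const double* xp = x.begin();
  double* yp = y.begin();

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      im2col(xp, H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      // weight block for this group: columns g*Cout_g .. (g+1)*Cout_g-1
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)kh * kw * Cg * (g * Cout_g),
                   kh * kw * Cg, Cout_g, false, true);
      arma::mat out = col.t() * Wm; // (Ho*Wo) x Cout_g
      for (int co = 0; co < Cout_g; ++co) {
        double bias = b.size() ? b[g * Cout_g + co] : 0.0;
        double* yc = yp + (size_t)(g * Cout_g + co) * Ho * Wo +
                     (size_t)n * Ho * Wo * Cout;
        const double* oc = out.colptr(co);
        for (int j = 0; j < Ho * Wo; ++j) yc[j] = oc[j] + bias;
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               int stride, int pad, int groups, bool has_bias) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int kh = wd[0], kw = wd[1], Cg = wd[2], Cout = wd[3];
  int Ho = (H + 2 * pad - kh) / stride + 1;
  int Wo = (W + 2 * pad - kw) / stride + 1;
  int Cout_g = Cout / groups;

  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((size_t)kh * kw * Cg * Cout);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cg, Cout);
  NumericVector db(has_bias ? Cout : 0);

  arma::mat col(kh * kw * Cg, Ho * Wo);
  arma::mat dYm(Ho * Wo, Cout_g);
  const double* xp = x.begin();
  const double* dyp = dy.begin();

  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      // gather dY for this (n, group) into (Ho*Wo) x Cout_g
      for (int co = 0; co < Cout_g; ++co) {
        const double* dc = dyp + (size_t)(g * Cout_g + co) * Ho * Wo +
                           (size_t)n * Ho * Wo * Cout;
        for (int j = 0; j < Ho * Wo; ++j) dYm(j, co) = dc[j];
        if (has_bias) {
          double s = 0.0;
          for (int j = 0; j < Ho * Wo; ++j) s += dc[j];
          db[g * Cout_g + co] += s;
        }
      }
      im2col(xp, H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo, col);
      arma::mat dWg = col * dYm; // R x Cout_g
      double* dwp = dw.begin() + (size_t)kh * kw * Cg * (g * Cout_g);
      for (int co = 0; co < Cout_g; ++co)
        for (int r = 0; r < kh * kw * Cg; ++r)
          dwp[r + (size_t)kh * kw * Cg * co] += dWg(r, co);
      arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)kh * kw * Cg * (g * Cout_g),
                   kh * kw * Cg, Cout_g, false, true);
      arma::mat dCol = Wm * dYm.t(); // R x (Ho*Wo)
      col2im(dCol, dx.begin(), H, W, C, n, g * Cg, Cg, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size()); // flat index into x of the max element
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (size_t)c * H * W + (size_t)n * H * W * C;
      size_t base = (size_t)c * H * W + (size_t)n * H * W * C;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          long bi = -1;
          for (int dw = 0; dw < k; ++dw) {
            int wi = wo * stride - pad + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = ho * stride - pad + dh;
              if (hi < 0 || hi >= H) continue;
              double v = xc[hi + (size_t)H * wi];
              if (v > best) { best = v; bi = hi + (size_t)H * wi; }
            }
          }
          if (bi < 0) { best = 0.0; bi = 0; } // fully padded window
          yp[(size_t)ho + Ho * ((size_t)wo) + (size_t)Ho * Wo * c +
             (size_t)Ho * Wo * C * n] = best;
          arg[(size_t)ho + Ho * ((size_t)wo) + (size_t)Ho * Wo * c +
              (size_t)Ho * Wo * C * n] = (int)(base + bi);
          ++q;
        }
    }
  (void)q;
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(NumericVector dy, IntegerVector arg, IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[arg[i]] += dy[i];
  return dx;
}
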