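// Hot numerical kernels: depthwise 3x3 convolution (forward/backward), GELU
// (forward/backward), row softmax (forward/backward), bilinear sampling and
// thin-plate-spline evaluation.  Everything else in the network is BLAS
// matrix algebra and stays in R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT2 = 0.70710678118654752440;
static const double INV_SQRT2PI = 0.39894228040143267794;

// depthwise 3x3 convolution on a g x g token grid; nbr holds 1-based row
// indices of each token's nine neighbors (0 = outside the grid).
// [[Rcpp::export(name = ".dwconv_fwd")]]
NumericMatrix dwconv_fwd(const NumericMatrix& xin, const NumericMatrix& Wdw,
                         const NumericVector& bdw, const IntegerMatrix& nbr) {
  const int N = xin.nrow(), C = xin.ncol();
  NumericMatrix out(N, C);
  for (int c = 0; c < C; ++c) {
    const double b = bdw[c];
    double* o_col = &out(0, c);
    const double* x_col = &xin(0, c);
    for (int t = 0; t < N; ++t) o_col[t] = b;
    for (int o = 0; o < 9; ++o) {
      const double w = Wdw(o, c);
      for (int t = 0; t < N; ++t) {
        const int r = nbr(t, o);
        if (r > 0) o_col[t] += w * x_col[r - 1];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".dwconv_bwd")]]
List dwconv_bwd(const NumericMatrix& dz, const NumericMatrix& xin,
                const NumericMatrix& Wdw, const IntegerMatrix& nbr) {
  const int N = xin.nrow(), C = xin.ncol();
  NumericMatrix dx(N, C), dW(9, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    const double* dz_col = &dz(0, c);
    const double* x_col = &xin(0, c);
    double* dx_col = &dx(0, c);
    double acc_b = 0.0;
    for (int t = 0; t < N; ++t) acc_b += dz_col[t];
    db[c] = acc_b;
    for (int o = 0; o < 9; ++o) {
      const double w = Wdw(o, c);
      double acc_w = 0.0;
      for (int t = 0; t < N; ++t) {
        const int r = nbr(t, o);
        if (r > 0) {
          dx_col[r - 1] += w * dz_col[t];
          acc_w += x_col[r - 1] * dz_col[t];
        }
      }
      dW(o, c) = acc_w;
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// exact GELU x * Phi(x); returns the activation and Phi(x) for the backward
// [[Rcpp::export(name = ".gelu_fwd")]]
List gelu_fwd(const NumericMatrix& x) {
  const int n = x.nrow() * x.ncol();
  NumericMatrix y(x.nrow(), x.ncol()), phi(x.nrow(), x.ncol());
  const double* xp = x.begin();
  double* yp = y.begin();
  double* pp = phi.begin();
  for (int i = 0; i < n; ++i) {
    const double p = 0.5 * std::erfc(-xp[i] * INV_SQRT2);
    pp[i] = p;
    yp[i] = xp[i] * p;
  }
  return List::create(_["y"] = y, _["phi"] = phi);
}

// [[Rcpp::export(name = ".gelu_bwd")]]
NumericMatrix gelu_bwd(const NumericMatrix& dy, const NumericMatrix& x,
                       const NumericMatrix& phi) {
  const int n = x.nrow() * x.ncol();
  NumericMatrix dx(x.nrow(), x.ncol());
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  const double* pp = phi.begin();
  double* dxp = dx.begin();
  for (int i = 0; i < n; ++i) {
    const double dens = INV_SQRT2PI * std::exp(-0.5 * xp[i] * xp[i]);
    dxp[i] = dyp[i] * (pp[i] + xp[i] * dens);
  }
  return dx;
}

// numerically-stable row-wise softmax (column-major scans, row accumulators)
// [[Rcpp::export(name = ".softmax_rows")]]
NumericMatrix softmax_rows_cpp(const NumericMatrix& z) {
  const int n = z.nrow(), m = z.ncol();
  NumericMatrix out(n, m);
  std::vector<double> mx(n, R_NegInf), sum(n, 0.0);
  const double* zp = z.begin();
  double* op = out.begin();
  for (int j = 0; j < m; ++j) {
    const double* col = zp + (size_t)j * n;
    for (int i = 0; i < n; ++i) if (col[i] > mx[i]) mx[i] = col[i];
  }
  for (int j = 0; j < m; ++j) {
    const double* col = zp + (size_t)j * n;
    double* ocol = op + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double e = std::exp(col[i] - mx[i]);
      ocol[i] = e;
      sum[i] += e;
    }
  }
  for (int i = 0; i < n; ++i) sum[i] = 1.0 / sum[i];
  for (int j = 0; j < m; ++j) {
    double* ocol = op + (size_t)j * n;
    for (int i = 0; i < n; ++i) ocol[i] *= sum[i];
  }
  return out;
}

// softmax jacobian applied to upstream dS: S * (dS - rowSums(dS * S))
// [[Rcpp::export(name = ".softmax_rows_bwd")]]
NumericMatrix softmax_rows_bwd(const NumericMatrix& dS,
                               const NumericMatrix& S) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix out(n, m);
  std::vector<double> dot(n, 0.0);
  const double* dp = dS.begin();
  const double* sp = S.begin();
  double* op = out.begin();
  for (int j = 0; j < m; ++j) {
    const double* dcol = dp + (size_t)j * n;
    const double* scol = sp + (size_t)j * n;
    for (int i = 0; i < n; ++i) dot[i] += dcol[i] * scol[i];
  }
  for (int j = 0; j < m; ++j) {
    const double* dcol = dp + (size_t)j * n;
    const double* scol = sp + (size_t)j * n;
    double* ocol = op + (size_t)j * n;
    for (int i = 0; i < n; ++i) ocol[i] = scol[i] * (dcol[i] - dot[i]);
  }
  return out;
}

// bilinear sampling at continuous (y, x); values sit at pixel centers
// (i + 0.5); samples blending outside the image mix with `fill`
// [[Rcpp::export(name = ".bilinear_sample")]]
NumericVector bilinear_sample_cpp(const NumericMatrix& px,
                                  const NumericVector& y,
                                  const NumericVector& x, double fill) {
  const int H = px.nrow(), W = px.ncol(), n = y.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    const double u = y[k] - 0.5, v = x[k] - 0.5;
    const int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
    const double fy = u - i0, fx = v - j0;
    double vals[4];
    const int ii[2] = {i0, i0 + 1};
    const int jj[2] = {j0, j0 + 1};
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        const int i = ii[a], j = jj[b];
        vals[a * 2 + b] =
          (i >= 0 && i < H && j >= 0 && j < W) ? px(i, j) : fill;
      }
    out[k] = (1 - fy) * ((1 - fx) * vals[0] + fx * vals[1]) +
      fy * ((1 - fx) * vals[2] + fx * vals[3]);
  }
  return out;
}

// thin-plate-spline evaluation: affine part plus r^2 log r radial terms
// [[Rcpp::export(name = ".tps_eval")]]
NumericMatrix tps_eval_cpp(const NumericMatrix& coords,
                           const NumericMatrix& src,
                           const NumericMatrix& affine,
                           const NumericMatrix& weights) {
  const int m = coords.nrow(), k = src.nrow();
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    const double y = coords(i, 0), x = coords(i, 1);
    double oy = affine(0, 0) + affine(1, 0) * y + affine(2, 0) * x;
    double ox = affine(0, 1) + affine(1, 1) * y + affine(2, 1) * x;
    for (int j = 0; j < k; ++j) {
      const double dy = y - src(j, 0), dx = x - src(j, 1);
      const double r2 = dy * dy + dx * dx;
      if (r2 > 0) {
        const double u = 0.5 * r2 * std::log(r2);  // r^2 log r
        oy += weights(j, 0) * u;
        ox += weights(j, 1) * u;
      }
    }
    out(i, 0) = oy;
    out(i, 1) = ox;
  }
  return out;
}
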