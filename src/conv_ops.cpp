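#include <RcppArmadillo.h>
using namespace Rcpp;

// 3x3 convolutions with stride 1 and zero padding 1, via im2col + BLAS.
// Tensor layout follows R column-major arrays: x is (H, W, C, N).

static arma::mat im2col3x3(const double* xp, int H, int W, int Cin, int N) {
  arma::mat Xcol(static_cast<size_t>(N) * H * W, 9 * Cin, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* base = xp + (static_cast<size_t>(n) * Cin + ci) * H * W;
      for (int kw = -1; kw <= 1; ++kw) {
        for (int kh = -1; kh <= 1; ++kh) {
          int col = (kh + 1) + 3 * (kw + 1) + 9 * ci;
          double* colp = Xcol.colptr(col);
          int w0 = std::max(0, -kw), w1 = std::min(W, W - kw);
          int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
          for (int w = w0; w < w1; ++w) {
            const double* src = base + static_cast<size_t>(H) * (w + kw) + kh;
            double* dst = colp + static_cast<size_t>(n) * H * W +
              static_cast<size_t>(w) * H;
            std::copy(src + h0, src + h1, dst + h0);
          }
        }
      }
    }
  }
  return Xcol;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != Cin)
    stop("kernel must be 3 x 3 x Cin x Cout with Cin matching the input");
  arma::mat Xcol = im2col3x3(x.begin(), H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  arma::mat Y = Xcol * Wm;
  NumericVector out(static_cast<R_xlen_t>(N) * H * W * Cout);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double bias = b[co];
      double* dst = op + (static_cast<size_t>(n) * Cout + co) * H * W;
      const double* src = Y.colptr(co) + static_cast<size_t>(n) * H * W;
      for (size_t i = 0; i < static_cast<size_t>(H) * W; ++i)
        dst[i] = src[i] + bias;
    }
  return out;
}

List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dx);

// fused layer kernels: 3x3 conv (+bias), leaky ReLU (slope 0.1) and
// optional 2x2 average pooling, with the matching backward pass.

// [[Rcpp::export(name = ".conv_block_fwd")]]
List conv_block_fwd(NumericVector x, NumericVector w, NumericVector b,
                    bool pool) {
  NumericVector z = conv2d_fwd(x, w, b);
  IntegerVector zd = z.attr("dim");
  int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  if (!pool) {
    NumericVector a(z.size());
    a.attr("dim") = zd;
    for (R_xlen_t i = 0; i < z.size(); ++i)
      a[i] = z[i] > 0 ? z[i] : 0.1 * z[i];
    return List::create(_["z"] = z, _["out"] = a);
  }
  int Ho = H / 2, Wo = W / 2;
  NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* zp = z.begin();
  double* op = out.begin();
  for (size_t cn = 0; cn < static_cast<size_t>(C) * N; ++cn) {
    const double* zi = zp + cn * H * W;
    double* oi = op + cn * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        double v00 = zi[2 * ho + H * (2 * wo)];
        double v10 = zi[2 * ho + 1 + H * (2 * wo)];
        double v01 = zi[2 * ho + H * (2 * wo + 1)];
        double v11 = zi[2 * ho + 1 + H * (2 * wo + 1)];
        v00 = v00 > 0 ? v00 : 0.1 * v00;
        v10 = v10 > 0 ? v10 : 0.1 * v10;
        v01 = v01 > 0 ? v01 : 0.1 * v01;
        v11 = v11 > 0 ? v11 : 0.1 * v11;
        oi[ho + Ho * wo] = 0.25 * (v00 + v10 + v01 + v11);
      }
  }
  return List::create(_["z"] = z, _["out"] = out);
}

// [[Rcpp::export(name = ".conv_block_bwd")]]
List conv_block_bwd(NumericVector x, NumericVector w, NumericVector z,
                    NumericVector dout, bool pool, bool need_dx) {
  IntegerVector zd = z.attr("dim");
  int H = zd[0], W = zd[1], C = zd[2], N = zd[3];
  NumericVector dz(z.size());
  dz.attr("dim") = zd;
  const double* zp = z.begin();
  const double* dp = dout.begin();
  double* dzp = dz.begin();
  if (pool) {
    int Ho = H / 2, Wo = W / 2;
    for (size_t cn = 0; cn < static_cast<size_t>(C) * N; ++cn) {
      const double* di = dp + cn * Ho * Wo;
      const double* zi = zp + cn * H * W;
      double* dzi = dzp + cn * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = 0.25 * di[ho + Ho * wo];
          size_t i00 = 2 * ho + H * (2 * wo);
          size_t i01 = 2 * ho + H * (2 * wo + 1);
          dzi[i00]     = zi[i00] > 0 ? g : 0.1 * g;
          dzi[i00 + 1] = zi[i00 + 1] > 0 ? g : 0.1 * g;
          dzi[i01]     = zi[i01] > 0 ? g : 0.1 * g;
          dzi[i01 + 1] = zi[i01 + 1] > 0 ? g : 0.1 * g;
        }
    }
  } else {
    for (R_xlen_t i = 0; i < z.size(); ++i)
      dzp[i] = zp[i] > 0 ? dp[i] : 0.1 * dp[i];
  }
  return conv2d_bwd(x, w, dz, need_dx);
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                bool need_dx = true) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int Cout = wd[3];
  arma::mat Xcol = im2col3x3(x.begin(), H, W, Cin, N);
  arma::mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);

  // gather dy into (N*H*W) x Cout
  arma::mat dYm(static_cast<size_t>(N) * H * W, Cout);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = dyp + (static_cast<size_t>(n) * Cout + co) * H * W;
      double* dst = dYm.colptr(co) + static_cast<size_t>(n) * H * W;
      std::copy(src, src + static_cast<size_t>(H) * W, dst);
    }

  arma::mat dW = Xcol.t() * dYm;                 // (9*Cin) x Cout
  arma::rowvec db = arma::sum(dYm, 0);

  NumericVector dWout(9 * Cin * Cout);
  dWout.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  NumericVector dbout(Cout);
  std::copy(db.begin(), db.end(), dbout.begin());
  if (!need_dx)
    return List::create(_["dx"] = R_NilValue, _["dw"] = dWout,
                        _["db"] = dbout);

  arma::mat dXcol = dYm * Wm.t();                // (N*H*W) x (9*Cin)
  NumericVector dx(static_cast<R_xlen_t>(N) * H * W * Cin);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ci = 0; ci < Cin; ++ci) {
      double* base = dxp + (static_cast<size_t>(n) * Cin + ci) * H * W;
      for (int kw = -1; kw <= 1; ++kw) {
        for (int kh = -1; kh <= 1; ++kh) {
          int col = (kh + 1) + 3 * (kw + 1) + 9 * ci;
          int w0 = std::max(0, -kw), w1 = std::min(W, W - kw);
          int h0 = std::max(0, -kh), h1 = std::min(H, H - kh);
          const double* colp = dXcol.colptr(col);
          for (int w = w0; w < w1; ++w) {
            double* dst = base + static_cast<size_t>(H) * (w + kw);
            size_t row0 = static_cast<size_t>(n) * H * W + static_cast<size_t>(w) * H;
            for (int h = h0; h < h1; ++h)
              dst[h + kh] += colp[row0 + h];
          }
        }
      }
    }
  }

  return List::create(_["dx"] = dx, _["dw"] = dWout, _["db"] = dbout);
}
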