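// 3D convolution primitives (im2col + BLAS) used by the generator and
// discriminator networks.  Feature maps are dense double arrays with
// dim = (nx, ny, nz, channels) in R's column-major layout; kernels have
// dim = (k, k, k, c_in, c_out).  Padding is zero-padding.
//
// im2col/col2im move data in contiguous x-runs: for a fixed kernel tap
// and output (y, z) the input positions are an arithmetic sequence in
// x, so the inner loop is a memcpy (stride 1) or a simple strided copy.
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline int out_len(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// valid output range [lo, hi) along one axis for kernel offset `off`
// (input index = out * stride + off, must lie in [0, n))
static inline void valid_range(int n, int o, int stride, int off,
                               int& lo, int& hi) {
  lo = off >= 0 ? 0 : ((-off + stride - 1) / stride);
  int last = n - 1 - off;           // largest input index reachable
  hi = last < 0 ? 0 : std::min(o, last / stride + 1);
  if (hi < lo) hi = lo;
}

static void im2col(const double* x, int nx, int ny, int nz, int cin,
                   int k, int stride, int pad,
                   int ox, int oy, int oz, arma::mat& P) {
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (size_t)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          arma::uword col = (arma::uword)c * k * k * k +
                            (arma::uword)kz * k * k + (arma::uword)ky * k + kx;
          double* Pcol = P.colptr(col);
          int offx = kx - pad, offy = ky - pad, offz = kz - pad;
          int xlo, xhi;
          valid_range(nx, ox, stride, offx, xlo, xhi);
          for (int z = 0; z < oz; ++z) {
            int iz = z * stride + offz;
            bool zok = iz >= 0 && iz < nz;
            for (int y = 0; y < oy; ++y) {
              int iy = y * stride + offy;
              double* dst = Pcol + ((size_t)z * oy + y) * ox;
              if (!zok || iy < 0 || iy >= ny) {
                std::memset(dst, 0, sizeof(double) * ox);
                continue;
              }
              const double* src = xc + ((size_t)iz * ny + iy) * nx;
              if (xlo > 0) std::memset(dst, 0, sizeof(double) * xlo);
              if (xhi < ox)
                std::memset(dst + xhi, 0, sizeof(double) * (ox - xhi));
              if (stride == 1) {
                std::memcpy(dst + xlo, src + offx + xlo,
                            sizeof(double) * (xhi - xlo));
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  dst[xo] = src[xo * stride + offx];
              }
            }
          }
        }
  }
}

// Scatter-add transpose of im2col.
static void col2im(const arma::mat& dP, int nx, int ny, int nz, int cin,
                   int k, int stride, int pad,
                   int ox, int oy, int oz, double* dx) {
  for (int c = 0; c < cin; ++c) {
    double* xc = dx + (size_t)c * nx * ny * nz;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          arma::uword col = (arma::uword)c * k * k * k +
                            (arma::uword)kz * k * k + (arma::uword)ky * k + kx;
          const double* Pcol = dP.colptr(col);
          int offx = kx - pad, offy = ky - pad, offz = kz - pad;
          int xlo, xhi;
          valid_range(nx, ox, stride, offx, xlo, xhi);
          for (int z = 0; z < oz; ++z) {
            int iz = z * stride + offz;
            if (iz < 0 || iz >= nz) continue;
            for (int y = 0; y < oy; ++y) {
              int iy = y * stride + offy;
              if (iy < 0 || iy >= ny) continue;
              const double* src = Pcol + ((size_t)z * oy + y) * ox;
              double* dst = xc + ((size_t)iz * ny + iy) * nx;
              if (stride == 1) {
                double* d2 = dst + offx + xlo;
                for (int xo = xlo; xo < xhi; ++xo)
                  d2[xo - xlo] += src[xo];
              } else {
                for (int xo = xlo; xo < xhi; ++xo)
                  dst[xo * stride + offx] += src[xo];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("conv3d_fw: channel mismatch (%d vs %d)", wd[3], cin);
  int ox = out_len(nx, k, stride, pad);
  int oy = out_len(ny, k, stride, pad);
  int oz = out_len(nz, k, stride, pad);
  if (ox < 1 || oy < 1 || oz < 1)
    stop("conv3d_fw: input smaller than kernel");
  arma::uword novox = (arma::uword)ox * oy * oz;
  arma::mat P(novox, (arma::uword)k * k * k * cin);
  im2col(x.begin(), nx, ny, nz, cin, k, stride, pad, ox, oy, oz, P);
  arma::mat W(w.begin(), (arma::uword)k * k * k * cin, cout, false, true);
  arma::rowvec bb(b.begin(), cout);
  arma::mat out = P * W;
  out.each_row() += bb;
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  return res;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
               int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  int k = wd[0], cout = wd[4];
  int ox = out_len(nx, k, stride, pad);
  int oy = out_len(ny, k, stride, pad);
  int oz = out_len(nz, k, stride, pad);
  arma::uword novox = (arma::uword)ox * oy * oz;
  arma::mat P(novox, (arma::uword)k * k * k * cin);
  im2col(x.begin(), nx, ny, nz, cin, k, stride, pad, ox, oy, oz, P);
  arma::mat G(gout.begin(), novox, cout, false, true);
  arma::mat W(w.begin(), (arma::uword)k * k * k * cin, cout, false, true);

  arma::mat dW = P.t() * G;
  arma::rowvec db = arma::sum(G, 0);
  arma::mat dP = G * W.t();

  NumericVector dx(x.size());
  std::fill(dx.begin(), dx.end(), 0.0);
  col2im(dP, nx, ny, nz, cin, k, stride, pad, ox, oy, oz, dx.begin());
  dx.attr("dim") = xd;

  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  NumericVector dbv(db.begin(), db.end());
  return List::create(Named("dx") = dx, Named("dw") = dwv, Named("db") = dbv);
}
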