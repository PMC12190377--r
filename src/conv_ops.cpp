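#include <Rcpp.h>
using namespace Rcpp;

// Spatial layout convention: a 3D volume with C channels is a matrix of
// n_vox rows (x fastest, then y, then z; column-major linear order) and C
// columns. Same-padded convolution with an odd cubic kernel k is expressed
// as im2col(X) %*% W with W of shape (k^3 * C_in) x C_out; the im2col
// column index is c * k^3 + kk with kk enumerating (dx fastest) offsets.

// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& x, const IntegerVector& dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int C = x.ncol();
  const int k3 = k * k * k;
  const int p = (k - 1) / 2;
  if (x.nrow() != nvox) stop("voxel count does not match dims");
  NumericMatrix out(nvox, k3 * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    int kk = 0;
    for (int dz = -p; dz <= p; ++dz) {
      for (int dy = -p; dy <= p; ++dy) {
        for (int dx = -p; dx <= p; ++dx, ++kk) {
          double* oc = &out(0, c * k3 + kk);
          for (int iz = 0; iz < nz; ++iz) {
            int sz = iz + dz;
            bool zok = sz >= 0 && sz < nz;
            for (int iy = 0; iy < ny; ++iy) {
              int sy = iy + dy;
              bool yok = zok && sy >= 0 && sy < ny;
              int obase = (iz * ny + iy) * nx;
              if (!yok) continue; // row stays zero
              int sbase = (sz * ny + sy) * nx;
              int lo = std::max(0, -dx), hi = std::min(nx, nx - dx);
              for (int ix = lo; ix < hi; ++ix)
                oc[obase + ix] = xc[sbase + ix + dx];
            }
          }
        }
      }
    }
  }
  return out;
}

// Max-pooling over cubic windows with floor-division output shape.
// Returns pooled values and 1-based linear indices into the input matrix
// (absolute over rows and columns) for the backward scatter.
// [[Rcpp::export]]
List cpp_maxpool3(const NumericMatrix& x, const IntegerVector& dims,
                  int pool, int stride) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int C = x.ncol();
  const int ox = (nx - pool) / stride + 1;
  const int oy = (ny - pool) / stride + 1;
  const int oz = (nz - pool) / stride + 1;
  if (ox < 1 || oy < 1 || oz < 1) stop("volume too small for pooling config");
  if (x.nrow() != nx * ny * nz) stop("voxel count does not match dims");
  const int novox = ox * oy * oz;
  NumericMatrix vals(novox, C);
  IntegerMatrix idx(novox, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = &x(0, c);
    for (int iz = 0; iz < oz; ++iz) {
      for (int iy = 0; iy < oy; ++iy) {
        for (int ix = 0; ix < ox; ++ix) {
          double best = R_NegInf; int bestpos = -1;
          for (int dz = 0; dz < pool; ++dz) {
            int sz = iz * stride + dz;
            for (int dy = 0; dy < pool; ++dy) {
              int sy = iy * stride + dy;
              int sbase = (sz * ny + sy) * nx + ix * stride;
              for (int dx = 0; dx < pool; ++dx) {
                double v = xc[sbase + dx];
                if (v > best) { best = v; bestpos = sbase + dx; }
              }
            }
          }
          int orow = (iz * oy + iy) * ox + ix;
          vals(orow, c) = best;
          idx(orow, c) = c * nx * ny * nz + bestpos + 1; // 1-based absolute
        }
      }
    }
  }
  return List::create(_["values"] = vals, _["idx"] = idx,
                      _["out_dims"] = IntegerVector::create(ox, oy, oz));
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3_backward(const NumericMatrix& dy,
                                    const IntegerMatrix& idx,
                                    int n_in_rows) {
  const int C = dy.ncol();
  NumericMatrix dx(n_in_rows, C);
  double* p = dx.begin();
  for (int c = 0; c < C; ++c)
    for (int r = 0; r < dy.nrow(); ++r)
      p[idx(r, c) - 1] += dy(r, c);
  return dx;
}
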