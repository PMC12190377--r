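#include <Rcpp.h>
using namespace Rcpp;

// Direct same-padded 3D convolution kernels used by the spatial encoder's
// training loop. Layout as in conv_ops.cpp: volumes are n_vox x C matrices
// (x fastest), weights are (k^3 * C_in) x C_out with the kernel offset
// index kk running x-fastest over (dx, dy, dz) in [-p, p]^3.

// Accumulate  out[:, co] += w * shift(in[:, ci], off)  over the valid range.
static inline void axpy_shift(const double* in, double* out,
                              int nx, int ny, int nz,
                              int dx, int dy, int dz, double w) {
  const int zlo = std::max(0, -dz), zhi = nz - std::max(0, dz);
  const int ylo = std::max(0, -dy), yhi = ny - std::max(0, dy);
  const int xlo = std::max(0, -dx), xhi = nx - std::max(0, dx);
  for (int z = zlo; z < zhi; ++z) {
    for (int y = ylo; y < yhi; ++y) {
      const double* ip = in + ((z + dz) * ny + (y + dy)) * nx + dx;
      double* op = out + (z * ny + y) * nx;
      for (int x = xlo; x < xhi; ++x) op[x] += w * ip[x];
    }
  }
}

// Dot product  sum_p in1[p + off] * in2[p]  over the valid range.
static inline double dot_shift(const double* in1, const double* in2,
                               int nx, int ny, int nz,
                               int dx, int dy, int dz) {
  const int zlo = std::max(0, -dz), zhi = nz - std::max(0, dz);
  const int ylo = std::max(0, -dy), yhi = ny - std::max(0, dy);
  const int xlo = std::max(0, -dx), xhi = nx - std::max(0, dx);
  double acc = 0.0;
  for (int z = zlo; z < zhi; ++z) {
    for (int y = ylo; y < yhi; ++y) {
      const double* p1 = in1 + ((z + dz) * ny + (y + dy)) * nx + dx;
      const double* p2 = in2 + (z * ny + y) * nx;
      for (int x = xlo; x < xhi; ++x) acc += p1[x] * p2[x];
    }
  }
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(const NumericMatrix& x, const IntegerVector& dims,
                            const NumericMatrix& W, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int Cin = x.ncol(), Cout = W.ncol(), k3 = k * k * k, p = (k - 1) / 2;
  if (x.nrow() != nvox) stop("voxel count does not match dims");
  if (W.nrow() != k3 * Cin) stop("weight rows must equal k^3 * C_in");
  NumericMatrix y(nvox, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* yp = &y(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xp = &x(0, ci);
      int kk = 0;
      for (int dz = -p; dz <= p; ++dz)
        for (int dy = -p; dy <= p; ++dy)
          for (int dx = -p; dx <= p; ++dx, ++kk) {
            double w = W(ci * k3 + kk, co);
            if (w != 0.0) axpy_shift(xp, yp, nx, ny, nz, dx, dy, dz, w);
          }
    }
  }
  return y;
}

// Gradient w.r.t. the convolution input:
// dX[q, ci] = sum_{co, kk} dY[q - off(kk), co] * W[ci*k3 + kk, co].
// [[Rcpp::export]]
NumericMatrix cpp_conv3_bwd_input(const NumericMatrix& dy, const IntegerVector& dims,
                                  const NumericMatrix& W, int k, int Cin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int Cout = dy.ncol(), k3 = k * k * k, p = (k - 1) / 2;
  if (dy.nrow() != nvox) stop("voxel count does not match dims");
  if (W.nrow() != k3 * Cin) stop("weight rows must equal k^3 * C_in");
  NumericMatrix dx(nvox, Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    double* dxp = &dx(0, ci);
    for (int co = 0; co < Cout; ++co) {
      const double* dyp = &dy(0, co);
      int kk = 0;
      for (int dz = -p; dz <= p; ++dz)
        for (int dy_ = -p; dy_ <= p; ++dy_)
          for (int dx_ = -p; dx_ <= p; ++dx_, ++kk) {
            double w = W(ci * k3 + kk, co);
            // dX[q] += w * dY[q - off] == axpy with offset -off
            if (w != 0.0) axpy_shift(dyp, dxp, nx, ny, nz, -dx_, -dy_, -dz, w);
          }
    }
  }
  return dx;
}

// Gradient w.r.t. the weights: dW[ci*k3+kk, co] = sum_q X[q + off, ci] dY[q, co].
// [[Rcpp::export]]
NumericMatrix cpp_conv3_bwd_weights(const NumericMatrix& x, const NumericMatrix& dy,
                                    const IntegerVector& dims, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz;
  const int Cin = x.ncol(), Cout = dy.ncol(), k3 = k * k * k, p = (k - 1) / 2;
  if (x.nrow() != nvox || dy.nrow() != nvox) stop("voxel count does not match dims");
  NumericMatrix dW(k3 * Cin, Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dyp = &dy(0, co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xp = &x(0, ci);
      int kk = 0;
      for (int dz = -p; dz <= p; ++dz)
        for (int dy_ = -p; dy_ <= p; ++dy_)
          for (int dx_ = -p; dx_ <= p; ++dx_, ++kk)
            dW(ci * k3 + kk, co) = dot_shift(xp, dyp, nx, ny, nz, dx_, dy_, dz);
    }
  }
  return dW;
}
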