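// Low-level numerical kernels: 3D convolution (im2col-free shifted GEMM),
// pooling, nearest-neighbour upsampling, separable axis filtering,
// grayscale morphology over arbitrary structuring-element offsets,
// per-voxel symmetric 3x3 eigensolver, 26/6-connected component labelling
// and spherical-shell flux sampling for oriented-flux filters.
//
// Volumes are column-major vectors with dims (nx, ny, nz); multi-channel
// feature maps are (nvox x C) matrices whose row index is the linear voxel
// index.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Copy src shifted by offset (ox,oy,oz) into dst (zero padding):
// dst[v] = src[v + o] when in bounds, else 0. If accumulate, add instead.
static void shift_into(const arma::mat &src, arma::mat &dst,
                       int nx, int ny, int nz,
                       int ox, int oy, int oz, bool accumulate) {
  const int C = src.n_cols;
  if (!accumulate) dst.zeros();
  for (int c = 0; c < C; ++c) {
    const double *s = src.colptr(c);
    double *d = dst.colptr(c);
    for (int z = 0; z < nz; ++z) {
      int sz = z + oz;
      if (sz < 0 || sz >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int sy = y + oy;
        if (sy < 0 || sy >= ny) continue;
        int x0 = std::max(0, -ox), x1 = std::min(nx - 1, nx - 1 - ox);
        if (x1 < x0) continue;
        const double *sp = s + lin(x0 + ox, sy, sz, nx, ny);
        double *dp = d + lin(x0, y, z, nx, ny);
        int n = x1 - x0 + 1;
        if (accumulate) {
          for (int i = 0; i < n; ++i) dp[i] += sp[i];
        } else {
          std::memcpy(dp, sp, n * sizeof(double));
        }
      }
    }
  }
}

// 3x3x3 convolution (cross-correlation), stride 1, zero padding.
// W: (27*Cin) x Cout, row index = k*Cin + c with k = (oz+1)*9+(oy+1)*3+(ox+1).
//
// Implemented as one large GEMM against all 27 offset blocks at once
// (Y = x * Wbig with Wbig: Cin x 27*Cout) followed by shifted
// accumulation of the per-offset output blocks; this keeps the GEMM at an
// efficient shape and moves only Cout channels per offset.

static arma::fmat conv_wbig(const arma::mat &W, int Cin, int Cout) {
  arma::fmat Wbig(Cin, 27 * Cout);
  for (int k = 0; k < 27; ++k)
    for (int j = 0; j < Cout; ++j)
      for (int c = 0; c < Cin; ++c)
        Wbig(c, k * Cout + j) = (float)W(k * Cin + c, j);
  return Wbig;
}

// float shifted-accumulate analogue of shift_into
static void shift_into_f(const arma::fmat &src, arma::fmat &dst,
                         int nx, int ny, int nz,
                         int ox, int oy, int oz, bool accumulate) {
  const int C = src.n_cols;
  if (!accumulate) dst.zeros();
  for (int c = 0; c < C; ++c) {
    const float *s = src.colptr(c);
    float *d = dst.colptr(c);
    for (int z = 0; z < nz; ++z) {
      int sz = z + oz;
      if (sz < 0 || sz >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int sy = y + oy;
        if (sy < 0 || sy >= ny) continue;
        int x0 = std::max(0, -ox), x1 = std::min(nx - 1, nx - 1 - ox);
        if (x1 < x0) continue;
        const float *sp = s + lin(x0 + ox, sy, sz, nx, ny);
        float *dp = d + lin(x0, y, z, nx, ny);
        int n = x1 - x0 + 1;
        if (accumulate) {
          for (int i = 0; i < n; ++i) dp[i] += sp[i];
        } else {
          std::memcpy(dp, sp, n * sizeof(float));
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3_fw(const arma::mat &x, IntegerVector dims,
                       const arma::mat &W, const arma::vec &bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, Cin = x.n_cols, Cout = W.n_cols;
  if ((int)W.n_rows != 27 * Cin) stop("conv3 weight shape mismatch");
  arma::fmat xf = arma::conv_to<arma::fmat>::from(x);
  arma::fmat Y = xf * conv_wbig(W, Cin, Cout);  // nvox x 27*Cout
  arma::fmat outf(nvox, Cout, arma::fill::zeros);
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++k) {
        // out(p) += Y_k(p + o)  (zero padding)
        const arma::fmat Yk(const_cast<float *>(Y.colptr(k * Cout)),
                            nvox, Cout, false, true);
        shift_into_f(Yk, outf, nx, ny, nz, ox, oy, oz, true);
      }
  arma::mat out = arma::conv_to<arma::mat>::from(outf);
  out.each_row() += bias.t();
  return out;
}

// Per-weight DropConnect: Weff = W .* mask / (1-p) with mask ~ Bernoulli(1-p)
// drawn from R's RNG (so runs are seed-reproducible). Returns Weff and the
// scaled mask (mask/(1-p)) used to adjust the weight gradient.
// [[Rcpp::export]]
List cpp_dropconnect(const arma::mat &W, double p) {
  const double inv = 1.0 / (1.0 - p);
  arma::mat Weff(W.n_rows, W.n_cols), msc(W.n_rows, W.n_cols);
  const double *w = W.memptr();
  double *we = Weff.memptr(), *ms = msc.memptr();
  const size_t n = W.n_elem;
  for (size_t i = 0; i < n; ++i) {
    double m = (unif_rand() >= p) ? inv : 0.0;
    ms[i] = m;
    we[i] = w[i] * m;
  }
  return List::create(_["Weff"] = Weff, _["mask_scaled"] = msc);
}

// Backward pass: returns gx, gW, gb given input x and output gradient gout.
// Z_k = gout shifted by -o_k; gx = Z * Wbig', gW = reorg(x' * Z).
// need_gx = false skips the input-gradient GEMM (used when the conv input
// is the network input, which has no upstream parameters).
// [[Rcpp::export]]
List cpp_conv3_bw(const arma::mat &x, IntegerVector dims,
                  const arma::mat &W, const arma::mat &gout,
                  bool need_gx = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, Cin = x.n_cols, Cout = W.n_cols;
  arma::fmat goutf = arma::conv_to<arma::fmat>::from(gout);
  arma::fmat Z(nvox, 27 * Cout);
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++k) {
        arma::fmat Zk(Z.colptr(k * Cout), nvox, Cout, false, true);
        shift_into_f(goutf, Zk, nx, ny, nz, -ox, -oy, -oz, false);
      }
  arma::fmat xf = arma::conv_to<arma::fmat>::from(x);
  arma::fmat gxf;
  if (need_gx) gxf = Z * conv_wbig(W, Cin, Cout).t();
  arma::fmat gWbig = xf.t() * Z;               // Cin x 27*Cout
  arma::mat gW(27 * Cin, Cout);
  for (k = 0; k < 27; ++k)
    for (int j = 0; j < Cout; ++j)
      for (int c = 0; c < Cin; ++c)
        gW(k * Cin + c, j) = (double)gWbig(c, k * Cout + j);
  arma::vec gb = arma::sum(gout, 0).t();
  return List::create(_["gx"] = need_gx
                        ? wrap(arma::conv_to<arma::mat>::from(gxf))
                        : R_NilValue,
                      _["gW"] = gW, _["gb"] = gb);
}

// Double-precision variants of the convolution kernels, used for numerical
// verification (full-net gradient checks) where float rounding would mask
// small finite-difference signals.
// [[Rcpp::export]]
arma::mat cpp_conv3_fw_d(const arma::mat &x, IntegerVector dims,
                         const arma::mat &W, const arma::vec &bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, Cin = x.n_cols, Cout = W.n_cols;
  if ((int)W.n_rows != 27 * Cin) stop("conv3 weight shape mismatch");
  arma::mat out(nvox, Cout);
  out.each_row() = bias.t();
  arma::mat xs(nvox, Cin);
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++k) {
        shift_into(x, xs, nx, ny, nz, ox, oy, oz, false);
        out += xs * W.rows(k * Cin, (k + 1) * Cin - 1);
      }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bw_d(const arma::mat &x, IntegerVector dims,
                    const arma::mat &W, const arma::mat &gout,
                    bool need_gx = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nvox = nx * ny * nz, Cin = x.n_cols, Cout = W.n_cols;
  arma::mat gx(nvox, Cin, arma::fill::zeros);
  arma::mat gW(27 * Cin, Cout);
  arma::vec gb = arma::sum(gout, 0).t();
  arma::mat xs(nvox, Cin), tmp;
  int k = 0;
  for (int oz = -1; oz <= 1; ++oz)
    for (int oy = -1; oy <= 1; ++oy)
      for (int ox = -1; ox <= 1; ++ox, ++k) {
        shift_into(x, xs, nx, ny, nz, ox, oy, oz, false);
        const arma::mat Wk = W.rows(k * Cin, (k + 1) * Cin - 1);
        gW.rows(k * Cin, (k + 1) * Cin - 1) = xs.t() * gout;
        if (need_gx) {
          tmp = gout * Wk.t();
          shift_into(tmp, gx, nx, ny, nz, -ox, -oy, -oz, true);
        }
      }
  return List::create(_["gx"] = need_gx ? wrap(gx) : R_NilValue,
                      _["gW"] = gW, _["gb"] = gb);
}

// Batch-norm forward: returns xhat and out = xhat*gamma + beta columnwise.
// [[Rcpp::export]]
List cpp_bn_fw(const arma::mat &x, const arma::vec &mu,
               const arma::vec &invstd, const arma::vec &gamma,
               const arma::vec &beta) {
  const int n = x.n_rows, C = x.n_cols;
  arma::mat xhat(n, C), out(n, C);
  for (int c = 0; c < C; ++c) {
    const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
    const double *xp = x.colptr(c);
    double *hp = xhat.colptr(c), *op = out.colptr(c);
    for (int i = 0; i < n; ++i) {
      hp[i] = (xp[i] - m) * is;
      op[i] = hp[i] * g + b;
    }
  }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}

// Batch-norm backward (training statistics): returns gx, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_bn_bw(const arma::mat &g, const arma::mat &xhat,
               const arma::vec &invstd, const arma::vec &gamma,
               bool batch_stats) {
  const int n = g.n_rows, C = g.n_cols;
  arma::mat gx(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *gp = g.colptr(c), *hp = xhat.colptr(c);
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s1 += gp[i]; s2 += gp[i] * hp[i]; }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double gm = gamma[c], is = invstd[c];
    double *op = gx.colptr(c);
    if (batch_stats) {
      const double t1 = s1 / n, t2 = s2 / n;
      for (int i = 0; i < n; ++i)
        op[i] = (gp[i] * gm - (t1 * gm + hp[i] * t2 * gm)) * is;
    } else {
      for (int i = 0; i < n; ++i) op[i] = gp[i] * gm * is;
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 1x1x1 convolution is a plain matrix product; done in R.

// Max pooling f x f x f with stride f; dims must be divisible by f.
// [[Rcpp::export]]
List cpp_maxpool_fw(const arma::mat &x, IntegerVector dims, int f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = x.n_cols;
  if (nx % f || ny % f || nz % f)
    stop("spatial extent not divisible by pooling factor %d", f);
  const int mx = nx / f, my = ny / f, mz = nz / f, mvox = mx * my * mz;
  arma::mat out(mvox, C);
  arma::umat amax(mvox, C);
  for (int c = 0; c < C; ++c) {
    const double *s = x.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int xq = 0; xq < mx; ++xq) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dz = 0; dz < f; ++dz)
            for (int dy = 0; dy < f; ++dy)
              for (int dx = 0; dx < f; ++dx) {
                int i = lin(xq * f + dx, y * f + dy, z * f + dz, nx, ny);
                if (s[i] > best) { best = s[i]; bi = i; }
              }
          int o = lin(xq, y, z, mx, my);
          out(o, c) = best;
          amax(o, c) = bi;
        }
  }
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bw(const arma::mat &gout, const arma::umat &amax,
                         int nvox_in) {
  const int C = gout.n_cols;
  arma::mat gx(nvox_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword v = 0; v < gout.n_rows; ++v)
      gx(amax(v, c), c) += gout(v, c);
  return gx;
}

// Nearest-neighbour upsampling by factor f.
// [[Rcpp::export]]
arma::mat cpp_upsample_fw(const arma::mat &x, IntegerVector dims, int f) {
  const int mx = dims[0], my = dims[1], mz = dims[2], C = x.n_cols;
  const int nx = mx * f, ny = my * f, nz = mz * f;
  arma::mat out(nx * ny * nz, C);
  for (int c = 0; c < C; ++c) {
    const double *s = x.colptr(c);
    double *d = out.colptr(c);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int xq = 0; xq < nx; ++xq)
          d[lin(xq, y, z, nx, ny)] =
            s[lin(xq / f, y / f, z / f, mx, my)];
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_upsample_bw(const arma::mat &gout, IntegerVector dims_in, int f) {
  const int mx = dims_in[0], my = dims_in[1], mz = dims_in[2], C = gout.n_cols;
  const int nx = mx * f, ny = my * f;
  arma::mat gx(mx * my * mz, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double *g = gout.colptr(c);
    double *d = gx.colptr(c);
    for (int z = 0; z < mz * f; ++z)
      for (int y = 0; y < my * f; ++y)
        for (int xq = 0; xq < nx; ++xq)
          d[lin(xq / f, y / f, z / f, mx, my)] += g[lin(xq, y, z, nx, ny)];
  }
  return gx;
}

// Separable correlation along one axis (0=x,1=y,2=z), symmetric
// (half-sample) boundary reflection. kernel has odd length.
// [[Rcpp::export]]
NumericVector cpp_filter_axis(NumericVector x, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int kl = kernel.size(), r = kl / 2;
  NumericVector out(x.size());
  const int n[3] = {nx, ny, nz};
  const int len = n[axis];
  const int stride = axis == 0 ? 1 : (axis == 1 ? nx : nx * ny);
  // iterate over all lines along `axis`
  const int n1 = axis == 0 ? ny : nx;
  const int n2 = axis == 2 ? ny : nz;
  const int s1 = axis == 0 ? nx : 1;
  const int s2 = axis == 2 ? nx : nx * ny;
  std::vector<double> line(len);
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      const int base = a * s1 + b * s2;
      for (int i = 0; i < len; ++i) line[i] = x[base + i * stride];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int j = -r; j <= r; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx - 1;
          if (idx >= len) idx = 2 * len - 1 - idx;
          acc += kernel[j + r] * line[idx];
        }
        out[base + i * stride] = acc;
      }
    }
  return out;
}

// Grayscale min/max filter over an explicit offset list (n_off x 3 integer
// matrix, voxel units). Out-of-bounds offsets are ignored (the neighbourhood
// is clipped at the volume border).
// [[Rcpp::export]]
NumericVector cpp_minmax_filter(NumericVector x, IntegerVector dims,
                                IntegerMatrix offsets, bool take_max) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = offsets.nrow();
  NumericVector out(x.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xq = 0; xq < nx; ++xq) {
        double best = take_max ? -std::numeric_limits<double>::infinity()
                               : std::numeric_limits<double>::infinity();
        for (int k = 0; k < m; ++k) {
          int xi = xq + offsets(k, 0), yi = y + offsets(k, 1),
              zi = z + offsets(k, 2);
          if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
            continue;
          double v = x[lin(xi, yi, zi, nx, ny)];
          if (take_max ? (v > best) : (v < best)) best = v;
        }
        out[lin(xq, y, z, nx, ny)] = best;
      }
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix per voxel via cyclic Jacobi.
// Input: six component vectors (a11,a22,a33,a12,a13,a23).
// Output: nvox x 3 matrix of eigenvalues sorted ascending.
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigs(NumericVector a11, NumericVector a22,
                            NumericVector a33, NumericVector a12,
                            NumericVector a13, NumericVector a23) {
  const int n = a11.size();
  NumericMatrix out(n, 3);
  double A[3][3];
  for (int v = 0; v < n; ++v) {
    A[0][0] = a11[v]; A[1][1] = a22[v]; A[2][2] = a33[v];
    A[0][1] = A[1][0] = a12[v];
    A[0][2] = A[2][0] = a13[v];
    A[1][2] = A[2][1] = a23[v];
    for (int sweep = 0; sweep < 30; ++sweep) {
      double off = A[0][1] * A[0][1] + A[0][2] * A[0][2] + A[1][2] * A[1][2];
      if (off < 1e-24) break;
      for (int p = 0; p < 2; ++p)
        for (int q = p + 1; q < 3; ++q) {
          if (std::fabs(A[p][q]) < 1e-30) continue;
          double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
          double t = (theta >= 0 ? 1.0 : -1.0) /
                     (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
          double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
          for (int k = 0; k < 3; ++k) {
            double akp = A[k][p], akq = A[k][q];
            A[k][p] = c * akp - s * akq;
            A[k][q] = s * akp + c * akq;
          }
          for (int k = 0; k < 3; ++k) {
            double apk = A[p][k], aqk = A[q][k];
            A[p][k] = c * apk - s * aqk;
            A[q][k] = s * apk + c * aqk;
          }
        }
    }
    double e[3] = {A[0][0], A[1][1], A[2][2]};
    std::sort(e, e + 3);
    out(v, 0) = e[0]; out(v, 1) = e[1]; out(v, 2) = e[2];
  }
  return out;
}

// Connected component labelling (BFS), connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  int next = 0;
  std::queue<int> q;
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int vz = v / (nx * ny), rem = v % (nx * ny), vy = rem / nx, vx = rem % nx;
      for (auto &d : nb) {
        int xi = vx + d[0], yi = vy + d[1], zi = vz + d[2];
        if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
          continue;
        int u = lin(xi, yi, zi, nx, ny);
        if (mask[u] && !lab[u]) { lab[u] = next; q.push(u); }
      }
    }
  }
  return lab;
}

// Oriented-flux matrix by spherical-shell sampling: for every voxel,
// Q_ij = mean_k 0.5 * (g_i(p + r n_k) n_kj + g_j(p + r n_k) n_ki)
// with trilinear sampling of the gradient field (coordinates clamped to the
// grid). pts: m x 3 unit vectors; off_vox: m x 3 offsets in voxel units.
// Returns nvox x 6 matrix (q11,q22,q33,q12,q13,q23).
// [[Rcpp::export]]
NumericMatrix cpp_sphere_flux(NumericVector gx, NumericVector gy,
                              NumericVector gz, IntegerVector dims,
                              NumericMatrix pts, NumericMatrix off_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz, m = pts.nrow();
  NumericMatrix out(n, 6);
  const double *g[3] = {gx.begin(), gy.begin(), gz.begin()};
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int xq = 0; xq < nx; ++xq) {
        double Q[6] = {0, 0, 0, 0, 0, 0};
        for (int k = 0; k < m; ++k) {
          double px = xq + off_vox(k, 0), py = y + off_vox(k, 1),
                 pz = z + off_vox(k, 2);
          if (px < 0) px = 0; if (px > nx - 1) px = nx - 1;
          if (py < 0) py = 0; if (py > ny - 1) py = ny - 1;
          if (pz < 0) pz = 0; if (pz > nz - 1) pz = nz - 1;
          int x0 = (int)px, y0 = (int)py, z0 = (int)pz;
          int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
              z1 = std::min(z0 + 1, nz - 1);
          double fx = px - x0, fy = py - y0, fz = pz - z0;
          double gs[3];
          for (int c = 0; c < 3; ++c) {
            const double *G = g[c];
            double c00 = G[lin(x0, y0, z0, nx, ny)] * (1 - fx) +
                         G[lin(x1, y0, z0, nx, ny)] * fx;
            double c10 = G[lin(x0, y1, z0, nx, ny)] * (1 - fx) +
                         G[lin(x1, y1, z0, nx, ny)] * fx;
            double c01 = G[lin(x0, y0, z1, nx, ny)] * (1 - fx) +
                         G[lin(x1, y0, z1, nx, ny)] * fx;
            double c11 = G[lin(x0, y1, z1, nx, ny)] * (1 - fx) +
                         G[lin(x1, y1, z1, nx, ny)] * fx;
            gs[c] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                    (c01 * (1 - fy) + c11 * fy) * fz;
          }
          double nkx = pts(k, 0), nky = pts(k, 1), nkz = pts(k, 2);
          Q[0] += gs[0] * nkx;
          Q[1] += gs[1] * nky;
          Q[2] += gs[2] * nkz;
          Q[3] += 0.5 * (gs[0] * nky + gs[1] * nkx);
          Q[4] += 0.5 * (gs[0] * nkz + gs[2] * nkx);
          Q[5] += 0.5 * (gs[1] * nkz + gs[2] * nky);
        }
        int v = lin(xq, y, z, nx, ny);
        for (int c = 0; c < 6; ++c) out(v, c) = Q[c] / m;
      }
  return out;
}

// Distance-to-polyline rasterization support: minimum distance from each
// voxel centre in a bounding box to a polyline (physical mm coordinates).
// verts: nv x 3 polyline vertices (mm); box lo/hi: inclusive voxel index
// bounds; spacing: mm per voxel. Returns vector over the box (column-major
// within the box) of min distances.
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(NumericMatrix verts, IntegerVector lo,
                                IntegerVector hi, NumericVector spacing) {
  const int nv = verts.nrow();
  const int bx = hi[0] - lo[0] + 1, by = hi[1] - lo[1] + 1,
            bz = hi[2] - lo[2] + 1;
  NumericVector out(bx * by * bz);
  int idx = 0;
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x, ++idx) {
        double p[3] = {x * spacing[0], y * spacing[1], z * spacing[2]};
        double best = std::numeric_limits<double>::infinity();
        for (int s = 0; s + 1 < nv || (nv == 1 && s == 0); ++s) {
          double a[3] = {verts(s, 0), verts(s, 1), verts(s, 2)};
          double d2;
          if (nv == 1) {
            d2 = 0;
            for (int c = 0; c < 3; ++c) d2 += (p[c] - a[c]) * (p[c] - a[c]);
          } else {
            double b[3] = {verts(s + 1, 0), verts(s + 1, 1), verts(s + 1, 2)};
            double ab[3], ap[3], t = 0, ab2 = 0;
            for (int c = 0; c < 3; ++c) {
              ab[c] = b[c] - a[c]; ap[c] = p[c] - a[c];
              t += ab[c] * ap[c]; ab2 += ab[c] * ab[c];
            }
            t = ab2 > 0 ? std::max(0.0, std::min(1.0, t / ab2)) : 0.0;
            d2 = 0;
            for (int c = 0; c < 3; ++c) {
              double dd = ap[c] - t * ab[c];
              d2 += dd * dd;
            }
          }
          if (d2 < best) best = d2;
          if (nv == 1) break;
        }
        out[idx] = std::sqrt(best);
      }
  return out;
}
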