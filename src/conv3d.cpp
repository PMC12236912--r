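// 3D convolution / max-pooling primitives for the brain-age CNN.
//
// Volumes are passed as (nvox x C) matrices whose rows follow R's
// column-major voxel order for a (nx, ny, nz) array: i = x + nx*(y + ny*z),
// zero-based. Convolution weights are (27*C_in x C_out): row c*27 + p where
// p = (kx+1) + 3*(ky+1) + 9*(kz+1) indexes the 3x3x3 kernel offset.
// Kernel size is fixed at 3 with zero padding 1 (shape preserving), the only
// configuration the architecture uses. Work is sliced along z so the im2col
// buffer never exceeds one slice (keeps the 91x109x91-scale forward pass in
// bounded memory).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// gather the 3x3x3 patch columns of output slice z into rows
// [row_off, row_off + nx*ny) of col; col must be pre-zeroed
static inline void build_slice_col(const mat &x, int nx, int ny, int nz,
                                   int z, mat &col, size_t row_off) {
  const int C = x.n_cols;
  for (int c = 0; c < C; ++c) {
    const double *xc = x.colptr(c);
    for (int p = 0; p < 27; ++p) {
      const int kx = p % 3 - 1, ky = (p / 3) % 3 - 1, kz = p / 9 - 1;
      const int zz = z + kz;
      if (zz < 0 || zz >= nz) continue;
      double *dst = col.colptr(c * 27 + p) + row_off;
      for (int y = 0; y < ny; ++y) {
        const int yy = y + ky;
        if (yy < 0 || yy >= ny) continue;
        const int x0 = (kx < 0) ? 1 : 0;          // first valid output x
        const int x1 = (kx > 0) ? nx - 1 : nx;    // one past last valid
        const double *src = xc + (size_t)nx * (yy + (size_t)ny * zz);
        double *d = dst + (size_t)nx * y;
        for (int xo = x0; xo < x1; ++xo) d[xo] = src[xo + kx];
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fwd")]]
arma::mat conv3d_fwd(const arma::mat &x, const arma::ivec &dims,
                     const arma::mat &W, const arma::vec &b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nslice = (size_t)nx * ny;
  const int C = x.n_cols, F = W.n_cols;
  if ((int)W.n_rows != 27 * C)
    Rcpp::stop("weight rows (%d) != 27 * input channels (%d)", (int)W.n_rows, 27 * C);
  const size_t nvox = nslice * nz;
  mat out(nvox, F);
  if (nvox * 27 * C <= 8000000) {
    // small volume: one gather + one GEMM
    mat col(nvox, 27 * C, fill::zeros);
    for (int z = 0; z < nz; ++z)
      build_slice_col(x, nx, ny, nz, z, col, z * nslice);
    out = col * W;
  } else {
    // large volume: bounded-memory z-slice gather
    mat col(nslice, 27 * C);
    for (int z = 0; z < nz; ++z) {
      col.zeros();
      build_slice_col(x, nx, ny, nz, z, col, 0);
      out.rows(z * nslice, (z + 1) * nslice - 1) = col * W;
    }
  }
  out.each_row() += b.t();
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd")]]
Rcpp::List conv3d_bwd(const arma::mat &x, const arma::ivec &dims,
                      const arma::mat &W, const arma::mat &gout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nslice = (size_t)nx * ny;
  const int C = x.n_cols, F = W.n_cols;
  const size_t nvox = nslice * nz;
  mat gW(27 * C, F, fill::zeros);
  mat gx(x.n_rows, C, fill::zeros);
  if (nvox * 27 * C <= 8000000) {
    mat col(nvox, 27 * C, fill::zeros);
    for (int z = 0; z < nz; ++z)
      build_slice_col(x, nx, ny, nz, z, col, z * nslice);
    gW = col.t() * gout;
    const mat gcol = gout * W.t();  // nvox x 27C
    for (int c = 0; c < C; ++c) {
      double *gxc = gx.colptr(c);
      for (int p = 0; p < 27; ++p) {
        const int kx = p % 3 - 1, ky = (p / 3) % 3 - 1, kz = p / 9 - 1;
        const double *src = gcol.colptr(c * 27 + p);
        for (int z = 0; z < nz; ++z) {
          const int zz = z + kz;
          if (zz < 0 || zz >= nz) continue;
          for (int y = 0; y < ny; ++y) {
            const int yy = y + ky;
            if (yy < 0 || yy >= ny) continue;
            const int x0 = (kx < 0) ? 1 : 0;
            const int x1 = (kx > 0) ? nx - 1 : nx;
            double *d = gxc + (size_t)nx * (yy + (size_t)ny * zz);
            const double *s = src + (size_t)nx * y + z * nslice;
            for (int xo = x0; xo < x1; ++xo) d[xo + kx] += s[xo];
          }
        }
      }
    }
    vec gb0 = sum(gout, 0).t();
    return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                              Rcpp::Named("gb") = gb0);
  }
  mat col(nslice, 27 * C);
  for (int z = 0; z < nz; ++z) {
    col.zeros();
    build_slice_col(x, nx, ny, nz, z, col, 0);
    const mat gslice = gout.rows(z * nslice, (z + 1) * nslice - 1);
    gW += col.t() * gslice;
    const mat gcol = gslice * W.t();  // nslice x 27C
    // scatter-add: reverse of build_slice_col
    for (int c = 0; c < C; ++c) {
      double *gxc = gx.colptr(c);
      for (int p = 0; p < 27; ++p) {
        const int kx = p % 3 - 1, ky = (p / 3) % 3 - 1, kz = p / 9 - 1;
        const int zz = z + kz;
        if (zz < 0 || zz >= nz) continue;
        const double *src = gcol.colptr(c * 27 + p);
        for (int y = 0; y < ny; ++y) {
          const int yy = y + ky;
          if (yy < 0 || yy >= ny) continue;
          const int x0 = (kx < 0) ? 1 : 0;
          const int x1 = (kx > 0) ? nx - 1 : nx;
          double *d = gxc + (size_t)nx * (yy + (size_t)ny * zz);
          const double *s = src + (size_t)nx * y;
          for (int xo = x0; xo < x1; ++xo) d[xo + kx] += s[xo];
        }
      }
    }
  }
  vec gb = sum(gout, 0).t();
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool3d_fwd")]]
Rcpp::List maxpool3d_fwd(const arma::mat &x, const arma::ivec &dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / 2, my = ny / 2, mz = nz / 2;
  const int C = x.n_cols;
  mat out((size_t)mx * my * mz, C);
  imat idx((size_t)mx * my * mz, C);
  for (int c = 0; c < C; ++c) {
    const double *xc = x.colptr(c);
    double *oc = out.colptr(c);
    arma::sword *ic = idx.colptr(c);
    for (int z = 0; z < mz; ++z)
      for (int y = 0; y < my; ++y)
        for (int xo = 0; xo < mx; ++xo) {
          double best = -datum::inf;
          size_t besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const size_t ii = (size_t)(2 * xo + dx) +
                  (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                if (xc[ii] > best) { best = xc[ii]; besti = ii; }
              }
          const size_t oi = (size_t)xo + (size_t)mx * (y + (size_t)my * z);
          oc[oi] = best;
          ic[oi] = (arma::sword)besti;
        }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx,
                            Rcpp::Named("out_dims") =
                              Rcpp::IntegerVector::create(mx, my, mz));
}

// [[Rcpp::export(name = ".maxpool3d_bwd")]]
arma::mat maxpool3d_bwd(const arma::mat &gout, const arma::imat &idx,
                        const int nvox_in) {
  const int C = gout.n_cols;
  mat gx(nvox_in, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double *gc = gx.colptr(c);
    const double *go = gout.colptr(c);
    const arma::sword *ic = idx.colptr(c);
    for (size_t i = 0; i < gout.n_rows; ++i) gc[ic[i]] += go[i];
  }
  return gx;
}

// ---- batched variants: X holds n samples stacked rowwise, nvox rows each ----

// [[Rcpp::export(name = ".conv3d_fwd_batch")]]
arma::mat conv3d_fwd_batch(const arma::mat &x, const arma::ivec &dims,
                           const int n, const arma::mat &W,
                           const arma::vec &b) {
  const size_t nvox = (size_t)dims[0] * dims[1] * dims[2];
  mat out(x.n_rows, W.n_cols);
  for (int i = 0; i < n; ++i)
    out.rows(i * nvox, (i + 1) * nvox - 1) =
      conv3d_fwd(x.rows(i * nvox, (i + 1) * nvox - 1), dims, W, b);
  return out;
}

// [[Rcpp::export(name = ".conv3d_bwd_batch")]]
Rcpp::List conv3d_bwd_batch(const arma::mat &x, const arma::ivec &dims,
                            const int n, const arma::mat &W,
                            const arma::mat &gout) {
  const size_t nvox = (size_t)dims[0] * dims[1] * dims[2];
  mat gx(x.n_rows, x.n_cols);
  mat gW(W.n_rows, W.n_cols, fill::zeros);
  vec gb(W.n_cols, fill::zeros);
  for (int i = 0; i < n; ++i) {
    Rcpp::List r = conv3d_bwd(x.rows(i * nvox, (i + 1) * nvox - 1), dims, W,
                              gout.rows(i * nvox, (i + 1) * nvox - 1));
    gx.rows(i * nvox, (i + 1) * nvox - 1) = Rcpp::as<mat>(r["gx"]);
    gW += Rcpp::as<mat>(r["gW"]);
    gb += Rcpp::as<vec>(r["gb"]);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export(name = ".maxpool3d_fwd_batch")]]
Rcpp::List maxpool3d_fwd_batch(const arma::mat &x, const arma::ivec &dims,
                               const int n) {
  const size_t nvox = (size_t)dims[0] * dims[1] * dims[2];
  const size_t mvox = (size_t)(dims[0] / 2) * (dims[1] / 2) * (dims[2] / 2);
  mat out(mvox * n, x.n_cols);
  imat idx(mvox * n, x.n_cols);
  Rcpp::IntegerVector od;
  for (int i = 0; i < n; ++i) {
    Rcpp::List r = maxpool3d_fwd(x.rows(i * nvox, (i + 1) * nvox - 1), dims);
    out.rows(i * mvox, (i + 1) * mvox - 1) = Rcpp::as<mat>(r["out"]);
    // shift per-sample indices into the stacked row space
    imat ii = Rcpp::as<imat>(r["idx"]);
    idx.rows(i * mvox, (i + 1) * mvox - 1) = ii + (sword)(i * nvox);
    od = r["out_dims"];
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("idx") = idx,
                            Rcpp::Named("out_dims") = od);
}

// [[Rcpp::export(name = ".maxpool3d_bwd_batch")]]
arma::mat maxpool3d_bwd_batch(const arma::mat &gout, const arma::imat &idx,
                              const int nrow_in) {
  return maxpool3d_bwd(gout, idx, nrow_in);
}

// fused batch-norm (training statistics) + ReLU forward
// [[Rcpp::export(name = ".bn_relu_fwd_train")]]
Rcpp::List bn_relu_fwd_train(const arma::mat &A, const arma::vec &gamma,
                             const arma::vec &beta, const double eps) {
  const int C = A.n_cols;
  const size_t nr = A.n_rows;
  mat out(nr, C), xhat(nr, C);
  vec mu(C), varb(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double *a = A.colptr(c);
    double s = 0;
    for (size_t i = 0; i < nr; ++i) s += a[i];
    const double m = s / nr;
    double v = 0;
    for (size_t i = 0; i < nr; ++i) { const double d = a[i] - m; v += d * d; }
    v /= nr;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[c] = m; varb[c] = v; invstd[c] = is;
    const double g = gamma[c], be = beta[c];
    double *xh = xhat.colptr(c), *o = out.colptr(c);
    for (size_t i = 0; i < nr; ++i) {
      const double z = (a[i] - m) * is;
      xh[i] = z;
      const double y = g * z + be;
      o[i] = y > 0 ? y : 0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("invstd") = invstd,
                            Rcpp::Named("mu") = mu,
                            Rcpp::Named("var_biased") = varb);
}

// batch-norm with fixed (running) statistics + ReLU forward
// [[Rcpp::export(name = ".bn_relu_fwd_eval")]]
arma::mat bn_relu_fwd_eval(const arma::mat &A, const arma::vec &gamma,
                           const arma::vec &beta, const arma::vec &rm,
                           const arma::vec &rv, const double eps) {
  const int C = A.n_cols;
  const size_t nr = A.n_rows;
  mat out(nr, C);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rv[c] + eps);
    const double g = gamma[c], be = beta[c], m = rm[c];
    const double *a = A.colptr(c);
    double *o = out.colptr(c);
    for (size_t i = 0; i < nr; ++i) {
      const double y = g * (a[i] - m) * is + be;
      o[i] = y > 0 ? y : 0;
    }
  }
  return out;
}

// fused ReLU + batch-norm backward: G is dL/d(relu out); out is the forward
// output (its positivity encodes the ReLU mask)
// [[Rcpp::export(name = ".bn_relu_bwd")]]
Rcpp::List bn_relu_bwd(const arma::mat &G, const arma::mat &out,
                       const arma::mat &xhat, const arma::vec &invstd,
                       const arma::vec &gamma) {
  const int C = G.n_cols;
  const size_t nr = G.n_rows;
  mat gx(nr, C);
  vec ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *g = G.colptr(c), *o = out.colptr(c), *xh = xhat.colptr(c);
    double sg = 0, sgx = 0;
    for (size_t i = 0; i < nr; ++i) {
      const double gm = o[i] > 0 ? g[i] : 0;
      sg += gm;
      sgx += gm * xh[i];
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    const double k = gamma[c] * invstd[c];
    const double mg = sg / nr, mgx = sgx / nr;
    double *d = gx.colptr(c);
    for (size_t i = 0; i < nr; ++i) {
      const double gm = o[i] > 0 ? g[i] : 0;
      d[i] = k * (gm - mg - xh[i] * mgx);
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
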