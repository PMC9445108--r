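// Direct zero-padded convolution of a volume with a kernel that is
// separable into an in-plane 2D factor and an axial 1D factor (the form of
// every discretised PSF kernel here).  When the in-plane factor itself is
// separable (kernel axes aligned with the grid, theta = 0) the x and y
// passes run as 1D convolutions.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::cube;
using arma::mat;
using arma::vec;

namespace {

// 1D convolution along the first dimension of each slice column block
static void conv_dim1(const cube& in, const vec& k, cube& out) {
  const int n = in.n_rows, m = in.n_cols, nz = in.n_slices;
  const int r = (static_cast<int>(k.n_elem) - 1) / 2;
  out.zeros();
  for (int iz = 0; iz < nz; ++iz)
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) {
        const double v = in(i, j, iz);
        if (v == 0.0) continue;
        const int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
        for (int ii = lo; ii <= hi; ++ii) out(ii, j, iz) += v * k(ii - i + r);
      }
}

static void conv_dim2(const cube& in, const vec& k, cube& out) {
  const int n = in.n_rows, m = in.n_cols, nz = in.n_slices;
  const int r = (static_cast<int>(k.n_elem) - 1) / 2;
  out.zeros();
  for (int iz = 0; iz < nz; ++iz)
    for (int j = 0; j < m; ++j) {
      const int lo = std::max(0, j - r), hi = std::min(m - 1, j + r);
      for (int jj = lo; jj <= hi; ++jj) {
        const double kv = k(jj - j + r);
        for (int i = 0; i < n; ++i) out(i, jj, iz) += kv * in(i, j, iz);
      }
    }
}

static void conv_dim3(const cube& in, const vec& k, cube& out) {
  const int nz = in.n_slices;
  const int r = (static_cast<int>(k.n_elem) - 1) / 2;
  out.zeros();
  for (int iz = 0; iz < nz; ++iz) {
    const int lo = std::max(0, iz - r), hi = std::min(nz - 1, iz + r);
    for (int zz = lo; zz <= hi; ++zz)
      out.slice(zz) += k(zz - iz + r) * in.slice(iz);
  }
}

}  // namespace

// vol convolved with outer(k2, kz); if kx/ky are non-empty they replace the
// 2D pass with two 1D passes (k2 == outer(kx, ky)).
// [[Rcpp::export]]
arma::cube cpp_convolve_k2z(const arma::cube& vol, const arma::mat& k2,
                            const arma::vec& kz, const arma::vec& kx,
                            const arma::vec& ky) {
  const int n = vol.n_rows, m = vol.n_cols, nz = vol.n_slices;
  cube tmp(n, m, nz), out(n, m, nz);
  if (kx.n_elem > 0) {
    conv_dim1(vol, kx, out);
    conv_dim2(out, ky, tmp);
  } else {
    // direct in-plane 2D convolution
    const int rx = (static_cast<int>(k2.n_rows) - 1) / 2;
    const int ry = (static_cast<int>(k2.n_cols) - 1) / 2;
    tmp.zeros();
    for (int iz = 0; iz < nz; ++iz) {
      const mat& s = vol.slice(iz);
      mat& o = tmp.slice(iz);
      for (int j = 0; j < m; ++j)
        for (int i = 0; i < n; ++i) {
          const double v = s(i, j);
          if (v == 0.0) continue;
          const int ilo = std::max(0, i - rx), ihi = std::min(n - 1, i + rx);
          const int jlo = std::max(0, j - ry), jhi = std::min(m - 1, j + ry);
          for (int jj = jlo; jj <= jhi; ++jj) {
            const double* kcol = k2.colptr(jj - j + ry);
            for (int ii = ilo; ii <= ihi; ++ii)
              o(ii, jj) += v * kcol[ii - i + rx];
          }
        }
    }
  }
  conv_dim3(tmp, kz, out);
  return out;
}
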