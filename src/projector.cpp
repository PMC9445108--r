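// Rotation-based SPECT projector core.
//
// Conventions (shared with the R layer):
//  * volumes are arma::cube with dims (nx, ny, nz), nx == ny (square transaxial
//    grid); world coordinate of voxel centre i (0-based) is (i-(n-1)/2)*voxel mm,
//    origin at the grid centre, z axial;
//  * view v has detector normal (cos a_v, sin a_v); bin direction (-sin, cos);
//  * projections are cubes (n_bins = ny, n_slices = nz, n_views);
//  * detector sampling mirrors the grid (bin_mm = voxel_mm).
//
// The simulator path (forward_blur) applies a distance-dependent 2D Gaussian
// per constant-distance plane *before* multiplying by the cumulative
// attenuation of that plane's column (midpoint rule).  The reconstruction
// path (forward_geom / backproject_geom / osem) is unblurred with voxelwise
// central-ray attenuation, an exact adjoint pair.

// element accesses in the inner projector loops are index-verified by
// construction; disable Armadillo's per-access bounds checks
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Tap {
  int i0, j0;      // lower index pair, -1 if fully outside
  double w00, w10, w01, w11;
  bool in00, in10, in01, in11;
};

// Bilinear sampling taps for the rotated transaxial grid of one view.
// taps[ia + nx*ib] maps rotated-frame gridpoint (depth ia, bin ib) to the
// original (x, y) indices.
static void make_taps(int n, double cosA, double sinA, std::vector<Tap>& taps) {
  const double c = (n - 1) / 2.0;
  taps.resize(static_cast<size_t>(n) * n);
  for (int ib = 0; ib < n; ++ib) {
    const double b = ib - c;
    for (int ia = 0; ia < n; ++ia) {
      const double a = ia - c;
      // world (in voxel units): p = a*e_d + b*e_u
      const double fx = a * cosA - b * sinA + c;
      const double fy = a * sinA + b * cosA + c;
      Tap t;
      const int ix0 = static_cast<int>(std::floor(fx));
      const int iy0 = static_cast<int>(std::floor(fy));
      const double wx = fx - ix0, wy = fy - iy0;
      t.i0 = ix0; t.j0 = iy0;
      t.w00 = (1 - wx) * (1 - wy);
      t.w10 = wx * (1 - wy);
      t.w01 = (1 - wx) * wy;
      t.w11 = wx * wy;
      t.in00 = ix0 >= 0 && ix0 < n && iy0 >= 0 && iy0 < n;
      t.in10 = ix0 + 1 >= 0 && ix0 + 1 < n && iy0 >= 0 && iy0 < n;
      t.in01 = ix0 >= 0 && ix0 < n && iy0 + 1 >= 0 && iy0 + 1 < n;
      t.in11 = ix0 + 1 >= 0 && ix0 + 1 < n && iy0 + 1 >= 0 && iy0 + 1 < n;
      taps[static_cast<size_t>(ia) + static_cast<size_t>(n) * ib] = t;
    }
  }
}

// rot(ia, ib, iz) = vol sampled at the rotated gridpoint (gather form).
static void rotate_into(const cube& vol, const std::vector<Tap>& taps, cube& rot) {
  const int n = vol.n_rows, nz = vol.n_slices;
  rot.zeros();
  for (int iz = 0; iz < nz; ++iz) {
    const mat& s = vol.slice(iz);
    mat& r = rot.slice(iz);
    for (int ib = 0; ib < n; ++ib) {
      for (int ia = 0; ia < n; ++ia) {
        const Tap& t = taps[static_cast<size_t>(ia) + static_cast<size_t>(n) * ib];
        double v = 0.0;
        if (t.in00) v += t.w00 * s(t.i0, t.j0);
        if (t.in10) v += t.w10 * s(t.i0 + 1, t.j0);
        if (t.in01) v += t.w01 * s(t.i0, t.j0 + 1);
        if (t.in11) v += t.w11 * s(t.i0 + 1, t.j0 + 1);
        r(ia, ib) = v;
      }
    }
  }
}

// Adjoint of rotate_into: scatter rot back into vol (accumulating).
static void rotate_adjoint_into(const cube& rot, const std::vector<Tap>& taps, cube& vol) {
  const int n = vol.n_rows, nz = vol.n_slices;
  for (int iz = 0; iz < nz; ++iz) {
    mat& s = vol.slice(iz);
    const mat& r = rot.slice(iz);
    for (int ib = 0; ib < n; ++ib) {
      for (int ia = 0; ia < n; ++ia) {
        const Tap& t = taps[static_cast<size_t>(ia) + static_cast<size_t>(n) * ib];
        const double v = r(ia, ib);
        if (v == 0.0) continue;
        if (t.in00) s(t.i0, t.j0) += t.w00 * v;
        if (t.in10) s(t.i0 + 1, t.j0) += t.w10 * v;
        if (t.in01) s(t.i0, t.j0 + 1) += t.w01 * v;
        if (t.in11) s(t.i0 + 1, t.j0 + 1) += t.w11 * v;
      }
    }
  }
}

// Cumulative central-ray attenuation factors in the rotated frame:
// att(ia, ib, iz) = exp(-voxel*(0.5*mu(ia) + sum_{ia' > ia} mu(ia'))),
// the survival factor from plane ia to the detector at large +depth.
static void atten_from_rotated_mu(const cube& murot, double voxel, cube& att) {
  const int n = murot.n_rows, nz = murot.n_slices;
  for (int iz = 0; iz < nz; ++iz) {
    const mat& m = murot.slice(iz);
    mat& a = att.slice(iz);
    for (int ib = 0; ib < n; ++ib) {
      double cum = 0.0;
      for (int ia = n - 1; ia >= 0; --ia) {
        const double mv = m(ia, ib);
        a(ia, ib) = std::exp(-voxel * (cum + 0.5 * mv));
        cum += mv;
      }
    }
  }
}

static vec gauss_kernel(double sigma_vox, int max_r) {
  if (sigma_vox < 1e-8) return vec(1, arma::fill::ones);
  int r = static_cast<int>(std::ceil(4.0 * sigma_vox));
  if (r > max_r) r = max_r;
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
  return k / arma::accu(k);
}

// Separable padded convolution of an (nb x nz) plane, normalised kernel.
static void blur_plane(const mat& p, const vec& k, mat& tmp, mat& out) {
  const int nb = p.n_rows, nz = p.n_cols;
  const int r = (static_cast<int>(k.n_elem) - 1) / 2;
  if (r == 0) { out = p; return; }
  tmp.zeros();
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nb; ++i) {
      const double v = p(i, j);
      if (v == 0.0) continue;
      const int lo = std::max(0, i - r), hi = std::min(nb - 1, i + r);
      for (int ii = lo; ii <= hi; ++ii) tmp(ii, j) += v * k(ii - i + r);
    }
  out.zeros();
  for (int j = 0; j < nz; ++j) {
    const int lo = std::max(0, j - r), hi = std::min(nz - 1, j + r);
    for (int jj = lo; jj <= hi; ++jj) {
      const double kv = k(jj - j + r);
      out.col(jj) += kv * tmp.col(j);
    }
  }
}

}  // namespace

// Simulator forward projection: distance-dependent blur + (optional)
// cumulative attenuation.  radii_mm gives the orbit radius per view.
// [[Rcpp::export]]
arma::cube cpp_forward_blur(const arma::cube& act, const arma::cube& mu,
                            const arma::vec& angles, const arma::vec& radii_mm,
                            double voxel_mm, double fwhm0_mm, double slope,
                            bool attenuate) {
  const int n = act.n_rows, nz = act.n_slices, nv = angles.n_elem;
  if (static_cast<int>(act.n_cols) != n) stop("square transaxial grid required");
  cube proj(n, nz, nv, arma::fill::zeros);
  cube arot(n, n, nz), mrot(n, n, nz), att(n, n, nz);
  mat tmp(n, nz), blr(n, nz), plane(n, nz);
  std::vector<Tap> taps;
  const double c = (n - 1) / 2.0;
  const double FWHM2SIG = 1.0 / 2.354820045;
  // projections are physical: bin value = bin area x line integral of the
  // concentration, i.e. voxel^3 x sum over depth samples
  const double vscale = voxel_mm * voxel_mm * voxel_mm;
  for (int v = 0; v < nv; ++v) {
    make_taps(n, std::cos(angles(v)), std::sin(angles(v)), taps);
    rotate_into(act, taps, arot);
    if (attenuate) {
      rotate_into(mu, taps, mrot);
      atten_from_rotated_mu(mrot, voxel_mm, att);
    }
    mat& out = proj.slice(v);
    for (int ia = 0; ia < n; ++ia) {
      double d = radii_mm(v) - (ia - c) * voxel_mm;
      if (d < 0) d = 0;
      const double sigma_vox = (fwhm0_mm + slope * d) * FWHM2SIG / voxel_mm;
      const vec k = gauss_kernel(sigma_vox, n - 1);
      // plane(ib, iz) at constant depth ia
      for (int iz = 0; iz < nz; ++iz)
        for (int ib = 0; ib < n; ++ib) plane(ib, iz) = arot(ia, ib, iz);
      blur_plane(plane, k, tmp, blr);
      if (attenuate) {
        for (int iz = 0; iz < nz; ++iz)
          for (int ib = 0; ib < n; ++ib) out(ib, iz) += att(ia, ib, iz) * blr(ib, iz);
      } else {
        out += blr;
      }
    }
    out *= vscale;
  }
  return proj;
}

// Unblurred (geometric) forward projection with voxelwise central-ray
// attenuation -- the reconstruction system model.
// [[Rcpp::export]]
arma::cube cpp_forward_geom(const arma::cube& act, const arma::cube& mu,
                            const arma::vec& angles, double voxel_mm,
                            bool attenuate) {
  const int n = act.n_rows, nz = act.n_slices, nv = angles.n_elem;
  const double vscale = voxel_mm * voxel_mm * voxel_mm;
  cube proj(n, nz, nv, arma::fill::zeros);
  cube arot(n, n, nz), mrot(n, n, nz), att(n, n, nz);
  std::vector<Tap> taps;
  for (int v = 0; v < nv; ++v) {
    make_taps(n, std::cos(angles(v)), std::sin(angles(v)), taps);
    rotate_into(act, taps, arot);
    if (attenuate) {
      rotate_into(mu, taps, mrot);
      atten_from_rotated_mu(mrot, voxel_mm, att);
    }
    mat& out = proj.slice(v);
    for (int iz = 0; iz < nz; ++iz)
      for (int ib = 0; ib < n; ++ib) {
        double s = 0.0;
        if (attenuate) {
          for (int ia = 0; ia < n; ++ia) s += att(ia, ib, iz) * arot(ia, ib, iz);
        } else {
          for (int ia = 0; ia < n; ++ia) s += arot(ia, ib, iz);
        }
        out(ib, iz) += s * vscale;
      }
  }
  return proj;
}

// Exact adjoint of cpp_forward_geom.
// [[Rcpp::export]]
arma::cube cpp_backproject_geom(const arma::cube& proj, const arma::cube& mu,
                                const arma::vec& angles, double voxel_mm,
                                int nx, int nz, bool attenuate) {
  const int n = nx, nv = angles.n_elem;
  const double vscale = voxel_mm * voxel_mm * voxel_mm;
  cube vol(n, n, nz, arma::fill::zeros);
  cube g(n, n, nz), mrot(n, n, nz), att(n, n, nz);
  std::vector<Tap> taps;
  for (int v = 0; v < nv; ++v) {
    make_taps(n, std::cos(angles(v)), std::sin(angles(v)), taps);
    if (attenuate) {
      rotate_into(mu, taps, mrot);
      atten_from_rotated_mu(mrot, voxel_mm, att);
    }
    const mat& r = proj.slice(v);
    for (int iz = 0; iz < nz; ++iz) {
      mat& gs = g.slice(iz);
      for (int ib = 0; ib < n; ++ib) {
        const double rv = r(ib, iz);
        if (attenuate) {
          for (int ia = 0; ia < n; ++ia) gs(ia, ib) = att(ia, ib, iz) * rv;
        } else {
          for (int ia = 0; ia < n; ++ia) gs(ia, ib) = rv;
        }
      }
    }
    rotate_adjoint_into(g, taps, vol);
  }
  vol *= vscale;
  return vol;
}

// OSEM with interleaved subsets, fixed subset order, epsilon-guarded
// ratios, checkpointed at the requested update numbers (1-based).
// [[Rcpp::export]]
Rcpp::List cpp_osem(const arma::cube& y, const arma::cube& mu,
                    const arma::vec& angles, double voxel_mm,
                    int n_subsets, int n_iter,
                    const arma::ivec& checkpoints,
                    const arma::cube& init, bool attenuate,
                    double eps, double sens_rel_thresh) {
  const int n = y.n_rows, nz = y.n_cols, nv = angles.n_elem;
  const double vscale = voxel_mm * voxel_mm * voxel_mm;
  if (nv % n_subsets != 0) stop("n_views not divisible by n_subsets");
  const int per = nv / n_subsets;

  // interleaved partition: subset s takes views s, s+n_subsets, ...
  std::vector<std::vector<int>> subsets(n_subsets);
  for (int s = 0; s < n_subsets; ++s)
    for (int k = 0; k < per; ++k) subsets[s].push_back(s + k * n_subsets);

  cube arot(n, n, nz), mrot(n, n, nz), att(n, n, nz), g(n, n, nz);
  std::vector<Tap> taps;

  // per-subset sensitivity images (backprojection of ones)
  std::vector<cube> sens(n_subsets);
  for (int s = 0; s < n_subsets; ++s) {
    cube sv(n, n, nz, arma::fill::zeros);
    for (int vi : subsets[s]) {
      make_taps(n, std::cos(angles(vi)), std::sin(angles(vi)), taps);
      if (attenuate) {
        rotate_into(mu, taps, mrot);
        atten_from_rotated_mu(mrot, voxel_mm, att);
        rotate_adjoint_into(att, taps, sv);
      } else {
        g.ones();
        rotate_adjoint_into(g, taps, sv);
      }
    }
    sens[s] = sv;
  }
  double smax = 0.0;
  for (int s = 0; s < n_subsets; ++s) smax = std::max(smax, sens[s].max());
  const double sthr = sens_rel_thresh * smax;

  cube x = init;
  Rcpp::List out;
  std::vector<int> cps(checkpoints.begin(), checkpoints.end());
  int update = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < n_subsets; ++s) {
      cube bp(n, n, nz, arma::fill::zeros);
      for (int vi : subsets[s]) {
        make_taps(n, std::cos(angles(vi)), std::sin(angles(vi)), taps);
        rotate_into(x, taps, arot);
        if (attenuate) {
          rotate_into(mu, taps, mrot);
          atten_from_rotated_mu(mrot, voxel_mm, att);
        }
        const mat& yv = y.slice(vi);
        // ratio image in rotated frame: att * (y / (P x + eps)) spread along depth
        for (int iz = 0; iz < nz; ++iz) {
          mat& gs = g.slice(iz);
          for (int ib = 0; ib < n; ++ib) {
            double fp = 0.0;
            if (attenuate) {
              for (int ia = 0; ia < n; ++ia) fp += att(ia, ib, iz) * arot(ia, ib, iz);
            } else {
              for (int ia = 0; ia < n; ++ia) fp += arot(ia, ib, iz);
            }
            const double ratio = yv(ib, iz) / (fp * vscale + eps);
            if (attenuate) {
              for (int ia = 0; ia < n; ++ia) gs(ia, ib) = att(ia, ib, iz) * ratio;
            } else {
              for (int ia = 0; ia < n; ++ia) gs(ia, ib) = ratio;
            }
          }
        }
        rotate_adjoint_into(g, taps, bp);
      }
      const cube& sv = sens[s];
      for (uword i = 0; i < x.n_elem; ++i) {
        const double se = sv(i);
        x(i) = (se > sthr) ? x(i) * bp(i) / se : 0.0;
      }
      ++update;
      if (std::find(cps.begin(), cps.end(), update) != cps.end()) {
        out.push_back(Rcpp::wrap(x));
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
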