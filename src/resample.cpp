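#include <Rcpp.h>
using namespace Rcpp;

// Resample a 3D volume onto an output grid. `M` is a 4x4 matrix mapping
// 0-based output voxel indices to continuous 0-based input voxel indices.
// Out-of-field samples are set to `fill` (0 for pipeline use, NA for
// registration metrics so the overlap domain can be identified).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim_in,
                           NumericMatrix M, IntegerVector dim_out,
                           bool linear, double fill) {
  const int nx = dim_in[0], ny = dim_in[1], nz = dim_in[2];
  const int ox = dim_out[0], oy = dim_out[1], oz = dim_out[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double *v = vol.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = m00*i + m01*j + m02*k + m03;
        const double y = m10*i + m11*j + m12*k + m13;
        const double z = m20*i + m21*j + m22*k + m23;
        if (linear) {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          if (x0 < 0 || x0 >= nx - 1 || y0 < 0 || y0 >= ny - 1 ||
              z0 < 0 || z0 >= nz - 1) {
            // allow samples exactly on the far boundary
            if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 ||
                z < 0 || z > nz - 1) { out[idx] = fill; continue; }
            const int xi = std::min(x0, nx - 2), yi = std::min(y0, ny - 2),
                      zi = std::min(z0, nz - 2);
            const double fx = x - xi, fy = y - yi, fz = z - zi;
            double acc = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
                                   (dz ? fz : 1 - fz);
                  acc += w * v[(R_xlen_t)(zi + dz) * nx * ny +
                               (R_xlen_t)(yi + dy) * nx + (xi + dx)];
                }
            out[idx] = acc;
            continue;
          }
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          const R_xlen_t base = (R_xlen_t)z0 * nx * ny + (R_xlen_t)y0 * nx + x0;
          const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
          const double c000 = v[base],          c100 = v[base + 1];
          const double c010 = v[base + sy],     c110 = v[base + sy + 1];
          const double c001 = v[base + sz],     c101 = v[base + sz + 1];
          const double c011 = v[base + sy + sz],c111 = v[base + sy + sz + 1];
          const double c00 = c000 * (1 - fx) + c100 * fx;
          const double c10 = c010 * (1 - fx) + c110 * fx;
          const double c01 = c001 * (1 - fx) + c101 * fx;
          const double c11 = c011 * (1 - fx) + c111 * fx;
          out[idx] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                     (c01 * (1 - fy) + c11 * fy) * fz;
        } else {
          const int xi = (int)std::lround(x), yi = (int)std::lround(y),
                    zi = (int)std::lround(z);
          if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
            out[idx] = fill;
          else
            out[idx] = v[(R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx + xi];
        }
      }
    }
  }
  return out;
}

// Joint histogram of two equal-length vectors with `nbins` bins per axis over
// fixed ranges; entries where either value is NA are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int nbins,
                             double amin, double amax, double bmin, double bmax) {
  NumericMatrix H(nbins, nbins);
  const double ascale = nbins / (amax - amin), bscale = nbins / (bmax - bmin);
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double av = a[i], bv = b[i];
    if (ISNAN(av) || ISNAN(bv)) continue;
    int ai = (int)((av - amin) * ascale);
    int bi = (int)((bv - bmin) * bscale);
    if (ai < 0) ai = 0; if (ai >= nbins) ai = nbins - 1;
    if (bi < 0) bi = 0; if (bi >= nbins) bi = nbins - 1;
    H(ai, bi) += 1.0;
  }
  return H;
}
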