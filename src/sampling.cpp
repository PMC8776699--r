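#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D volume at continuous 0-based voxel
// coordinates. Points outside the volume (beyond the centers of the border
// voxels) get `fill` (use NA_REAL to mark drops, -1000 for air padding).
// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  const double *v = REAL(vol);
  NumericVector out(n);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= 0.0 && x <= nx - 1.0 && y >= 0.0 && y <= ny - 1.0 &&
          z >= 0.0 && z <= nz - 1.0)) {
      out[i] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == nx - 1) x0--;
    if (y0 == ny - 1) y0--;
    if (z0 == nz - 1) z0--;
    if (x0 < 0) x0 = 0;
    if (y0 < 0) y0 = 0;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    const double *base = v + x0 * sx + y0 * sy + z0 * sz;
    double c000 = base[0], c100 = base[sx];
    double c010 = base[sy], c110 = base[sx + sy];
    double c001 = base[sz], c101 = base[sx + sz];
    double c011 = base[sy + sz], c111 = base[sx + sy + sz];
    double c00 = c000 + fx * (c100 - c000);
    double c10 = c010 + fx * (c110 - c010);
    double c01 = c001 + fx * (c101 - c001);
    double c11 = c011 + fx * (c111 - c011);
    double c0 = c00 + fy * (c10 - c00);
    double c1 = c01 + fy * (c11 - c01);
    out[i] = c0 + fz * (c1 - c0);
  }
  return out;
}

// Nearest-neighbour sampling under the same out-of-volume rule.
// [[Rcpp::export]]
NumericVector cpp_sample_nearest(NumericVector vol, IntegerVector dim,
                                 NumericMatrix pts, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = pts.nrow();
  const double *v = REAL(vol);
  NumericVector out(n);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (!(x >= -0.5 && x < nx - 0.5 && y >= -0.5 && y < ny - 0.5 &&
          z >= -0.5 && z < nz - 0.5)) {
      out[i] = fill;
      continue;
    }
    int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
    if (xi < 0) xi = 0; else if (xi > nx - 1) xi = nx - 1;
    if (yi < 0) yi = 0; else if (yi > ny - 1) yi = ny - 1;
    if (zi < 0) zi = 0; else if (zi > nz - 1) zi = nz - 1;
    out[i] = v[xi + yi * sy + zi * sz];
  }
  return out;
}

// Joint histogram accumulation: a_bin is a precomputed 1-based bin index for
// the fixed image; b holds moving-image intensities (NA = dropped pair).
// Returns a bins x bins count matrix; total count is its sum.
// [[Rcpp::export]]
IntegerMatrix cpp_joint_hist(IntegerVector a_bin, NumericVector b, int bins,
                             double lo, double hi) {
  IntegerMatrix counts(bins, bins);
  const double scale = bins / (hi - lo);
  const R_xlen_t n = a_bin.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double bv = b[i];
    if (ISNAN(bv)) continue;
    if (bv < lo) bv = lo;
    if (bv > hi) bv = hi;
    int bb = (int)((bv - lo) * scale);
    if (bb >= bins) bb = bins - 1;
    counts(a_bin[i] - 1, bb)++;
  }
  return counts;
}
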