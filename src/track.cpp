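// Deterministic streamline integration through a masked tensor field.
//
// Coordinates: tracking happens in the image frame scaled to mm
// (position = voxel index * voxel size); voxel (i,j,k) is centred at
// index (i,j,k), 0-based. Directions are principal eigenvectors of the
// tensor trilinearly interpolated over in-mask voxels only (weights of
// out-of-mask or non-finite neighbours set to zero and renormalised), so
// a homogeneous muscle stays homogeneous up to its boundary. Euler steps
// of fixed length; per-step sign alignment with the incoming direction.
//
// Termination codes: 0 mask-exit, 1 fa-bound, 2 angle, 3 max-steps.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

struct Field {
  const double *tens;  // nvox x 6, column-major (R matrix)
  const int *mask;     // nvox
  int nx, ny, nz;
  vec3 vs;  // voxel size mm
  uword nvox;
  inline long idx(int i, int j, int k) const {
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
  inline bool in_bounds(int i, int j, int k) const {
    return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
  }
  inline bool in_mask_point(const vec3 &p_mm) const {
    // nearest-voxel membership
    int i = (int)std::lround(p_mm(0) / vs(0));
    int j = (int)std::lround(p_mm(1) / vs(1));
    int k = (int)std::lround(p_mm(2) / vs(2));
    return in_bounds(i, j, k) && mask[idx(i, j, k)] != 0;
  }
  // masked trilinear interpolation of the 6 tensor components;
  // returns false if no in-mask neighbour carries weight
  bool interp(const vec3 &p_mm, double out[6]) const {
    double fx = p_mm(0) / vs(0), fy = p_mm(1) / vs(1), fz = p_mm(2) / vs(2);
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy),
        k0 = (int)std::floor(fz);
    double dx = fx - i0, dy = fy - j0, dz = fz - k0;
    double wsum = 0.0;
    for (int c = 0; c < 6; ++c) out[c] = 0.0;
    for (int a = 0; a <= 1; ++a)
      for (int b = 0; b <= 1; ++b)
        for (int c = 0; c <= 1; ++c) {
          int i = i0 + a, j = j0 + b, k = k0 + c;
          if (!in_bounds(i, j, k)) continue;
          long id = idx(i, j, k);
          if (!mask[id]) continue;
          double w = (a ? dx : 1 - dx) * (b ? dy : 1 - dy) * (c ? dz : 1 - dz);
          if (w <= 0) continue;
          bool finite = true;
          for (int q = 0; q < 6; ++q)
            if (!std::isfinite(tens[id + (long)q * nvox])) finite = false;
          if (!finite) continue;  // non-finite voxel acts as a barrier
          for (int q = 0; q < 6; ++q) out[q] += w * tens[id + (long)q * nvox];
          wsum += w;
        }
    if (wsum <= 0.0) return false;
    for (int q = 0; q < 6; ++q) out[q] /= wsum;
    return true;
  }
};

static bool principal_dir(const double t[6], vec3 &v, double &fa) {
  mat33 Dm = {{t[0], t[3], t[4]}, {t[3], t[1], t[5]}, {t[4], t[5], t[2]}};
  vec3 ev;
  mat33 evec;
  if (!eig_sym(ev, evec, Dm)) return false;
  double md = (ev(0) + ev(1) + ev(2)) / 3.0;
  double ss = dot(ev, ev);
  fa = ss == 0.0 ? 0.0
                 : std::sqrt(1.5 * (std::pow(ev(0) - md, 2) +
                                    std::pow(ev(1) - md, 2) +
                                    std::pow(ev(2) - md, 2)) / ss);
  v = evec.col(2);
  double n = norm(v);
  if (n == 0.0 || !std::isfinite(n)) return false;
  v /= n;
  return true;
}

// integrate one direction from a seed; appends points (excluding the seed)
// to pts; returns the termination code
static int integrate(const Field &f, vec3 p, vec3 dir, double step_mm,
                     double fa_min, double fa_max, double cos_max,
                     int max_steps, std::vector<vec3> &pts) {
  double t[6];
  vec3 v;
  double fa;
  for (int s = 0; s < max_steps; ++s) {
    if (!f.interp(p, t)) return 1;             // barrier: treat as FA = 0
    if (!principal_dir(t, v, fa)) return 1;
    if (dot(v, dir) < 0) v = -v;               // sign alignment
    if (s > 0 && dot(v, dir) < cos_max) return 2;  // turning angle exceeded
    vec3 p_next = p + step_mm * v;
    if (!f.in_mask_point(p_next)) return 0;    // next point leaves the mask
    double tn[6];
    double fan;
    vec3 vn;
    if (!f.interp(p_next, tn) || !principal_dir(tn, vn, fan)) return 1;
    if (fan < fa_min || fan > fa_max) return 1;
    pts.push_back(p_next);
    p = p_next;
    dir = v;
  }
  return 3;
}

// [[Rcpp::export]]
Rcpp::List track_field(const arma::mat &tensors, const arma::ivec &mask,
                       const arma::ivec &dims, const arma::vec &voxel_size,
                       const arma::imat &seeds, double step_mm,
                       double max_angle_deg, double fa_min, double fa_max,
                       double min_length_mm, int max_steps) {
  Field f;
  f.tens = tensors.memptr();
  f.mask = mask.memptr();
  f.nx = dims(0);
  f.ny = dims(1);
  f.nz = dims(2);
  f.vs = {voxel_size(0), voxel_size(1), voxel_size(2)};
  f.nvox = tensors.n_rows;
  const double cos_max = std::cos(max_angle_deg * datum::pi / 180.0);

  std::vector<Rcpp::NumericMatrix> lines;
  std::vector<int> term_a, term_b, seed_id;
  double t[6];
  vec3 v1;
  double fa;
  for (uword s = 0; s < seeds.n_rows; ++s) {
    vec3 p = {seeds(s, 0) * f.vs(0), seeds(s, 1) * f.vs(1),
              seeds(s, 2) * f.vs(2)};
    if (!f.in_mask_point(p)) continue;
    if (!f.interp(p, t) || !principal_dir(t, v1, fa)) continue;
    if (fa < fa_min || fa > fa_max) continue;
    std::vector<vec3> fwd, bwd;
    int tf = integrate(f, p, v1, step_mm, fa_min, fa_max, cos_max, max_steps,
                       fwd);
    int tb = integrate(f, p, -v1, step_mm, fa_min, fa_max, cos_max, max_steps,
                       bwd);
    size_t npts = fwd.size() + bwd.size() + 1;
    double len = step_mm * (double)(npts - 1);
    if (npts < 2 || len < min_length_mm) continue;
    Rcpp::NumericMatrix M((int)npts, 3);
    int row = 0;
    for (size_t i = bwd.size(); i-- > 0;) {
      for (int c = 0; c < 3; ++c) M(row, c) = bwd[i](c) / f.vs(c);
      ++row;
    }
    for (int c = 0; c < 3; ++c) M(row, c) = p(c) / f.vs(c);
    ++row;
    for (size_t i = 0; i < fwd.size(); ++i) {
      for (int c = 0; c < 3; ++c) M(row, c) = fwd[i](c) / f.vs(c);
      ++row;
    }
    lines.push_back(M);
    term_a.push_back(tb);  // start end = backward direction's termination
    term_b.push_back(tf);
    seed_id.push_back((int)s + 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("streamlines") = Rcpp::wrap(lines),
      Rcpp::Named("term_start") = term_a, Rcpp::Named("term_end") = term_b,
      Rcpp::Named("seed") = seed_id);
}
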