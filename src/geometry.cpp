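// Geometry kernels: convex-hull volume, maximum-volume data-constrained
// simplex, and the column-shuffle t-ratio null loop. Kept in C++ because the
// randomization test refits the simplex and recomputes the hull up to 1e5
// times. All randomness comes from R's RNG so set.seed() governs everything.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <algorithm>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Facet {
  std::vector<unsigned int> v;  // d vertex indices (a (d-1)-simplex)
  vec nrm;                      // unit outward normal
  double off;                   // nrm . x = off on the facet hyperplane
};

// Unit normal of the hyperplane through the d points pts[vtx, ], oriented
// away from interior point c. Returns false if the points are affinely
// degenerate (nullity != 1).
bool facet_normal(const mat& pts, const std::vector<unsigned int>& vtx,
                  const vec& c, vec& nrm, double& off) {
  const unsigned int d = pts.n_cols;
  mat E(d - 1, d);
  for (unsigned int i = 1; i < d; ++i)
    E.row(i - 1) = pts.row(vtx[i]) - pts.row(vtx[0]);
  mat N = null(E);
  if (N.n_cols != 1) return false;
  nrm = N.col(0);
  double nn = norm(nrm);
  if (nn <= 0) return false;
  nrm /= nn;
  off = dot(nrm, pts.row(vtx[0]).t());
  if (dot(nrm, c) - off > 0) { nrm = -nrm; off = -off; }
  return true;
}

double hull_volume_impl(const mat& X) {
  const unsigned int n = X.n_rows, d = X.n_cols;
  if (d == 0) Rcpp::stop("points must have at least one column");
  if (d == 1) {
    double vol = X.max() - X.min();
    if (vol <= 0) Rcpp::stop("points do not span the requested dimension");
    return vol;
  }
  if (n < d + 1)
    Rcpp::stop("need at least d+1 points for a d-dimensional hull");
  double scale = abs(X).max();
  if (scale <= 0) scale = 1.0;
  const double eps = 1e-9 * scale;

  // Initial d-simplex: greedy height maximization from point 0.
  std::vector<unsigned int> init;
  init.push_back(0);
  rowvec x0 = X.row(0);
  mat Q(d, 0);
  for (unsigned int j = 0; j < d; ++j) {
    mat D = X.each_row() - x0;
    mat res = (Q.n_cols > 0) ? mat(D - (D * Q) * Q.t()) : D;
    vec h = sqrt(sum(res % res, 1));
    unsigned int best = h.index_max();
    if (h(best) <= eps)
      Rcpp::stop("points are rank-deficient for this dimension; reduce the dimensionality first");
    init.push_back(best);
    Q.insert_cols(Q.n_cols, res.row(best).t() / h(best));
  }

  vec c(d, fill::zeros);
  for (unsigned int i = 0; i <= d; ++i) c += X.row(init[i]).t();
  c /= (d + 1.0);

  std::vector<Facet> F;
  std::vector<char> alive;
  for (unsigned int leave = 0; leave <= d; ++leave) {
    Facet f;
    for (unsigned int i = 0; i <= d; ++i)
      if (i != leave) f.v.push_back(init[i]);
    if (!facet_normal(X, f.v, c, f.nrm, f.off))
      Rcpp::stop("degenerate initial facet");
    F.push_back(f);
    alive.push_back(1);
  }

  std::vector<char> used(n, 0);
  for (unsigned int i = 0; i <= d; ++i) used[init[i]] = 1;

  for (unsigned int p = 0; p < n; ++p) {
    if (used[p]) continue;
    vec xp = X.row(p).t();
    std::vector<unsigned int> vis;
    for (unsigned int i = 0; i < F.size(); ++i)
      if (alive[i] && dot(F[i].nrm, xp) - F[i].off > eps) vis.push_back(i);
    if (vis.empty()) continue;

    std::map<std::vector<unsigned int>, int> ridge_count;
    for (unsigned int vi : vis) {
      for (unsigned int j = 0; j < d; ++j) {
        std::vector<unsigned int> r;
        for (unsigned int t = 0; t < d; ++t)
          if (t != j) r.push_back(F[vi].v[t]);
        std::sort(r.begin(), r.end());
        ridge_count[r]++;
      }
    }
    for (unsigned int vi : vis) alive[vi] = 0;
    for (std::map<std::vector<unsigned int>, int>::iterator it = ridge_count.begin();
         it != ridge_count.end(); ++it) {
      if (it->second != 1) continue;  // interior ridge of the visible patch
      Facet f;
      f.v = it->first;
      f.v.push_back(p);
      if (!facet_normal(X, f.v, c, f.nrm, f.off))
        Rcpp::stop("degenerate facet while expanding hull");
      F.push_back(f);
      alive.push_back(1);
    }
  }

  double dfact = 1.0;
  for (unsigned int j = 2; j <= d; ++j) dfact *= j;
  double vol = 0.0;
  mat M(d, d);
  for (unsigned int i = 0; i < F.size(); ++i) {
    if (!alive[i]) continue;
    for (unsigned int r = 0; r < d; ++r)
      M.row(r) = X.row(F[i].v[r]) - c.t();
    vol += std::abs(det(M));
  }
  return vol / dfact;
}

// Orthonormal basis of span{X[idx[i],] - X[idx[0],]} (d x (m-1), rank-trimmed)
mat affine_basis(const mat& X, const std::vector<unsigned int>& idx) {
  const unsigned int d = X.n_cols, m = idx.size();
  if (m <= 1) return mat(d, 0);
  mat B(d, m - 1);
  for (unsigned int i = 1; i < m; ++i)
    B.col(i - 1) = (X.row(idx[i]) - X.row(idx[0])).t();
  mat Q, R;
  if (!qr_econ(Q, R, B)) return mat(d, 0);
  double tol = 1e-12 * (1.0 + abs(R).max());
  std::vector<unsigned int> keep;
  for (unsigned int i = 0; i < R.n_rows && i < R.n_cols; ++i)
    if (std::abs(R(i, i)) > tol) keep.push_back(i);
  mat Qk(d, keep.size());
  for (unsigned int i = 0; i < keep.size(); ++i) Qk.col(i) = Q.col(keep[i]);
  return Qk;
}

// Heights of every point above the affine span of the anchor set.
vec point_heights(const mat& X, const std::vector<unsigned int>& idx, const mat& Q) {
  mat D = X.each_row() - X.row(idx[0]);
  mat res = (Q.n_cols > 0) ? mat(D - (D * Q) * Q.t()) : D;
  return sqrt(sum(res % res, 1));
}

double subset_volume(const mat& X, const std::vector<unsigned int>& idx) {
  const unsigned int k = idx.size();
  if (k < 2) return 0.0;
  mat A(k - 1, X.n_cols);
  for (unsigned int i = 1; i < k; ++i)
    A.row(i - 1) = X.row(idx[i]) - X.row(idx[0]);
  double g = det(A * A.t());
  if (g < 0) g = 0;
  double fact = 1.0;
  for (unsigned int j = 2; j <= k - 1; ++j) fact *= j;
  return std::sqrt(g) / fact;
}

// Greedy successive volume maximization from a given start, then
// single-vertex swap hill-climbing. Ties go to the lowest point index
// (index_max returns the first maximum).
std::vector<unsigned int> greedy_swap_fit(const mat& X, unsigned int k,
                                          unsigned int start, double eps) {
  const unsigned int n = X.n_rows;
  std::vector<unsigned int> chosen;
  chosen.push_back(start);
  mat Q(X.n_cols, 0);
  for (unsigned int j = 1; j < k; ++j) {
    vec h = point_heights(X, chosen, Q);
    for (unsigned int c0 : chosen) h(c0) = -1.0;
    unsigned int best = h.index_max();
    if (h(best) <= eps) return chosen;  // degenerate: all remaining points in span
    chosen.push_back(best);
    mat D = X.each_row() - X.row(chosen[0]);
    rowvec rb = D.row(best);
    vec res = rb.t() - Q * (Q.t() * rb.t());
    Q.insert_cols(Q.n_cols, res / norm(res));
  }

  for (int sweep = 0; sweep < 100; ++sweep) {
    bool improved = false;
    for (unsigned int i = 0; i < k; ++i) {
      std::vector<unsigned int> base;
      for (unsigned int j = 0; j < k; ++j)
        if (j != i) base.push_back(chosen[j]);
      mat Qb = affine_basis(X, base);
      vec h = point_heights(X, base, Qb);
      for (unsigned int b : base) h(b) = -1.0;
      double cur = h(chosen[i]);
      unsigned int best = h.index_max();
      if (h(best) > cur + eps && best != chosen[i]) {
        chosen[i] = best;
        improved = true;
      }
    }
    if (!improved) break;
  }
  std::sort(chosen.begin(), chosen.end());
  return chosen;
}

std::vector<unsigned int> max_volume_simplex_impl(const mat& X, unsigned int k,
                                                  unsigned int n_restarts,
                                                  double* vol_out) {
  const unsigned int n = X.n_rows;
  double scale = abs(X).max();
  if (scale <= 0) scale = 1.0;
  const double eps = 1e-12 * scale;

  std::vector<unsigned int> best;
  double best_vol = -1.0;
  for (unsigned int r = 0; r < n_restarts; ++r) {
    unsigned int start = (unsigned int)(unif_rand() * n);
    if (start >= n) start = n - 1;
    std::vector<unsigned int> cand = greedy_swap_fit(X, k, start, eps);
    if (cand.size() < k) { if (best_vol < 0) { best = cand; best_vol = 0; } continue; }
    double v = subset_volume(X, cand);
    double rel = (best_vol > 0) ? (v - best_vol) / best_vol : (v - best_vol);
    if (rel > 1e-12 || best_vol < 0) {
      best = cand; best_vol = v;
    } else if (std::abs(rel) <= 1e-12 && cand < best) {
      best = cand;  // deterministic tie-break on the sorted index set
    }
  }
  if (vol_out) *vol_out = (best_vol < 0) ? 0.0 : best_vol;
  return best;
}

}  // namespace

//' @useDynLib paretoscope, .registration = TRUE
//' @importFrom Rcpp evalCpp

// [[Rcpp::export(name = ".hull_volume_cpp")]]
double hull_volume_cpp(const arma::mat& X) {
  return hull_volume_impl(X);
}

// [[Rcpp::export(name = ".max_volume_simplex_cpp")]]
Rcpp::List max_volume_simplex_cpp(const arma::mat& X, int k, int n_restarts) {
  if (k < 2) Rcpp::stop("k must be at least 2");
  if ((unsigned int)k > X.n_rows) Rcpp::stop("k exceeds the number of points");
  double vol = 0.0;
  std::vector<unsigned int> idx =
      max_volume_simplex_impl(X, (unsigned int)k, (unsigned int)std::max(1, n_restarts), &vol);
  Rcpp::IntegerVector out(idx.size());
  for (unsigned int i = 0; i < idx.size(); ++i) out[i] = idx[i] + 1;
  return Rcpp::List::create(Rcpp::Named("indices") = out,
                            Rcpp::Named("volume") = vol);
}

// Column-wise permutation t-ratio null: each replicate independently shuffles
// every coordinate column, refits the maximum-volume simplex with the same
// settings and divides its volume by the hull volume of the shuffled cloud.
// [[Rcpp::export(name = ".t_ratio_null_cpp")]]
Rcpp::List t_ratio_null_cpp(const arma::mat& X, int k, int n_rand, int n_restarts) {
  const unsigned int n = X.n_rows, d = X.n_cols;
  if ((unsigned int)(k - 1) != d)
    Rcpp::stop("points must live in k-1 dimensions for the t-ratio");
  vec tnull(n_rand);
  int n_degenerate = 0;
  mat Xp(n, d);
  for (int r = 0; r < n_rand; ++r) {
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
    bool ok = false;
    for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
      Xp = X;
      for (unsigned int col = 0; col < d; ++col) {
        for (unsigned int i = n - 1; i > 0; --i) {
          unsigned int j = (unsigned int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(Xp(i, col), Xp(j, col));
        }
      }
      double vol = 0.0;
      std::vector<unsigned int> idx =
          max_volume_simplex_impl(Xp, (unsigned int)k, (unsigned int)n_restarts, &vol);
      if (idx.size() < (unsigned int)k) { ++n_degenerate; continue; }
      double hull;
      try {
        hull = hull_volume_impl(Xp);
      } catch (...) {
        ++n_degenerate;
        continue;
      }
      if (hull <= 0) { ++n_degenerate; continue; }
      tnull(r) = vol / hull;
      ok = true;
    }
    if (!ok) Rcpp::stop("could not obtain a non-degenerate randomization replicate");
  }
  return Rcpp::List::create(Rcpp::Named("t_null") = tnull,
                            Rcpp::Named("n_degenerate") = n_degenerate);
}
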