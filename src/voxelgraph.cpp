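// Core numerical kernels: connected-component labeling of suprathreshold
// voxels on a 3-D grid, and the group-label permutation null for clusterwise
// correction. The permutation refit uses the Frisch-Waugh-Lovell identity:
// residualizing Y once on the nuisance design Z, and each permuted group
// vector on Z, reproduces the exact OLS t-statistic of the full model.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

// Build neighbour offsets for 6- or 26-connectivity.
std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  if (connectivity == 6) {
    off = {{{1, 0, 0}}, {{-1, 0, 0}}, {{0, 1, 0}},
           {{0, -1, 0}}, {{0, 0, 1}}, {{0, 0, -1}}};
  } else {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          if (dx || dy || dz) off.push_back({{dx, dy, dz}});
  }
  return off;
}

struct Grid {
  int nx, ny, nz;
  std::vector<int> lookup;  // linear grid index -> voxel row (or -1)
  Grid(const IntegerMatrix& coords, const IntegerVector& dims)
      : nx(dims[0]), ny(dims[1]), nz(dims[2]),
        lookup(static_cast<size_t>(nx) * ny * nz, -1) {
    for (int v = 0; v < coords.nrow(); ++v) {
      int x = coords(v, 0) - 1, y = coords(v, 1) - 1, z = coords(v, 2) - 1;
      if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
        stop("voxel coordinate outside grid");
      lookup[x + static_cast<size_t>(nx) * (y + static_cast<size_t>(ny) * z)] = v;
    }
  }
  int at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return -1;
    return lookup[x + static_cast<size_t>(nx) * (y + static_cast<size_t>(ny) * z)];
  }
};

// Precompute per-voxel neighbour lists restricted to in-mask voxels.
std::vector<std::vector<int>> neighbour_lists(const IntegerMatrix& coords,
                                              const Grid& grid,
                                              int connectivity) {
  auto off = neighbour_offsets(connectivity);
  int V = coords.nrow();
  std::vector<std::vector<int>> nb(V);
  for (int v = 0; v < V; ++v) {
    int x = coords(v, 0) - 1, y = coords(v, 1) - 1, z = coords(v, 2) - 1;
    for (auto& o : off) {
      int w = grid.at(x + o[0], y + o[1], z + o[2]);
      if (w >= 0) nb[v].push_back(w);
    }
  }
  return nb;
}

// Label connected components among voxels with sign[v] != 0, where
// neighbouring voxels join only if they share the same sign. Returns number
// of components; labels[v] in 1..K (0 = background). Also records extents.
int label_sign_components(const std::vector<signed char>& sign,
                          const std::vector<std::vector<int>>& nb,
                          std::vector<int>& labels,
                          std::vector<int>& extents) {
  int V = static_cast<int>(sign.size());
  std::fill(labels.begin(), labels.end(), 0);
  extents.clear();
  int K = 0;
  std::vector<int> stack;
  for (int v = 0; v < V; ++v) {
    if (sign[v] == 0 || labels[v] != 0) continue;
    ++K;
    int size = 0;
    stack.push_back(v);
    labels[v] = K;
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      ++size;
      for (int w : nb[u]) {
        if (sign[w] == sign[u] && labels[w] == 0) {
          labels[w] = K;
          stack.push_back(w);
        }
      }
    }
    extents.push_back(size);
  }
  return K;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerMatrix coords, IntegerVector dims,
                                   IntegerVector sign, int connectivity) {
  if (sign.size() != coords.nrow()) stop("sign length must match voxel count");
  Grid grid(coords, dims);
  auto nb = neighbour_lists(coords, grid, connectivity);
  int V = coords.nrow();
  std::vector<signed char> s(V);
  for (int v = 0; v < V; ++v) {
    int sv = sign[v];
    s[v] = sv > 0 ? 1 : (sv < 0 ? -1 : 0);
  }
  std::vector<int> labels(V), extents;
  label_sign_components(s, nb, labels, extents);
  return wrap(labels);
}

// Permutation null distribution of the maximum suprathreshold cluster
// extent. Y: n x V data (subjects x voxels); Z: n x k nuisance design
// (intercept + covariates); g: group indicator. Each iteration permutes g
// across subjects (covariates stay attached), recomputes the exact OLS
// t-map for the group coefficient and records the largest cluster extent
// among voxels with |t| > t_thresh (sign-separated when two_sided).
// Uses R's RNG, so results are reproducible under set.seed().
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_perm_null(const arma::mat& Y, const arma::mat& Z,
                            const arma::vec& g, IntegerMatrix coords,
                            IntegerVector dims, double t_thresh,
                            bool two_sided, int connectivity, int n_iter) {
  const int n = static_cast<int>(Y.n_rows);
  const int V = static_cast<int>(Y.n_cols);
  if (static_cast<int>(Z.n_rows) != n || static_cast<int>(g.n_elem) != n)
    stop("design dimensions do not match data");
  if (coords.nrow() != V) stop("voxel coordinates do not match data columns");
  const int k = static_cast<int>(Z.n_cols);
  const int df = n - k - 1;
  if (df < 1) stop("non-positive residual degrees of freedom");

  Grid grid(coords, dims);
  auto nb = neighbour_lists(coords, grid, connectivity);

  // Residualize Y on Z once (FWL); P = Z (Z'Z)^-1.
  arma::mat ZtZ = Z.t() * Z;
  arma::mat P = Z * arma::solve(ZtZ, arma::eye<arma::mat>(k, k),
                                arma::solve_opts::likely_sympd);
  arma::mat Yres = Y - P * (Z.t() * Y);
  arma::rowvec yss = arma::sum(arma::square(Yres), 0);

  IntegerVector out(n_iter);
  arma::vec gp = g;
  std::vector<signed char> sign(V);
  std::vector<int> labels(V), extents;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // Fisher-Yates shuffle driven by R's RNG.
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(gp[i], gp[j]);
    }
    arma::vec gres = gp - P * (Z.t() * gp);
    double gg = arma::dot(gres, gres);
    if (gg < 1e-12) {  // degenerate permutation (constant group column)
      out[it] = 0;
      continue;
    }
    arma::rowvec b = (gres.t() * Yres) / gg;
    int max_ext = 0;
    for (int v = 0; v < V; ++v) {
      double rss = yss[v] - b[v] * b[v] * gg;
      if (rss < 1e-300) rss = 1e-300;
      double t = b[v] * std::sqrt(gg * df / rss);
      sign[v] = t > t_thresh ? 1 : (two_sided && t < -t_thresh ? -1 : 0);
    }
    label_sign_components(sign, nb, labels, extents);
    for (int e : extents)
      if (e > max_ext) max_ext = e;
    out[it] = max_ext;
  }
  return out;
}
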