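#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Optimal assignment for a dense square cost matrix by shortest augmenting
// paths with dual potentials (Jonker-Volgenant style, O(n^3)).
// Returns, for every row, the 1-based column it is assigned to.
// [[Rcpp::export]]
IntegerVector cpp_lap_solve(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return IntegerVector(0);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j;
  return ans;
}

static inline void neighbour_offsets(const IntegerVector &dim, int connectivity,
                                     std::vector<int> &offs,
                                     std::vector<std::array<int, 3>> &steps) {
  const int d1 = dim[0], d2 = dim[1];
  offs.clear(); steps.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        offs.push_back(dx + dy * d1 + dz * d1 * d2); // dims (d1=y?, arbitrary)
        steps.push_back({dx, dy, dz});
      }
}

// Connected-component labelling of a 3D logical array (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity = 6) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<int> offs;
  std::vector<std::array<int, 3>> steps;
  neighbour_offsets(dim, connectivity, offs, steps);
  int next = 0;
  std::vector<int> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.clear(); q.push_back((int)s);
    while (!q.empty()) {
      int cur = q.back(); q.pop_back();
      int i1 = cur % d1, rest = cur / d1, i2 = rest % d2, i3 = rest / d2;
      for (size_t k = 0; k < offs.size(); ++k) {
        int a = i1 + steps[k][0], b = i2 + steps[k][1], c = i3 + steps[k][2];
        if (a < 0 || a >= d1 || b < 0 || b >= d2 || c < 0 || c >= d3) continue;
        int nb = cur + offs[k];
        if (mask[nb] && !lab[nb]) { lab[nb] = next; q.push_back(nb); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

struct PQItem {
  double value;
  unsigned long order;
  int idx;
  int label;
};
struct PQCmp {
  bool operator()(const PQItem &a, const PQItem &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.order > b.order; // FIFO on ties -> deterministic
  }
};

// Seeded watershed by priority flooding: every voxel of `mask` is assigned to
// the seed basin that reaches it first along ascending `intensity` (membrane
// signal ridges become basin boundaries). 6-connectivity, deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector intensity, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (intensity.size() != n || seeds.size() != n || mask.size() != n)
    stop("array lengths do not match dim");
  IntegerVector lab(n, 0);
  std::vector<int> offs;
  std::vector<std::array<int, 3>> steps;
  neighbour_offsets(dim, 6, offs, steps);
  std::priority_queue<PQItem, std::vector<PQItem>, PQCmp> pq;
  unsigned long order = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seeds[s] > 0 && mask[s]) {
      lab[s] = seeds[s];
      pq.push({intensity[s], order++, (int)s, seeds[s]});
    }
  }
  while (!pq.empty()) {
    PQItem it = pq.top(); pq.pop();
    int cur = it.idx;
    int i1 = cur % d1, rest = cur / d1, i2 = rest % d2, i3 = rest / d2;
    for (size_t k = 0; k < offs.size(); ++k) {
      int a = i1 + steps[k][0], b = i2 + steps[k][1], c = i3 + steps[k][2];
      if (a < 0 || a >= d1 || b < 0 || b >= d2 || c < 0 || c >= d3) continue;
      int nb = cur + offs[k];
      if (!mask[nb] || lab[nb]) continue;
      lab[nb] = it.label;
      pq.push({intensity[nb], order++, nb, it.label});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
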