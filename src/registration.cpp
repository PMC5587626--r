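// Accelerated engine for the registration analysis inner loop.
//
// For every candidate mapping cell (i, j) of input peak i onto root peak j,
// the support set SS_{i,j} holds all pairs (m, n) whose difference vector
// d_mn = x_m - y_n agrees with d_ij within tolerance_units * std per
// comparable dimension. The best cell maximizes
//   robustness(i,j) = sum_{(m,n) in SS_{i,j}} Jaccard(SS_{i,j}, SS_{m,n}) *
//                     P(chisq_df > stat(i,j,m,n))
// Because each probability term is <= 1 and each Jaccard <= 1, the sum of
// member probabilities is an upper bound on the robustness, so cells are
// screened by that bound (computed during a cheap first pass over a spatial
// hash of the difference vectors) and exact robustness is only evaluated for
// cells whose bound can still beat the current best. The result is exact.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Grid {
  std::unordered_map<uint64_t, std::vector<int>> buckets;
  const NumericMatrix &D;
  std::vector<double> tol;
  int k;

  Grid(const NumericMatrix &D_, const std::vector<double> &tol_)
      : D(D_), tol(tol_), k(D_.ncol()) {
    for (int p = 0; p < D.nrow(); ++p) {
      buckets[key_of(p)].push_back(p);
    }
  }

  uint64_t mix(uint64_t h, int64_t c) const {
    h ^= (uint64_t)(c + 0x9e3779b97f4a7c15ULL) + (h << 6) + (h >> 2);
    return h;
  }

  uint64_t key_of(int p) const {
    uint64_t h = 1469598103934665603ULL;
    for (int l = 0; l < k; ++l) {
      int64_t c = (int64_t)std::floor(D(p, l) / tol[l]);
      h = mix(h, c);
    }
    return h;
  }

  // all points within the per-dimension box |D[p] - centre| <= tol
  void query(const double *centre, std::vector<int> &out) const {
    out.clear();
    int64_t base[4];
    for (int l = 0; l < k; ++l) {
      base[l] = (int64_t)std::floor(centre[l] / tol[l]);
    }
    int span = 1;
    for (int l = 0; l < k; ++l) span *= 3;
    for (int s = 0; s < span; ++s) {
      uint64_t h = 1469598103934665603ULL;
      int t = s;
      for (int l = 0; l < k; ++l) {
        int off = (t % 3) - 1;
        t /= 3;
        h = mix(h, base[l] + off);
      }
      auto it = buckets.find(h);
      if (it == buckets.end()) continue;
      for (int p : it->second) {
        bool ok = true;
        for (int l = 0; l < k; ++l) {
          if (std::fabs(centre[l] - D(p, l)) > tol[l]) { ok = false; break; }
        }
        if (ok) out.push_back(p);
      }
    }
  }
};

// support set of cell c (encoded pair index), as sorted encoded members
void support_of(const Grid &grid, const NumericMatrix &D, int cell,
                bool self, int n_root, std::vector<int> &out) {
  double centre[4];
  for (int l = 0; l < grid.k; ++l) centre[l] = D(cell, l);
  grid.query(centre, out);
  int ci = cell / n_root, cj = cell % n_root;
  size_t w = 0;
  for (size_t r = 0; r < out.size(); ++r) {
    int p = out[r];
    int m = p / n_root, n = p % n_root;
    if (p == cell) continue;
    if (self && m == n) continue;
    (void)ci; (void)cj;
    out[w++] = p;
  }
  out.resize(w);
  std::sort(out.begin(), out.end());
}

// sorted copy of v with e inserted (e is never already present: a support
// set excludes its own defining pair)
std::vector<int> augment(const std::vector<int> &v, int e) {
  std::vector<int> out;
  out.reserve(v.size() + 1);
  auto it = std::lower_bound(v.begin(), v.end(), e);
  out.insert(out.end(), v.begin(), it);
  out.push_back(e);
  out.insert(out.end(), it, v.end());
  return out;
}

double jaccard(const std::vector<int> &a, const std::vector<int> &b) {
  size_t ia = 0, ib = 0, inter = 0;
  while (ia < a.size() && ib < b.size()) {
    if (a[ia] == b[ib]) { ++inter; ++ia; ++ib; }
    else if (a[ia] < b[ib]) ++ia;
    else ++ib;
  }
  size_t uni = a.size() + b.size() - inter;
  return uni == 0 ? 0.0 : (double)inter / (double)uni;
}

} // namespace

// [[Rcpp::export]]
List cpp_best_cell(NumericMatrix x, NumericMatrix y, NumericVector stds,
                   double tolerance_units, double std_factor, bool self) {
  const int n_in = x.nrow(), n_root = y.nrow(), k = x.ncol();
  if (k < 1 || k > 4) stop("1-4 comparable dimensions supported");
  if (y.ncol() != k) stop("dimension mismatch");
  for (int l = 0; l < k; ++l) {
    if (stds[l] <= 0) stop("stds must be positive");
  }
  const int n_pairs = n_in * n_root;
  List failed = List::create(_["i"] = -1, _["j"] = -1,
                             _["robustness"] = 0.0,
                             _["members_m"] = IntegerVector(0),
                             _["members_n"] = IntegerVector(0),
                             _["probs"] = NumericVector(0));
  if (n_pairs == 0) return failed;

  // difference vectors, row index p = (m-1)*n_root + (n-1) in 0-based form
  NumericMatrix D(n_pairs, k);
  for (int m = 0; m < n_in; ++m) {
    for (int n = 0; n < n_root; ++n) {
      for (int l = 0; l < k; ++l) {
        D(m * n_root + n, l) = x(m, l) - y(n, l);
      }
    }
  }
  std::vector<double> tol(k), denom(k);
  for (int l = 0; l < k; ++l) {
    tol[l] = tolerance_units * stds[l];
    denom[l] = stds[l] * std_factor;
  }
  Grid grid(D, tol);

  // pass 1: probability-sum bound per cell
  std::vector<double> sum_p(n_pairs, 0.0);
  std::vector<int> cand;
  const double df = (double)k;
  for (int cell = 0; cell < n_pairs; ++cell) {
    int i = cell / n_root, j = cell % n_root;
    if (self && i == j) { sum_p[cell] = -1.0; continue; }
    double centre[4];
    for (int l = 0; l < k; ++l) centre[l] = D(cell, l);
    grid.query(centre, cand);
    double s = 0.0;
    for (int p : cand) {
      if (p == cell) continue;
      int m = p / n_root, n = p % n_root;
      if (self && m == n) continue;
      double stat = 0.0;
      for (int l = 0; l < k; ++l) {
        double z = (centre[l] - D(p, l)) / denom[l];
        stat += z * z;
      }
      s += R::pchisq(stat, df, 0, 0);
    }
    sum_p[cell] = s;
  }

  std::vector<int> order;
  order.reserve(n_pairs);
  for (int cell = 0; cell < n_pairs; ++cell) {
    if (sum_p[cell] > 0.0) order.push_back(cell);
  }
  if (order.empty()) return failed;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (sum_p[a] != sum_p[b]) return sum_p[a] > sum_p[b];
    return a < b;
  });

  // pass 2: exact robustness, branch-and-bound on the probability-sum bound
  std::unordered_map<int, std::vector<int>> cache;
  size_t cache_budget = 20000000; // total cached ints
  size_t cache_used = 0;
  std::vector<int> scratch;
  auto get_support = [&](int cell) -> const std::vector<int> & {
    auto it = cache.find(cell);
    if (it != cache.end()) return it->second;
    support_of(grid, D, cell, self, n_root, scratch);
    if (cache_used + scratch.size() <= cache_budget) {
      cache_used += scratch.size();
      auto res = cache.emplace(cell, scratch);
      return res.first->second;
    }
    static std::vector<int> tmp;
    tmp = scratch;
    return tmp;
  };

  double best_rob = -1.0;
  int best_cell = -1;
  size_t best_size = 0;
  std::vector<int> ss_ij;
  for (int cell : order) {
    if (sum_p[cell] < best_rob) break;
    if (sum_p[cell] == best_rob && best_cell >= 0) {
      // a tie on the bound cannot strictly beat the best; it could only tie
      // exactly, which the deterministic tie-break below handles
    }
    support_of(grid, D, cell, self, n_root, ss_ij);
    double centre[4];
    for (int l = 0; l < k; ++l) centre[l] = D(cell, l);
    // the Jaccard comparison includes each set's defining mapping pair
    std::vector<int> aug_ij = augment(ss_ij, cell);
    double rob = 0.0;
    for (int p : ss_ij) {
      double stat = 0.0;
      for (int l = 0; l < k; ++l) {
        double z = (centre[l] - D(p, l)) / denom[l];
        stat += z * z;
      }
      double prob = R::pchisq(stat, df, 0, 0);
      const std::vector<int> &ss_mn = get_support(p);
      rob += jaccard(aug_ij, augment(ss_mn, p)) * prob;
    }
    bool better = rob > best_rob;
    if (!better && rob == best_rob && best_cell >= 0) {
      if (ss_ij.size() > best_size) better = true;
      else if (ss_ij.size() == best_size) {
        int bi = best_cell / n_root, bj = best_cell % n_root;
        int ci = cell / n_root, cj = cell % n_root;
        better = (ci < bi) || (ci == bi && cj < bj);
      }
    }
    if (better) {
      best_rob = rob;
      best_cell = cell;
      best_size = ss_ij.size();
    }
  }
  if (best_cell < 0 || best_rob <= 0.0) return failed;

  support_of(grid, D, best_cell, self, n_root, ss_ij);
  int bi = best_cell / n_root, bj = best_cell % n_root;
  IntegerVector mem_m(ss_ij.size()), mem_n(ss_ij.size());
  NumericVector probs(ss_ij.size());
  double centre[4];
  for (int l = 0; l < k; ++l) centre[l] = D(best_cell, l);
  for (size_t r = 0; r < ss_ij.size(); ++r) {
    int p = ss_ij[r];
    mem_m[r] = p / n_root + 1;
    mem_n[r] = p % n_root + 1;
    double stat = 0.0;
    for (int l = 0; l < k; ++l) {
      double z = (centre[l] - D(p, l)) / denom[l];
      stat += z * z;
    }
    probs[r] = R::pchisq(stat, df, 0, 0);
  }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1,
                      _["robustness"] = best_rob,
                      _["members_m"] = mem_m, _["members_n"] = mem_n,
                      _["probs"] = probs);
}
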