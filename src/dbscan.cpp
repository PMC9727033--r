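// Grid-accelerated DBSCAN on 2D points (Euclidean metric).
//
// Conventions pinned for reproducibility:
//  * a point is core if >= min_pts points INCLUDING ITSELF lie within eps;
//  * clusters are grown breadth-first from seeds scanned in input order, so
//    labels are deterministic for a given row order;
//  * border points (non-core within eps of a core) join the first core
//    cluster whose expansion reaches them;
//  * label 0 marks noise.
//
// Two exact optimisations keep dense blobs (thousands of localizations in
// one cluster) near-linear instead of quadratic:
//  * the core test counts neighbours with early exit at min_pts;
//  * expansion skips grid cells in which every point is already labelled —
//    such points can never change cluster, so rescanning them is a no-op.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export(name = ".dbscan_grid")]]
IntegerVector dbscan_grid(NumericVector x, NumericVector y, double eps,
                          int min_pts) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector label(n, 0);
  if (n == 0) return label;
  const double eps2 = eps * eps;

  // hash points into cells of side eps; neighbours live in the 3x3 block
  std::unordered_map<int64_t, int> cell_of;  // cell key -> cell index
  std::vector<int64_t> cx(n), cy(n);
  std::vector<int> cell_idx(n);
  std::vector<std::vector<int> > members;
  cell_of.reserve((size_t)n * 2);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int64_t)std::floor(x[i] / eps);
    cy[i] = (int64_t)std::floor(y[i] / eps);
    const int64_t key = (cx[i] << 32) ^ (cy[i] & 0xffffffffLL);
    auto it = cell_of.find(key);
    int ci;
    if (it == cell_of.end()) {
      ci = (int)members.size();
      cell_of.emplace(key, ci);
      members.push_back(std::vector<int>());
    } else {
      ci = it->second;
    }
    cell_idx[i] = ci;
    members[ci].push_back(i);
  }
  std::vector<int> unlabeled(members.size());
  for (size_t c = 0; c < members.size(); ++c) {
    unlabeled[c] = (int)members[c].size();
  }

  auto cell_at = [&](int64_t gx, int64_t gy) -> int {
    auto it = cell_of.find((gx << 32) ^ (gy & 0xffffffffLL));
    return it == cell_of.end() ? -1 : it->second;
  };

  std::vector<signed char> core(n, -1);  // -1 unknown, 0 no, 1 yes
  auto is_core = [&](int i) -> bool {
    if (core[i] >= 0) return core[i] == 1;
    int cnt = 0;
    for (int64_t dx = -1; dx <= 1 && cnt < min_pts; ++dx) {
      for (int64_t dy = -1; dy <= 1 && cnt < min_pts; ++dy) {
        const int c = cell_at(cx[i] + dx, cy[i] + dy);
        if (c < 0) continue;
        for (int j : members[c]) {
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= eps2 && ++cnt >= min_pts) break;
        }
      }
    }
    core[i] = cnt >= min_pts ? 1 : 0;
    return core[i] == 1;
  };

  auto claim = [&](int i, int cluster) {
    if (label[i] == 0) {
      label[i] = cluster;
      --unlabeled[cell_idx[i]];
    }
  };

  std::vector<char> enqueued(n, 0);
  std::vector<int> queue_;
  int next_cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (enqueued[i] || label[i] != 0) continue;
    enqueued[i] = 1;
    if (!is_core(i)) continue;  // noise unless a cluster claims it later
    ++next_cluster;
    claim(i, next_cluster);
    queue_.clear();
    queue_.push_back(i);
    for (size_t qi = 0; qi < queue_.size(); ++qi) {
      const int j = queue_[qi];
      if (!is_core(j)) continue;  // border point: no expansion
      for (int64_t dx = -1; dx <= 1; ++dx) {
        for (int64_t dy = -1; dy <= 1; ++dy) {
          const int c = cell_at(cx[j] + dx, cy[j] + dy);
          if (c < 0 || unlabeled[c] == 0) continue;
          for (int q : members[c]) {
            if (label[q] != 0) continue;
            const double ddx = x[j] - x[q], ddy = y[j] - y[q];
            if (ddx * ddx + ddy * ddy > eps2) continue;
            claim(q, next_cluster);
            if (!enqueued[q]) {
              enqueued[q] = 1;
              queue_.push_back(q);
            }
          }
        }
      }
    }
  }
  return label;
}
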