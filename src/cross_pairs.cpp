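#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Cell-list close-pairs query between two point sets in d = 2 or 3
// dimensions. Returns all displacements b - a with |(b - a) - center| <=
// radius (closed ball). Points of B are pre-shifted by -center so the query
// reduces to |b' - a| <= radius; the stored displacement is re-offset by
// center afterwards. Cells have side length = radius, so each query point
// only inspects its 3^d neighbouring cells.

// [[Rcpp::export]]
NumericMatrix cross_pairs_cpp(NumericMatrix A, NumericMatrix B,
                              NumericVector center, double radius) {
  const int d = A.ncol();
  const int nA = A.nrow(), nB = B.nrow();
  const double r2 = radius * radius;

  // shifted copy of B
  std::vector<double> Bs(static_cast<size_t>(nB) * d);
  for (int j = 0; j < nB; ++j)
    for (int k = 0; k < d; ++k)
      Bs[static_cast<size_t>(j) * d + k] = B(j, k) - center[k];

  // integer cell coordinates of B points
  std::vector<long long> cell(static_cast<size_t>(nB) * d);
  long long cmin[3] = {0, 0, 0}, cmax[3] = {0, 0, 0};
  for (int j = 0; j < nB; ++j) {
    for (int k = 0; k < d; ++k) {
      long long c = static_cast<long long>(std::floor(
          Bs[static_cast<size_t>(j) * d + k] / radius));
      cell[static_cast<size_t>(j) * d + k] = c;
      if (j == 0 || c < cmin[k]) cmin[k] = c;
      if (j == 0 || c > cmax[k]) cmax[k] = c;
    }
  }
  long long span[3] = {1, 1, 1};
  for (int k = 0; k < d; ++k) span[k] = cmax[k] - cmin[k] + 3; // +1 halo

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(static_cast<size_t>(nB));
  for (int j = 0; j < nB; ++j) {
    long long key = 0;
    for (int k = d - 1; k >= 0; --k)
      key = key * span[k] + (cell[static_cast<size_t>(j) * d + k] - cmin[k] + 1);
    grid[key].push_back(j);
  }

  std::vector<double> out;
  long long cc[3];
  for (int i = 0; i < nA; ++i) {
    bool inRange = true;
    for (int k = 0; k < d; ++k) {
      cc[k] = static_cast<long long>(std::floor(A(i, k) / radius));
      // outside the halo of B's occupied cells: no neighbours possible
      if (cc[k] < cmin[k] - 1 || cc[k] > cmax[k] + 1) { inRange = false; break; }
    }
    if (!inRange) continue;
    const long long lo2 = (d == 3) ? -1 : 0, hi2 = (d == 3) ? 1 : 0;
    for (long long dx = -1; dx <= 1; ++dx) {
      long long cx = cc[0] + dx;
      if (cx < cmin[0] - 1 || cx > cmax[0] + 1) continue;
      for (long long dy = -1; dy <= 1; ++dy) {
        long long cy = cc[1] + dy;
        if (cy < cmin[1] - 1 || cy > cmax[1] + 1) continue;
        for (long long dz = lo2; dz <= hi2; ++dz) {
          long long key;
          if (d == 3) {
            long long cz = cc[2] + dz;
            if (cz < cmin[2] - 1 || cz > cmax[2] + 1) continue;
            key = ((cz - cmin[2] + 1) * span[1] + (cy - cmin[1] + 1)) * span[0] +
                  (cx - cmin[0] + 1);
          } else {
            key = (cy - cmin[1] + 1) * span[0] + (cx - cmin[0] + 1);
          }
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              grid.find(key);
          if (it == grid.end()) continue;
          const std::vector<int>& idx = it->second;
          for (size_t m = 0; m < idx.size(); ++m) {
            const int j = idx[m];
            double dist2 = 0.0, v[3];
            for (int k = 0; k < d; ++k) {
              v[k] = Bs[static_cast<size_t>(j) * d + k] - A(i, k);
              dist2 += v[k] * v[k];
            }
            if (dist2 <= r2) {
              for (int k = 0; k < d; ++k) out.push_back(v[k] + center[k]);
            }
          }
        }
      }
    }
  }

  const int n = static_cast<int>(out.size()) / d;
  NumericMatrix res(n, d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k)
      res(i, k) = out[static_cast<size_t>(i) * d + k];
  return res;
}
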