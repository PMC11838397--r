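#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact fixed-radius neighbor pairs via a cell list (grid hashing).
// Points are binned into axis-aligned cells of side r; all true neighbor
// pairs at distance < r lie in the same or an adjacent cell, so scanning
// the 3^D neighborhood of each point's cell is exhaustive. Returns the
// ordered pairs (i, j), i < j, with strict dist(i, j) < r, 1-based.
//
// Time is O(M * occupancy of the 3^D surrounding cells); for density-
// rescaled coordinates (about one spot per unit volume) and r in [1, 3]
// that is O(M) with a modest constant.

static inline int64_t cell_key(const std::vector<int64_t>& c, int D) {
  // pack up to 3 cell indices (each offset to be >= 0 beforehand) into one key
  int64_t key = 0;
  for (int d = 0; d < D; ++d) key = key * 2097152LL + c[d]; // 2^21 per axis
  return key;
}

// [[Rcpp::export(name = ".radius_pairs")]]
List radius_pairs(NumericMatrix coords, double r) {
  const int M = coords.nrow();
  const int D = coords.ncol();
  if (r <= 0) stop("radius must be positive");
  if (D < 1 || D > 3) stop("only 1-3 dimensions supported");

  std::vector<double> mins(D);
  for (int d = 0; d < D; ++d) {
    double mn = coords(0, d);
    for (int i = 1; i < M; ++i) mn = std::min(mn, coords(i, d));
    mins[d] = mn;
  }

  // cell index per point, offset so all indices are >= 1
  std::vector<int64_t> cell(static_cast<size_t>(M) * D);
  for (int i = 0; i < M; ++i)
    for (int d = 0; d < D; ++d)
      cell[static_cast<size_t>(i) * D + d] =
        static_cast<int64_t>(std::floor((coords(i, d) - mins[d]) / r)) + 1;

  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(static_cast<size_t>(M));
  {
    std::vector<int64_t> c(D);
    for (int i = 0; i < M; ++i) {
      for (int d = 0; d < D; ++d) c[d] = cell[static_cast<size_t>(i) * D + d];
      grid[cell_key(c, D)].push_back(i);
    }
  }

  const double r2 = r * r;
  std::vector<int> out_i, out_j;
  out_i.reserve(static_cast<size_t>(M) * 4);
  out_j.reserve(static_cast<size_t>(M) * 4);

  std::vector<int64_t> nb(D);
  const int span = (D == 1) ? 3 : (D == 2 ? 9 : 27);
  for (int i = 0; i < M; ++i) {
    for (int o = 0; o < span; ++o) {
      int rem = o;
      for (int d = 0; d < D; ++d) {
        nb[d] = cell[static_cast<size_t>(i) * D + d] + (rem % 3) - 1;
        rem /= 3;
      }
      auto it = grid.find(cell_key(nb, D));
      if (it == grid.end()) continue;
      for (int j : it->second) {
        if (j <= i) continue;
        double d2 = 0.0;
        for (int d = 0; d < D; ++d) {
          double diff = coords(i, d) - coords(j, d);
          d2 += diff * diff;
        }
        if (d2 < r2) {
          out_i.push_back(i + 1);
          out_j.push_back(j + 1);
        }
      }
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j));
}
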