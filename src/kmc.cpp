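#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Move classes (kept in sync with move_classes on the R side):
// 0 unit_free, 1 unit_penalized, 2 unit_exchange, 3 obstacle_free,
// 4 reflect_out_of_bounds, 5 reflect_occupied
enum MoveClass {
  UNIT_FREE = 0, UNIT_PENALIZED = 1, UNIT_EXCHANGE = 2,
  OBSTACLE_FREE = 3, REFLECT_OOB = 4, REFLECT_OCC = 5
};

static const int DX[4] = {1, -1, 0, 0};
static const int DY[4] = {0, 0, 1, -1};

// Number of protein units among the 4 von Neumann neighbours of (x, y),
// optionally ignoring the cell (ex, ey) (the mover's own origin square).
static inline int contacts_at(const IntegerMatrix& g, int x, int y,
                              int W, int H, int ex, int ey) {
  int c = 0;
  for (int d = 0; d < 4; ++d) {
    int nx = x + DX[d], ny = y + DY[d];
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
    if (nx == ex && ny == ey) continue;
    if (g(nx, ny) == 1) ++c;
  }
  return c;
}

// Rejection kinetic Monte Carlo inner loop.
//
// occ:  W x H occupancy (0 empty, 1 protein unit, 2 obstacle), 0-based (x, y)
// px, py: per-molecule 0-based coordinates; kind: 1 unit, 2 obstacle.
//
// Per step the random-number discipline is fixed: one uniform for the
// target molecule, one for the direction, and one for the acceptance
// threshold r only when the move class carries a rate (free, penalized or
// obstacle moves). Exchange and reflection classes consume no r draw and
// deterministically leave the target in place. Uses R's RNG stream, so a
// set.seed() on the R side makes whole trajectories reproducible and a run
// of n steps is draw-for-draw identical to n single steps taken in R.
// [[Rcpp::export]]
List kmc_run_cpp(const IntegerMatrix& occ,
                 const IntegerVector& px, const IntegerVector& py,
                 const IntegerVector& kind,
                 double k1, double k5, double A, double dE_over_theta,
                 double n_steps) {
  IntegerMatrix g = clone(occ);
  IntegerVector x = clone(px), y = clone(py);
  const int W = g.nrow(), H = g.ncol(), N = x.size();
  const R_xlen_t steps = (R_xlen_t) n_steps;
  NumericVector proposed(6), accepted(6);

  for (R_xlen_t s = 0; s < steps; ++s) {
    int i = (int)(unif_rand() * N); if (i >= N) i = N - 1;
    int d = (int)(unif_rand() * 4); if (d > 3) d = 3;
    const int ox = x[i], oy = y[i];
    const int nx = ox + DX[d], ny = oy + DY[d];

    int cls;
    double k = 0.0;
    bool needs_r = false;
    if (nx < 0 || nx >= W || ny < 0 || ny >= H) {
      cls = REFLECT_OOB;
    } else {
      const int dest = g(nx, ny);
      if (dest == 0) {
        if (kind[i] == 2) {
          cls = OBSTACLE_FREE; k = k5; needs_r = true;
        } else {
          const int c_orig = contacts_at(g, ox, oy, W, H, -1, -1);
          const int c_dest = contacts_at(g, nx, ny, W, H, ox, oy);
          int n_lost = c_orig - c_dest;
          if (n_lost < 0) n_lost = 0;
          if (n_lost == 0) {
            cls = UNIT_FREE; k = k1;
          } else {
            cls = UNIT_PENALIZED; k = A * std::exp(-n_lost * dE_over_theta);
          }
          needs_r = true;
        }
      } else if (kind[i] == 1 && dest == 1) {
        cls = UNIT_EXCHANGE;
      } else {
        cls = REFLECT_OCC;
      }
    }

    proposed[cls] += 1.0;
    if (needs_r) {
      const double r = unif_rand();
      if (k > r) {
        accepted[cls] += 1.0;
        g(nx, ny) = kind[i];
        g(ox, oy) = 0;
        x[i] = nx; y[i] = ny;
      }
    }
  }

  return List::create(_["occ"] = g, _["x"] = x, _["y"] = y,
                      _["proposed"] = proposed, _["accepted"] = accepted);
}

// 4-connected component labelling of protein-unit squares (occ == 1).
// Obstacles and empty squares stay 0. Iterative flood fill, labels 1..n.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const IntegerMatrix& occ) {
  const int W = occ.nrow(), H = occ.ncol();
  IntegerMatrix lab(W, H);
  int next = 0;
  std::vector<int> stack;
  for (int y0 = 0; y0 < H; ++y0) {
    for (int x0 = 0; x0 < W; ++x0) {
      if (occ(x0, y0) != 1 || lab(x0, y0) != 0) continue;
      ++next;
      stack.push_back(x0 + y0 * W);
      lab(x0, y0) = next;
      while (!stack.empty()) {
        const int cur = stack.back(); stack.pop_back();
        const int cx = cur % W, cy = cur / W;
        for (int d = 0; d < 4; ++d) {
          const int nx = cx + DX[d], ny = cy + DY[d];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (occ(nx, ny) == 1 && lab(nx, ny) == 0) {
            lab(nx, ny) = next;
            stack.push_back(nx + ny * W);
          }
        }
      }
    }
  }
  return lab;
}
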