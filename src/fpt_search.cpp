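// Branch-and-bound core of the exact bi-cluster editing solver.
// The graph lives in two matrices (shifted weights, pair marks); rows are
// side-A vertices and columns side-B vertices, both in lexicographic
// order. The global lexicographic vertex order interleaving the two sides
// is passed in, so the canonical (lexicographically smallest) P4 is
// resolved first, exactly as in the R-level find_p4(), and search traces
// are reproducible.

#include <Rcpp.h>
#include <ctime>
#include <vector>
using namespace Rcpp;

namespace {

const int FREE = 0, PERMANENT = 1, FORBIDDEN = 2;

struct Edit {
  int op;   // 0 = insert, 1 = delete
  int i, j; // 0-based row / column
  double cost;
};

struct Search {
  NumericMatrix w;
  IntegerMatrix marks;
  int na, nb;
  double eps;
  double best_cost;
  bool found;
  double nodes, node_cap;
  double time_limit;
  std::clock_t t0;
  bool aborted;
  std::vector<Edit> stack, best;
  IntegerVector ord_side, ord_idx;

  bool edge(int i, int j) const {
    int m = marks(i, j);
    return m == PERMANENT || (m == FREE && w(i, j) > eps);
  }

  // Canonical first P4. On success fills the four branch pairs (row, col)
  // in the fixed branch order: insert ux, delete uv, delete wv, delete wx.
  bool find_p4(int pr[4], int pc[4]) {
    int n = ord_side.size();
    for (int t = 0; t < n; ++t) {
      if (ord_side[t] == 0) {
        // endpoint u on side A (a row); path u - v(col) - w(row) - x(col)
        int u = ord_idx[t];
        for (int v = 0; v < nb; ++v) {
          if (!edge(u, v)) continue;
          for (int ww = 0; ww < na; ++ww) {
            if (ww == u || !edge(ww, v)) continue;
            for (int x = 0; x < nb; ++x) {
              if (edge(ww, x) && !edge(u, x)) {
                pr[0] = u;  pc[0] = x; // insert ux
                pr[1] = u;  pc[1] = v; // delete uv
                pr[2] = ww; pc[2] = v; // delete wv
                pr[3] = ww; pc[3] = x; // delete wx
                return true;
              }
            }
          }
        }
      } else {
        // endpoint u on side B (a column); path u - v(row) - w(col) - x(row)
        int u = ord_idx[t];
        for (int v = 0; v < na; ++v) {
          if (!edge(v, u)) continue;
          for (int ww = 0; ww < nb; ++ww) {
            if (ww == u || !edge(v, ww)) continue;
            for (int x = 0; x < na; ++x) {
              if (edge(x, ww) && !edge(x, u)) {
                pr[0] = x; pc[0] = u;  // insert ux
                pr[1] = v; pc[1] = u;  // delete uv
                pr[2] = v; pc[2] = ww; // delete wv
                pr[3] = x; pc[3] = ww; // delete wx
                return true;
              }
            }
          }
        }
      }
    }
    return false;
  }

  void rec(double spent) {
    nodes += 1;
    if (nodes > node_cap) { aborted = true; return; }
    if (time_limit < 1e300 && ((long long)nodes & 1023LL) == 0 &&
        double(std::clock() - t0) / CLOCKS_PER_SEC > time_limit) {
      aborted = true;
      return;
    }
    int pr[4], pc[4];
    if (!find_p4(pr, pc)) {
      if (spent < best_cost - eps) {
        best_cost = spent;
        best = stack;
        found = true;
      }
      return;
    }
    for (int b = 0; b < 4; ++b) {
      if (aborted) return;
      int i = pr[b], j = pc[b];
      if (marks(i, j) != FREE) continue; // pair already locked
      int op = b == 0 ? 0 : 1;
      double cost = op == 0 ? std::max(0.0, -w(i, j))
                            : std::max(0.0, w(i, j));
      if (spent + cost > best_cost - eps) continue; // budget exceeded
      marks(i, j) = op == 0 ? PERMANENT : FORBIDDEN;
      Edit e; e.op = op; e.i = i; e.j = j; e.cost = cost;
      stack.push_back(e);
      rec(spent + cost);
      stack.pop_back();
      marks(i, j) = FREE;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List fpt_search_cpp(NumericMatrix w, IntegerMatrix marks, double eps,
                    double bound, bool accept_equal, double node_cap,
                    double time_limit, IntegerVector ord_side,
                    IntegerVector ord_idx) {
  Search s;
  s.w = w;
  s.marks = clone(marks);
  s.na = w.nrow();
  s.nb = w.ncol();
  s.eps = eps;
  s.best_cost = accept_equal ? bound + 2 * eps : bound;
  s.found = false;
  s.nodes = 0;
  s.node_cap = node_cap;
  s.time_limit = time_limit;
  s.t0 = std::clock();
  s.aborted = false;
  s.ord_side = ord_side;
  s.ord_idx = ord_idx;
  s.rec(0.0);
  int ne = s.best.size();
  IntegerVector eop(ne), ei(ne), ej(ne);
  NumericVector ecost(ne);
  for (int k = 0; k < ne; ++k) {
    eop[k] = s.best[k].op;
    ei[k] = s.best[k].i + 1;
    ej[k] = s.best[k].j + 1;
    ecost[k] = s.best[k].cost;
  }
  return List::create(_["found"] = s.found, _["op"] = eop, _["i"] = ei,
                      _["j"] = ej, _["cost"] = ecost,
                      _["best_cost"] = s.best_cost, _["nodes"] = s.nodes,
                      _["aborted"] = s.aborted);
}
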