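#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <queue>
#include <vector>

using namespace Rcpp;

// Pivot scoring: rank points by squared Euclidean distance from the pivot
// (ties broken by input index via stable sort), accumulate prefix one-counts
// and minimise the hypergeometric tail looked up in `tails`, a precomputed
// (N+1) x (B+1) matrix with row n = prefix length, column b = prefix ones.

struct ScoreOut {
  double score;
  int n;  // optimal prefix length, 1-based; smallest n attaining the minimum
  int b;  // ones within that prefix
  double radius;
};

static ScoreOut score_one(const double *p, const NumericMatrix &X,
                          const IntegerVector &y, const NumericMatrix &tails,
                          std::vector<int> &idx, std::vector<double> &d2,
                          std::vector<int> *cumb_out) {
  const int N = X.nrow(), d = X.ncol();
  for (int i = 0; i < N; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      const double t = p[j] - X(i, j);
      s += t * t;
    }
    d2[i] = s;
    idx[i] = i;
  }
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return d2[a] < d2[b]; });
  double best = 2.0;
  int bn = 1, bb = 0, b = 0;
  for (int n = 1; n <= N; ++n) {
    b += y[idx[n - 1]];
    if (cumb_out) (*cumb_out)[n - 1] = b;
    const double t = tails(n, b);
    if (t < best) {
      best = t;
      bn = n;
      bb = b;
    }
  }
  return ScoreOut{best, bn, bb, std::sqrt(d2[idx[bn - 1]])};
}

// [[Rcpp::export]]
NumericMatrix score_pivots_cpp(const NumericMatrix &X, const IntegerVector &y,
                               const NumericMatrix &P,
                               const NumericMatrix &tails) {
  const int N = X.nrow(), d = X.ncol(), np = P.nrow();
  if (P.ncol() != d) stop("pivot dimension does not match cloud dimension");
  if (y.size() != N) stop("label length does not match coordinate count");
  NumericMatrix out(np, 4);
  std::vector<int> idx(N);
  std::vector<double> d2(N), p(d);
  for (int r = 0; r < np; ++r) {
    for (int j = 0; j < d; ++j) p[j] = P(r, j);
    const ScoreOut s = score_one(p.data(), X, y, tails, idx, d2, nullptr);
    out(r, 0) = s.score;
    out(r, 1) = s.n;
    out(r, 2) = s.b;
    out(r, 3) = s.radius;
  }
  return out;
}

// Gaussian elimination with partial pivoting for the small (d x d) systems
// arising from bisector tuples; returns false on a (near-)singular system.
static bool solve_square(std::vector<double> M, std::vector<double> rhs,
                         std::vector<double> &x, int d) {
  double scale = 0.0;
  for (double v : M) scale = std::max(scale, std::fabs(v));
  if (scale <= 0.0) return false;
  const double tol = 1e-10 * scale;
  for (int c = 0; c < d; ++c) {
    int piv = c;
    for (int r = c + 1; r < d; ++r)
      if (std::fabs(M[r * d + c]) > std::fabs(M[piv * d + c])) piv = r;
    if (std::fabs(M[piv * d + c]) < tol) return false;
    if (piv != c) {
      for (int j = 0; j < d; ++j) std::swap(M[c * d + j], M[piv * d + j]);
      std::swap(rhs[c], rhs[piv]);
    }
    for (int r = c + 1; r < d; ++r) {
      const double f = M[r * d + c] / M[c * d + c];
      for (int j = c; j < d; ++j) M[r * d + j] -= f * M[c * d + j];
      rhs[r] -= f * rhs[c];
    }
  }
  x.assign(d, 0.0);
  for (int r = d - 1; r >= 0; --r) {
    double s = rhs[r];
    for (int j = r + 1; j < d; ++j) s -= M[r * d + j] * x[j];
    x[r] = s / M[r * d + r];
  }
  return true;
}

// For each d-tuple of bisectors (rows of A = [normal | offset], unit normals)
// solve for the intersection point and produce the in-cell representative:
// perturb one coordinate by +eps, re-solve each bisector for the dependent
// coordinate, and average.  Degenerate (singular) tuples yield an NA row.
// [[Rcpp::export]]
NumericMatrix solve_tuples_cpp(const NumericMatrix &A,
                               const IntegerMatrix &tuples, double eps) {
  const int d = A.ncol() - 1;
  const int nt = tuples.nrow();
  if (tuples.ncol() != d) stop("tuples must have one column per dimension");
  NumericMatrix out(nt, d);
  std::vector<double> M(d * d), rhs(d), x, p(d);
  for (int t = 0; t < nt; ++t) {
    for (int i = 0; i < d; ++i) {
      const int r = tuples(t, i) - 1;
      if (r < 0 || r >= A.nrow()) stop("tuple index out of range");
      for (int j = 0; j < d; ++j) M[i * d + j] = A(r, j);
      rhs[i] = -A(r, d);
    }
    if (!solve_square(M, rhs, x, d)) {
      for (int j = 0; j < d; ++j) out(t, j) = NA_REAL;
      continue;
    }
    // Dependent ("solve") axis: the first axis on which every bisector of
    // the tuple has a usable coefficient, preferring X as in the canonical
    // construction (solve X after perturbing Y); otherwise the axis with
    // the largest worst-case coefficient.
    int s_axis = -1;
    double best_min = 0.0;
    for (int sa = 0; sa < d; ++sa) {
      double mn = R_PosInf;
      for (int i = 0; i < d; ++i)
        mn = std::min(mn, std::fabs(A(tuples(t, i) - 1, sa)));
      if (sa == 0 && mn >= 1e-9) {
        s_axis = 0;
        best_min = mn;
        break;
      }
      if (mn > best_min) {
        best_min = mn;
        s_axis = sa;
      }
    }
    if (s_axis < 0 || best_min < 1e-9) {
      // Axis-aligned tuples (some bisector orthogonal to every candidate
      // axis pairing): step off the vertex along the averaged normal.
      std::vector<double> g(d, 0.0);
      for (int i = 0; i < d; ++i) {
        const int r = tuples(t, i) - 1;
        double sgn = 0.0;
        for (int j = 0; j < d; ++j)
          if (std::fabs(A(r, j)) > 1e-12) {
            sgn = A(r, j) > 0 ? 1.0 : -1.0;
            break;
          }
        for (int j = 0; j < d; ++j) g[j] += sgn * A(r, j);
      }
      double nrm = 0.0;
      for (int j = 0; j < d; ++j) nrm += g[j] * g[j];
      nrm = std::sqrt(nrm);
      if (nrm < 1e-12) {
        for (int j = 0; j < d; ++j) out(t, j) = NA_REAL;
      } else {
        for (int j = 0; j < d; ++j) out(t, j) = x[j] + eps * g[j] / nrm;
      }
      continue;
    }
    const int t_axis = (s_axis == 0) ? 1 : 0;
    for (int j = 0; j < d; ++j) p[j] = x[j];
    p[t_axis] += eps;
    double acc = 0.0;
    for (int i = 0; i < d; ++i) {
      const int r = tuples(t, i) - 1;
      double s = A(r, d);
      for (int j = 0; j < d; ++j)
        if (j != s_axis) s += A(r, j) * p[j];
      acc += -s / A(r, s_axis);
    }
    p[s_axis] = acc / d;
    for (int j = 0; j < d; ++j) out(t, j) = p[j];
  }
  return out;
}

// Does the hyperplane (row r of A) intersect the axis-aligned cube?  The
// extremes of a linear function over the cube are value(center) +/-
// half * sum_j |a_j|; the plane intersects iff 0 lies in that interval.
static void cube_active(const NumericMatrix &A, const std::vector<int> &cand,
                        const std::vector<double> &center, double half,
                        std::vector<int> &out) {
  const int d = A.ncol() - 1;
  out.clear();
  for (int r : cand) {
    double v0 = A(r, d);
    double span = 0.0;
    for (int j = 0; j < d; ++j) {
      v0 += A(r, j) * center[j];
      span += std::fabs(A(r, j));
    }
    span *= half;
    if (v0 - span <= 0.0 && v0 + span >= 0.0) out.push_back(r);
  }
}

// Optimistic bound: after every prefix of the center's ranking, promote up
// to k '0'->'1' swaps (never exceeding B ones in total) and take the best
// resulting tail.  Sound for any pivot in the cube whose ranking differs
// from the center's only across the k unsatisfied active bisectors.
static double bound_from_center(double center_score,
                                const std::vector<int> &cumb, int k, int N,
                                int B, const NumericMatrix &tails) {
  double bound = center_score;
  if (k <= 0) return bound;
  for (int n = 0; n <= N; ++n) {
    const int b = (n == 0) ? 0 : cumb[n - 1];
    const int kk = std::min(k, B - b);
    if (kk <= 0) continue;
    const int n2 = n + kk;
    if (n2 > N) continue;
    const double t = tails(n2, b + kk);
    if (t < bound) bound = t;
  }
  return bound;
}

// [[Rcpp::export]]
List cube_bound_cpp(const NumericVector &center, double half,
                    const NumericMatrix &X, const IntegerVector &y,
                    const NumericMatrix &tails, const NumericMatrix &A) {
  const int N = X.nrow(), d = X.ncol();
  if (center.size() != d) stop("cube center dimension mismatch");
  int B = 0;
  for (int i = 0; i < N; ++i) B += y[i];
  std::vector<int> all(A.nrow());
  for (int i = 0; i < (int)all.size(); ++i) all[i] = i;
  std::vector<double> c(center.begin(), center.end());
  std::vector<int> act;
  cube_active(A, all, c, half, act);
  std::vector<int> idx(N), cumb(N);
  std::vector<double> d2(N);
  const ScoreOut cs = score_one(c.data(), X, y, tails, idx, d2, &cumb);
  int k = 0;
  for (int r : act) {
    double v = A(r, d);
    for (int j = 0; j < d; ++j) v += A(r, j) * c[j];
    if (v >= 0.0) ++k;
  }
  const double bnd = bound_from_center(cs.score, cumb, k, N, B, tails);
  return List::create(_["bound"] = bnd, _["k"] = k,
                      _["n_active"] = (int)act.size(),
                      _["center_score"] = cs.score);
}

struct GNode {
  std::vector<double> center;
  double half;
  int depth;
  std::vector<int> active;
  double key;
  long id;
};

// Best-first octree branch and bound.  Nodes are prioritised by ascending
// bound, ties broken by shallower depth then insertion order.
// [[Rcpp::export]]
List grid_search_cpp(const NumericMatrix &X, const IntegerVector &y,
                     const NumericMatrix &tails, const NumericMatrix &A,
                     const NumericVector &center0, double half0, double budget,
                     int max_depth, bool prune) {
  const int N = X.nrow(), d = X.ncol(), m = A.nrow();
  int B = 0;
  for (int i = 0; i < N; ++i) B += y[i];

  std::deque<GNode> nodes;
  auto cmp = [&nodes](long a, long b) {
    const GNode &na = nodes[a], &nb = nodes[b];
    if (na.key != nb.key) return na.key > nb.key;
    if (na.depth != nb.depth) return na.depth > nb.depth;
    return na.id > nb.id;
  };
  std::priority_queue<long, std::vector<long>, decltype(cmp)> pq(cmp);

  long next_id = 0;
  {
    GNode root;
    root.center.assign(center0.begin(), center0.end());
    root.half = half0;
    root.depth = 0;
    root.key = -1.0;
    root.id = next_id;
    std::vector<int> all(m);
    for (int i = 0; i < m; ++i) all[i] = i;
    cube_active(A, all, root.center, root.half, root.active);
    nodes.push_back(std::move(root));
    pq.push(next_id++);
  }

  std::vector<int> idx(N), cumb(N);
  std::vector<double> d2(N);
  double OPT = 3.0;
  bool have_best = false;
  ScoreOut best{1.0, 1, 0, 0.0};
  std::vector<double> best_pivot(d, NA_REAL);
  double evaluated = 0;
  std::vector<double> trace_t, trace_s;

  while (!pq.empty() && evaluated < budget) {
    const long ni = pq.top();
    pq.pop();
    GNode nd = std::move(nodes[ni]);
    if (prune && have_best && nd.key > OPT) continue;
    const ScoreOut cs =
        score_one(nd.center.data(), X, y, tails, idx, d2, &cumb);
    evaluated += 1;
    if (!have_best || cs.score < OPT) {
      OPT = cs.score;
      best = cs;
      best_pivot = nd.center;
      have_best = true;
      trace_t.push_back(evaluated);
      trace_s.push_back(cs.score);
    }
    if (nd.active.empty() || nd.depth >= max_depth) continue;
    int k = 0;
    for (int r : nd.active) {
      double v = A(r, d);
      for (int j = 0; j < d; ++j) v += A(r, j) * nd.center[j];
      if (v >= 0.0) ++k;
    }
    const double bnd = bound_from_center(cs.score, cumb, k, N, B, tails);
    if (prune && bnd > OPT) continue;
    const double h2 = nd.half / 2.0;
    for (int ci = 0; ci < (1 << d); ++ci) {
      GNode ch;
      ch.center.resize(d);
      for (int j = 0; j < d; ++j)
        ch.center[j] = nd.center[j] + (((ci >> j) & 1) ? h2 : -h2);
      ch.half = h2;
      ch.depth = nd.depth + 1;
      ch.key = bnd;
      ch.id = next_id;
      cube_active(A, nd.active, ch.center, h2, ch.active);
      nodes.push_back(std::move(ch));
      pq.push(next_id++);
    }
  }

  return List::create(
      _["score"] = best.score,
      _["pivot"] = NumericVector(best_pivot.begin(), best_pivot.end()),
      _["threshold_n"] = best.n, _["b_at_threshold"] = best.b,
      _["radius"] = best.radius, _["pivots_evaluated"] = evaluated,
      _["trace_t"] = trace_t, _["trace_score"] = trace_s);
}
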