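// Random survival forest core: bootstrap trees with log-rank splitting,
// Nelson-Aalen terminal cumulative hazards on the pooled event-time grid,
// out-of-bag ensemble prediction, Harrell concordance, and per-tree OOB
// permutation importance. All randomness goes through R's RNG so that a
// single set.seed() on the R side fixes the whole forest.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// Standardized two-sample log-rank statistic over node members given in
// ascending time order. `left` marks the first daughter. Also returns the
// per-daughter event counts and sizes for split admissibility.
double logrank_pass(const std::vector<int>& idx,
                    const double* time, const int* event,
                    const std::vector<char>& left, int n_left,
                    int& events_left, int& events_right) {
  const int m = (int)idx.size();
  int Y = m, YL = n_left;
  events_left = events_right = 0;
  double U = 0.0, V = 0.0;
  int i = 0;
  while (i < m) {
    const double t = time[idx[i]];
    int d = 0, dL = 0, removed = 0, removedL = 0;
    int j = i;
    while (j < m && time[idx[j]] == t) {
      if (event[idx[j]]) {
        ++d;
        if (left[j]) ++dL;
      }
      ++removed;
      if (left[j]) ++removedL;
      ++j;
    }
    if (d > 0 && Y > 0) {
      const double pL = (double)YL / Y;
      U += dL - d * pL;
      if (Y > 1)
        V += d * pL * (1.0 - pL) * ((double)(Y - d) / (Y - 1));
      events_left  += dL;
      events_right += d - dL;
    }
    Y  -= removed;
    YL -= removedL;
    i = j;
  }
  if (V <= 0.0) return NA_REAL;
  return U / std::sqrt(V);
}

// sample k distinct integers from 0..(n-1) via partial Fisher-Yates (R RNG)
void sample_k(std::vector<int>& pool, int k) {
  const int n = (int)pool.size();
  for (int i = 0; i < k && i < n - 1; ++i) {
    int j = i + (int)std::floor(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

struct TreeNodes {
  std::vector<int> var;      // 0-based split variable, -1 terminal
  std::vector<double> cut;   // x <= cut goes left
  std::vector<int> left, right;  // 0-based node ids, -1 none
  std::vector<int> depth;
  std::vector<int> term;     // 0-based row into chf matrix, -1 internal
};

struct WorkItem {
  std::vector<int> idx;  // member rows (with bootstrap multiplicity), time-ordered
  int node;
  int depth;
};

// Nelson-Aalen estimator of node members evaluated on the pooled grid.
void terminal_chf(const std::vector<int>& idx, const double* time,
                  const int* event, const std::vector<double>& grid,
                  std::vector<double>& out) {
  const int m = (int)idx.size(), G = (int)grid.size();
  out.assign(G, 0.0);
  int Y = m, i = 0, g = 0;
  double H = 0.0;
  while (i < m) {
    const double t = time[idx[i]];
    int d = 0, removed = 0;
    int j = i;
    while (j < m && time[idx[j]] == t) {
      if (event[idx[j]]) ++d;
      ++removed; ++j;
    }
    if (d > 0) {
      while (g < G && grid[g] < t) { out[g] = H; ++g; }
      H += (double)d / Y;
    }
    Y -= removed;
    i = j;
  }
  while (g < G) { out[g] = H; ++g; }
}

// xrow: one subject's variable vector, contiguous (a column of the
// transposed design matrix), so tree descent stays cache-local.
int drop_down(const TreeNodes& tr, const double* xrow, int perm_var,
              double perm_val) {
  int node = 0;
  while (tr.var[node] >= 0) {
    const int v = tr.var[node];
    const double x = (v == perm_var) ? perm_val : xrow[v];
    node = (x <= tr.cut[node]) ? tr.left[node] : tr.right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export]]
double cpp_logrank_statistic(NumericVector time, IntegerVector event,
                             IntegerVector group) {
  const int n = time.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  std::vector<char> left(n);
  int nL = 0;
  for (int i = 0; i < n; ++i) {
    left[i] = group[idx[i]] != 0;
    nL += left[i] ? 1 : 0;
  }
  int eL, eR;
  return logrank_pass(idx, REAL(time), INTEGER(event), left, nL, eL, eR);
}

// Exhaustive (nsplit = 0) or randomized split search on a single variable,
// exported so tests can compare against a brute-force scan.
// [[Rcpp::export]]
List cpp_best_split(NumericVector x, NumericVector time, IntegerVector event,
                    int nsplit, int min_node_events) {
  const int n = x.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  std::vector<double> cuts;
  if (nsplit <= 0) {
    cuts.assign(x.begin(), x.end());
  } else {
    for (int k = 0; k < nsplit; ++k)
      cuts.push_back(x[(int)std::floor(unif_rand() * n)]);
  }
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  double best = -1.0, best_cut = NA_REAL;
  const double xmax = *std::max_element(x.begin(), x.end());
  std::vector<char> left(n);
  for (double c : cuts) {
    if (c >= xmax) continue;
    int nL = 0;
    for (int i = 0; i < n; ++i) {
      left[i] = x[idx[i]] <= c;
      nL += left[i] ? 1 : 0;
    }
    if (nL == 0 || nL == n) continue;
    int eL, eR;
    double s = logrank_pass(idx, REAL(time), INTEGER(event), left, nL, eL, eR);
    if (ISNA(s)) continue;
    if (eL < min_node_events || eR < min_node_events)
      continue;
    if (std::fabs(s) > best) { best = std::fabs(s); best_cut = c; }
  }
  return List::create(_["cut"] = best_cut,
                      _["statistic"] = best < 0 ? NA_REAL : best);
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector time, IntegerVector event,
                     int ntree, int mtry, int nsplit, int min_node_events,
                     int max_depth, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  const double* tptr = REAL(time);
  const int* eptr = INTEGER(event);

  // subjects ordered by follow-up time (stable)
  std::vector<int> order0(n);
  for (int i = 0; i < n; ++i) order0[i] = i;
  std::stable_sort(order0.begin(), order0.end(),
                   [&](int a, int b) { return tptr[a] < tptr[b]; });

  // pooled grid of distinct event times
  std::vector<double> grid;
  for (int i = 0; i < n; ++i)
    if (eptr[i]) grid.push_back(tptr[i]);
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  const int G = (int)grid.size();

  IntegerMatrix inbag(n, ntree);
  List trees(ntree);
  std::vector<double> chf_store;   // terminal rows, G values each
  int n_terminals = 0;
  std::vector<int> varpool(p);
  std::vector<double> chf_row;

  for (int t = 0; t < ntree; ++t) {
    std::vector<int> counts(n, bootstrap ? 0 : 1);
    if (bootstrap)
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * n);
        if (j >= n) j = n - 1;
        ++counts[j];
      }
    for (int i = 0; i < n; ++i) inbag(i, t) = counts[i];

    std::vector<int> root;
    root.reserve(n);
    for (int k = 0; k < n; ++k) {
      const int s = order0[k];
      for (int c = 0; c < counts[s]; ++c) root.push_back(s);
    }

    TreeNodes tr;
    std::vector<WorkItem> stack;
    tr.var.push_back(-1); tr.cut.push_back(NA_REAL);
    tr.left.push_back(-1); tr.right.push_back(-1);
    tr.depth.push_back(0); tr.term.push_back(-1);
    stack.push_back(WorkItem{std::move(root), 0, 0});

    while (!stack.empty()) {
      WorkItem w = std::move(stack.back());
      stack.pop_back();
      const int m = (int)w.idx.size();
      int d_node = 0;
      for (int i = 0; i < m; ++i) d_node += eptr[w.idx[i]];

      bool split_ok = m >= 2 && d_node >= 2 * min_node_events &&
                      (max_depth <= 0 || w.depth < max_depth);
      int best_var = -1, best_nL = 0;
      double best_stat = -1.0, best_cut = 0.0;
      if (split_ok) {
        for (int i = 0; i < p; ++i) varpool[i] = i;
        const int k = std::min(mtry, p);
        sample_k(varpool, k);
        std::vector<char> left(m);
        std::vector<double> xv(m), cuts;
        for (int vi = 0; vi < k; ++vi) {
          const int v = varpool[vi];
          const double* xcol = &X(0, v);
          double xmin, xmax;
          xv[0] = xmin = xmax = xcol[w.idx[0]];
          for (int i = 1; i < m; ++i) {
            const double x = xcol[w.idx[i]];
            xv[i] = x;
            if (x < xmin) xmin = x;
            if (x > xmax) xmax = x;
          }
          if (xmin == xmax) continue;
          cuts.clear();
          if (nsplit > 0) {
            for (int s = 0; s < nsplit; ++s)
              cuts.push_back(xv[(int)std::floor(unif_rand() * m)]);
          } else {
            cuts.assign(xv.begin(), xv.end());
          }
          std::sort(cuts.begin(), cuts.end());
          cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
          for (double c : cuts) {
            if (c >= xmax) continue;
            int nL = 0;
            for (int i = 0; i < m; ++i) {
              left[i] = xv[i] <= c;
              nL += left[i] ? 1 : 0;
            }
            if (nL == 0 || nL == m) continue;
            int eL, eR;
            double s = logrank_pass(w.idx, tptr, eptr, left, nL, eL, eR);
            if (ISNA(s)) continue;
            if (eL < min_node_events || eR < min_node_events) continue;
            if (std::fabs(s) > best_stat) {
              best_stat = std::fabs(s);
              best_var = v;
              best_cut = c;
              best_nL = nL;
            }
          }
        }
      }

      const int node = w.node;
      if (best_var < 0) {
        terminal_chf(w.idx, tptr, eptr, grid, chf_row);
        chf_store.insert(chf_store.end(), chf_row.begin(), chf_row.end());
        tr.term[node] = n_terminals++;
        continue;
      }
      const double* xcol = &X(0, best_var);
      std::vector<int> li, ri;
      li.reserve(best_nL); ri.reserve(m - best_nL);
      for (int i = 0; i < m; ++i)
        (xcol[w.idx[i]] <= best_cut ? li : ri).push_back(w.idx[i]);
      tr.var[node] = best_var;
      tr.cut[node] = best_cut;
      const int lid = (int)tr.var.size();
      tr.var.push_back(-1); tr.cut.push_back(NA_REAL);
      tr.left.push_back(-1); tr.right.push_back(-1);
      tr.depth.push_back(w.depth + 1); tr.term.push_back(-1);
      const int rid = (int)tr.var.size();
      tr.var.push_back(-1); tr.cut.push_back(NA_REAL);
      tr.left.push_back(-1); tr.right.push_back(-1);
      tr.depth.push_back(w.depth + 1); tr.term.push_back(-1);
      tr.left[node] = lid;
      tr.right[node] = rid;
      stack.push_back(WorkItem{std::move(li), lid, w.depth + 1});
      stack.push_back(WorkItem{std::move(ri), rid, w.depth + 1});
    }

    const int nn = (int)tr.var.size();
    IntegerVector var(nn), leftv(nn), rightv(nn), depthv(nn), termv(nn);
    NumericVector cutv(nn);
    for (int i = 0; i < nn; ++i) {
      var[i] = tr.var[i] + 1;          // 1-based, 0 = terminal
      cutv[i] = tr.cut[i];
      leftv[i] = tr.left[i] + 1;       // 1-based, 0 = none
      rightv[i] = tr.right[i] + 1;
      depthv[i] = tr.depth[i];
      termv[i] = tr.term[i] + 1;       // 1-based row into chf, 0 = internal
    }
    trees[t] = List::create(_["var"] = var, _["cut"] = cutv,
                            _["left"] = leftv, _["right"] = rightv,
                            _["depth"] = depthv, _["terminal"] = termv);
  }

  NumericMatrix chf(n_terminals, G);
  for (int r = 0; r < n_terminals; ++r)
    for (int g = 0; g < G; ++g)
      chf(r, g) = chf_store[(size_t)r * G + g];
  return List::create(_["trees"] = trees, _["chf"] = chf,
                      _["grid"] = NumericVector(grid.begin(), grid.end()),
                      _["inbag"] = inbag);
}

static TreeNodes unpack_tree(List tree) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"],
                term = tree["terminal"];
  NumericVector cut = tree["cut"];
  TreeNodes tr;
  const int nn = var.size();
  tr.var.resize(nn); tr.cut.resize(nn); tr.left.resize(nn);
  tr.right.resize(nn); tr.term.resize(nn);
  for (int i = 0; i < nn; ++i) {
    tr.var[i] = var[i] - 1;
    tr.cut[i] = cut[i];
    tr.left[i] = left[i] - 1;
    tr.right[i] = right[i] - 1;
    tr.term[i] = term[i] - 1;
  }
  return tr;
}

// Ensemble cumulative hazard on the pooled grid; oob restricts each
// subject's average to trees where that subject was out of bag.
// Xt is the transposed design matrix (variables x subjects).
// [[Rcpp::export]]
NumericMatrix cpp_ensemble_chf(List trees, NumericMatrix chf,
                               NumericMatrix Xt, IntegerMatrix inbag,
                               bool oob) {
  const int n = Xt.ncol(), G = chf.ncol(), ntree = trees.size();
  NumericMatrix out(n, G);
  std::vector<int> used(n, 0);
  for (int t = 0; t < ntree; ++t) {
    TreeNodes tr = unpack_tree(trees[t]);
    for (int i = 0; i < n; ++i) {
      if (oob && inbag(i, t) > 0) continue;
      const int node = drop_down(tr, &Xt(0, i), -1, 0.0);
      const int row = tr.term[node];
      for (int g = 0; g < G; ++g) out(i, g) += chf(row, g);
      ++used[i];
    }
  }
  for (int i = 0; i < n; ++i) {
    if (used[i] == 0) {
      for (int g = 0; g < G; ++g) out(i, g) = NA_REAL;
    } else {
      for (int g = 0; g < G; ++g) out(i, g) /= used[i];
    }
  }
  return out;
}

// OOB ensemble mortality with one variable's values permuted among each
// tree's OOB subjects (identity permutation of values when the column is
// constant, so a constant column gets importance exactly zero).
// [[Rcpp::export]]
NumericVector cpp_oob_mortality_permuted(List trees, NumericVector term_mort,
                                         NumericMatrix Xt, IntegerMatrix inbag,
                                         int var) {
  const int n = Xt.ncol(), ntree = trees.size();
  const int v = var - 1;
  std::vector<double> mort(n, 0.0);
  std::vector<int> used(n, 0);
  std::vector<int> oob_ids;
  std::vector<double> vals;
  for (int t = 0; t < ntree; ++t) {
    TreeNodes tr = unpack_tree(trees[t]);
    oob_ids.clear();
    for (int i = 0; i < n; ++i)
      if (inbag(i, t) == 0) oob_ids.push_back(i);
    const int m = (int)oob_ids.size();
    if (m == 0) continue;
    vals.resize(m);
    for (int i = 0; i < m; ++i) vals[i] = Xt(v, oob_ids[i]);
    // Fisher-Yates on the OOB values
    for (int i = m - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(vals[i], vals[j]);
    }
    for (int i = 0; i < m; ++i) {
      const int s = oob_ids[i];
      const int node = drop_down(tr, &Xt(0, s), v, vals[i]);
      mort[s] += term_mort[tr.term[node]];
      ++used[s];
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = used[i] ? mort[i] / used[i] : NA_REAL;
  return out;
}

namespace {
// Fenwick tree over compressed risk ranks
struct BIT {
  std::vector<double> t;
  int n;
  explicit BIT(int n_) : t(n_ + 1, 0.0), n(n_) {}
  void add(int i, double v) { for (++i; i <= n; i += i & -i) t[i] += v; }
  double sum(int i) const {  // sum of ranks 0..i
    double s = 0.0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};
}  // namespace

// Harrell concordance: pair (i, j) is usable when i is observed to fail
// before j (t_i < t_j with an event for i, or tied times with an event for
// i only); concordant when the earlier failure has the higher risk score
// (risk ties count 1/2). O(n log n) via a Fenwick tree over risk ranks.
// [[Rcpp::export]]
double cpp_cindex(NumericVector time, IntegerVector event,
                  NumericVector risk) {
  const int n = time.size();
  std::vector<int> keep;
  keep.reserve(n);
  for (int i = 0; i < n; ++i)
    if (!ISNAN(risk[i])) keep.push_back(i);
  const int m = (int)keep.size();
  if (m < 2) return NA_REAL;
  // compress risks to ranks
  std::vector<double> rs(m);
  for (int i = 0; i < m; ++i) rs[i] = risk[keep[i]];
  std::vector<double> uniq(rs);
  std::sort(uniq.begin(), uniq.end());
  uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
  std::vector<int> rrank(m);
  for (int i = 0; i < m; ++i)
    rrank[i] = (int)(std::lower_bound(uniq.begin(), uniq.end(), rs[i]) -
                     uniq.begin());
  const int R = (int)uniq.size();
  // order by time ascending
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[keep[a]] < time[keep[b]];
  });
  BIT bit(R);
  std::vector<double> cnt(R, 0.0);
  for (int i = 0; i < m; ++i) { bit.add(rrank[i], 1.0); cnt[rrank[i]] += 1.0; }
  double conc = 0.0, npairs = 0.0, remaining = m;
  int i = 0;
  while (i < m) {
    const double t = time[keep[ord[i]]];
    int j = i;
    std::vector<int> ev_grp, cens_grp;
    while (j < m && time[keep[ord[j]]] == t) {
      (event[keep[ord[j]]] ? ev_grp : cens_grp).push_back(ord[j]);
      ++j;
    }
    // remove the whole tie group so the tree holds subjects with later times
    for (int s = i; s < j; ++s) {
      bit.add(rrank[ord[s]], -1.0);
      cnt[rrank[ord[s]]] -= 1.0;
      remaining -= 1.0;
    }
    for (int e : ev_grp) {
      const int r = rrank[e];
      // later-time subjects
      double less = r > 0 ? bit.sum(r - 1) : 0.0;
      double eq = bit.sum(r) - less;
      conc += less + 0.5 * eq;
      npairs += remaining;
      // tied-time censored subjects are usable too
      for (int c : cens_grp) {
        npairs += 1.0;
        if (rrank[e] > rrank[c]) conc += 1.0;
        else if (rrank[e] == rrank[c]) conc += 0.5;
      }
    }
    i = j;
  }
  if (npairs == 0.0) return NA_REAL;
  return conc / npairs;
}
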