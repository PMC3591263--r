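// Module-guided regression forest engine.
//
// Trees are grown on bootstrap samples; at each node the candidate split
// variables are drawn by two-stage sampling: modules first (weighted by
// module importance), then one representative variable per chosen module
// (weighted by variable importance). Weighted sampling without replacement
// uses exponential (Efraimidis-Spirakis) keys, whose order is distributed
// exactly as sequential draws with probability proportional to the
// remaining weights. All randomness comes from R's RNG, so set.seed()
// makes forests bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double MIN_REDUCTION = 1e-10;

struct BestSplit {
  int var = -1;               // 0-based column
  double thr = 0.0;           // continuous threshold (midpoint)
  unsigned long long mask = 0;// categorical: bit set => level goes left
  bool is_cat = false;
  double red = 0.0;           // SSE reduction
};

// Draw `take` items without replacement, probability of each successive
// draw proportional to the remaining weights; zero-weight items are drawn
// uniformly once positive weights are exhausted. Equal weights => uniform.
static void es_sample(const std::vector<int> &items, const double *w,
                      bool weighted, int take, std::vector<int> &out,
                      std::vector<std::pair<double, int>> &keys) {
  const int K = (int)items.size();
  if (take > K) take = K;
  keys.clear();
  for (int t = 0; t < K; ++t) {
    double u = unif_rand();
    if (u <= 0) u = 1e-300;
    const double wt = weighted ? w[items[t]] : 1.0;
    const double key = (wt > 0) ? std::log(u) / wt : -1e300 * (2.0 - u);
    keys.push_back(std::make_pair(key, items[t]));
  }
  std::partial_sort(keys.begin(), keys.begin() + take, keys.end(),
                    [](const std::pair<double, int> &a,
                       const std::pair<double, int> &b) {
                      if (a.first != b.first) return a.first > b.first;
                      return a.second < b.second;
                    });
  out.clear();
  for (int t = 0; t < take; ++t) out.push_back(keys[t].second);
}

// Uniform subsample of `take` from pool (partial Fisher-Yates; mutates pool).
static void uniform_take(std::vector<int> &pool, int take,
                         std::vector<int> &out) {
  const int K = (int)pool.size();
  if (take > K) take = K;
  out.clear();
  for (int t = 0; t < take; ++t) {
    int j = t + (int)std::floor(unif_rand() * (K - t));
    if (j >= K) j = K - 1;
    std::swap(pool[t], pool[j]);
    out.push_back(pool[t]);
  }
}

struct Grower {
  const NumericMatrix &X;
  const NumericVector &y;
  const IntegerVector &nlev;                  // 0 = continuous
  const std::vector<std::vector<int>> &modules;
  const std::vector<int> &var_module;         // var -> module index
  const double *mod_w;
  const double *var_w;
  bool weighted;
  int k_mod, nodesize, plain_mtry;
  int n, m, M;
  bool trace;

  // rows presorted by value, per continuous variable (split-scan shortcut)
  std::vector<std::vector<int>> sort_order;
  std::vector<int> node_cnt;                  // bootstrap multiplicity in node

  // node records of the tree being grown
  std::vector<double> nd_var, nd_thr, nd_mask, nd_left, nd_right,
      nd_pred, nd_red, nd_n;
  std::vector<std::vector<int>> node_cand_modules;  // only when trace
  std::vector<double> &vi;                          // forest-wide accumulator

  // scratch
  std::vector<int> all_vars, all_mods, s1, s2, cand, pool;
  std::vector<std::pair<double, int>> keys;
  std::vector<std::pair<double, double>> xy;
  std::vector<double> lv_sum;
  std::vector<int> lv_cnt;
  std::vector<std::pair<double, int>> lv_ord;

  Grower(const NumericMatrix &X_, const NumericVector &y_,
         const IntegerVector &nlev_,
         const std::vector<std::vector<int>> &modules_,
         const std::vector<int> &var_module_, const double *mw,
         const double *vw, bool weighted_, int k_mod_, int nodesize_,
         int plain_mtry_, bool trace_, std::vector<double> &vi_)
      : X(X_), y(y_), nlev(nlev_), modules(modules_), var_module(var_module_),
        mod_w(mw), var_w(vw), weighted(weighted_), k_mod(k_mod_),
        nodesize(nodesize_), plain_mtry(plain_mtry_), n(X_.nrow()),
        m(X_.ncol()), M((int)modules_.size()), trace(trace_), vi(vi_) {
    all_vars.resize(m);
    for (int j = 0; j < m; ++j) all_vars[j] = j;
    all_mods.resize(M);
    for (int j = 0; j < M; ++j) all_mods[j] = j;
    int maxlev = 2;
    for (int j = 0; j < m; ++j) maxlev = std::max(maxlev, nlev[j]);
    lv_sum.resize(maxlev);
    lv_cnt.resize(maxlev);
    node_cnt.assign(n, 0);
    sort_order.resize(m);
    for (int j = 0; j < m; ++j) {
      if (nlev[j] != 0) continue;
      const double *xc = &X(0, j);
      std::vector<int> &ord = sort_order[j];
      ord.resize(n);
      for (int i = 0; i < n; ++i) ord[i] = i;
      std::sort(ord.begin(), ord.end(),
                [xc](int a, int b) { return xc[a] < xc[b]; });
    }
  }

  void reset() {
    nd_var.clear(); nd_thr.clear(); nd_mask.clear(); nd_left.clear();
    nd_right.clear(); nd_pred.clear(); nd_red.clear(); nd_n.clear();
    node_cand_modules.clear();
  }

  int new_node() {
    nd_var.push_back(0); nd_thr.push_back(0); nd_mask.push_back(0);
    nd_left.push_back(0); nd_right.push_back(0); nd_pred.push_back(0);
    nd_red.push_back(0); nd_n.push_back(0);
    return (int)nd_var.size() - 1;
  }

  void draw_candidates() {
    cand.clear();
    if (plain_mtry > 0) {
      // conventional-RF mode: uniform mtry sample of variables
      es_sample(all_vars, nullptr, false, plain_mtry, cand, keys);
    } else {
      const int k2 = std::min(k_mod, M);
      const int N1 = std::max((M + 2) / 3, k2);     // ceil(M/3), grown to k2
      es_sample(all_mods, mod_w, weighted, N1, s1, keys);
      uniform_take(s1, k2, s2);
      for (size_t t = 0; t < s2.size(); ++t) {
        const std::vector<int> &mem = modules[s2[t]];
        const int N1v = ((int)mem.size() + 2) / 3;  // ceil(|module|/3)
        es_sample(mem, var_w, weighted, N1v, s1, keys);
        uniform_take(s1, 1, pool);
        cand.push_back(pool[0]);
      }
    }
    std::sort(cand.begin(), cand.end());  // ties across vars -> smaller index
  }

  // gather + sort (cheap for deep, small nodes)
  void eval_continuous_sorted(int v, const std::vector<int> &idx, double ymean,
                              BestSplit &best) {
    const int nn = (int)idx.size();
    const double *xc = &X(0, v);
    xy.clear();
    for (int t = 0; t < nn; ++t)
      xy.push_back(std::make_pair(xc[idx[t]], y[idx[t]] - ymean));
    std::sort(xy.begin(), xy.end());
    double S = 0;
    for (int t = 0; t < nn; ++t) S += xy[t].second;
    const double base = S * S / nn;
    double SL = 0;
    for (int t = 0; t < nn - 1; ++t) {
      SL += xy[t].second;
      if (xy[t + 1].first <= xy[t].first) continue;  // need distinct x
      const int nL = t + 1, nR = nn - nL;
      const double SR = S - SL;
      const double red = SL * SL / nL + SR * SR / nR - base;
      if (red > best.red && red > MIN_REDUCTION) {
        best.var = v; best.red = red; best.is_cat = false;
        best.thr = (xy[t].first + xy[t + 1].first) / 2.0;
        best.mask = 0;
      }
    }
  }

  // presorted scan over all samples, filtered by node membership counts
  // (cheap for large nodes: no per-candidate sort)
  void eval_continuous_scan(int v, int nn, double ymean, double S,
                            BestSplit &best) {
    const double *xc = &X(0, v);
    const std::vector<int> &ord = sort_order[v];
    const double base = S * S / nn;
    double SL = 0;
    int nL = 0;
    double prev_x = 0;
    bool started = false;
    for (int t = 0; t < n; ++t) {
      const int r = ord[t];
      const int c = node_cnt[r];
      if (!c) continue;
      const double x = xc[r];
      if (started && x > prev_x && nL < nn) {
        const int nR = nn - nL;
        const double SR = S - SL;
        const double red = SL * SL / nL + SR * SR / nR - base;
        if (red > best.red && red > MIN_REDUCTION) {
          best.var = v; best.red = red; best.is_cat = false;
          best.thr = (prev_x + x) / 2.0;
          best.mask = 0;
        }
      }
      SL += c * (y[r] - ymean);
      nL += c;
      prev_x = x;
      started = true;
    }
  }

  void eval_categorical(int v, const std::vector<int> &idx, double ymean,
                        BestSplit &best) {
    const int L = nlev[v];
    for (int l = 0; l < L; ++l) { lv_sum[l] = 0; lv_cnt[l] = 0; }
    double S = 0;
    for (size_t t = 0; t < idx.size(); ++t) {
      const int l = (int)X(idx[t], v);
      const double yy = y[idx[t]] - ymean;
      lv_sum[l] += yy; lv_cnt[l] += 1; S += yy;
    }
    lv_ord.clear();
    for (int l = 0; l < L; ++l)
      if (lv_cnt[l] > 0)
        lv_ord.push_back(std::make_pair(lv_sum[l] / lv_cnt[l], l));
    if (lv_ord.size() < 2) return;
    std::sort(lv_ord.begin(), lv_ord.end());  // by mean response, then level
    const int nn = (int)idx.size();
    const double base = S * S / nn;
    double SL = 0; int nL = 0; unsigned long long mask = 0;
    for (size_t t = 0; t + 1 < lv_ord.size(); ++t) {
      const int l = lv_ord[t].second;
      SL += lv_sum[l]; nL += lv_cnt[l];
      mask |= (1ULL << l);
      const int nR = nn - nL;
      const double SR = S - SL;
      const double red = SL * SL / nL + SR * SR / nR - base;
      if (red > best.red && red > MIN_REDUCTION) {
        best.var = v; best.red = red; best.is_cat = true;
        best.thr = 0; best.mask = mask;
      }
    }
  }

  int grow(std::vector<int> &idx) {
    const int me = new_node();
    const int nn = (int)idx.size();
    double S = 0, ymin = R_PosInf, ymax = R_NegInf;
    for (int t = 0; t < nn; ++t) {
      S += y[idx[t]];
      ymin = std::min(ymin, y[idx[t]]);
      ymax = std::max(ymax, y[idx[t]]);
    }
    const double ymean = S / nn;
    nd_pred[me] = ymean;
    nd_n[me] = nn;
    if (nn <= nodesize || ymax - ymin < 1e-12) return me;

    draw_candidates();
    if (trace) {
      std::vector<int> mods;
      if (plain_mtry == 0)
        for (size_t t = 0; t < cand.size(); ++t)
          mods.push_back(var_module[cand[t]]);
      node_cand_modules.push_back(mods);
    }

    BestSplit best;
    best.red = MIN_REDUCTION;
    const bool use_scan = (size_t)nn * 4 >= (size_t)n;
    double Sc = 0;
    if (use_scan) {
      for (int t = 0; t < nn; ++t) node_cnt[idx[t]] += 1;
      for (int t = 0; t < nn; ++t) Sc += y[idx[t]] - ymean;
    }
    for (size_t c = 0; c < cand.size(); ++c) {
      const int v = cand[c];
      if (nlev[v] == 0) {
        if (use_scan) eval_continuous_scan(v, nn, ymean, Sc, best);
        else eval_continuous_sorted(v, idx, ymean, best);
      } else eval_categorical(v, idx, ymean, best);
    }
    if (use_scan)
      for (int t = 0; t < nn; ++t) node_cnt[idx[t]] = 0;
    if (best.var < 0) return me;

    std::vector<int> left_idx, right_idx;
    for (int t = 0; t < nn; ++t) {
      const double xv = X(idx[t], best.var);
      const bool go_left = best.is_cat
          ? (((best.mask >> (unsigned long long)xv) & 1ULL) != 0)
          : (xv <= best.thr);
      if (go_left) left_idx.push_back(idx[t]);
      else right_idx.push_back(idx[t]);
    }
    if (left_idx.empty() || right_idx.empty()) return me;  // degenerate

    nd_var[me] = best.var + 1;
    nd_thr[me] = best.thr;
    nd_mask[me] = (double)best.mask;
    nd_red[me] = best.red;
    vi[best.var] += best.red;

    idx.clear(); idx.shrink_to_fit();
    const int li = grow(left_idx);
    nd_left[me] = li + 1;
    const int ri = grow(right_idx);
    nd_right[me] = ri + 1;
    return me;
  }
};

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, IntegerVector nlev,
                     List module_list, NumericVector mod_w, NumericVector var_w,
                     int ntrees, int k_mod, int nodesize, bool weighted,
                     int plain_mtry, bool trace) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<std::vector<int>> modules;
  std::vector<int> var_module(m, -1);
  for (int i = 0; i < module_list.size(); ++i) {
    IntegerVector mi = module_list[i];
    std::vector<int> mem(mi.begin(), mi.end());   // 0-based
    for (size_t t = 0; t < mem.size(); ++t) {
      if (mem[t] < 0 || mem[t] >= m) stop("module member out of range");
      var_module[mem[t]] = i;
    }
    modules.push_back(mem);
  }
  if (plain_mtry == 0)
    for (int j = 0; j < m; ++j)
      if (var_module[j] < 0) stop("variable %d not assigned to a module", j + 1);

  std::vector<double> vi(m, 0.0);
  Grower g(X, y, nlev, modules, var_module, mod_w.begin(), var_w.begin(),
           weighted, k_mod, nodesize, plain_mtry, trace, vi);

  List trees(ntrees);
  for (int tr = 0; tr < ntrees; ++tr) {
    // bootstrap of size n with replacement
    std::vector<int> boot(n);
    std::vector<char> in_bag(n, 0);
    for (int t = 0; t < n; ++t) {
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      boot[t] = j;
      in_bag[j] = 1;
    }
    IntegerVector bootR(n);
    for (int t = 0; t < n; ++t) bootR[t] = boot[t] + 1;
    std::vector<int> oob_v;
    for (int t = 0; t < n; ++t) if (!in_bag[t]) oob_v.push_back(t + 1);
    IntegerVector oob(oob_v.begin(), oob_v.end());

    g.reset();
    std::vector<int> idx(boot);
    g.grow(idx);

    const int nnodes = (int)g.nd_var.size();
    NumericMatrix nodes(nnodes, 8);
    std::vector<int> split_vars;
    for (int q = 0; q < nnodes; ++q) {
      nodes(q, 0) = g.nd_var[q];
      nodes(q, 1) = g.nd_thr[q];
      nodes(q, 2) = g.nd_mask[q];
      nodes(q, 3) = g.nd_left[q];
      nodes(q, 4) = g.nd_right[q];
      nodes(q, 5) = g.nd_pred[q];
      nodes(q, 6) = g.nd_red[q];
      nodes(q, 7) = g.nd_n[q];
      if (g.nd_var[q] > 0) split_vars.push_back((int)g.nd_var[q]);
    }
    colnames(nodes) = CharacterVector::create("var", "thr", "mask", "left",
                                              "right", "pred", "red", "n");
    std::sort(split_vars.begin(), split_vars.end());
    split_vars.erase(std::unique(split_vars.begin(), split_vars.end()),
                     split_vars.end());
    List tree = List::create(
        Named("nodes") = nodes, Named("boot") = bootR, Named("oob") = oob,
        Named("split_vars") = IntegerVector(split_vars.begin(), split_vars.end()));
    if (trace) {
      List tl(g.node_cand_modules.size());
      for (size_t q = 0; q < g.node_cand_modules.size(); ++q)
        tl[q] = IntegerVector(g.node_cand_modules[q].begin(),
                              g.node_cand_modules[q].end());
      tree["candidate_modules"] = tl;
    }
    trees[tr] = tree;
  }
  return List::create(Named("trees") = trees,
                      Named("vi_total") = NumericVector(vi.begin(), vi.end()));
}

// Evaluate the best split over explicit candidates on the full sample set
// (exposed for direct testing of the split search).
// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector y, IntegerVector nlev,
                    IntegerVector candidates) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<std::vector<int>> modules;
  std::vector<int> var_module(m, 0);
  std::vector<double> vi(m, 0.0);
  Grower g(X, y, nlev, modules, var_module, nullptr, nullptr, false, 1, 1, 1,
           false, vi);
  double S = 0;
  for (int i = 0; i < n; ++i) S += y[i];
  const double ymean = S / n;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  for (size_t c = 0; c < cand.size(); ++c) cand[c] -= 1;  // 1-based in
  std::sort(cand.begin(), cand.end());
  BestSplit best;
  best.red = MIN_REDUCTION;
  for (size_t c = 0; c < cand.size(); ++c) {
    if (nlev[cand[c]] == 0) g.eval_continuous_sorted(cand[c], idx, ymean, best);
    else g.eval_categorical(cand[c], idx, ymean, best);
  }
  if (best.var < 0) return List::create(Named("var") = 0);
  std::vector<int> left_levels;
  if (best.is_cat)
    for (int l = 0; l < nlev[best.var]; ++l)
      if ((best.mask >> l) & 1ULL) left_levels.push_back(l);
  return List::create(
      Named("var") = best.var + 1, Named("is_cat") = best.is_cat,
      Named("threshold") = best.is_cat ? NA_REAL : best.thr,
      Named("left_levels") = IntegerVector(left_levels.begin(), left_levels.end()),
      Named("reduction") = best.red);
}

static double predict_one(const NumericMatrix &nodes, const NumericMatrix &X,
                          int row) {
  int q = 0;
  for (;;) {
    const int v = (int)nodes(q, 0);
    if (v == 0) return nodes(q, 5);
    const double xv = X(row, v - 1);
    bool go_left;
    const double mask = nodes(q, 2);
    if (mask > 0)  // categorical split
      go_left = ((((unsigned long long)mask) >> (unsigned long long)xv) & 1ULL) != 0;
    else
      go_left = xv <= nodes(q, 1);
    q = go_left ? (int)nodes(q, 3) - 1 : (int)nodes(q, 4) - 1;
  }
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int tr = 0; tr < T; ++tr) {
    List tree = trees[tr];
    NumericMatrix nodes = tree["nodes"];
    for (int i = 0; i < n; ++i) out[i] += predict_one(nodes, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// OOB prediction on the training matrix: each sample averaged over trees
// whose bootstrap it did not enter. Counts returned so callers can flag
// never-OOB samples.
// [[Rcpp::export]]
List cpp_oob_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector sum(n);
  IntegerVector cnt(n);
  for (int tr = 0; tr < T; ++tr) {
    List tree = trees[tr];
    NumericMatrix nodes = tree["nodes"];
    IntegerVector oob = tree["oob"];
    for (int t = 0; t < oob.size(); ++t) {
      const int i = oob[t] - 1;
      sum[i] += predict_one(nodes, X, i);
      cnt[i] += 1;
    }
  }
  NumericVector pred(n);
  for (int i = 0; i < n; ++i)
    pred[i] = cnt[i] > 0 ? sum[i] / cnt[i] : NA_REAL;
  return List::create(Named("pred") = pred, Named("n_oob") = cnt);
}
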