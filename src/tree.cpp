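// C4.5-style decision tree: binary splits chosen by information gain,
// pessimistic-error pruning, native handling of missing values (rows with a
// missing test value follow the majority branch; split gain is damped by the
// non-missing fraction). Compiled because the wrapper search evaluates tens
// of thousands of tree fits per run; per-feature index arrays are presorted
// once and stably partitioned down the tree, so no per-node sorting occurs.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;          // 0-based column; -1 for leaf
  double threshold;     // numeric split: x <= threshold goes left
  unsigned int catmask; // categorical split: bit (code-1) set -> left
  int left, right;      // node indices; -1 for leaf
  int pred;             // 0-based majority class
  std::vector<double> dist; // class counts at node
  int miss_branch;      // 0 = left, 1 = right for missing test values
  int n;                // rows reaching the node during training
};

// per-node view of the training rows: `rows` lists every row (with
// bootstrap multiplicity); `by_feat[j]` lists the non-missing rows for
// feature j in non-decreasing value order (numeric features only need the
// order; categorical arrays are unordered)
struct NodeRows {
  std::vector<int> rows;
  std::vector<std::vector<int> > by_feat;
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  const IntegerVector &ncat;
  int K;
  int minbucket;
  int maxdepth;
  std::vector<Node> nodes;
  std::vector<signed char> side; // scratch: per-row split side

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_,
              const IntegerVector &ncat_, int K_, int minbucket_, int maxdepth_)
      : X(X_), y(y_), ncat(ncat_), K(K_), minbucket(minbucket_ < 1 ? 1 : minbucket_),
        maxdepth(maxdepth_), xlog(xlog_table(X_.nrow() + 1)) {}

  // class counts are always integers, so entropy reduces to lookups in a
  // cached x*log2(x) table: H = (xlog[T] - sum xlog[c]) / T
  static const double *xlog_table(int upto) {
    static std::vector<double> t(2, 0.0);
    while ((int)t.size() <= upto) {
      int i = (int)t.size();
      t.push_back((double)i * std::log2((double)i));
    }
    return t.data();
  }

  const double *xlog;

  double entropy(const std::vector<double> &cnt, double total) const {
    int T = (int)(total + 0.5);
    if (T <= 0) return 0.0;
    double s = 0.0;
    for (double c : cnt) s += xlog[(int)(c + 0.5)];
    return (xlog[T] - s) / (double)T;
  }

  int build(NodeRows &nr, int depth) {
    Node nd;
    nd.feature = -1; nd.threshold = NA_REAL; nd.catmask = 0;
    nd.left = nd.right = -1; nd.miss_branch = 0;
    nd.n = (int)nr.rows.size();
    nd.dist.assign(K, 0.0);
    for (int i : nr.rows) nd.dist[y[i]] += 1.0;
    nd.pred = (int)(std::max_element(nd.dist.begin(), nd.dist.end()) - nd.dist.begin());

    double node_h = entropy(nd.dist, (double)nd.n);
    bool pure = nd.dist[nd.pred] == (double)nd.n;
    if (pure || nd.n < 2 * minbucket || depth >= maxdepth || node_h <= 0) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    unsigned int best_mask = 0;
    int d = X.ncol();
    std::vector<double> tot(K), lc(K), rc(K);

    for (int f = 0; f < d; ++f) {
      const std::vector<int> &fi = nr.by_feat[f];
      int m = (int)fi.size();
      if (m < 2 * minbucket) continue;
      double frac = (double)m / (double)nd.n; // C4.5 missing-value damping
      std::fill(tot.begin(), tot.end(), 0.0);
      for (int i : fi) tot[y[i]] += 1.0;
      double h_all = entropy(tot, (double)m);
      if (h_all <= 0) continue;

      if (ncat[f] == 0) {
        // best threshold for this feature, with the MDL correction for
        // continuous splits: gain is reduced by log2(#thresholds)/m, the
        // description cost of transmitting which cut was chosen. The
        // left/right xlog sums are maintained incrementally, so each row
        // costs a handful of table lookups.
        std::fill(lc.begin(), lc.end(), 0.0);
        for (int k = 0; k < K; ++k) rc[k] = tot[k];
        double slc = 0.0, src = 0.0;
        for (int k = 0; k < K; ++k) src += xlog[(int)(tot[k] + 0.5)];
        double feat_gain = -1.0, feat_thr = 0.0;
        int n_thresh = 0;
        const double *xf = &X(0, f);
        const int *yp = &y[0];
        for (int q = 0; q + 1 < m; ++q) {
          int cls = yp[fi[q]];
          int l0 = (int)(lc[cls] + 0.5), r0 = (int)(rc[cls] + 0.5);
          slc += xlog[l0 + 1] - xlog[l0];
          src += xlog[r0 - 1] - xlog[r0];
          lc[cls] += 1.0; rc[cls] -= 1.0;
          double v = xf[fi[q]], vn = xf[fi[q + 1]];
          if (v == vn) continue;
          ++n_thresh;
          int nl = q + 1, nr_ = m - nl;
          if (nl < minbucket || nr_ < minbucket) continue;
          // m*h = nl*H_left + nr*H_right via the xlog identity
          double mh = (xlog[nl] - slc) + (xlog[nr_] - src);
          double gain = frac * (h_all - mh / m);
          if (gain > feat_gain) {
            feat_gain = gain;
            feat_thr = v + (vn - v) / 2.0;
          }
        }
        if (n_thresh > 0 && feat_gain > 0) {
          double adj = feat_gain - std::log2((double)n_thresh) / (double)m;
          if (adj > best_gain) {
            best_gain = adj; best_f = f; best_thr = feat_thr; best_mask = 0;
          }
        }
      } else {
        int k_f = ncat[f];
        if (k_f > 20) continue; // degenerate cardinality; skip
        std::vector<double> cc((size_t)k_f * K, 0.0), csz(k_f, 0.0);
        for (int i : fi) {
          int code = (int)X(i, f) - 1;
          if (code < 0 || code >= k_f) continue;
          cc[(size_t)code * K + y[i]] += 1.0;
          csz[code] += 1.0;
        }
        unsigned int lim = 1u << (k_f - 1); // complement-free enumeration
        double feat_gain = -1.0;
        unsigned int feat_mask = 0;
        for (unsigned int mask = 1; mask < lim; ++mask) {
          std::fill(lc.begin(), lc.end(), 0.0);
          double nl = 0;
          for (int c = 0; c < k_f; ++c)
            if (mask & (1u << c)) {
              nl += csz[c];
              for (int k = 0; k < K; ++k) lc[k] += cc[(size_t)c * K + k];
            }
          double nr_ = m - nl;
          if (nl < minbucket || nr_ < minbucket) continue;
          for (int k = 0; k < K; ++k) rc[k] = tot[k] - lc[k];
          double h = (nl * entropy(lc, nl) + nr_ * entropy(rc, nr_)) / m;
          double gain = frac * (h_all - h);
          if (gain > feat_gain) { feat_gain = gain; feat_mask = mask; }
        }
        if (feat_gain > 0) {
          // MDL cost of naming one of the 2^(k-1)-1 category bipartitions
          double adj = feat_gain - std::log2((double)(lim - 1)) / (double)m;
          if (adj > best_gain) {
            best_gain = adj; best_f = f; best_mask = feat_mask;
            best_thr = NA_REAL;
          }
        }
      }
    }

    if (best_f < 0) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }

    // side of the split, computed once per row then reused for every
    // per-feature array partition: 0 left, 1 right, -1 missing
    const bool cat_split = ISNAN(best_thr);
    const double thr = best_thr;
    const unsigned int cmask = best_mask;
    const int bf = best_f;
    if ((int)side.size() < X.nrow()) side.assign(X.nrow(), 0);
    const double *xbf = &X(0, bf);
    int nl_cnt = 0, nr_cnt = 0, nm_cnt = 0;
    for (int i : nr.rows) {
      double v = xbf[i];
      int s;
      if (ISNAN(v)) s = -1;
      else s = (cat_split ? (((cmask >> ((int)v - 1)) & 1u) != 0)
                          : (v <= thr)) ? 0 : 1;
      side[i] = (signed char)s;
      if (s == 0) ++nl_cnt; else if (s == 1) ++nr_cnt; else ++nm_cnt;
    }
    int miss_branch = (nl_cnt >= nr_cnt) ? 0 : 1;
    int nl_tot = nl_cnt + (miss_branch == 0 ? nm_cnt : 0);
    int nr_tot = nr_cnt + (miss_branch == 1 ? nm_cnt : 0);
    if (nl_tot < minbucket || nr_tot < minbucket) {
      nodes.push_back(nd);
      return (int)nodes.size() - 1;
    }
    if (nm_cnt > 0) {
      for (int i : nr.rows) if (side[i] < 0) side[i] = (signed char)miss_branch;
    }

    // stable partition of every per-feature array
    NodeRows L, R;
    L.rows.reserve(nl_tot); R.rows.reserve(nr_tot);
    for (int i : nr.rows) (side[i] == 0 ? L.rows : R.rows).push_back(i);
    L.by_feat.resize(d); R.by_feat.resize(d);
    for (int f = 0; f < d; ++f) {
      const std::vector<int> &fi = nr.by_feat[f];
      std::vector<int> &lf = L.by_feat[f];
      std::vector<int> &rf = R.by_feat[f];
      lf.reserve(fi.size()); rf.reserve(fi.size());
      for (int i : fi) (side[i] == 0 ? lf : rf).push_back(i);
    }
    { NodeRows tmp; tmp.by_feat.swap(nr.by_feat); tmp.rows.swap(nr.rows); } // free parent

    nd.feature = best_f; nd.threshold = best_thr; nd.catmask = best_mask;
    nd.miss_branch = miss_branch;
    nodes.push_back(nd);
    int self = (int)nodes.size() - 1;
    int l = build(L, depth + 1);
    int r = build(R, depth + 1);
    nodes[self].left = l;
    nodes[self].right = r;
    return self;
  }
};

// global per-feature sort of all n rows (non-missing only), reused across
// the bootstrap replicates of one evaluation
std::vector<std::vector<int> > presort(const NumericMatrix &X,
                                       const IntegerVector &ncat) {
  int n = X.nrow(), d = X.ncol();
  std::vector<std::vector<int> > ord(d);
  for (int f = 0; f < d; ++f) {
    std::vector<int> &o = ord[f];
    o.reserve(n);
    for (int i = 0; i < n; ++i)
      if (!ISNAN(X(i, f))) o.push_back(i);
    if (ncat[f] == 0) {
      std::stable_sort(o.begin(), o.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
    }
  }
  return ord;
}

// root NodeRows for a multiset of rows given by multiplicity counts
NodeRows root_rows(const std::vector<std::vector<int> > &ord,
                   const std::vector<int> &mult, const std::vector<int> &rows) {
  NodeRows nr;
  nr.rows = rows;
  nr.by_feat.resize(ord.size());
  for (size_t f = 0; f < ord.size(); ++f) {
    std::vector<int> &o = nr.by_feat[f];
    o.reserve(rows.size());
    for (int i : ord[f])
      for (int t = 0; t < mult[i]; ++t) o.push_back(i);
  }
  return nr;
}

// C4.5 upper confidence limit on the error count of a leaf seeing N cases
// with E errors (inverse binomial tail at confidence cf).
double ucb_errors(double E, double N, double cf) {
  if (N <= 0) return 0.0;
  if (E >= N) return N;
  double p;
  if (E <= 0) p = 1.0 - std::pow(cf, 1.0 / N);
  else p = R::qbeta(1.0 - cf, E + 1.0, N - E, 1, 0);
  return N * p;
}

// bottom-up pessimistic pruning; returns estimated subtree errors
double prune_rec(std::vector<Node> &nodes, int id, double cf) {
  Node &nd = nodes[id];
  double n_err = nd.n - nd.dist[nd.pred];
  double leaf_est = ucb_errors(n_err, nd.n, cf);
  if (nd.feature < 0) return leaf_est;
  double sub = prune_rec(nodes, nd.left, cf) + prune_rec(nodes, nd.right, cf);
  if (leaf_est <= sub + 0.1) { // collapse to leaf
    nd.feature = -1; nd.left = nd.right = -1;
    return leaf_est;
  }
  return sub;
}

// leaf node index for one row (NaN follows the majority branch)
int predict_node(const std::vector<Node> &nodes, const NumericMatrix &X,
                 int row) {
  int id = 0;
  while (nodes[id].feature >= 0) {
    const Node &nd = nodes[id];
    double v = X(row, nd.feature);
    bool go_left;
    if (ISNAN(v)) go_left = (nd.miss_branch == 0);
    else if (ISNAN(nd.threshold))
      go_left = ((nd.catmask >> ((int)v - 1)) & 1u) != 0;
    else go_left = (v <= nd.threshold);
    id = go_left ? nd.left : nd.right;
  }
  return id;
}

// deterministic 64-bit RNG (splitmix64), independent of R's RNG stream
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

} // namespace

// Fast path for the wrapper merit of a feature subset under the C4.5
// learner: stratified-fold CV (fold ids supplied) of a B-member bagged tree
// ensemble, majority vote with a class-prior tie-break, mean fold accuracy.
// [[Rcpp::export(name = ".c45_merit_cpp")]]
double c45_merit_cpp(NumericMatrix M, IntegerVector y, IntegerVector ncat,
                     int nclass, IntegerVector cols, IntegerVector fold_id,
                     int B, int minbucket, int maxdepth, bool prune,
                     double cf, NumericVector priors, double seed) {
  int n = M.nrow();
  int m = (int)cols.size();
  // column-subset copy once per evaluation
  NumericMatrix S(n, m);
  IntegerVector nc(m);
  for (int j = 0; j < m; ++j) {
    int c = cols[j];
    nc[j] = ncat[c];
    for (int i = 0; i < n; ++i) S(i, j) = M(i, c);
  }
  std::vector<std::vector<int> > ord = presort(S, nc);
  int k = 0;
  for (int i = 0; i < n; ++i) k = std::max(k, fold_id[i]);
  SplitMix rng((uint64_t)seed * 0x2545F4914F6CDD1DULL + 0x9e3779b9ULL);
  double acc_sum = 0.0;
  std::vector<int> train, test, mult(n), boot;
  for (int f = 1; f <= k; ++f) {
    train.clear(); test.clear();
    for (int i = 0; i < n; ++i) {
      if (fold_id[i] == f) test.push_back(i); else train.push_back(i);
    }
    int nt = (int)train.size();
    std::vector<double> votes((size_t)test.size() * nclass, 0.0);
    for (int b = 0; b < B; ++b) {
      for (int attempt = 0; attempt < 20; ++attempt) {
        boot.clear();
        std::fill(mult.begin(), mult.end(), 0);
        for (int i = 0; i < nt; ++i) {
          int r = train[rng.below(nt)];
          boot.push_back(r);
          ++mult[r];
        }
        int first = y[boot[0]];
        bool two = false;
        for (int i = 1; i < nt; ++i) if (y[boot[i]] != first) { two = true; break; }
        if (two) break;
      }
      TreeBuilder tb(S, y, nc, nclass, minbucket, maxdepth);
      NodeRows nr = root_rows(ord, mult, boot);
      tb.build(nr, 0);
      if (prune) prune_rec(tb.nodes, 0, cf);
      for (size_t t = 0; t < test.size(); ++t) {
        int leaf = predict_node(tb.nodes, S, test[t]);
        votes[t * nclass + tb.nodes[leaf].pred] += 1.0;
      }
    }
    int correct = 0;
    for (size_t t = 0; t < test.size(); ++t) {
      int best = 0;
      double bv = -1.0;
      for (int c = 0; c < nclass; ++c) {
        double v = votes[t * nclass + c] + 0.5 * priors[c];
        if (v > bv) { bv = v; best = c; }
      }
      if (best == y[test[t]]) ++correct;
    }
    acc_sum += test.empty() ? 0.0 : (double)correct / (double)test.size();
  }
  return acc_sum / (double)k;
}

// [[Rcpp::export(name = ".c45_fit_cpp")]]
List c45_fit_cpp(NumericMatrix X, IntegerVector y, IntegerVector ncat,
                 int nclass, int minbucket, int maxdepth, bool prune,
                 double cf) {
  int n = X.nrow();
  if (n == 0) stop("no rows to fit");
  TreeBuilder tb(X, y, ncat, nclass, minbucket, maxdepth);
  std::vector<std::vector<int> > ord = presort(X, ncat);
  std::vector<int> mult(n, 1), rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  NodeRows nr = root_rows(ord, mult, rows);
  tb.build(nr, 0);
  if (prune) prune_rec(tb.nodes, 0, cf);

  int nn = (int)tb.nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), pred(nn), miss(nn), nrow_(nn);
  NumericVector threshold(nn), catmask(nn);
  NumericMatrix dist(nn, nclass);
  for (int i = 0; i < nn; ++i) {
    const Node &nd = tb.nodes[i];
    feature[i] = nd.feature + 1; // 1-based, 0 = leaf
    threshold[i] = nd.threshold;
    catmask[i] = (double)nd.catmask;
    left[i] = nd.left + 1;
    right[i] = nd.right + 1;
    pred[i] = nd.pred + 1;
    miss[i] = nd.miss_branch;
    nrow_[i] = nd.n;
    for (int k = 0; k < nclass; ++k) dist(i, k) = nd.dist[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["catmask"] = catmask, _["left"] = left,
                      _["right"] = right, _["pred"] = pred,
                      _["miss_branch"] = miss, _["n"] = nrow_,
                      _["dist"] = dist);
}

// [[Rcpp::export(name = ".c45_predict_cpp")]]
List c45_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"], pred = tree["pred"],
                miss = tree["miss_branch"];
  NumericVector threshold = tree["threshold"], catmask = tree["catmask"];
  NumericMatrix dist = tree["dist"];
  int n = X.nrow(), K = dist.ncol();
  IntegerVector out(n);
  NumericMatrix prob(n, K);
  for (int i = 0; i < n; ++i) {
    int id = 0;
    while (feature[id] != 0) {
      int f = feature[id] - 1;
      double v = X(i, f);
      bool go_left;
      if (ISNAN(v)) go_left = (miss[id] == 0);
      else if (ISNAN(threshold[id]))
        go_left = (((unsigned int)catmask[id] >> ((int)v - 1)) & 1u) != 0;
      else go_left = (v <= threshold[id]);
      id = (go_left ? left[id] : right[id]) - 1;
    }
    out[i] = pred[id];
    double tot = 0;
    for (int k = 0; k < K; ++k) tot += dist(id, k);
    for (int k = 0; k < K; ++k) prob(i, k) = tot > 0 ? dist(id, k) / tot : 1.0 / K;
  }
  return List::create(_["class"] = out, _["prob"] = prob);
}
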