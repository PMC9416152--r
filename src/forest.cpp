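// Random-forest core: bootstrap-aggregated binary classification trees with
// Gini-impurity splitting, out-of-bag voting and per-node impurity-decrease
// bookkeeping. A self-contained SplitMix64 generator gives per-tree streams
// derived from one master seed, so results are bit-reproducible and
// independent of execution order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t sm64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) sm64(s);
  }
  double unif() { return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int r = (int)(unif() * n);
    return r >= n ? n - 1 : r;
  }
};

// n * Gini(a, b) = (a+b) - (a^2 + b^2) / (a+b); weighted node impurity.
static inline double ng(double a, double b) {
  double n = a + b;
  if (n <= 0.0) return 0.0;
  return n - (a * a + b * b) / n;
}

struct Tree {
  std::vector<int> var;        // 1-based split predictor; NA for leaf
  std::vector<double> thr;
  std::vector<int> left, right; // 1-based child node ids; NA for leaf
  std::vector<int> n0, n1;      // class counts of bagged samples at node
  std::vector<int> pred;        // majority class (ties -> 1)
};

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  int p, mtry, min_node_size;
  Rng &rng;
  Tree t;
  std::vector<double> &imp;     // accumulated impurity decrease per predictor
  std::vector<int> cand;        // scratch for predictor sampling

  Grower(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
         int min_node_size_, Rng &rng_, std::vector<double> &imp_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_),
        min_node_size(min_node_size_), rng(rng_), imp(imp_), cand(p) {}

  int new_node(int c0, int c1) {
    t.var.push_back(NA_INTEGER);
    t.thr.push_back(NA_REAL);
    t.left.push_back(NA_INTEGER);
    t.right.push_back(NA_INTEGER);
    t.n0.push_back(c0);
    t.n1.push_back(c1);
    t.pred.push_back(c1 >= c0 ? 1 : 0);
    return (int)t.var.size() - 1;
  }

  int grow(std::vector<int> &bag) {
    int c0 = 0, c1 = 0;
    for (int i : bag) (y[i] == 1) ? ++c1 : ++c0;
    int id = new_node(c0, c1);
    int n = c0 + c1;
    if (c0 == 0 || c1 == 0 || n < 2 * min_node_size || n < 2) return id;

    // sample mtry distinct predictors, then scan them in ascending id order
    // so quality ties break toward the lowest predictor id
    for (int j = 0; j < p; ++j) cand[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + rng.below(p - j);
      std::swap(cand[j], cand[k]);
    }
    std::sort(cand.begin(), cand.begin() + m);

    double parent = ng((double)c0, (double)c1);
    double best_dec = 0.0, best_thr = 0.0;
    int best_var = -1;
    std::vector<std::pair<double, int> > xv(n);
    for (int j = 0; j < m; ++j) {
      int v = cand[j];
      for (int k = 0; k < n; ++k) xv[k] = std::make_pair(X(bag[k], v), y[bag[k]]);
      std::sort(xv.begin(), xv.end());
      int l0 = 0, l1 = 0;
      for (int k = 0; k < n - 1; ++k) {
        (xv[k].second == 1) ? ++l1 : ++l0;
        if (xv[k + 1].first <= xv[k].first) continue;  // not a value boundary
        int nl = l0 + l1, nr = n - nl;
        if (nl < min_node_size || nr < min_node_size) continue;
        double dec = parent - ng((double)l0, (double)l1) -
                     ng((double)(c0 - l0), (double)(c1 - l1));
        if (dec > best_dec + 1e-12) {
          best_dec = dec;
          best_var = v;
          best_thr = 0.5 * (xv[k].first + xv[k + 1].first);
        }
      }
    }
    if (best_var < 0) return id;  // no admissible impurity-reducing split

    std::vector<int> lbag, rbag;
    lbag.reserve(n); rbag.reserve(n);
    for (int i : bag) {
      (X(i, best_var) <= best_thr ? lbag : rbag).push_back(i);
    }
    imp[best_var] += best_dec;
    t.var[id] = best_var + 1;
    t.thr[id] = best_thr;
    int lid = grow(lbag);
    int rid = grow(rbag);
    t.left[id] = lid + 1;
    t.right[id] = rid + 1;
    return id;
  }
};

static int predict_one(const Tree &t, const NumericMatrix &X, int i) {
  int node = 0;
  while (t.var[node] != NA_INTEGER) {
    node = (X(i, t.var[node] - 1) <= t.thr[node]) ? t.left[node] - 1
                                                  : t.right[node] - 1;
  }
  return t.pred[node];
}

static List tree_to_list(const Tree &t) {
  return List::create(_["var"] = wrap(t.var), _["threshold"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["n0"] = wrap(t.n0), _["n1"] = wrap(t.n1),
                      _["pred"] = wrap(t.pred));
}

static uint64_t tree_seed(double seed, int tree_index) {
  uint64_t s = (uint64_t)(int64_t)seed;
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  s ^= (uint64_t)(tree_index + 1) * 0x9E3779B97F4A7C15ULL;
  return s;
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int min_node_size, int bootstrap_size, double seed) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> imp(p, 0.0);
  IntegerMatrix votes(n, 2);
  List trees(n_trees);
  std::vector<int> in_bag(n);
  for (int tr = 0; tr < n_trees; ++tr) {
    Rng rng(tree_seed(seed, tr));
    std::fill(in_bag.begin(), in_bag.end(), 0);
    std::vector<int> bag(bootstrap_size);
    for (int b = 0; b < bootstrap_size; ++b) {
      int i = rng.below(n);
      bag[b] = i;
      in_bag[i] = 1;
    }
    Grower g(X, y, mtry, min_node_size, rng, imp);
    g.grow(bag);
    for (int i = 0; i < n; ++i) {
      if (!in_bag[i]) votes(i, predict_one(g.t, X, i)) += 1;
    }
    trees[tr] = tree_to_list(g.t);
  }
  NumericVector importance(p);
  for (int j = 0; j < p; ++j) importance[j] = imp[j] / n_trees;
  return List::create(_["trees"] = trees, _["oob_votes"] = votes,
                      _["importance"] = importance);
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector bag1,
                   int mtry, int min_node_size, double seed) {
  std::vector<double> imp(X.ncol(), 0.0);
  Rng rng(tree_seed(seed, 0));
  Grower g(X, y, mtry, min_node_size, rng, imp);
  std::vector<int> bag(bag1.size());
  for (int k = 0; k < bag1.size(); ++k) bag[k] = bag1[k] - 1;
  g.grow(bag);
  return tree_to_list(g.t);
}

// [[Rcpp::export]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X) {
  Tree t;
  t.var = as<std::vector<int> >(tree["var"]);
  t.thr = as<std::vector<double> >(tree["threshold"]);
  t.left = as<std::vector<int> >(tree["left"]);
  t.right = as<std::vector<int> >(tree["right"]);
  t.pred = as<std::vector<int> >(tree["pred"]);
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = predict_one(t, X, i);
  return out;
}
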