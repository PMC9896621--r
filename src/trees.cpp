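// Decision-tree ensembles used by the learner panel and as the genetic
// search's fitness engine. Split search is histogram-based: every column is
// binned once (<= nbins quantile bins) so that evaluating a node costs
// O(rows + bins) per feature. Recorded split thresholds are raw values, so
// fitted models predict directly on unbinned matrices.
#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct BinnedMatrix {
  std::vector<int> bins;              // column-major n * p
  std::vector<std::vector<double>> thr; // thr[f][b]: x <= thr[f][b] <=> bin <= b
  int n, p;
  int bin(int i, int f) const { return bins[(size_t)f * n + i]; }
};

BinnedMatrix bin_matrix(const NumericMatrix& X, int nbins) {
  BinnedMatrix B;
  B.n = X.nrow();
  B.p = X.ncol();
  B.bins.resize((size_t)B.n * B.p);
  B.thr.resize(B.p);
  std::vector<double> v(B.n);
  for (int f = 0; f < B.p; ++f) {
    for (int i = 0; i < B.n; ++i) v[i] = X(i, f);
    // fast path for small-integer columns (0/1 bits, prebinned indices):
    // no sorting, just a presence histogram
    {
      bool small_int = true;
      int vmax = -1;
      for (int i = 0; i < B.n; ++i) {
        const double x = v[i];
        if (x < 0 || x > 255 || x != std::floor(x)) { small_int = false; break; }
        vmax = std::max(vmax, (int)x);
      }
      if (small_int) {
        std::vector<char> present(vmax + 1, 0);
        for (int i = 0; i < B.n; ++i) present[(int)v[i]] = 1;
        std::vector<int> vals;
        for (int u = 0; u <= vmax; ++u)
          if (present[u]) vals.push_back(u);
        if ((int)vals.size() <= nbins) {
          std::vector<int> bin_of(vmax + 1, 0);
          std::vector<double> edges;
          for (size_t k = 0; k < vals.size(); ++k) {
            bin_of[vals[k]] = (int)k;
            if (k + 1 < vals.size())
              edges.push_back(0.5 * (vals[k] + vals[k + 1]));
          }
          B.thr[f] = edges;
          for (int i = 0; i < B.n; ++i)
            B.bins[(size_t)f * B.n + i] = bin_of[(int)v[i]];
          continue;
        }
      }
    }
    std::vector<double> u(v);
    std::sort(u.begin(), u.end());
    u.erase(std::unique(u.begin(), u.end()), u.end());
    std::vector<double> edges; // upper-inclusive edge per bin except last
    if ((int)u.size() <= nbins) {
      for (size_t k = 0; k + 1 < u.size(); ++k)
        edges.push_back(0.5 * (u[k] + u[k + 1]));
    } else {
      for (int b = 1; b < nbins; ++b) {
        size_t q = (size_t)((double)b / nbins * u.size());
        if (q >= u.size() - 1) q = u.size() - 2;
        edges.push_back(0.5 * (u[q] + u[q + 1]));
      }
      edges.erase(std::unique(edges.begin(), edges.end()), edges.end());
    }
    B.thr[f] = edges;
    for (int i = 0; i < B.n; ++i) {
      // first edge >= value; splits are "x <= edge goes left", so values
      // equal to an edge belong to that edge's bin
      const int b = (int)(std::lower_bound(edges.begin(), edges.end(), v[i]) -
                          edges.begin());
      B.bins[(size_t)f * B.n + i] = b;
    }
  }
  return B;
}

struct FlatTree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<double> value;          // gbt leaf weight
  std::vector<std::vector<double>> dist; // rf leaf class distribution
};

// ---------- gradient boosting (binary logistic) ----------

void gbt_grow(const BinnedMatrix& B, const std::vector<double>& g,
              const std::vector<double>& h, std::vector<int>& rows,
              int depth_left, double lambda, double min_hess, FlatTree& T,
              int& node_out) {
  double G = 0, H = 0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  int node = (int)T.feature.size();
  node_out = node;
  T.feature.push_back(-1);
  T.thresh.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(-G / (H + lambda));
  if (depth_left <= 0 || rows.size() < 2) return;

  const double parent_score = G * G / (H + lambda);
  double best_gain = 1e-12;
  int best_f = -1, best_b = -1;
  std::vector<double> Gb, Hb;
  for (int f = 0; f < B.p; ++f) {
    const int nb = (int)B.thr[f].size() + 1;
    if (nb < 2) continue;
    Gb.assign(nb, 0.0);
    Hb.assign(nb, 0.0);
    for (int r : rows) { int b = B.bin(r, f); Gb[b] += g[r]; Hb[b] += h[r]; }
    double GL = 0, HL = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      GL += Gb[b]; HL += Hb[b];
      const double GR = G - GL, HR = H - HL;
      if (HL < min_hess || HR < min_hess) continue;
      const double gain =
          GL * GL / (HL + lambda) + GR * GR / (HR + lambda) - parent_score;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_b = b; }
    }
  }
  if (best_f < 0) return;

  std::vector<int> lrows, rrows;
  for (int r : rows)
    (B.bin(r, best_f) <= best_b ? lrows : rrows).push_back(r);
  if (lrows.empty() || rrows.empty()) return;
  rows.clear();
  rows.shrink_to_fit();

  T.feature[node] = best_f;
  T.thresh[node] = B.thr[best_f][best_b];
  int lid, rid;
  gbt_grow(B, g, h, lrows, depth_left - 1, lambda, min_hess, T, lid);
  gbt_grow(B, g, h, rrows, depth_left - 1, lambda, min_hess, T, rid);
  T.left[node] = lid;
  T.right[node] = rid;
}

double tree_predict_one(const FlatTree& T, const NumericMatrix& X, int i) {
  int node = 0;
  while (T.feature[node] >= 0)
    node = (X(i, T.feature[node]) <= T.thresh[node]) ? T.left[node]
                                                     : T.right[node];
  return T.value[node];
}

NumericMatrix flatten(const FlatTree& T) {
  const int n = (int)T.feature.size();
  NumericMatrix M(n, 5);
  for (int i = 0; i < n; ++i) {
    M(i, 0) = T.feature[i];
    M(i, 1) = T.thresh[i];
    M(i, 2) = T.left[i];
    M(i, 3) = T.right[i];
    M(i, 4) = T.value[i];
  }
  colnames(M) = CharacterVector::create("feature", "thresh", "left", "right",
                                        "value");
  return M;
}

FlatTree unflatten(const NumericMatrix& M) {
  FlatTree T;
  const int n = M.nrow();
  T.feature.resize(n); T.thresh.resize(n);
  T.left.resize(n); T.right.resize(n); T.value.resize(n);
  for (int i = 0; i < n; ++i) {
    T.feature[i] = (int)M(i, 0);
    T.thresh[i] = M(i, 1);
    T.left[i] = (int)M(i, 2);
    T.right[i] = (int)M(i, 3);
    T.value[i] = M(i, 4);
  }
  return T;
}

std::vector<FlatTree> gbt_fit_core(const BinnedMatrix& B,
                                   const NumericMatrix& X,
                                   const std::vector<double>& y,
                                   const std::vector<int>& use_rows,
                                   int nrounds, int max_depth, double eta,
                                   double lambda, double min_hess,
                                   double base) {
  const size_t n = use_rows.size();
  std::vector<double> margin(n, base), g(B.n), h(B.n);
  std::vector<FlatTree> trees;
  trees.reserve(nrounds);
  for (int round = 0; round < nrounds; ++round) {
    for (size_t k = 0; k < n; ++k) {
      const int r = use_rows[k];
      const double p = 1.0 / (1.0 + std::exp(-margin[k]));
      g[r] = p - y[k];
      h[r] = std::max(p * (1.0 - p), 1e-12);
    }
    FlatTree T;
    int root;
    std::vector<int> rows(use_rows);
    gbt_grow(B, g, h, rows, max_depth, lambda, min_hess, T, root);
    for (size_t k = 0; k < n; ++k)
      margin[k] += eta * tree_predict_one(T, X, use_rows[k]);
    trees.push_back(std::move(T));
  }
  return trees;
}

double logit(double p) {
  p = std::min(std::max(p, 1e-6), 1.0 - 1e-6);
  return std::log(p / (1.0 - p));
}

} // namespace

// Replace every column by its bin index (quantile bins, <= nbins levels).
// Trees grown on the result are identical to trees grown on the raw data up
// to threshold relabeling, so a matrix can be prebinned once and column
// subsets of it evaluated cheaply (the small-integer fast path above).
// [[Rcpp::export]]
NumericMatrix cpp_prebin(NumericMatrix X, int nbins) {
  BinnedMatrix B = bin_matrix(X, nbins);
  NumericMatrix out(B.n, B.p);
  for (int f = 0; f < B.p; ++f)
    for (int i = 0; i < B.n; ++i) out(i, f) = B.bin(i, f);
  colnames(out) = colnames(X);
  return out;
}

// [[Rcpp::export]]
List cpp_gbt_fit(NumericMatrix X, NumericVector y, int nrounds, int max_depth,
                 double eta, double lambda, int nbins, double min_hess) {
  BinnedMatrix B = bin_matrix(X, nbins);
  std::vector<int> rows(X.nrow());
  std::vector<double> yy(X.nrow());
  double mean = 0;
  for (int i = 0; i < X.nrow(); ++i) {
    rows[i] = i;
    yy[i] = y[i];
    mean += y[i];
  }
  mean /= X.nrow();
  const double base = logit(mean);
  std::vector<FlatTree> trees = gbt_fit_core(B, X, yy, rows, nrounds,
                                             max_depth, eta, lambda, min_hess,
                                             base);
  List tl(trees.size());
  for (size_t t = 0; t < trees.size(); ++t) tl[t] = flatten(trees[t]);
  return List::create(_["trees"] = tl, _["base"] = base, _["eta"] = eta);
}

// [[Rcpp::export]]
NumericVector cpp_gbt_predict(List model, NumericMatrix X) {
  List tl = model["trees"];
  const double base = as<double>(model["base"]);
  const double eta = as<double>(model["eta"]);
  std::vector<FlatTree> trees;
  for (int t = 0; t < tl.size(); ++t)
    trees.push_back(unflatten(as<NumericMatrix>(tl[t])));
  NumericVector out(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) {
    double m = base;
    for (const FlatTree& T : trees) m += eta * tree_predict_one(T, X, i);
    out[i] = 1.0 / (1.0 + std::exp(-m));
  }
  return out;
}

// Binary Cohen's kappa of 0.5-thresholded out-of-fold predictions; the hot
// path of the genetic feature search (called thousands of times per run).
// fold: 0-based fold id per row.
// [[Rcpp::export]]
double cpp_gbt_cv_kappa(NumericMatrix X, NumericVector y, IntegerVector fold,
                        int nrounds, int max_depth, double eta, double lambda,
                        int nbins, double min_hess) {
  const int n = X.nrow();
  BinnedMatrix B = bin_matrix(X, nbins);
  int nfold = 0;
  for (int i = 0; i < n; ++i) nfold = std::max(nfold, fold[i] + 1);
  std::vector<int> pred(n, 0);
  for (int k = 0; k < nfold; ++k) {
    std::vector<int> tr_rows;
    std::vector<double> tr_y;
    double mean = 0;
    for (int i = 0; i < n; ++i)
      if (fold[i] != k) {
        tr_rows.push_back(i);
        tr_y.push_back(y[i]);
        mean += y[i];
      }
    if (tr_rows.empty()) continue;
    mean /= tr_rows.size();
    const double base = logit(mean);
    std::vector<FlatTree> trees = gbt_fit_core(
        B, X, tr_y, tr_rows, nrounds, max_depth, eta, lambda, min_hess, base);
    for (int i = 0; i < n; ++i) {
      if (fold[i] != k) continue;
      double m = base;
      for (const FlatTree& T : trees) m += eta * tree_predict_one(T, X, i);
      pred[i] = m > 0 ? 1 : 0;
    }
  }
  double c[2][2] = {{0, 0}, {0, 0}};
  for (int i = 0; i < n; ++i) c[(int)y[i]][pred[i]] += 1.0;
  const double N = n;
  const double p0 = (c[0][0] + c[1][1]) / N;
  const double pe = ((c[0][0] + c[0][1]) * (c[0][0] + c[1][0]) +
                     (c[1][0] + c[1][1]) * (c[0][1] + c[1][1])) /
                    (N * N);
  if (std::abs(1.0 - pe) < 1e-12) return 0.0;
  return (p0 - pe) / (1.0 - pe);
}

// ---------- random forest (gini, multi-class) ----------

namespace {

void rf_grow(const BinnedMatrix& B, const std::vector<int>& y, int K,
             std::vector<int>& rows, int depth_left, int min_node, int mtry,
             std::mt19937& rng, FlatTree& T, int& node_out) {
  const int node = (int)T.feature.size();
  node_out = node;
  std::vector<double> counts(K, 0.0);
  for (int r : rows) counts[y[r]] += 1.0;
  const double total = (double)rows.size();
  T.feature.push_back(-1);
  T.thresh.push_back(0.0);
  T.left.push_back(-1);
  T.right.push_back(-1);
  T.value.push_back(0.0);
  std::vector<double> dist(K);
  for (int k = 0; k < K; ++k) dist[k] = counts[k] / total;
  T.dist.push_back(dist);

  int nonzero = 0;
  for (int k = 0; k < K; ++k) nonzero += counts[k] > 0;
  if (depth_left <= 0 || (int)rows.size() < 2 * min_node || nonzero < 2)
    return;

  double parent_gini = 1.0;
  for (int k = 0; k < K; ++k) parent_gini -= dist[k] * dist[k];

  std::vector<int> feats(B.p);
  for (int f = 0; f < B.p; ++f) feats[f] = f;
  std::shuffle(feats.begin(), feats.end(), rng);
  const int ntry = std::min(mtry, B.p);

  double best_gain = 1e-12;
  int best_f = -1, best_b = -1;
  std::vector<double> bc; // bin-class counts
  for (int fi = 0; fi < ntry; ++fi) {
    const int f = feats[fi];
    const int nb = (int)B.thr[f].size() + 1;
    if (nb < 2) continue;
    bc.assign((size_t)nb * K, 0.0);
    for (int r : rows) bc[(size_t)B.bin(r, f) * K + y[r]] += 1.0;
    std::vector<double> lc(K, 0.0);
    double ln = 0;
    for (int b = 0; b + 1 < nb; ++b) {
      for (int k = 0; k < K; ++k) { lc[k] += bc[(size_t)b * K + k]; }
      ln = 0;
      for (int k = 0; k < K; ++k) ln += lc[k];
      const double rn = total - ln;
      if (ln < min_node || rn < min_node) continue;
      double gl = 1.0, gr = 1.0;
      for (int k = 0; k < K; ++k) {
        const double pl = lc[k] / ln, pr = (counts[k] - lc[k]) / rn;
        gl -= pl * pl;
        gr -= pr * pr;
      }
      const double gain = parent_gini - (ln / total) * gl - (rn / total) * gr;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_b = b; }
    }
  }
  if (best_f < 0) return;
  std::vector<int> lrows, rrows;
  for (int r : rows)
    (B.bin(r, best_f) <= best_b ? lrows : rrows).push_back(r);
  if (lrows.empty() || rrows.empty()) return;
  rows.clear();
  rows.shrink_to_fit();
  T.feature[node] = best_f;
  T.thresh[node] = B.thr[best_f][best_b];
  int lid, rid;
  rf_grow(B, y, K, lrows, depth_left - 1, min_node, mtry, rng, T, lid);
  rf_grow(B, y, K, rrows, depth_left - 1, min_node, mtry, rng, T, rid);
  T.left[node] = lid;
  T.right[node] = rid;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int K, int ntree, int mtry,
                int max_depth, int min_node, int seed) {
  const int n = X.nrow();
  BinnedMatrix B = bin_matrix(X, 255);
  std::vector<int> yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[i];
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = pick(rng);
    FlatTree T;
    int root;
    rf_grow(B, yy, K, rows, max_depth, min_node, mtry, rng, T, root);
    const int nn = (int)T.feature.size();
    NumericMatrix M(nn, 4 + K);
    for (int i = 0; i < nn; ++i) {
      M(i, 0) = T.feature[i];
      M(i, 1) = T.thresh[i];
      M(i, 2) = T.left[i];
      M(i, 3) = T.right[i];
      for (int k = 0; k < K; ++k) M(i, 4 + k) = T.dist[i][k];
    }
    forest[t] = M;
  }
  return List::create(_["trees"] = forest, _["K"] = K);
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(List model, NumericMatrix X) {
  List forest = model["trees"];
  const int K = as<int>(model["K"]);
  const int n = X.nrow();
  NumericMatrix out(n, K);
  for (int t = 0; t < forest.size(); ++t) {
    NumericMatrix M = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)M(node, 0) >= 0)
        node = (X(i, (int)M(node, 0)) <= M(node, 1)) ? (int)M(node, 2)
                                                     : (int)M(node, 3);
      for (int k = 0; k < K; ++k) out(i, k) += M(node, 4 + k);
    }
  }
  const double nt = (double)forest.size();
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) out(i, k) /= nt;
  return out;
}
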