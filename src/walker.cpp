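#include <Rcpp.h>
using namespace Rcpp;

// Adjacency is CSR over 0-based node ids with neighbour lists sorted,
// so edge lookups are binary searches.

static inline bool has_edge(const IntegerVector& ptr, const IntegerVector& idx,
                            int u, int v) {
  int lo = ptr[u], hi = ptr[u + 1];
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (idx[mid] == v) return true;
    if (idx[mid] < v) lo = mid + 1; else hi = mid;
  }
  return false;
}

// Second-order biased random walks (node2vec rule): from current node cur
// with previous node prev, a neighbour x of cur has unnormalized weight
// 1/p if x == prev, 1 if x is adjacent to prev, 1/q otherwise. The first
// step of each walk is uniform over neighbours. Uses the R RNG so walks
// are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_biased_walks(IntegerVector adj_ptr, IntegerVector adj_idx,
                      double p, double q, int walk_length,
                      int walks_per_node) {
  int n = adj_ptr.size() - 1;
  List out(n * walks_per_node);
  int k = 0;
  std::vector<double> w;
  for (int start = 0; start < n; ++start) {
    int deg0 = adj_ptr[start + 1] - adj_ptr[start];
    for (int r = 0; r < walks_per_node; ++r) {
      if (deg0 == 0) { out[k++] = IntegerVector(0); continue; }
      IntegerVector walk(walk_length);
      walk[0] = start;
      int prev = -1, cur = start, len = 1;
      for (int step = 1; step < walk_length; ++step) {
        int lo = adj_ptr[cur], hi = adj_ptr[cur + 1];
        int deg = hi - lo;
        if (deg == 0) break;
        int nxt;
        if (prev < 0) {
          nxt = adj_idx[lo + (int)(unif_rand() * deg) % deg];
        } else {
          w.resize(deg);
          double tot = 0.0;
          for (int t = 0; t < deg; ++t) {
            int x = adj_idx[lo + t];
            double wt;
            if (x == prev) wt = 1.0 / p;
            else if (has_edge(adj_ptr, adj_idx, prev, x)) wt = 1.0;
            else wt = 1.0 / q;
            w[t] = wt;
            tot += wt;
          }
          double u = unif_rand() * tot, acc = 0.0;
          int pick = deg - 1;
          for (int t = 0; t < deg; ++t) {
            acc += w[t];
            if (u <= acc) { pick = t; break; }
          }
          nxt = adj_idx[lo + pick];
        }
        walk[step] = nxt;
        prev = cur;
        cur = nxt;
        ++len;
      }
      out[k++] = walk[Rcpp::Range(0, len - 1)];
    }
  }
  return out;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over walk corpora. noise_cdf is the
// cumulative unigram^0.75 distribution over 0-based node ids. Input and
// output vectors are updated with plain SGD and a linearly decaying
// learning rate (word2vec convention). Single-threaded; R RNG.
// [[Rcpp::export]]
NumericMatrix cpp_train_skipgram(List walks, int n_nodes, int dim,
                                 int window, int negatives, int epochs,
                                 double lr, NumericVector noise_cdf) {
  NumericMatrix W(n_nodes, dim);   // input (returned) vectors
  NumericMatrix C(n_nodes, dim);   // output/context vectors
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      W(i, d) = (unif_rand() - 0.5) / dim;

  long total = 0;
  for (int w = 0; w < walks.size(); ++w)
    total += ((IntegerVector)walks[w]).size();
  total *= epochs;
  long seen = 0;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < walks.size(); ++wi) {
      IntegerVector walk = walks[wi];
      int L = walk.size();
      for (int c = 0; c < L; ++c) {
        double alpha = lr * (1.0 - (double)seen / (double)(total + 1));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        ++seen;
        int center = walk[c];
        int lo = std::max(0, c - window);
        int hi = std::min(L - 1, c + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == c) continue;
          int context = walk[j];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int s = 0; s < negatives + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = context; label = 1.0; }
            else {
              double u = unif_rand();
              int a = 0, b = n_nodes - 1;
              while (a < b) {
                int mid = (a + b) / 2;
                if (noise_cdf[mid] < u) a = mid + 1; else b = mid;
              }
              target = a;
              if (target == context) continue;
              label = 0.0;
            }
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += W(center, d) * C(target, d);
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * C(target, d);
              C(target, d) += g * W(center, d);
            }
          }
          for (int d = 0; d < dim; ++d) W(center, d) += grad[d];
        }
      }
    }
  }
  return W;
}
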