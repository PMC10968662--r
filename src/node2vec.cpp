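// node2vec graph embedding: second-order biased random walks followed by
// skip-gram training with negative sampling. Single-threaded and fully
// deterministic for a given seed: all randomness comes from one
// std::mt19937 consumed through fixed arithmetic (no distribution
// objects, whose mappings vary across standard libraries).

#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const int EXP_TABLE_SIZE = 1000;
static const double MAX_EXP = 6.0;

namespace {

inline double rand_unit(std::mt19937 &rng) {
  // 32-bit uniform in [0, 1): ample granularity for sampling decisions
  return rng() * (1.0 / 4294967296.0);
}

inline int rand_below(std::mt19937 &rng, int n) {
  return static_cast<int>(rand_unit(rng) * n);
}

struct SigmoidTable {
  std::vector<double> tab;
  SigmoidTable() : tab(EXP_TABLE_SIZE) {
    for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
      double x = (2.0 * i / EXP_TABLE_SIZE - 1.0) * MAX_EXP;
      tab[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
  inline double operator()(double x) const {
    if (x >= MAX_EXP) return 1.0;
    if (x <= -MAX_EXP) return 0.0;
    int i = static_cast<int>((x + MAX_EXP) * (EXP_TABLE_SIZE / (2.0 * MAX_EXP)));
    if (i >= EXP_TABLE_SIZE) i = EXP_TABLE_SIZE - 1;
    return tab[i];
  }
};

inline bool has_edge(const std::vector<std::vector<int>> &nb, int u, int v) {
  const std::vector<int> &l = nb[u];
  return std::binary_search(l.begin(), l.end(), v);
}

} // namespace

// [[Rcpp::export]]
NumericMatrix node2vec_embed_cpp(List neighbors, int dim, int walk_length,
                                 int walks_per_node, int window,
                                 double p, double q, int negative,
                                 int epochs, int seed) {
  const int n = neighbors.size();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = neighbors[i];
    nb[i].assign(v.begin(), v.end());
    std::sort(nb[i].begin(), nb[i].end());
  }

  std::mt19937 rng(static_cast<uint32_t>(seed));
  const bool uniform_walk = (p == 1.0 && q == 1.0);

  // ---- generate walks --------------------------------------------------
  std::vector<std::vector<int>> walks;
  walks.reserve(static_cast<size_t>(n) * walks_per_node);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> wbuf;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    // fresh node order each pass
    for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rand_below(rng, i + 1)]);
    for (int oi = 0; oi < n; ++oi) {
      int start = order[oi];
      if (nb[start].empty()) continue;
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, cur = start;
      while ((int)walk.size() < walk_length) {
        const std::vector<int> &cands = nb[cur];
        if (cands.empty()) break;
        int nxt;
        if (uniform_walk || prev < 0) {
          nxt = cands[rand_below(rng, (int)cands.size())];
        } else {
          wbuf.resize(cands.size());
          double tot = 0.0;
          for (size_t k = 0; k < cands.size(); ++k) {
            int x = cands[k];
            double w = (x == prev) ? 1.0 / p
                       : (has_edge(nb, prev, x) ? 1.0 : 1.0 / q);
            wbuf[k] = w;
            tot += w;
          }
          double r = rand_unit(rng) * tot, acc = 0.0;
          size_t k = 0;
          for (; k < cands.size(); ++k) {
            acc += wbuf[k];
            if (r < acc) break;
          }
          if (k == cands.size()) k = cands.size() - 1;
          nxt = cands[k];
        }
        walk.push_back(nxt);
        prev = cur;
        cur = nxt;
      }
      if (walk.size() >= 2) walks.push_back(std::move(walk));
    }
  }

  // ---- unigram^0.75 negative-sampling table (O(1) draws) --------------
  std::vector<double> freq(n, 0.0);
  for (const auto &w : walks)
    for (int v : w) freq[v] += 1.0;
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    tot += (freq[i] > 0) ? std::pow(freq[i], 0.75) : 0.0;
  const int TABLE_SIZE = 1 << 20;
  std::vector<int> neg_table(TABLE_SIZE, 0);
  {
    int i = 0;
    double acc = (freq[0] > 0) ? std::pow(freq[0], 0.75) / tot : 0.0;
    for (int k = 0; k < TABLE_SIZE; ++k) {
      double frac = (k + 0.5) / TABLE_SIZE;
      while (frac > acc && i < n - 1) {
        ++i;
        acc += (freq[i] > 0) ? std::pow(freq[i], 0.75) / tot : 0.0;
      }
      neg_table[k] = i;
    }
  }

  // ---- skip-gram with negative sampling -------------------------------
  NumericMatrix emb(n, dim);
  std::vector<double> syn0(static_cast<size_t>(n) * dim);
  std::vector<double> syn1(static_cast<size_t>(n) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rand_unit(rng) - 0.5) / dim;

  SigmoidTable sigm;
  const double lr_start = 0.025, lr_min = 0.0001;
  size_t total_tokens = 0;
  for (const auto &w : walks) total_tokens += w.size();
  const double total_work = std::max<double>(1.0, (double)total_tokens * epochs);
  size_t done = 0;
  std::vector<double> grad_acc(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto &walk : walks) {
      const int L = (int)walk.size();
      for (int t = 0; t < L; ++t) {
        double lr = lr_start * (1.0 - (double)done / total_work);
        if (lr < lr_min) lr = lr_min;
        ++done;
        int center = walk[t];
        double *v_in = &syn0[(size_t)center * dim];
        int b = rand_below(rng, window) ;  // dynamic window shrink
        for (int o = b - window; o <= window - b; ++o) {
          if (o == 0) continue;
          int cpos = t + o;
          if (cpos < 0 || cpos >= L) continue;
          int target = walk[cpos];
          std::fill(grad_acc.begin(), grad_acc.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int label, out;
            if (neg == 0) {
              out = target;
              label = 1;
            } else {
              out = neg_table[rng() & (TABLE_SIZE - 1)];
              if (out == target) continue;
              label = 0;
            }
            double *u_out = &syn1[(size_t)out * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * u_out[d];
            double g = (label - sigm(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad_acc[d] += g * u_out[d];
              u_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad_acc[d];
        }
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int d = 0; d < dim; ++d)
      emb(i, d) = syn0[(size_t)i * dim + d];
  return emb;
}
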