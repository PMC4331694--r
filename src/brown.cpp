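// Agglomerative Brown clustering over adjacent-bigram statistics.
//
// Words arrive as frequency-rank ids (0 = most frequent); -1 marks a sequence
// boundary (bigrams never cross it). The classic windowed procedure: seed the
// k most frequent words as singleton clusters, insert each remaining word as
// a (k+1)-th cluster and merge the pair whose merge loses the least average
// mutual information (AMI), then keep merging the final k clusters up to a
// single root, recording the merge tree. A word's binary code is the path
// from the root to its *cluster* (0 = branch of the lower-id cluster of the
// pair): all members of one cluster share one code — codes identify leaf
// clusters, not individual words.
//
// AMI of a clustering: sum over cluster bigrams (c1,c2) of
//   p(c1,c2) * log( p(c1,c2) / (pl(c1) * pr(c2)) )
// Ties between equal-loss merges break on the lexicographically smallest
// (min id, max id) pair, cluster id = smallest member word id.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Slot {
  bool active = false;
  int id = 0;                 // smallest member word id
  int node = -1;              // tree node index
  std::vector<int> members;
};

struct Ctx {
  int V, L;                   // vocab size, slot count
  double N;                   // total bigrams
  std::vector<double> cc;     // L x L cluster bigram counts
  std::vector<double> cl, cr; // left / right marginals per slot
  std::vector<Slot> slot;

  inline double q(double joint, double l, double r) const {
    if (joint <= 0.0) return 0.0;
    return (joint / N) * std::log(joint * N / (l * r));
  }
  // AMI contribution of all terms involving slot a (rows + cols, q(a,a) once)
  double s_of(int a) const {
    double acc = 0.0;
    for (int c = 0; c < L; ++c) {
      if (!slot[c].active) continue;
      acc += q(cc[a * L + c], cl[a], cr[c]);
      if (c != a) acc += q(cc[c * L + a], cl[c], cr[a]);
    }
    return acc;
  }
  // AMI loss of merging slots a and b
  double merge_loss(int a, int b) const {
    double before = s_of(a) + s_of(b) - q(cc[a * L + b], cl[a], cr[b])
                  - q(cc[b * L + a], cl[b], cr[a]);
    const double ml = cl[a] + cl[b], mr = cr[a] + cr[b];
    double after = 0.0;
    for (int c = 0; c < L; ++c) {
      if (!slot[c].active || c == a || c == b) continue;
      after += q(cc[a * L + c] + cc[b * L + c], ml, cr[c]);
      after += q(cc[c * L + a] + cc[c * L + b], cl[c], mr);
    }
    after += q(cc[a * L + a] + cc[a * L + b] + cc[b * L + a] + cc[b * L + b],
               ml, mr);
    return before - after;
  }
};

} // namespace

// [[Rcpp::export]]
List brown_cluster_cpp(IntegerVector corpus, int V, int k) {
  // bigram counts over word ids
  std::vector<double> big((size_t)V * V, 0.0);
  double N = 0.0;
  for (R_xlen_t i = 0; i + 1 < corpus.size(); ++i) {
    const int a = corpus[i], b = corpus[i + 1];
    if (a < 0 || b < 0) continue;
    big[(size_t)a * V + b] += 1.0;
    N += 1.0;
  }
  if (N <= 0.0) stop("corpus has no bigrams");

  const int L = k + 1; // slot capacity
  Ctx ctx;
  ctx.V = V; ctx.L = L; ctx.N = N;
  ctx.cc.assign((size_t)L * L, 0.0);
  ctx.cl.assign(L, 0.0);
  ctx.cr.assign(L, 0.0);
  ctx.slot.assign(L, Slot());

  // tree: leaves 0..V-1; internal nodes appended
  std::vector<int> left, right;
  auto new_internal = [&](int a_node, int b_node) {
    left.push_back(a_node);
    right.push_back(b_node);
    return V + (int)left.size() - 1;
  };

  std::vector<int> word_slot(V, -1);
  auto add_word = [&](int w, int s) {
    ctx.slot[s].active = true;
    ctx.slot[s].id = w;
    ctx.slot[s].node = w;
    ctx.slot[s].members.assign(1, w);
    word_slot[w] = s;
    // counts vs existing active slots (including itself)
    for (int c = 0; c < L; ++c) {
      if (!ctx.slot[c].active) continue;
      double ab = 0.0, ba = 0.0;
      for (int m : ctx.slot[c].members) {
        ab += big[(size_t)w * V + m];
        if (m != w) ba += big[(size_t)m * V + w];
      }
      ctx.cc[(size_t)s * L + c] += ab;
      ctx.cc[(size_t)c * L + s] += ba;
    }
    // marginals over the full vocabulary (words not yet inserted contribute
    // only once they are inserted), so recompute from cluster counts
  };
  auto refresh_marginals = [&]() {
    for (int a = 0; a < L; ++a) { ctx.cl[a] = 0.0; ctx.cr[a] = 0.0; }
    for (int a = 0; a < L; ++a) {
      if (!ctx.slot[a].active) continue;
      for (int b = 0; b < L; ++b) {
        if (!ctx.slot[b].active) continue;
        ctx.cl[a] += ctx.cc[(size_t)a * L + b];
        ctx.cr[a] += ctx.cc[(size_t)b * L + a];
      }
    }
  };

  auto do_merge = [&](int a, int b) {
    // keep the smaller-id cluster's slot; its branch bit is 0
    if (ctx.slot[b].id < ctx.slot[a].id) std::swap(a, b);
    for (int c = 0; c < L; ++c) {
      ctx.cc[(size_t)a * L + c] += ctx.cc[(size_t)b * L + c];
      ctx.cc[(size_t)b * L + c] = 0.0;
    }
    for (int c = 0; c < L; ++c) {
      ctx.cc[(size_t)c * L + a] += ctx.cc[(size_t)c * L + b];
      ctx.cc[(size_t)c * L + b] = 0.0;
    }
    ctx.slot[a].node = new_internal(ctx.slot[a].node, ctx.slot[b].node);
    ctx.slot[a].members.insert(ctx.slot[a].members.end(),
                               ctx.slot[b].members.begin(),
                               ctx.slot[b].members.end());
    for (int m : ctx.slot[b].members) word_slot[m] = a;
    ctx.slot[b] = Slot();
  };

  auto best_pair = [&](int& ba, int& bb) {
    double best = R_PosInf;
    ba = -1; bb = -1;
    int bid1 = -1, bid2 = -1;
    for (int a = 0; a < L; ++a) {
      if (!ctx.slot[a].active) continue;
      for (int b = a + 1; b < L; ++b) {
        if (!ctx.slot[b].active) continue;
        const double loss = ctx.merge_loss(a, b);
        int id1 = std::min(ctx.slot[a].id, ctx.slot[b].id);
        int id2 = std::max(ctx.slot[a].id, ctx.slot[b].id);
        const bool better =
          (loss < best - 1e-12) ||
          (std::fabs(loss - best) <= 1e-12 &&
           (id1 < bid1 || (id1 == bid1 && id2 < bid2)));
        if (ba < 0 || better) {
          best = loss; ba = a; bb = b; bid1 = id1; bid2 = id2;
        }
      }
    }
  };

  // phase 1: seed + insert
  const int seed_n = std::min(k, V);
  for (int w = 0; w < seed_n; ++w) add_word(w, w);
  refresh_marginals();
  for (int w = seed_n; w < V; ++w) {
    int s = -1;
    for (int c = 0; c < L; ++c) if (!ctx.slot[c].active) { s = c; break; }
    add_word(w, s);
    refresh_marginals();
    int a, b;
    best_pair(a, b);
    do_merge(a, b);
    refresh_marginals();
  }

  // final partition: k (or V if V<k) clusters, numbered by ascending id
  std::vector<int> order;
  for (int c = 0; c < L; ++c) if (ctx.slot[c].active) order.push_back(c);
  std::sort(order.begin(), order.end(),
            [&](int x, int y) { return ctx.slot[x].id < ctx.slot[y].id; });
  IntegerVector cluster(V);
  std::vector<int> cluster_node(order.size());
  for (size_t ci = 0; ci < order.size(); ++ci) {
    cluster_node[ci] = ctx.slot[order[ci]].node;
    for (int m : ctx.slot[order[ci]].members) cluster[m] = (int)ci;
  }

  // phase 2: merge to root
  int active_n = (int)order.size();
  while (active_n > 1) {
    int a, b;
    best_pair(a, b);
    do_merge(a, b);
    refresh_marginals();
    --active_n;
  }
  int root = -1;
  for (int c = 0; c < L; ++c) if (ctx.slot[c].active) root = ctx.slot[c].node;

  // codes: DFS from the root, stopping at each final cluster's subtree node
  // so that all members of a cluster share the cluster's path code
  std::vector<std::string> ccode(order.size());
  {
    std::vector<long long> node_to_cluster((size_t)V + left.size(), -1);
    for (size_t ci = 0; ci < order.size(); ++ci)
      node_to_cluster[cluster_node[ci]] = (long long)ci;
    std::vector<std::pair<int, std::string>> stack;
    stack.emplace_back(root, "");
    while (!stack.empty()) {
      auto nd = stack.back(); stack.pop_back();
      if (node_to_cluster[nd.first] >= 0) {
        ccode[node_to_cluster[nd.first]] = nd.second;
      } else {
        const int idx = nd.first - V;
        stack.emplace_back(left[idx], nd.second + "0");
        stack.emplace_back(right[idx], nd.second + "1");
      }
    }
  }
  CharacterVector codes(V);
  for (int w = 0; w < V; ++w) codes[w] = ccode[cluster[w]];
  return List::create(_["cluster"] = cluster, _["code"] = codes);
}
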