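// Branch-and-bound engine for score-based DAG selection with lazily
// generated cycle (cluster) constraints. Mirrors the R-side algorithm:
// relaxation = each node takes its cheapest allowed candidate parent
// set; bound strengthened by a greedy node-disjoint cycle packing;
// branching partitions on the edges of a violated cycle; children are
// explored best-bound-first. Candidates arrive pre-sorted (score, set
// size, lexicographic encoding), which fixes all tie-breaks.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <chrono>
using namespace Rcpp;

namespace {

struct Instance {
  int m;
  std::vector<std::vector<double>> score;        // per node: candidate scores
  std::vector<std::vector<std::vector<int>>> pa; // per node/candidate: scored parents (0-based)
  std::vector<std::vector<std::vector<char>>> has; // per node/candidate: membership mask over nodes
};

typedef std::vector<std::vector<char>> Mask;     // allowed[v][k]

bool relax_choose(const Instance& I, const Mask& allowed,
                  std::vector<int>& chosen) {
  for (int v = 0; v < I.m; ++v) {
    int pick = -1;
    const std::vector<char>& a = allowed[v];
    for (size_t k = 0; k < a.size(); ++k) if (a[k]) { pick = (int)k; break; }
    if (pick < 0) return false;
    chosen[v] = pick;
  }
  return true;
}

double plain_bound(const Instance& I, const std::vector<int>& chosen) {
  double s = 0.0;
  for (int v = 0; v < I.m; ++v) s += I.score[v][chosen[v]];
  return s;
}

// find one directed cycle in the chosen-parent graph restricted to
// `avail` nodes; returns node sequence v1 -> v2 -> ... -> v1 (empty if
// acyclic). Iterative colored DFS over children.
std::vector<int> find_cycle_chosen(const Instance& I,
                                   const std::vector<int>& chosen,
                                   const std::vector<char>& avail) {
  int m = I.m;
  std::vector<std::vector<int>> children(m);
  for (int v = 0; v < m; ++v) {
    if (!avail[v]) continue;
    for (int u : I.pa[v][chosen[v]]) if (avail[u]) children[u].push_back(v);
  }
  std::vector<int> state(m, 0), pred(m, -1);
  for (int root = 0; root < m; ++root) {
    if (state[root] != 0 || !avail[root]) continue;
    std::vector<std::pair<int, size_t>> stack;
    stack.push_back({root, 0});
    state[root] = 1;
    while (!stack.empty()) {
      int v = stack.back().first;
      size_t& i = stack.back().second;
      if (i >= children[v].size()) {
        state[v] = 2;
        stack.pop_back();
        continue;
      }
      int w = children[v][i++];
      if (state[w] == 1) {
        // unwind: cycle w -> ... -> v -> w
        std::vector<int> cyc;
        size_t k = stack.size();
        while (k > 0 && stack[k - 1].first != w) --k;
        for (size_t j = k - 1; j < stack.size(); ++j)
          cyc.push_back(stack[j].first);
        return cyc;
      }
      if (state[w] == 0) {
        state[w] = 1;
        stack.push_back({w, 0});
      }
    }
  }
  return std::vector<int>();
}

// strengthened bound: plain bound + cheapest repairs of a greedy
// node-disjoint cycle packing
double strong_bound(const Instance& I, const Mask& allowed,
                    const std::vector<int>& chosen,
                    std::vector<int>* first_cycle) {
  double bound = plain_bound(I, chosen);
  std::vector<char> avail(I.m, 1);
  bool first = true;
  while (true) {
    std::vector<int> cyc = find_cycle_chosen(I, chosen, avail);
    if (cyc.empty()) break;
    if (first && first_cycle) *first_cycle = cyc;
    first = false;
    int k = (int)cyc.size();
    double best = R_PosInf;
    for (int i = 0; i < k; ++i) {
      int u = cyc[i];
      int w = cyc[(i + 1) % k];
      // cheapest allowed candidate of w avoiding parent u
      const std::vector<char>& a = allowed[w];
      const std::vector<std::vector<char>>& hw = I.has[w];
      for (size_t c = 0; c < a.size(); ++c) {
        if (a[c] && !hw[c][u]) {
          double cost = I.score[w][c] - I.score[w][chosen[w]];
          if (cost < best) best = cost;
          break;
        }
      }
    }
    bound += best;
    for (int v : cyc) avail[v] = 0;
  }
  return bound;
}

struct Node { Mask allowed; double bound; };

}  // namespace

// [[Rcpp::export(name = ".solve_ilp_engine")]]
List solve_ilp_engine(List node_scores, List node_parents, int m,
                      double time_limit_s, IntegerVector incumbent0,
                      double incumbent_score0) {
  Instance I;
  I.m = m;
  I.score.resize(m); I.pa.resize(m); I.has.resize(m);
  for (int v = 0; v < m; ++v) {
    I.score[v] = as<std::vector<double>>(node_scores[v]);
    List pl = node_parents[v];
    int K = pl.size();
    I.pa[v].resize(K);
    I.has[v].assign(K, std::vector<char>(m, 0));
    for (int k = 0; k < K; ++k) {
      IntegerVector p = pl[k];           // 0-based scored-parent indices
      I.pa[v][k] = as<std::vector<int>>(p);
      for (int u : I.pa[v][k]) I.has[v][k][u] = 1;
    }
  }

  std::vector<int> best_chosen = as<std::vector<int>>(incumbent0);
  double best_score = incumbent_score0;
  long branches = 0, cuts = 0;
  bool hit_limit = false;
  const double eps = 1e-12;
  auto t0 = std::chrono::steady_clock::now();
  auto elapsed = [&]() {
    return std::chrono::duration<double>(
      std::chrono::steady_clock::now() - t0).count();
  };

  Mask root(m);
  for (int v = 0; v < m; ++v)
    root[v].assign(I.score[v].size(), 1);
  std::vector<Node> stack;
  stack.push_back({root, R_NegInf});

  std::vector<int> chosen(m), child_chosen(m);
  long iter = 0;
  while (!stack.empty()) {
    if (++iter % 64 == 0 && elapsed() > time_limit_s) { hit_limit = true; break; }
    Node top = std::move(stack.back());
    stack.pop_back();
    if (top.bound >= best_score - eps) continue;
    if (!relax_choose(I, top.allowed, chosen)) continue;
    std::vector<int> cyc;
    double bound = strong_bound(I, top.allowed, chosen, &cyc);
    if (bound >= best_score - eps) continue;
    if (cyc.empty()) {
      best_score = plain_bound(I, chosen);
      best_chosen = chosen;
      continue;
    }
    ++cuts;
    int k = (int)cyc.size();
    std::vector<Node> children;
    for (int i = 0; i < k; ++i) {
      Mask sub = top.allowed;
      bool ok = true;
      for (int j = 0; j <= i && ok; ++j) {
        int u = cyc[j];
        int w = cyc[(j + 1) % k];
        bool any = false;
        for (size_t c = 0; c < sub[w].size(); ++c) {
          if (!sub[w][c]) continue;
          char hu = I.has[w][c][u];
          if ((j < i && !hu) || (j == i && hu)) sub[w][c] = 0;
          else any = true;
        }
        if (!any) ok = false;
      }
      if (!ok) continue;
      if (!relax_choose(I, sub, child_chosen)) continue;
      double b = strong_bound(I, sub, child_chosen, nullptr);
      if (b >= best_score - eps) continue;
      children.push_back({std::move(sub), b});
      ++branches;
    }
    std::sort(children.begin(), children.end(),
              [](const Node& a, const Node& b) { return a.bound > b.bound; });
    for (auto& ch : children) stack.push_back(std::move(ch));
  }

  return List::create(
    _["chosen"] = IntegerVector(best_chosen.begin(), best_chosen.end()),
    _["total"] = best_score,
    _["optimal"] = !hit_limit,
    _["branches"] = (double)branches,
    _["cycle_cuts"] = (double)cuts,
    _["seconds"] = elapsed());
}
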