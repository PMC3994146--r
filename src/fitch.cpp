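#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Minimum-change (Fitch) parsimony score by Hartigan's generalization:
// at each internal node, keep the states present in the maximal number of
// children's state sets; the node contributes (n_children - max_count)
// changes. Reduces to classic Fitch on binary trees and is exact on
// multifurcations. Edges must be in ape postorder (children before parents);
// every node is the child of exactly one edge except the root.
static int score_once(const IntegerMatrix& edge, int ntip,
                      const int* tipset, int k,
                      std::vector<int>& cnt, std::vector<int>& nchild) {
  std::fill(cnt.begin(), cnt.end(), 0);
  std::fill(nchild.begin(), nchild.end(), 0);
  const int ne = edge.nrow();
  const int root = edge(ne - 1, 0);
  int score = 0;
  for (int e = 0; e < ne; ++e) {
    const int p = edge(e, 0), c = edge(e, 1);  // 1-based node ids
    int cset;
    if (c <= ntip) {
      cset = tipset[c - 1];
    } else {
      const int* cc = &cnt[(size_t)(c - 1) * k];
      int K = 0;
      for (int s = 0; s < k; ++s) if (cc[s] > K) K = cc[s];
      score += nchild[c - 1] - K;
      cset = 0;
      for (int s = 0; s < k; ++s) if (cc[s] == K) cset |= (1 << s);
    }
    int* pc = &cnt[(size_t)(p - 1) * k];
    for (int s = 0; s < k; ++s) if (cset & (1 << s)) ++pc[s];
    ++nchild[p - 1];
  }
  const int* rc = &cnt[(size_t)(root - 1) * k];
  int K = 0;
  for (int s = 0; s < k; ++s) if (rc[s] > K) K = rc[s];
  score += nchild[root - 1] - K;
  return score;
}

// [[Rcpp::export]]
int fitch_score_impl(IntegerMatrix edge, int ntip, int k,
                     IntegerVector tip_states) {
  if (k < 2 || k > 30) stop("k must be in [2, 30]");
  if (tip_states.size() != ntip) stop("one state per tip required");
  int nnode = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  std::vector<int> tipset(ntip);
  for (int i = 0; i < ntip; ++i) {
    if (tip_states[i] < 1 || tip_states[i] > k) stop("tip state out of range");
    tipset[i] = 1 << (tip_states[i] - 1);
  }
  std::vector<int> cnt((size_t)nnode * k), nchild(nnode);
  return score_once(edge, ntip, tipset.data(), k, cnt, nchild);
}

// Scores each column of a tip-state matrix (one permutation per column).
// [[Rcpp::export]]
IntegerVector fitch_scores_batch_impl(IntegerMatrix edge, int ntip, int k,
                                      IntegerMatrix tip_state_matrix) {
  if (k < 2 || k > 30) stop("k must be in [2, 30]");
  if (tip_state_matrix.nrow() != ntip) stop("one row per tip required");
  int nnode = 0;
  for (int e = 0; e < edge.nrow(); ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  const int nperm = tip_state_matrix.ncol();
  std::vector<int> cnt((size_t)nnode * k), nchild(nnode), tipset(ntip);
  IntegerVector out(nperm);
  for (int j = 0; j < nperm; ++j) {
    for (int i = 0; i < ntip; ++i) {
      const int s = tip_state_matrix(i, j);
      if (s < 1 || s > k) stop("tip state out of range");
      tipset[i] = 1 << (s - 1);
    }
    out[j] = score_once(edge, ntip, tipset.data(), k, cnt, nchild);
  }
  return out;
}
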