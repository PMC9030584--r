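#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fitch small parsimony on state-set bitmasks.
//
// Trees arrive as (parent, child) edge matrices in any row order; tips are
// numbered 1..ntip, internal nodes ntip+1.., the root is the node that never
// appears as a child.  A tip's state set for character ch is states(tip-1, ch),
// a nonzero bitmask over at most 32 states (missing data = full mask).

// Sort edge indices so that every edge (p,c) comes after all edges inside the
// subtree of c.  Reverse of a stack DFS visit order has children before
// parents; ordering edges by the child's position in it is a valid postorder.
static void postorder_index(const IntegerMatrix &edge, int root, int nnodes,
                            std::vector<int> &eidx) {
  int m = edge.nrow();
  std::vector<std::vector<int> > kids(nnodes + 1);
  for (int i = 0; i < m; ++i) kids[edge(i, 0)].push_back(i);
  std::vector<int> st, seq;
  st.push_back(root);
  seq.reserve(nnodes);
  while (!st.empty()) {
    int v = st.back();
    st.pop_back();
    seq.push_back(v);
    const std::vector<int> &k = kids[v];
    for (size_t j = 0; j < k.size(); ++j) st.push_back(edge(k[j], 1));
  }
  std::vector<int> ord(nnodes + 1, -1);
  int pos = 0;
  for (int i = (int)seq.size() - 1; i >= 0; --i) ord[seq[i]] = pos++;
  eidx.resize(m);
  for (int i = 0; i < m; ++i) eidx[i] = i;
  std::sort(eidx.begin(), eidx.end(),
            [&](int a, int b) { return ord[edge(a, 1)] < ord[edge(b, 1)]; });
}

static int find_root(const IntegerMatrix &edge, int nnodes) {
  std::vector<char> is_child(nnodes + 1, 0);
  for (int i = 0; i < edge.nrow(); ++i) is_child[edge(i, 1)] = 1;
  for (int i = 0; i < edge.nrow(); ++i)
    if (!is_child[edge(i, 0)]) return edge(i, 0);
  return -1; // unreachable on a valid tree
}

static int max_node(const IntegerMatrix &edge) {
  int mx = 0;
  for (int i = 0; i < edge.nrow(); ++i)
    mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
  return mx;
}

// Per-character Fitch lengths for one tree.
// [[Rcpp::export]]
IntegerVector fitch_lengths_cpp(IntegerMatrix edge, int ntip,
                                IntegerMatrix states) {
  int m = edge.nrow();
  int nnodes = max_node(edge);
  int root = find_root(edge, nnodes);
  if (root < 0) stop("edge matrix does not describe a rooted tree");
  std::vector<int> eidx;
  postorder_index(edge, root, nnodes, eidx);
  int nchar = states.ncol();
  IntegerVector out(nchar);
  std::vector<int> stt(nnodes + 1);
  for (int ch = 0; ch < nchar; ++ch) {
    std::fill(stt.begin(), stt.end(), 0);
    int cnt = 0;
    for (int k = 0; k < m; ++k) {
      int i = eidx[k];
      int p = edge(i, 0), c = edge(i, 1);
      int sc = (c <= ntip) ? states(c - 1, ch) : stt[c];
      if (sc == 0) stop("tip with empty state set");
      if (stt[p] == 0) {
        stt[p] = sc;
      } else {
        int a = stt[p] & sc;
        if (a) stt[p] = a;
        else { stt[p] |= sc; ++cnt; }
      }
    }
    out[ch] = cnt;
  }
  return out;
}

static int fitch_total_one(const IntegerMatrix &edge, int ntip,
                           const IntegerMatrix &states,
                           const IntegerVector &weights) {
  IntegerVector per = fitch_lengths_cpp(edge, ntip, states);
  int tot = 0;
  for (int i = 0; i < per.size(); ++i) tot += per[i] * weights[i];
  return tot;
}

// Weighted total Fitch length for each tree in a list (batch scorer used by
// the tree-search drivers; weights compress duplicate site patterns).
// [[Rcpp::export]]
IntegerVector fitch_total_many_cpp(List edges, int ntip, IntegerMatrix states,
                                   IntegerVector weights) {
  int n = edges.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerMatrix e = edges[i];
    out[i] = fitch_total_one(e, ntip, states, weights);
  }
  return out;
}
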