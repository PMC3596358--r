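#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rooted-at-a-leaf dynamic programme for the maximum agreement subtree
// (MAST) of two unrooted binary trees that share a leaf-label set.
//
// Any agreement set A with |A| >= 3 contains some leaf x; restricting both
// trees to A and reading them as rooted at x turns unrooted agreement into
// rooted agreement on A \ {x}.  So
//     UMAST(T1, T2) = max over shared leaves x of 1 + rMAST(T1^x, T2^x)
// where T^x is T re-rooted at the neighbour of x with x removed.  The rooted
// MAST is the classical O(m1*m2) recurrence over node pairs.

namespace {

struct RootedTree {
  // node indexing is local: 0..m-1 in postorder
  std::vector<int> kid1, kid2;  // -1 for leaves
  std::vector<int> lab;         // leaf label id, -1 for internal
  int m;                        // node count
};

// Build adjacency lists from an ape-style edge matrix (1-based node ids,
// tips 1..ntip).
void build_adj(const IntegerMatrix& edge, int nnode,
               std::vector<std::vector<int> >& adj) {
  adj.assign(nnode + 1, std::vector<int>());
  for (int i = 0; i < edge.nrow(); ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
}

// Orient the tree away from `parent` starting at `r`; nodes reachable from
// r (excluding parent) are emitted in postorder.  With r = neighbour of a
// leaf x and parent = x this roots an unrooted tree at x and drops x; with
// r = the root of an already-rooted tree and parent = 0 it reads the rooted
// tree as is.
RootedTree build_rooted(const std::vector<std::vector<int> >& adj,
                        const IntegerVector& lab, int ntip, int r, int x) {
  RootedTree rt;
  // iterative postorder DFS from r with parent x
  std::vector<int> stack_node, stack_parent, order, order_parent;
  stack_node.push_back(r);
  stack_parent.push_back(x);
  while (!stack_node.empty()) {
    int v = stack_node.back(); stack_node.pop_back();
    int p = stack_parent.back(); stack_parent.pop_back();
    order.push_back(v);
    order_parent.push_back(p);
    for (size_t i = 0; i < adj[v].size(); ++i) {
      int w = adj[v][i];
      if (w != p) { stack_node.push_back(w); stack_parent.push_back(v); }
    }
  }
  int m = (int) order.size();
  rt.m = m;
  rt.kid1.assign(m, -1); rt.kid2.assign(m, -1); rt.lab.assign(m, -1);
  // postorder = reverse of the DFS emission order; map ape ids -> local ids
  std::vector<int> local(adj.size(), -1);
  for (int i = m - 1; i >= 0; --i) {
    int v = order[i];
    int id = m - 1 - i;
    local[v] = id;
    if (v <= ntip) rt.lab[id] = lab[v - 1];
  }
  for (int i = m - 1; i >= 0; --i) {
    int v = order[i], p = order_parent[i];
    if (v == r) continue;
    int pv = local[p], cv = local[v];
    if (rt.kid1[pv] == -1) rt.kid1[pv] = cv;
    else if (rt.kid2[pv] == -1) rt.kid2[pv] = cv;
    else stop("tree is not binary: a node has more than two children");
  }
  for (int i = 0; i < m; ++i) {
    if (rt.lab[i] < 0 && (rt.kid1[i] < 0 || rt.kid2[i] < 0))
      stop("tree has an unresolved (degree-2) internal node");
    if (rt.lab[i] >= 0 && rt.kid1[i] >= 0)
      stop("labelled node is not a leaf");
  }
  return rt;
}

// rooted MAST DP; fills score table r (m1 x m2, row-major)
int rooted_mast(const RootedTree& A, const RootedTree& B,
                std::vector<int>& r) {
  int m1 = A.m, m2 = B.m;
  r.assign((size_t) m1 * m2, 0);
  for (int u = 0; u < m1; ++u) {
    bool uleaf = A.kid1[u] < 0;
    int a1 = A.kid1[u], a2 = A.kid2[u];
    for (int v = 0; v < m2; ++v) {
      bool vleaf = B.kid1[v] < 0;
      int b1 = B.kid1[v], b2 = B.kid2[v];
      int best;
      if (uleaf && vleaf) {
        best = (A.lab[u] == B.lab[v]) ? 1 : 0;
      } else if (uleaf) {
        best = std::max(r[(size_t) u * m2 + b1], r[(size_t) u * m2 + b2]);
      } else if (vleaf) {
        best = std::max(r[(size_t) a1 * m2 + v], r[(size_t) a2 * m2 + v]);
      } else {
        int s1 = r[(size_t) a1 * m2 + b1] + r[(size_t) a2 * m2 + b2];
        int s2 = r[(size_t) a1 * m2 + b2] + r[(size_t) a2 * m2 + b1];
        best = std::max(s1, s2);
        best = std::max(best, r[(size_t) u * m2 + b1]);
        best = std::max(best, r[(size_t) u * m2 + b2]);
        best = std::max(best, r[(size_t) a1 * m2 + v]);
        best = std::max(best, r[(size_t) a2 * m2 + v]);
      }
      r[(size_t) u * m2 + v] = best;
    }
  }
  return r[(size_t) (m1 - 1) * m2 + (m2 - 1)];
}

// traceback collecting leaf labels of one maximum agreement set; case
// priority is fixed (matched child pairs first, then descents) so the
// result is deterministic for a given rooting.
void traceback(const RootedTree& A, const RootedTree& B,
               const std::vector<int>& r, int u, int v,
               std::vector<int>& out) {
  int m2 = B.m;
  int sc = r[(size_t) u * m2 + v];
  if (sc == 0) return;
  bool uleaf = A.kid1[u] < 0, vleaf = B.kid1[v] < 0;
  if (uleaf && vleaf) { out.push_back(A.lab[u]); return; }
  int a1 = A.kid1[u], a2 = A.kid2[u], b1 = B.kid1[v], b2 = B.kid2[v];
  if (uleaf) {
    if (r[(size_t) u * m2 + b1] == sc) traceback(A, B, r, u, b1, out);
    else traceback(A, B, r, u, b2, out);
    return;
  }
  if (vleaf) {
    if (r[(size_t) a1 * m2 + v] == sc) traceback(A, B, r, a1, v, out);
    else traceback(A, B, r, a2, v, out);
    return;
  }
  if (r[(size_t) a1 * m2 + b1] + r[(size_t) a2 * m2 + b2] == sc) {
    traceback(A, B, r, a1, b1, out);
    traceback(A, B, r, a2, b2, out);
  } else if (r[(size_t) a1 * m2 + b2] + r[(size_t) a2 * m2 + b1] == sc) {
    traceback(A, B, r, a1, b2, out);
    traceback(A, B, r, a2, b1, out);
  } else if (r[(size_t) u * m2 + b1] == sc) {
    traceback(A, B, r, u, b1, out);
  } else if (r[(size_t) u * m2 + b2] == sc) {
    traceback(A, B, r, u, b2, out);
  } else if (r[(size_t) a1 * m2 + v] == sc) {
    traceback(A, B, r, a1, v, out);
  } else {
    traceback(A, B, r, a2, v, out);
  }
}

}  // namespace

// [[Rcpp::export(name = ".umast_cpp")]]
List umast_cpp(IntegerMatrix edge1, int ntip1, IntegerVector lab1,
               IntegerMatrix edge2, int ntip2, IntegerVector lab2,
               bool want_leaves) {
  if (ntip1 < 3 || ntip2 < 3) stop("need at least 3 leaves");
  int nn1 = max(edge1), nn2 = max(edge2);
  std::vector<std::vector<int> > adj1, adj2;
  build_adj(edge1, nn1, adj1);
  build_adj(edge2, nn2, adj2);
  // tip id by label for each tree
  int nlab = std::max(max(lab1), max(lab2)) + 1;
  std::vector<int> tip1(nlab, -1), tip2(nlab, -1);
  for (int i = 0; i < ntip1; ++i) tip1[lab1[i]] = i + 1;
  for (int i = 0; i < ntip2; ++i) tip2[lab2[i]] = i + 1;

  int best = 0;
  std::vector<std::vector<int> > best_sets;
  std::vector<int> r;
  for (int L = 0; L < nlab; ++L) {
    if (tip1[L] < 0 || tip2[L] < 0) continue;
    int x1 = tip1[L], x2 = tip2[L];
    RootedTree A = build_rooted(adj1, lab1, ntip1, adj1[x1][0], x1);
    RootedTree B = build_rooted(adj2, lab2, ntip2, adj2[x2][0], x2);
    int sc = 1 + rooted_mast(A, B, r);
    if (sc < best) continue;
    if (sc > best) { best = sc; best_sets.clear(); }
    if (want_leaves) {
      std::vector<int> set;
      set.push_back(L);
      traceback(A, B, r, A.m - 1, B.m - 1, set);
      std::sort(set.begin(), set.end());
      best_sets.push_back(set);
    }
  }
  if (!want_leaves) return List::create(_["size"] = best);
  // lexicographically smallest among the per-rooting optima
  size_t pick = 0;
  for (size_t i = 1; i < best_sets.size(); ++i)
    if (best_sets[i] < best_sets[pick]) pick = i;
  return List::create(_["size"] = best,
                      _["leaves"] = wrap(best_sets[pick]));
}

// Rooted MAST where each tree is an unrooted edge matrix plus a marker
// leaf whose attachment point is the root; the marker itself is dropped.
// Used by the null-distribution calibration, where uniform rooted trees on
// n leaves are drawn as uniform unrooted trees on n + 1 leaves.
// [[Rcpp::export(name = ".rmast_marked_cpp")]]
int rmast_marked_cpp(IntegerMatrix edge1, int ntip1, IntegerVector lab1,
                     int rootleaf1,
                     IntegerMatrix edge2, int ntip2, IntegerVector lab2,
                     int rootleaf2) {
  int nn1 = max(edge1), nn2 = max(edge2);
  std::vector<std::vector<int> > adj1, adj2;
  build_adj(edge1, nn1, adj1);
  build_adj(edge2, nn2, adj2);
  RootedTree A = build_rooted(adj1, lab1, ntip1, adj1[rootleaf1][0],
                              rootleaf1);
  RootedTree B = build_rooted(adj2, lab2, ntip2, adj2[rootleaf2][0],
                              rootleaf2);
  std::vector<int> r;
  return rooted_mast(A, B, r);
}

// MAST of two rooted binary trees, taken as rooted (ape convention: root
// node id = ntip + 1).  Leaves carried by only one tree score 0, so callers
// should restrict to the shared leaf set first.
// [[Rcpp::export(name = ".rmast_cpp")]]
List rmast_cpp(IntegerMatrix edge1, int ntip1, IntegerVector lab1,
               IntegerMatrix edge2, int ntip2, IntegerVector lab2,
               bool want_leaves) {
  if (ntip1 < 2 || ntip2 < 2) stop("need at least 2 leaves");
  int nn1 = max(edge1), nn2 = max(edge2);
  std::vector<std::vector<int> > adj1, adj2;
  build_adj(edge1, nn1, adj1);
  build_adj(edge2, nn2, adj2);
  RootedTree A = build_rooted(adj1, lab1, ntip1, ntip1 + 1, 0);
  RootedTree B = build_rooted(adj2, lab2, ntip2, ntip2 + 1, 0);
  std::vector<int> r;
  int sc = rooted_mast(A, B, r);
  if (!want_leaves) return List::create(_["size"] = sc);
  std::vector<int> set;
  traceback(A, B, r, A.m - 1, B.m - 1, set);
  std::sort(set.begin(), set.end());
  return List::create(_["size"] = sc, _["leaves"] = wrap(set));
}
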