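#include <Rcpp.h>
using namespace Rcpp;

// Sankoff maximum-parsimony reconstruction with unit transition costs,
// batched over columns of tip-state assignments (one column per
// permutation replicate). Ambiguous most-parsimonious labelings are
// resolved by preferring the parent's state during the top-down pass,
// then the lowest state index (organ labels are ordered lexicographically
// on the R side).
//
// edge:       2-column matrix of 1-based node ids in postorder (all edges
//             within a child's subtree precede the edge to its parent),
//             as produced by ape::reorder.phylo(tree, "postorder").
// ntip:       number of tips (nodes 1..ntip); internal nodes follow.
// nnode:      number of internal nodes.
// tip_states: ntip x B integer matrix of 0-based tip states.
// nstates:    number of organ states.
//
// Returns a list with:
//   transitions: (nstates*nstates) x B counts of parent->child label
//                changes, row index = from * nstates + to (0-based).
//   changes:     total changes per replicate (column sums of off-diagonal
//                transitions; equals the minimum parsimony score).
//   node_states: (ntip + nnode) x B matrix of 0-based reconstructed
//                states for all nodes.
// [[Rcpp::export]]
List sankoff_batch(IntegerMatrix edge, int ntip, int nnode,
                   IntegerMatrix tip_states, int nstates) {
  const int nedge = edge.nrow();
  const int ntot = ntip + nnode;
  const int B = tip_states.ncol();
  const double INF = 1e12;

  IntegerMatrix transitions(nstates * nstates, B);
  IntegerVector changes(B);
  IntegerMatrix node_states(ntot, B);

  std::vector<double> cost((size_t)ntot * nstates);
  std::vector<int> state(ntot);

  for (int b = 0; b < B; ++b) {
    // bottom-up: additive Sankoff costs
    for (int v = 0; v < ntip; ++v) {
      int s0 = tip_states(v, b);
      for (int s = 0; s < nstates; ++s)
        cost[(size_t)v * nstates + s] = (s == s0) ? 0.0 : INF;
    }
    for (int v = ntip; v < ntot; ++v)
      for (int s = 0; s < nstates; ++s)
        cost[(size_t)v * nstates + s] = 0.0;

    for (int e = 0; e < nedge; ++e) {
      int par = edge(e, 0) - 1;
      int child = edge(e, 1) - 1;
      double m = INF;
      for (int s = 0; s < nstates; ++s)
        m = std::min(m, cost[(size_t)child * nstates + s]);
      for (int s = 0; s < nstates; ++s)
        cost[(size_t)par * nstates + s] +=
            std::min(cost[(size_t)child * nstates + s], m + 1.0);
    }

    // root state: minimal cost, ties to the lowest index
    int root = edge(nedge - 1, 0) - 1;
    int rs = 0;
    for (int s = 1; s < nstates; ++s)
      if (cost[(size_t)root * nstates + s] <
          cost[(size_t)root * nstates + rs])
        rs = s;
    state[root] = rs;

    // top-down: resolve child states, count directional transitions
    int tot = 0;
    for (int e = nedge - 1; e >= 0; --e) {
      int par = edge(e, 0) - 1;
      int child = edge(e, 1) - 1;
      int ps = state[par];
      int cs;
      if (child < ntip) {
        cs = tip_states(child, b);
      } else {
        // prefer the parent's state, then the lowest index
        double best = cost[(size_t)child * nstates + ps];
        cs = ps;
        for (int s = 0; s < nstates; ++s) {
          if (s == ps) continue;
          double val = cost[(size_t)child * nstates + s] + 1.0;
          if (val < best - 1e-9) {
            best = val;
            cs = s;
          }
        }
      }
      state[child] = cs;
      if (cs != ps) {
        ++transitions(ps * nstates + cs, b);
        ++tot;
      }
    }
    changes[b] = tot;
    for (int v = 0; v < ntot; ++v) node_states(v, b) = state[v];
  }

  return List::create(Named("transitions") = transitions,
                      Named("changes") = changes,
                      Named("node_states") = node_states);
}
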