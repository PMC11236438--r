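#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Backward-in-time coalescent for one microsatellite locus under a
// piecewise-constant demography with lineage movements (splits/admixture)
// at epoch boundaries, followed by strict stepwise (+/-1) mutations dropped
// as Poisson(mu * branch length).
//
// deme0:   0-based deme of each sampled gene copy
// bounds:  epoch start times, bounds[0] = 0; epoch e spans
//          [bounds[e], bounds[e+1]), the last epoch is unbounded
// sizes:   n_epoch x n_deme matrix of diploid effective sizes; pairwise
//          coalescence rate in deme d during epoch e is 1 / (2 * sizes(e,d))
// mv_*:    movements applied on entering epoch mv_epoch[k] (1-based epoch
//          index, i.e. at time bounds[mv_epoch[k]]): every lineage in
//          mv_from goes to mv_toa with probability mv_prob, else mv_tob
//          (mv_tob = -1 encodes a deterministic split)
// mu:      per-generation stepwise mutation rate
//
// Returns the allele state (net repeat-unit offset from the root) of each
// sampled copy and the time to the most recent common ancestor.
// [[Rcpp::export]]
List sim_locus_cpp(IntegerVector deme0, NumericVector bounds,
                   NumericMatrix sizes, IntegerVector mv_epoch,
                   IntegerVector mv_from, IntegerVector mv_toa,
                   IntegerVector mv_tob, NumericVector mv_prob, double mu) {
  const int n = deme0.size();
  const int n_epoch = sizes.nrow();
  if (n < 2) stop("need at least two sampled gene copies");

  std::vector<double> node_time(2 * n - 1, 0.0);
  std::vector<int> left(2 * n - 1, -1), right(2 * n - 1, -1);
  std::vector<int> active(n), deme(n);
  for (int i = 0; i < n; ++i) { active[i] = i; deme[i] = deme0[i]; }
  int next_node = n;
  double t = 0.0;
  int e = 0;

  while ((int)active.size() > 1) {
    // per-deme lineage counts and total coalescence rate in current epoch
    std::vector<int> cnt(sizes.ncol(), 0);
    for (size_t i = 0; i < active.size(); ++i) cnt[deme[i]]++;
    double total = 0.0;
    for (int d = 0; d < sizes.ncol(); ++d) {
      if (cnt[d] > 1) total += cnt[d] * (cnt[d] - 1) / 2.0 / (2.0 * sizes(e, d));
    }
    double dt = (total > 0.0) ? R::exp_rand() / total : R_PosInf;
    if (e + 1 < n_epoch && t + dt >= bounds[e + 1]) {
      t = bounds[e + 1];
      ++e;
      // apply movements scheduled at this boundary, in given order
      for (int k = 0; k < mv_epoch.size(); ++k) {
        if (mv_epoch[k] != e) continue;
        for (size_t i = 0; i < active.size(); ++i) {
          if (deme[i] == mv_from[k]) {
            if (mv_tob[k] < 0 || R::unif_rand() < mv_prob[k])
              deme[i] = mv_toa[k];
            else
              deme[i] = mv_tob[k];
          }
        }
      }
      continue;
    }
    if (!R_finite(dt))
      stop("coalescent stalled: multiple lineages in isolated demes with no remaining events");
    t += dt;
    // choose deme proportional to its rate, then a uniform pair within it
    double u = R::unif_rand() * total, acc = 0.0;
    int dsel = -1;
    for (int d = 0; d < sizes.ncol(); ++d) {
      if (cnt[d] > 1) {
        acc += cnt[d] * (cnt[d] - 1) / 2.0 / (2.0 * sizes(e, d));
        if (u <= acc) { dsel = d; break; }
      }
    }
    if (dsel < 0) continue; // numerical edge; redraw
    std::vector<int> in_d;
    for (size_t i = 0; i < active.size(); ++i)
      if (deme[i] == dsel) in_d.push_back((int)i);
    int ii = (int)(R::unif_rand() * in_d.size());
    int jj = (int)(R::unif_rand() * (in_d.size() - 1));
    if (jj >= ii) ++jj;
    int ai = in_d[ii], aj = in_d[jj];
    if (ai > aj) std::swap(ai, aj);
    int parent = next_node++;
    node_time[parent] = t;
    left[parent] = active[ai];
    right[parent] = active[aj];
    active[ai] = parent; // parent stays in dsel
    deme[ai] = dsel;
    active.erase(active.begin() + aj);
    deme.erase(deme.begin() + aj);
  }

  int root = active[0];
  double tmrca = node_time[root];

  // drop stepwise mutations root -> leaves
  std::vector<int> state(2 * n - 1, 0);
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int c : {left[v], right[v]}) {
      if (c < 0) continue;
      double L = node_time[v] - node_time[c];
      int nm = (int)R::rpois(mu * L);
      int up = (nm > 0) ? (int)R::rbinom(nm, 0.5) : 0;
      state[c] = state[v] + 2 * up - nm;
      stack.push_back(c);
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = state[i];
  return List::create(_["state"] = out, _["tmrca"] = tmrca);
}
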