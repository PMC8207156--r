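#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent SNP simulator.
//
// Lineages start in demes (diploid size N_d => pairwise coalescence rate
// 1/(2N_d) per generation). Backward-in-time events, sorted by time:
//   type 0 (move): every lineage in deme `from` moves to deme `to` with
//          probability `prob`, otherwise to deme `to2`. prob = 1 is a plain
//          merge (deme `from` empties into `to`).
//   type 1 (resize): deme `from` takes size `newsize`.
// Each locus is an independent genealogy; exactly one mutation is placed on
// an edge chosen with probability proportional to branch length, so every
// locus is a polymorphic SNP. Loci whose pooled minor allele frequency falls
// below maf_min are redrawn (ascertainment conditioning).
//
// Uses R's RNG (unif_rand / exp_rand) so results are reproducible from
// set.seed() on the R side.

namespace {

struct Event {
  double time;
  int type;      // 0 move, 1 resize
  int from, to, to2;
  double prob, newsize;
};

struct SimState {
  int n_demes;
  std::vector<double> size;        // current diploid sizes
  std::vector<std::vector<int> > demes;  // node indices per deme
  // tree arrays: nodes 0..n_tips-1 are tips
  std::vector<double> node_time;
  std::vector<int> left, right;
};

// simulate one genealogy; fills tree arrays; returns root node index
int simulate_genealogy(SimState &st, const std::vector<Event> &events) {
  const int n_tips = (int) st.node_time.size() / 2 + 1; // 2n-1 nodes total
  int next_node = n_tips;
  double t = 0.0;
  size_t ev = 0;
  int n_active = n_tips;

  while (n_active > 1) {
    // total coalescence rate over demes
    double total = 0.0;
    for (int d = 0; d < st.n_demes; ++d) {
      int k = (int) st.demes[d].size();
      if (k >= 2) total += (double) k * (k - 1) / 2.0 / (2.0 * st.size[d]);
    }
    if (total <= 0.0 && ev >= events.size())
      Rcpp::stop("coalescent cannot complete: no events left and no deme with >= 2 lineages");
    double t_next = (ev < events.size()) ? events[ev].time : R_PosInf;
    double wait = (total > 0.0) ? exp_rand() / total : R_PosInf;

    if (ev < events.size() && t + wait >= t_next) {
      // process all events scheduled at t_next, in listed order
      t = t_next;
      while (ev < events.size() && events[ev].time == t_next) {
        const Event &e = events[ev];
        if (e.type == 1) {
          st.size[e.from] = e.newsize;
        } else {
          std::vector<int> &src = st.demes[e.from];
          for (size_t i = 0; i < src.size(); ++i) {
            int dest = (e.prob >= 1.0 || unif_rand() < e.prob) ? e.to : e.to2;
            st.demes[dest].push_back(src[i]);
          }
          src.clear();
        }
        ++ev;
      }
      continue;
    }
    // a coalescence happens at t + wait: pick deme proportional to rate
    t += wait;
    double u = unif_rand() * total, acc = 0.0;
    int d_pick = -1;
    for (int d = 0; d < st.n_demes; ++d) {
      int k = (int) st.demes[d].size();
      if (k >= 2) {
        acc += (double) k * (k - 1) / 2.0 / (2.0 * st.size[d]);
        if (u <= acc) { d_pick = d; break; }
      }
    }
    if (d_pick < 0) d_pick = st.n_demes - 1; // numerical guard
    std::vector<int> &dm = st.demes[d_pick];
    int k = (int) dm.size();
    int i = (int) (unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int) (unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = dm[i], b = dm[j];
    // remove the two (order-safe)
    if (i > j) std::swap(i, j);
    dm.erase(dm.begin() + j);
    dm.erase(dm.begin() + i);
    st.node_time[next_node] = t;
    st.left[next_node] = a;
    st.right[next_node] = b;
    dm.push_back(next_node);
    ++next_node;
    --n_active;
  }
  return next_node - 1;
}

// mark tips below `node` in `derived`
void mark_tips(const SimState &st, int node, int n_tips, std::vector<int> &derived) {
  // iterative DFS
  std::vector<int> stack;
  stack.push_back(node);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (v < n_tips) { derived[v] = 1; continue; }
    stack.push_back(st.left[v]);
    stack.push_back(st.right[v]);
  }
}

} // namespace

// [[Rcpp::export(name = ".sim_snp_cpp")]]
IntegerMatrix sim_snp_cpp(NumericVector deme_sizes,
                          IntegerVector samples_per_deme,
                          NumericVector event_time,
                          IntegerVector event_type,
                          IntegerVector event_from,
                          IntegerVector event_to,
                          IntegerVector event_to2,
                          NumericVector event_prob,
                          NumericVector event_newsize,
                          int n_loci,
                          double maf_min,
                          int max_tries) {
  const int n_demes = deme_sizes.size();
  if (samples_per_deme.size() != n_demes)
    stop("samples_per_deme length must match deme_sizes");
  int n_tips = 0;
  for (int d = 0; d < n_demes; ++d) {
    if (samples_per_deme[d] < 0) stop("negative sample size");
    n_tips += samples_per_deme[d];
  }
  if (n_tips < 2) stop("need at least 2 sampled gene copies");
  for (int d = 0; d < n_demes; ++d)
    if (deme_sizes[d] <= 0) stop("deme sizes must be positive");

  const int n_ev = event_time.size();
  std::vector<Event> events(n_ev);
  for (int i = 0; i < n_ev; ++i) {
    events[i].time = event_time[i];
    events[i].type = event_type[i];
    events[i].from = event_from[i];
    events[i].to = event_to[i];
    events[i].to2 = event_to2[i];
    events[i].prob = event_prob[i];
    events[i].newsize = event_newsize[i];
    if (i > 0 && event_time[i] < event_time[i - 1])
      stop("events must be sorted by time");
  }

  IntegerMatrix out(n_tips, n_loci);
  RNGScope scope;

  for (int l = 0; l < n_loci; ++l) {
    bool ok = false;
    for (int attempt = 0; attempt < max_tries && !ok; ++attempt) {
      SimState st;
      st.n_demes = n_demes;
      st.size.assign(deme_sizes.begin(), deme_sizes.end());
      st.demes.assign(n_demes, std::vector<int>());
      int tip = 0;
      for (int d = 0; d < n_demes; ++d)
        for (int s = 0; s < samples_per_deme[d]; ++s)
          st.demes[d].push_back(tip++);
      int n_nodes = 2 * n_tips - 1;
      st.node_time.assign(n_nodes, 0.0);
      st.left.assign(n_nodes, -1);
      st.right.assign(n_nodes, -1);

      int root = simulate_genealogy(st, events);

      // edge lengths for every non-root node
      std::vector<double> parent_time(n_nodes, -1.0);
      for (int v = n_tips; v < n_nodes; ++v) {
        parent_time[st.left[v]] = st.node_time[v];
        parent_time[st.right[v]] = st.node_time[v];
      }
      double total_len = 0.0;
      for (int v = 0; v < n_nodes; ++v)
        if (v != root) total_len += parent_time[v] - st.node_time[v];
      if (total_len <= 0.0) stop("zero-length genealogy");

      // place one mutation proportional to branch length
      double u = unif_rand() * total_len, acc = 0.0;
      int mut_node = -1;
      for (int v = 0; v < n_nodes; ++v) {
        if (v == root) continue;
        acc += parent_time[v] - st.node_time[v];
        if (u <= acc) { mut_node = v; break; }
      }
      if (mut_node < 0) mut_node = (root == n_nodes - 1) ? n_nodes - 2 : n_nodes - 1;

      std::vector<int> derived(n_tips, 0);
      mark_tips(st, mut_node, n_tips, derived);
      int c = 0;
      for (int i = 0; i < n_tips; ++i) c += derived[i];
      double maf = std::min(c, n_tips - c) / (double) n_tips;
      if (maf >= maf_min) {
        for (int i = 0; i < n_tips; ++i) out(i, l) = derived[i];
        ok = true;
      }
    }
    if (!ok)
      stop("could not obtain a locus with MAF >= maf_min after max_tries attempts");
  }
  return out;
}
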