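// Backward-time coalescent for multi-population split/admixture scenarios
// with stepwise microsatellite mutation. Uses R's RNG throughout so results
// are reproducible from set.seed() on the R side.
//
// Event matrix encoding (rows sorted by ascending time):
//   col 0: time (generations before present)
//   col 1: kind (0 = merge, 1 = admixture, 2 = size change)
//   col 2: a  (merge: source pop; admixture: target pop; size: pop)
//   col 3: b  (merge: destination; admixture: source 1)
//   col 4: c  (admixture: source 2)
//   col 5: x  (admixture: probability of source 1; size change: new N)
// Population indices are 0-based. Sizes are diploid N; the per-pair
// coalescence rate is 1 / (2 N scale), scale = 0.75 for Z-linked loci.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Tree {
  std::vector<int> parent;    // -1 for root
  std::vector<double> time;   // node times, tips at 0
};

static Tree sim_tree(std::vector<double> N, const NumericMatrix& ev,
                     const std::vector<int>& tip_pop, double scale) {
  const int n = (int) tip_pop.size();
  const int P = (int) N.size();
  Tree tr;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);
  std::vector< std::vector<int> > act(P);
  for (int i = 0; i < n; ++i) act[tip_pop[i]].push_back(i);
  int next_node = n;
  double t = 0.0;
  int ei = 0;
  const int nE = ev.nrow();
  int alive = n;
  while (alive > 1) {
    double rate = 0.0;
    for (int p = 0; p < P; ++p) {
      size_t k = act[p].size();
      if (k >= 2) rate += k * (k - 1.0) / 2.0 / (2.0 * N[p] * scale);
    }
    double t_next = (ei < nE) ? ev(ei, 0) : R_PosInf;
    double dt = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;
    if (t + dt >= t_next) {
      if (!R_FINITE(t_next))
        stop("lineages stranded in populations that never merge");
      t = t_next;
      int kind = (int) ev(ei, 1);
      int a = (int) ev(ei, 2);
      if (kind == 0) {
        int b = (int) ev(ei, 3);
        for (size_t q = 0; q < act[a].size(); ++q) act[b].push_back(act[a][q]);
        act[a].clear();
      } else if (kind == 1) {
        int b = (int) ev(ei, 3), c = (int) ev(ei, 4);
        double r = ev(ei, 5);
        for (size_t q = 0; q < act[a].size(); ++q) {
          if (unif_rand() < r) act[b].push_back(act[a][q]);
          else act[c].push_back(act[a][q]);
        }
        act[a].clear();
      } else {
        N[a] = ev(ei, 5);
      }
      ++ei;
      continue;
    }
    t += dt;
    double u = unif_rand() * rate, acc = 0.0;
    int pc = -1;
    for (int p = 0; p < P; ++p) {
      size_t k = act[p].size();
      if (k >= 2) {
        acc += k * (k - 1.0) / 2.0 / (2.0 * N[p] * scale);
        if (u <= acc) { pc = p; break; }
      }
    }
    if (pc < 0) { // numerical slack: take the last eligible population
      for (int p = P - 1; p >= 0; --p) if (act[p].size() >= 2) { pc = p; break; }
    }
    int k = (int) act[pc].size();
    int i1 = (int) (unif_rand() * k); if (i1 == k) --i1;
    int i2 = (int) (unif_rand() * (k - 1)); if (i2 == k - 1) --i2;
    if (i2 >= i1) ++i2;
    int c1 = act[pc][i1], c2 = act[pc][i2];
    int par = next_node++;
    tr.time[par] = t;
    tr.parent[c1] = par;
    tr.parent[c2] = par;
    if (i1 > i2) std::swap(i1, i2);
    act[pc].erase(act[pc].begin() + i2);
    act[pc].erase(act[pc].begin() + i1);
    act[pc].push_back(par);
    --alive;
  }
  return tr;
}

// Drop stepwise mutations on the tree and read off tip states.
// gsm_p = 0 gives the strict SMM (every step is +-1); gsm_p in (0,1) draws
// step magnitudes from a geometric distribution P(k) = (1-p) p^(k-1).
// Allele states reflect at 1 (repeat counts are positive) and, when
// range_high > 0, at range_high.
static std::vector<int> drop_mutations(const Tree& tr, int n_tips, double mu,
                                       double gsm_p, int ancestral,
                                       int range_high) {
  const int n_nodes = (int) tr.parent.size();
  std::vector<int> state(n_nodes, ancestral);
  // parents always have larger indices than children, so a reverse sweep
  // visits each parent before its children
  for (int v = n_nodes - 2; v >= 0; --v) {
    int par = tr.parent[v];
    if (par < 0) continue;
    double len = tr.time[par] - tr.time[v];
    int s = state[par];
    int nm = (int) R::rpois(mu * len);
    for (int m = 0; m < nm; ++m) {
      int step = 1;
      if (gsm_p > 0.0) step = 1 + (int) R::rgeom(1.0 - gsm_p);
      if (unif_rand() < 0.5) step = -step;
      s += step;
      while (s < 1 || (range_high > 0 && s > range_high)) {
        if (s < 1) s = 2 - s;
        if (range_high > 0 && s > range_high) s = 2 * range_high - s;
      }
    }
    state[v] = s;
  }
  return std::vector<int>(state.begin(), state.begin() + n_tips);
}

// [[Rcpp::export]]
List sim_genealogy_cpp(NumericVector pop_sizes, NumericMatrix events,
                       IntegerVector tip_pop, double scale) {
  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  std::vector<int> tp(tip_pop.begin(), tip_pop.end());
  Tree tr = sim_tree(N, events, tp, scale);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["node_time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["n_tips"] = (int) tp.size());
}

// [[Rcpp::export]]
IntegerVector sim_locus_states_cpp(NumericVector pop_sizes, NumericMatrix events,
                                   IntegerVector tip_pop, double scale,
                                   double mu, double gsm_p, int ancestral,
                                   int range_high) {
  std::vector<double> N(pop_sizes.begin(), pop_sizes.end());
  std::vector<int> tp(tip_pop.begin(), tip_pop.end());
  Tree tr = sim_tree(N, events, tp, scale);
  std::vector<int> st = drop_mutations(tr, (int) tp.size(), mu, gsm_p,
                                       ancestral, range_high);
  return IntegerVector(st.begin(), st.end());
}

// ---- summary statistics fast path -----------------------------------------
// Copies at a locus are laid out population block by population block; within
// a population, males first (two adjacent copies each), then females (two
// copies each at autosomal loci, one at Z-linked loci). Diploid genotypes for
// the F_ST components are the adjacent copy pairs of males plus, at
// autosomal loci, of females.

struct PopLocStats {
  double n_alleles, he, var;                 // per-population per-locus
  std::vector<double> mean_size;             // per population
};

// Weir-Cockerham a and a+b+c for one locus between two populations given
// diploid genotype arrays (g1a,g1b) and (g2a,g2b)
static void wc_pair(const std::vector<int>& g1a, const std::vector<int>& g1b,
                    const std::vector<int>& g2a, const std::vector<int>& g2b,
                    double& A, double& ABC) {
  int n1 = (int) g1a.size(), n2 = (int) g2a.size();
  if (n1 < 1 || n2 < 1) return;
  double nbar = (n1 + n2) / 2.0;
  if (nbar <= 1.0) return;
  const double r = 2.0;
  double nc = (r * nbar - (double(n1) * n1 + double(n2) * n2) / (r * nbar)) / (r - 1.0);
  if (nc <= 0.0) return;
  std::vector<int> alleles;
  for (int i = 0; i < n1; ++i) { alleles.push_back(g1a[i]); alleles.push_back(g1b[i]); }
  for (int i = 0; i < n2; ++i) { alleles.push_back(g2a[i]); alleles.push_back(g2b[i]); }
  std::sort(alleles.begin(), alleles.end());
  alleles.erase(std::unique(alleles.begin(), alleles.end()), alleles.end());
  for (size_t q = 0; q < alleles.size(); ++q) {
    int Aall = alleles[q];
    double c1 = 0, h1 = 0, c2 = 0, h2 = 0;
    for (int i = 0; i < n1; ++i) {
      c1 += (g1a[i] == Aall) + (g1b[i] == Aall);
      h1 += (g1a[i] == Aall) != (g1b[i] == Aall);
    }
    for (int i = 0; i < n2; ++i) {
      c2 += (g2a[i] == Aall) + (g2b[i] == Aall);
      h2 += (g2a[i] == Aall) != (g2b[i] == Aall);
    }
    double p1 = c1 / (2.0 * n1), p2 = c2 / (2.0 * n2);
    double hf1 = h1 / n1, hf2 = h2 / n2;
    double pbar = (n1 * p1 + n2 * p2) / (r * nbar);
    double s2 = (n1 * (p1 - pbar) * (p1 - pbar) + n2 * (p2 - pbar) * (p2 - pbar)) /
      ((r - 1.0) * nbar);
    double hbar = (n1 * hf1 + n2 * hf2) / (r * nbar);
    double a = (nbar / nc) *
      (s2 - (1.0 / (nbar - 1.0)) * (pbar * (1.0 - pbar) - ((r - 1.0) / r) * s2 - hbar / 4.0));
    double b = (nbar / (nbar - 1.0)) *
      (pbar * (1.0 - pbar) - ((r - 1.0) / r) * s2 - ((2.0 * nbar - 1.0) / (4.0 * nbar)) * hbar);
    double c = hbar / 2.0;
    A += a;
    ABC += a + b + c;
  }
}

// [[Rcpp::export]]
NumericVector sim_summary_cpp(NumericVector pop_sizes, NumericMatrix events,
                              IntegerVector n_males, IntegerVector n_females,
                              LogicalVector z_linked, double mu, double gsm_p,
                              int ancestral, int range_high) {
  const int P = pop_sizes.size();
  const int L = z_linked.size();
  const int npair = P * (P - 1) / 2;
  // accumulators
  std::vector<double> acc_nall(P, 0), acc_he(P, 0), acc_var(P, 0);
  std::vector<double> thA(npair, 0), thABC(npair, 0), dmu2(npair, 0);
  std::vector<double> N0(pop_sizes.begin(), pop_sizes.end());

  for (int l = 0; l < L; ++l) {
    bool z = z_linked[l];
    double scale = z ? 0.75 : 1.0;
    // tip layout
    std::vector<int> tip_pop;
    std::vector<int> block_start(P), block_len(P);
    for (int p = 0; p < P; ++p) {
      int nc = 2 * n_males[p] + (z ? 1 : 2) * n_females[p];
      block_start[p] = (int) tip_pop.size();
      block_len[p] = nc;
      for (int i = 0; i < nc; ++i) tip_pop.push_back(p);
    }
    Tree tr = sim_tree(N0, events, tip_pop, scale);
    std::vector<int> st = drop_mutations(tr, (int) tip_pop.size(), mu, gsm_p,
                                         ancestral, range_high);
    std::vector<double> msize(P, 0);
    for (int p = 0; p < P; ++p) {
      int s0 = block_start[p], len = block_len[p];
      // allele count, He, size variance on all copies
      std::vector<int> cp(st.begin() + s0, st.begin() + s0 + len);
      std::vector<int> u(cp); std::sort(u.begin(), u.end());
      u.erase(std::unique(u.begin(), u.end()), u.end());
      acc_nall[p] += (double) u.size();
      double sum = 0, sum2 = 0;
      for (int i = 0; i < len; ++i) { sum += cp[i]; sum2 += (double) cp[i] * cp[i]; }
      double mean = sum / len;
      msize[p] = mean;
      if (len > 1) {
        acc_var[p] += (sum2 - len * mean * mean) / (len - 1.0);
        double sp2 = 0;
        for (size_t q = 0; q < u.size(); ++q) {
          int cnt = 0;
          for (int i = 0; i < len; ++i) cnt += (cp[i] == u[q]);
          double f = (double) cnt / len;
          sp2 += f * f;
        }
        acc_he[p] += ((double) len / (len - 1.0)) * (1.0 - sp2);
      }
    }
    // pairwise theta (male-only genotypes at Z loci) and delta-mu^2
    int pair = 0;
    for (int i = 0; i < P; ++i) for (int j = i + 1; j < P; ++j, ++pair) {
      double d = msize[i] - msize[j];
      dmu2[pair] += d * d;
      // genotypes: males then (autosomal only) females
      std::vector<int> gia, gib, gja, gjb;
      int ndip_i = n_males[i] + (z ? 0 : n_females[i]);
      int ndip_j = n_males[j] + (z ? 0 : n_females[j]);
      for (int q = 0; q < ndip_i; ++q) {
        gia.push_back(st[block_start[i] + 2 * q]);
        gib.push_back(st[block_start[i] + 2 * q + 1]);
      }
      for (int q = 0; q < ndip_j; ++q) {
        gja.push_back(st[block_start[j] + 2 * q]);
        gjb.push_back(st[block_start[j] + 2 * q + 1]);
      }
      wc_pair(gia, gib, gja, gjb, thA[pair], thABC[pair]);
    }
  }
  NumericVector out(3 * P + 2 * npair);
  int o = 0;
  for (int p = 0; p < P; ++p) {
    out[o++] = acc_nall[p] / L;
    out[o++] = acc_he[p] / L;
    out[o++] = acc_var[p] / L;
  }
  for (int pair = 0; pair < npair; ++pair) {
    out[o++] = (thABC[pair] > 0.0) ? thA[pair] / thABC[pair] : 0.0;
    out[o++] = dmu2[pair] / L;
  }
  return out;
}
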