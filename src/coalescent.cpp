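#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured-coalescent genealogy simulation for independent loci under a
// two-epoch hierarchical island model:
//   [0, t_split)      : all demes active, emigration matrix mig1
//   [t_split, t_anc)  : demes flagged `young` have been fused into `anchor`,
//                       emigration matrix mig2 (within the surviving demes)
//   [t_anc, inf)      : every deme fused into `anchor`, no migration
// Time is in generations backward from sampling; `ne` are diploid sizes, so a
// pair of lineages in deme d coalesces at rate 1/(2 Ne_d) and k lineages at
// rate k(k-1)/(4 Ne_d). mig1/mig2 rows are per-lineage backward emigration
// rates to each target deme (diagonal ignored).

namespace {

struct Tree {
  // nodes 0..n-1 are tips; internals appended in coalescence (time) order,
  // so child index < parent index always; root is node 2n-2.
  std::vector<int> par, ch1, ch2;
  std::vector<double> tim;
  int n_tips;
  double total_len;

  void resize(int n) {
    n_tips = n;
    par.assign(2 * n - 1, -1);
    ch1.assign(2 * n - 1, -1);
    ch2.assign(2 * n - 1, -1);
    tim.assign(2 * n - 1, 0.0);
  }
};

class CoalSim {
 public:
  CoalSim(const IntegerVector& deme_of, const NumericVector& ne,
          const NumericMatrix& mig1, const NumericMatrix& mig2,
          double t_split, double t_anc, const LogicalVector& young, int anchor)
      : deme_of_(deme_of), mig1_(mig1), mig2_(mig2),
        t_split_(t_split), t_anc_(t_anc), young_(young), anchor_(anchor) {
    n_ = deme_of.size();
    nd_ = ne.size();
    inv4ne_.resize(nd_);
    for (int d = 0; d < nd_; ++d) {
      if (ne[d] <= 0) stop("non-positive effective size");
      inv4ne_[d] = 1.0 / (4.0 * ne[d]);
    }
    row1_.assign(nd_, 0.0);
    row2_.assign(nd_, 0.0);
    for (int d = 0; d < nd_; ++d) {
      for (int j = 0; j < nd_; ++j) {
        if (j == d) continue;
        row1_[d] += mig1(d, j);
        row2_[d] += mig2(d, j);
      }
    }
  }

  // simulate one genealogy of all tips; fills tree
  void simulate(Tree& tree) {
    tree.resize(n_);
    std::vector<std::vector<int> >& byd = byd_;
    byd.assign(nd_, std::vector<int>());
    for (int i = 0; i < n_; ++i) byd[deme_of_[i]].push_back(i);

    int active = n_;
    int next_node = n_;
    int phase = 0;  // 0: [0,t_split), 1: [t_split,t_anc), 2: beyond
    double t = 0.0;
    if (t_split_ <= 0.0) { fuse_young(byd); phase = 1; }

    while (active > 1) {
      const std::vector<double>& rowtot = (phase == 0) ? row1_ : row2_;
      const NumericMatrix& mig = (phase == 0) ? mig1_ : mig2_;
      double C = 0.0, M = 0.0;
      for (int d = 0; d < nd_; ++d) {
        double k = (double)byd[d].size();
        if (k > 1) C += k * (k - 1) * inv4ne_[d];
        if (phase < 2 && k > 0) M += k * rowtot[d];
      }
      double R = C + M;
      double bound = (phase == 0) ? t_split_ : ((phase == 1) ? t_anc_ : R_PosInf);
      if (R <= 0.0) {
        if (!R_FINITE(bound))
          stop("model has an unreachable common ancestor (no coalescence or migration possible)");
        t = bound;
        advance_phase(byd, phase);
        continue;
      }
      double dt = exp_rand() / R;
      if (R_FINITE(bound) && t + dt >= bound) {
        t = bound;
        advance_phase(byd, phase);
        continue;
      }
      t += dt;
      double u = unif_rand() * R;
      if (u < C) {
        // coalescence: pick deme proportional to k(k-1)/(4Ne)
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < nd_; ++dd) {
          double k = (double)byd[dd].size();
          if (k > 1) acc += k * (k - 1) * inv4ne_[dd];
          if (u < acc) { d = dd; break; }
        }
        if (d < 0) continue;  // numerical slip; redraw
        std::vector<int>& L = byd[d];
        int k = (int)L.size();
        int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
        int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
        if (j >= i) ++j;
        int a = L[i], b = L[j];
        int v = next_node++;
        tree.par[a] = v; tree.par[b] = v;
        tree.ch1[v] = a; tree.ch2[v] = b;
        tree.tim[v] = t;
        // remove i and j (larger index first), then push v
        if (i < j) std::swap(i, j);
        L[i] = L.back(); L.pop_back();
        L[j] = L.back(); L.pop_back();
        L.push_back(v);
        --active;
      } else {
        // migration: pick source deme proportional to k * rowtot
        u -= C;
        int d = -1;
        double acc = 0.0;
        for (int dd = 0; dd < nd_; ++dd) {
          acc += (double)byd[dd].size() * rowtot[dd];
          if (u < acc) { d = dd; break; }
        }
        if (d < 0) continue;
        std::vector<int>& L = byd[d];
        int k = (int)L.size();
        int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
        // destination proportional to mig(d, j)
        double w = unif_rand() * rowtot[d];
        int dest = -1;
        double acc2 = 0.0;
        for (int j = 0; j < nd_; ++j) {
          if (j == d) continue;
          acc2 += mig(d, j);
          if (w < acc2) { dest = j; break; }
        }
        if (dest < 0) continue;
        int lin = L[i];
        L[i] = L.back(); L.pop_back();
        byd[dest].push_back(lin);
      }
    }

    tree.total_len = 0.0;
    int root = 2 * n_ - 2;
    for (int v = 0; v < root; ++v)
      tree.total_len += tree.tim[tree.par[v]] - tree.tim[v];
  }

 private:
  void fuse_young(std::vector<std::vector<int> >& byd) {
    for (int d = 0; d < nd_; ++d) {
      if (d != anchor_ && young_[d]) {
        std::vector<int>& src = byd[d];
        byd[anchor_].insert(byd[anchor_].end(), src.begin(), src.end());
        src.clear();
      }
    }
  }
  void fuse_all(std::vector<std::vector<int> >& byd) {
    for (int d = 0; d < nd_; ++d) {
      if (d != anchor_) {
        std::vector<int>& src = byd[d];
        byd[anchor_].insert(byd[anchor_].end(), src.begin(), src.end());
        src.clear();
      }
    }
  }
  void advance_phase(std::vector<std::vector<int> >& byd, int& phase) {
    if (phase == 0) fuse_young(byd); else fuse_all(byd);
    ++phase;
  }

  IntegerVector deme_of_;
  NumericMatrix mig1_, mig2_;
  double t_split_, t_anc_;
  LogicalVector young_;
  int anchor_, n_, nd_;
  std::vector<double> inv4ne_, row1_, row2_;
  std::vector<std::vector<int> > byd_;
};

// mark the leaves descending from `node`; relies on child index < parent index
void mark_descendant_leaves(const Tree& tree, int node, std::vector<char>& flag) {
  std::fill(flag.begin(), flag.end(), 0);
  flag[node] = 1;
  for (int v = node - 1; v >= 0; --v)
    if (tree.par[v] >= 0 && flag[tree.par[v]]) flag[v] = 1;
}

}  // namespace

// SNP mode: one segregating site per locus, ascertained polymorphic in the
// total sample. Trees are sampled with weight proportional to their total
// branch length (the infinite-sites ascertainment measure) via Poisson
// acceptance: K ~ Poisson(r * len), accept with probability min(K, cmax)/cmax,
// then place the mutation uniformly along the accepted tree. The truncation
// error is below Poisson tail mass P(K > cmax), negligible for the defaults.
// Returns a (n_haplotypes x n_loci) 0/1 matrix of derived-allele indicators.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_snp(int n_loci, IntegerVector deme_of, NumericVector ne,
                          NumericMatrix mig1, NumericMatrix mig2,
                          double t_split, double t_anc, LogicalVector young,
                          int anchor, double lambda_target, int cmax) {
  int n = deme_of.size();
  if (n < 2) stop("need at least two haplotypes");
  CoalSim sim(deme_of, ne, mig1, mig2, t_split, t_anc, young, anchor);
  Tree tree;
  IntegerMatrix out(n, n_loci);

  // pilot trees calibrate the Poisson rate so acceptance ~ lambda_target/cmax
  double pilot_len = 0.0;
  const int n_pilot = 3;
  for (int i = 0; i < n_pilot; ++i) { sim.simulate(tree); pilot_len += tree.total_len; }
  double r = lambda_target / (pilot_len / n_pilot);

  std::vector<char> flag(2 * n - 1);
  for (int l = 0; l < n_loci; ++l) {
    if (l % 64 == 0) checkUserInterrupt();
    for (;;) {
      sim.simulate(tree);
      double k = R::rpois(r * tree.total_len);
      if (k < 1.0) continue;
      if (k > cmax) k = cmax;
      if (unif_rand() * cmax < k) break;
    }
    double u = unif_rand() * tree.total_len;
    int root = 2 * n - 2, hit = -1;
    double acc = 0.0;
    for (int v = 0; v < root; ++v) {
      acc += tree.tim[tree.par[v]] - tree.tim[v];
      if (u < acc) { hit = v; break; }
    }
    if (hit < 0) hit = root - 1;
    mark_descendant_leaves(tree, hit, flag);
    for (int i = 0; i < n; ++i) out(i, l) = flag[i] ? 1 : 0;
  }
  return out;
}

// Microsatellite mode: same genealogies, mutations Poisson along branches at
// rate `mu` per generation, stepwise mutation model (+-1 repeat with equal
// probability) from `root_state`. No ascertainment. Returns repeat counts.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_microsat(int n_loci, IntegerVector deme_of, NumericVector ne,
                               NumericMatrix mig1, NumericMatrix mig2,
                               double t_split, double t_anc, LogicalVector young,
                               int anchor, double mu, int root_state) {
  int n = deme_of.size();
  if (n < 2) stop("need at least two haplotypes");
  CoalSim sim(deme_of, ne, mig1, mig2, t_split, t_anc, young, anchor);
  Tree tree;
  IntegerMatrix out(n, n_loci);
  std::vector<int> allele(2 * n - 1);

  for (int l = 0; l < n_loci; ++l) {
    if (l % 64 == 0) checkUserInterrupt();
    sim.simulate(tree);
    int root = 2 * n - 2;
    allele[root] = root_state;
    for (int v = root - 1; v >= 0; --v) {
      double len = tree.tim[tree.par[v]] - tree.tim[v];
      int nm = (mu > 0.0 && len > 0.0) ? (int)R::rpois(mu * len) : 0;
      int a = allele[tree.par[v]];
      for (int m = 0; m < nm; ++m) a += (unif_rand() < 0.5) ? 1 : -1;
      allele[v] = a;
    }
    for (int i = 0; i < n; ++i) out(i, l) = allele[i];
  }
  return out;
}
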