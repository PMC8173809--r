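#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Backward-in-time coalescent over a set of populations with
// piecewise-constant diploid sizes and a sorted schedule of demographic
// events. Event matrix columns: time, type, a, b, c, x.
//   type 0: size change      -- population a takes diploid size x
//   type 1: merge            -- all lineages in a move to b (a stays empty)
//   type 2: admixture pulse  -- each lineage in a moves to b with
//                               probability x, otherwise to c (c may equal a)
// Times are generations before present; the schedule must be sorted
// ascending and must eventually funnel every lineage into one population.

namespace {

// reusable per-locus workspace; node indices respect creation order, so a
// parent always has a higher index than its children
struct Workspace {
  std::vector<int> parent;
  std::vector<double> node_time;
  std::vector< std::vector<int> > lin;   // active lineages per population
  std::vector<int> stay;                 // scratch for admixture pulses
  std::vector<char> derived;             // per-leaf derived-allele flags
  std::vector<char> mark;                // per-node descendant flags
  int n_leaves;
  int n_nodes;
  double tmrca;
};

inline int runif_int(int k) {
  int i = (int) (unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// One realisation of the genealogy of `nsam[p]` haploid lineages per
// population. Returns false if lineages failed to coalesce (bad schedule).
bool sim_genealogy(const NumericMatrix& events,
                   const NumericVector& sizes0,
                   const IntegerVector& nsam,
                   Workspace& w) {
  const int P = sizes0.size();
  double N[64];
  for (int p = 0; p < P; ++p) N[p] = sizes0[p];

  int n_leaves = 0;
  for (int p = 0; p < P; ++p) n_leaves += nsam[p];
  const int max_nodes = 2 * n_leaves - 1;

  w.parent.assign(max_nodes, -1);
  w.node_time.assign(max_nodes, 0.0);
  w.n_leaves = n_leaves;
  if ((int) w.lin.size() < P) w.lin.resize(P);
  int idx = 0;
  for (int p = 0; p < P; ++p) {
    w.lin[p].clear();
    for (int j = 0; j < nsam[p]; ++j) w.lin[p].push_back(idx++);
  }

  int next_node = n_leaves;
  double t = 0.0;
  int ev = 0;
  const int nE = events.nrow();
  int total = n_leaves;

  while (total > 1) {
    double rate = 0.0;
    for (int p = 0; p < P; ++p) {
      const double k = (double) w.lin[p].size();
      if (k >= 2.0) rate += k * (k - 1.0) / (4.0 * N[p]);
    }
    const double tnext = (ev < nE) ? events(ev, 0) : R_PosInf;
    const double wt = (rate > 0.0) ? R::rexp(1.0 / rate) : R_PosInf;

    if (rate > 0.0 && t + wt < tnext) {
      t += wt;
      // choose population proportional to its coalescence rate
      double u = unif_rand() * rate, acc = 0.0;
      int cp = -1;
      for (int p = 0; p < P; ++p) {
        const double k = (double) w.lin[p].size();
        if (k >= 2.0) {
          acc += k * (k - 1.0) / (4.0 * N[p]);
          cp = p;
          if (u <= acc) break;
        }
      }
      std::vector<int>& L = w.lin[cp];
      const int k = (int) L.size();
      int i = runif_int(k);
      int j = runif_int(k - 1);
      if (j >= i) ++j;
      const int a = L[i], b = L[j];
      const int nn = next_node++;
      w.node_time[nn] = t;
      w.parent[a] = nn;
      w.parent[b] = nn;
      // replace lineage i by the new node, swap-remove j
      L[i] = nn;
      L[j] = L.back();
      L.pop_back();
      --total;
    } else if (R_finite(tnext)) {
      t = tnext;
      const int type = (int) events(ev, 1);
      const int a = (int) events(ev, 2);
      if (type == 0) {
        N[a] = events(ev, 5);
      } else if (type == 1) {
        const int b = (int) events(ev, 3);
        std::vector<int>& src = w.lin[a];
        std::vector<int>& dst = w.lin[b];
        dst.insert(dst.end(), src.begin(), src.end());
        src.clear();
      } else if (type == 2) {
        const int b = (int) events(ev, 3);
        const int c = (int) events(ev, 4);
        const double pr = events(ev, 5);
        w.stay.clear();
        for (size_t q = 0; q < w.lin[a].size(); ++q) {
          const int node = w.lin[a][q];
          if (unif_rand() < pr) w.lin[b].push_back(node);
          else if (c == a) w.stay.push_back(node);
          else w.lin[c].push_back(node);
        }
        w.lin[a].swap(w.stay);
      }
      ++ev;
    } else {
      return false;  // stuck: no coalescence possible, no events left
    }
  }
  w.n_nodes = next_node;
  w.tmrca = w.node_time[next_node - 1];
  return true;
}

// Drop a single mutation uniformly on the genealogy's total branch length
// and flag carriers of the derived allele among the leaves. Descendant
// marking walks nodes top-down, exploiting parent index > child index.
void drop_mutation(Workspace& w) {
  const int root = w.n_nodes - 1;
  double total_len = 0.0;
  for (int i = 0; i < root; ++i)
    total_len += w.node_time[w.parent[i]] - w.node_time[i];

  double u = unif_rand() * total_len, acc = 0.0;
  int m = root - 1;
  for (int i = 0; i < root; ++i) {
    acc += w.node_time[w.parent[i]] - w.node_time[i];
    if (u <= acc) { m = i; break; }
  }

  w.derived.assign(w.n_leaves, 0);
  if (m < w.n_leaves) {
    w.derived[m] = 1;
    return;
  }
  w.mark.assign(w.n_nodes, 0);
  w.mark[m] = 1;
  for (int i = m - 1; i >= 0; --i)
    w.mark[i] = w.mark[w.parent[i]];
  for (int i = 0; i < w.n_leaves; ++i) w.derived[i] = w.mark[i];
}

}  // namespace

// [[Rcpp::export(name = ".simulate_genotypes_cpp")]]
List simulate_genotypes_cpp(NumericMatrix events,
                            NumericVector sizes0,
                            IntegerVector nsam_hap,
                            int n_loci,
                            double min_maf,
                            int max_retries) {
  const int P = sizes0.size();
  if (P > 64) stop("at most 64 populations supported");
  int n_leaves = 0;
  for (int p = 0; p < P; ++p) n_leaves += nsam_hap[p];
  if (n_leaves % 2 != 0)
    stop("total haploid sample size must be even to form diploids");
  const int n_ind = n_leaves / 2;

  IntegerMatrix G(n_ind, n_loci);
  Workspace w;
  long long retries_total = 0;

  for (int l = 0; l < n_loci; ++l) {
    int tries = 0;
    for (;;) {
      if (++tries > max_retries)
        stop("locus %d: exceeded %d retries at MAF floor %.3f",
             l + 1, max_retries, min_maf);
      if (!sim_genealogy(events, sizes0, nsam_hap, w))
        stop("lineages failed to coalesce; demographic schedule has no root");
      drop_mutation(w);
      int cnt = 0;
      for (int i = 0; i < n_leaves; ++i) cnt += w.derived[i];
      const double f = (double) cnt / (double) n_leaves;
      const double maf = f < 0.5 ? f : 1.0 - f;
      if (maf >= min_maf - 1e-12) break;
    }
    retries_total += tries - 1;
    for (int i = 0; i < n_ind; ++i)
      G(i, l) = w.derived[2 * i] + w.derived[2 * i + 1];
  }

  return List::create(_["genotypes"] = G,
                      _["n_retries"] = (double) retries_total);
}

// [[Rcpp::export(name = ".pair_tmrca_cpp")]]
NumericVector pair_tmrca_cpp(NumericMatrix events,
                             NumericVector sizes0,
                             int pop_a,
                             int pop_b,
                             int n_reps) {
  const int P = sizes0.size();
  IntegerVector nsam(P);
  nsam[pop_a] += 1;
  nsam[pop_b] += 1;
  NumericVector out(n_reps);
  Workspace w;
  for (int r = 0; r < n_reps; ++r) {
    if (!sim_genealogy(events, sizes0, nsam, w))
      stop("lineages failed to coalesce; demographic schedule has no root");
    out[r] = w.tmrca;
  }
  return out;
}
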