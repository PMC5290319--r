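#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Cell-level Gillespie birth-death growth of one tumour site, from a single
// founder cell until extinction or n_switch cells.  Each birth creates a
// daughter that acquires a new SNV genotype with probability u and a new
// CNV genotype with probability cnv_rate; with probability q_mig the
// daughter emigrates (a metastasis seeding attempt) instead of staying.
// Uses R's RNG so set.seed() in R controls reproducibility.
// [[Rcpp::export(name = ".grow_site")]]
List grow_site(double b, double d, double u, double cnv_rate, double q_mig,
               int n_switch, int founder_geno, int next_geno_id, double t0) {
  RNGScope scope;
  std::vector<int> cells;
  cells.reserve(n_switch + 1);
  cells.push_back(founder_geno);
  const double pb = b / (b + d);

  std::vector<int> g_id, g_parent, g_type;
  std::vector<double> g_time;
  std::vector<double> mig_time;
  std::vector<int> mig_geno;
  std::vector<double> checkpoints(31, NA_REAL);  // first time n >= 2^k
  checkpoints[0] = t0;
  double t = t0;
  long long births = 0;
  const long long max_events = 4e9;
  long long events = 0;

  while (!cells.empty() && (int)cells.size() < n_switch) {
    if (++events > max_events) stop("site growth exceeded event budget");
    const int n = cells.size();
    t += R::exp_rand() / (n * (b + d));
    int idx = (int)(unif_rand() * n);
    if (idx >= n) idx = n - 1;
    if (unif_rand() < pb) {
      ++births;
      int g = cells[idx];
      if (unif_rand() < u) {
        g_id.push_back(next_geno_id); g_parent.push_back(g);
        g_type.push_back(0); g_time.push_back(t);
        g = next_geno_id++;
      }
      if (unif_rand() < cnv_rate) {
        g_id.push_back(next_geno_id); g_parent.push_back(g);
        g_type.push_back(1); g_time.push_back(t);
        g = next_geno_id++;
      }
      if (q_mig > 0 && unif_rand() < q_mig) {
        mig_time.push_back(t); mig_geno.push_back(g);
      } else {
        cells.push_back(g);
        int k = 0, sz = cells.size();
        while ((1 << k) <= sz) ++k;  // k = floor(log2(sz)) + 1
        if (k - 1 < 31 && ISNA(checkpoints[k - 1])) checkpoints[k - 1] = t;
      }
    } else {
      cells[idx] = cells.back();
      cells.pop_back();
    }
  }

  std::unordered_map<int, int> comp;
  for (int g : cells) ++comp[g];
  IntegerVector comp_geno(comp.size()), comp_count(comp.size());
  int k = 0;
  for (auto &kv : comp) { comp_geno[k] = kv.first; comp_count[k] = kv.second; ++k; }

  return List::create(
    _["extinct"] = cells.empty(),
    _["t_end"] = t,
    _["births"] = (double)births,
    _["geno_id"] = wrap(g_id),
    _["geno_parent"] = wrap(g_parent),
    _["geno_type"] = wrap(g_type),
    _["geno_time"] = wrap(g_time),
    _["next_geno_id"] = next_geno_id,
    _["mig_time"] = wrap(mig_time),
    _["mig_geno"] = wrap(mig_geno),
    _["comp_geno"] = comp_geno,
    _["comp_count"] = comp_count,
    _["checkpoints"] = wrap(checkpoints));
}

// Count-only birth-death survival simulation: fraction of single lineages
// that reach `cap` cells before extinction (cap chosen so that later
// extinction is negligible, (d/b)^cap).
// [[Rcpp::export(name = ".sim_survival")]]
int sim_survival(double b, double d, int reps, int cap) {
  RNGScope scope;
  const double pb = b / (b + d);
  int surv = 0;
  for (int r = 0; r < reps; ++r) {
    int n = 1;
    while (n > 0 && n < cap) {
      if (unif_rand() < pb) ++n; else --n;
    }
    if (n > 0) ++surv;
  }
  return surv;
}

// Push per-genotype cell counts up the genotype tree: the result for node g
// is the total count of cells whose genotype is g or any descendant of g.
// `parent` is 1-based with 0 for the root's parent; nodes must be ordered so
// that parents precede children (true by construction).
// [[Rcpp::export(name = ".accumulate_descendants")]]
NumericVector accumulate_descendants(IntegerVector parent,
                                     NumericVector counts) {
  int n = parent.size();
  NumericVector out = clone(counts);
  for (int i = n - 1; i >= 0; --i) {
    int p = parent[i];
    if (p > 0) out[p - 1] += out[i];
  }
  return out;
}
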