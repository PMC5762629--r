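#include <Rcpp.h>
using namespace Rcpp;

// Unbiased expected heterozygosity from allele counts of n gene copies:
// (n / (n - 1)) * (1 - sum p_i^2)
static double het_unbiased(const std::vector<int>& cnt, int n) {
  double sum2 = 0.0;
  for (size_t i = 0; i < cnt.size(); ++i) {
    double p = (double)cnt[i] / n;
    sum2 += p * p;
  }
  return (double)n / (n - 1) * (1.0 - sum2);
}

// Ewens / Chinese-restaurant draw of an allele configuration for n copies
// under the infinite-alleles model at scaled mutation rate theta.
static void crp_draw(int n, double theta, std::vector<int>& cnt) {
  cnt.clear();
  for (int i = 0; i < n; ++i) {
    double u = unif_rand() * (theta + i);
    if (u < theta || cnt.empty()) {
      cnt.push_back(1);
    } else {
      // choose an existing copy uniformly
      double v = unif_rand() * i;
      double acc = 0.0;
      for (size_t j = 0; j < cnt.size(); ++j) {
        acc += cnt[j];
        if (v < acc) { cnt[j]++; break; }
      }
    }
  }
}

// One coalescent genealogy of n copies with stepwise mutations under the
// two-phase model: each mutation is +/-1 with probability p_ss, otherwise
// +/- a geometric(step_p) multi-step. Allele states are integers (sizes);
// returns counts of distinct states.
static void coal_tpm_draw(int n, double theta, double p_ss, double step_p,
                          std::vector<int>& cnt) {
  int total = 2 * n - 1;
  std::vector<int> parent(total, -1);
  std::vector<double> birth(total, 0.0), blen(total, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int next = n;
  double t = 0.0;
  while ((int)active.size() > 1) {
    int j = active.size();
    t += exp_rand() * 2.0 / (j * (j - 1));
    int i1 = (int)(unif_rand() * j);
    int i2 = (int)(unif_rand() * (j - 1));
    if (i2 >= i1) i2++;
    int a = active[i1], b = active[i2];
    parent[a] = next; parent[b] = next;
    blen[a] = t - birth[a]; blen[b] = t - birth[b];
    birth[next] = t;
    if (i1 > i2) std::swap(i1, i2);
    active.erase(active.begin() + i2);
    active[i1] = next;
    next++;
  }
  // allele sizes top-down (root state 0)
  std::vector<int> state(total, 0);
  for (int v = total - 2; v >= 0; --v) {
    int nm = (int)R::rpois(theta / 2.0 * blen[v]);
    int s = state[parent[v]];
    for (int m = 0; m < nm; ++m) {
      int step = 1;
      if (unif_rand() >= p_ss) step = (int)R::rgeom(step_p) + 1;
      s += (unif_rand() < 0.5) ? step : -step;
    }
    state[v] = s;
  }
  std::map<int, int> tab;
  for (int i = 0; i < n; ++i) tab[state[i]]++;
  cnt.clear();
  for (std::map<int, int>::iterator it = tab.begin(); it != tab.end(); ++it)
    cnt.push_back(it->second);
}

// Null distribution of heterozygosity conditional on the observed allele
// count: simulate samples of n gene copies at mutation rates theta_grid,
// retain those whose allele count equals k_obs, until n_sim values are
// collected or the attempt budget is exhausted. model: 0 = IAM (Ewens
// configuration), 1 = SMM/TPM coalescent (p_ss = 1 gives strict SMM).
// [[Rcpp::export(name = ".sim_heq_conditional")]]
NumericVector sim_heq_conditional(int n, int k_obs, NumericVector theta_grid,
                                  int model, double p_ss, double step_p,
                                  int n_sim, int max_attempts) {
  RNGScope scope;
  std::vector<double> out;
  out.reserve(n_sim);
  std::vector<int> cnt;
  int attempts = 0, g = 0;
  while ((int)out.size() < n_sim && attempts < max_attempts) {
    double theta = theta_grid[g % theta_grid.size()];
    g++;
    attempts++;
    if (model == 0) crp_draw(n, theta, cnt);
    else coal_tpm_draw(n, theta, p_ss, step_p, cnt);
    if ((int)cnt.size() == k_obs) out.push_back(het_unbiased(cnt, n));
  }
  return wrap(out);
}

// Raw (unconditional) samples of (k, He) at one theta — used for
// calibration fixtures and the mutation-model ordering checks.
// [[Rcpp::export(name = ".sim_k_het")]]
NumericMatrix sim_k_het(int n, double theta, int model, double p_ss,
                        double step_p, int n_sim) {
  RNGScope scope;
  NumericMatrix out(n_sim, 2);
  std::vector<int> cnt;
  for (int s = 0; s < n_sim; ++s) {
    if (model == 0) crp_draw(n, theta, cnt);
    else coal_tpm_draw(n, theta, p_ss, step_p, cnt);
    out(s, 0) = cnt.size();
    out(s, 1) = het_unbiased(cnt, n);
  }
  return out;
}

// Ewens configuration draw exposed for the synthetic equilibrium
// populations used in calibration studies.
// [[Rcpp::export(name = ".crp_counts")]]
IntegerVector crp_counts(int n, double theta) {
  RNGScope scope;
  std::vector<int> cnt;
  crp_draw(n, theta, cnt);
  return wrap(cnt);
}
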