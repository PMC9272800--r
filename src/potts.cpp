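#include <Rcpp.h>
using namespace Rcpp;

// Neighbour structure convention used throughout: `nbr` is an n x 4 integer
// matrix of 1-based site indices, 0 where a site has fewer than 4 neighbours.
// The relation is symmetric; unordered neighbour pairs are counted once by
// only looking at t > s.

// [[Rcpp::export]]
int cpp_concordant_pairs(const IntegerMatrix& nbr, const IntegerVector& z) {
  int n = nbr.nrow(), cnt = 0;
  for (int s = 0; s < n; ++s) {
    for (int a = 0; a < 4; ++a) {
      int t = nbr(s, a);
      if (t > s + 1 && z[t - 1] == z[s]) ++cnt;  // t is 1-based
    }
  }
  return cnt;
}

static inline void gibbs_site(int s, IntegerVector& z, const IntegerMatrix& nbr,
                              int K, double gamma, std::vector<double>& w) {
  // full conditional P(z_s = k) ~ exp(gamma * #neighbours with label k)
  for (int k = 0; k < K; ++k) w[k] = 0.0;
  for (int a = 0; a < 4; ++a) {
    int t = nbr(s, a);
    if (t > 0) w[z[t - 1] - 1] += 1.0;
  }
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { w[k] = std::exp(gamma * w[k]); tot += w[k]; }
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) { z[s] = k + 1; return; }
  }
  z[s] = K;
}

// [[Rcpp::export]]
IntegerVector cpp_potts_gibbs(const IntegerMatrix& nbr, int K, double gamma,
                              int sweeps, IntegerVector init) {
  int n = nbr.nrow();
  IntegerVector z = clone(init);
  std::vector<double> w(K);
  for (int it = 0; it < sweeps; ++it)
    for (int s = 0; s < n; ++s) gibbs_site(s, z, nbr, K, gamma, w);
  return z;
}

// Simulate a Potts field from a uniform random start and return the
// concordant-pair count (the model's sufficient statistic). Used by the ABC
// update, where only the summary statistic is needed.
// [[Rcpp::export]]
int cpp_potts_sim_stat(const IntegerMatrix& nbr, int K, double gamma,
                       int sweeps) {
  int n = nbr.nrow();
  IntegerVector z(n);
  for (int s = 0; s < n; ++s) z[s] = 1 + (int)(unif_rand() * K);
  std::vector<double> w(K);
  for (int it = 0; it < sweeps; ++it)
    for (int s = 0; s < n; ++s) gibbs_site(s, z, nbr, K, gamma, w);
  return cpp_concordant_pairs(nbr, z);
}

// One systematic-scan Gibbs sweep over the label field with emission terms:
// P(z_s = k | .) ~ exp(gamma * #{t in N_s : z_t = k}) * exp(log_emission(s,k))
// [[Rcpp::export]]
IntegerVector cpp_label_sweep(const IntegerMatrix& nbr,
                              const NumericMatrix& log_emission, double gamma,
                              IntegerVector z0) {
  int n = nbr.nrow(), K = log_emission.ncol();
  IntegerVector z = clone(z0);
  std::vector<double> lw(K);
  for (int s = 0; s < n; ++s) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double cnt = 0.0;
      for (int a = 0; a < 4; ++a) {
        int t = nbr(s, a);
        if (t > 0 && z[t - 1] == k + 1) cnt += 1.0;
      }
      lw[k] = gamma * cnt + log_emission(s, k);
      if (lw[k] > mx) mx = lw[k];
    }
    double tot = 0.0;
    for (int k = 0; k < K; ++k) { lw[k] = std::exp(lw[k] - mx); tot += lw[k]; }
    double u = unif_rand() * tot, acc = 0.0;
    int pick = K;
    for (int k = 0; k < K; ++k) {
      acc += lw[k];
      if (u <= acc) { pick = k + 1; break; }
    }
    z[s] = pick;
  }
  return z;
}

// Long-run configuration tally for small lattices: runs `sweeps` systematic
// Gibbs sweeps, recording after each sweep the configuration index
// sum_s (z_s - 1) * K^s. Test oracle support; refuses lattices with K^n too
// large to tally.
// [[Rcpp::export]]
NumericVector cpp_gibbs_config_tally(const IntegerMatrix& nbr, int K,
                                     double gamma,
                                     const NumericMatrix& log_emission,
                                     int sweeps) {
  int n = nbr.nrow();
  double ncfg = std::pow((double)K, n);
  if (ncfg > 4e6) stop("lattice too large to tally configurations");
  NumericVector tally((int)ncfg);
  IntegerVector z(n, 1);
  std::vector<double> lw(K);
  bool has_em = log_emission.nrow() == n;
  for (int it = 0; it < sweeps; ++it) {
    for (int s = 0; s < n; ++s) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double cnt = 0.0;
        for (int a = 0; a < 4; ++a) {
          int t = nbr(s, a);
          if (t > 0 && z[t - 1] == k + 1) cnt += 1.0;
        }
        lw[k] = gamma * cnt + (has_em ? log_emission(s, k) : 0.0);
        if (lw[k] > mx) mx = lw[k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { lw[k] = std::exp(lw[k] - mx); tot += lw[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K;
      for (int k = 0; k < K; ++k) {
        acc += lw[k];
        if (u <= acc) { pick = k + 1; break; }
      }
      z[s] = pick;
    }
    int idx = 0, mult = 1;
    for (int s = 0; s < n; ++s) { idx += (z[s] - 1) * mult; mult *= K; }
    tally[idx] += 1.0;
  }
  return tally;
}
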