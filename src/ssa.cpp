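// Exact stochastic simulation (direct method) for reaction systems with
// mass-action (falling-factorial), Michaelis-Menten and geometric-burst
// channels.  Each trajectory runs on its own RNG stream seeded from
// (seed, trajectory index), so ensembles are reproducible and order-
// independent.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline double falling_factorial(double n, int k) {
  double v = 1.0;
  for (int j = 0; j < k; ++j) v *= (n - j);
  return v > 0.0 ? v : 0.0;
}

// [[Rcpp::export(name = ".ssa_run")]]
IntegerVector ssa_run(IntegerMatrix stoich,      // n_species x n_reactions
                      NumericVector rate,
                      IntegerMatrix orders,      // n_species x n_reactions
                      IntegerVector kind,        // 0 mass-action, 1 MM
                      IntegerVector mm_sub,      // 0-based, -1 if none
                      NumericVector mm_K,
                      IntegerVector burst_sp,    // 0-based, -1 if none
                      NumericVector burst_p,
                      IntegerVector init,
                      NumericVector t_grid,
                      int n_traj,
                      int seed,
                      IntegerVector record_sp) { // 0-based species to record
  const int ns = stoich.nrow(), nr = stoich.ncol(), nt = t_grid.size();
  const int nrec = record_sp.size();

  // sparse per-reaction views of orders and stoichiometry
  std::vector<std::vector<std::pair<int,int> > > ord(nr), sto(nr);
  for (int r = 0; r < nr; ++r)
    for (int s = 0; s < ns; ++s) {
      if (orders(s, r) > 0) ord[r].push_back(std::make_pair(s, orders(s, r)));
      if (stoich(s, r) != 0) sto[r].push_back(std::make_pair(s, stoich(s, r)));
    }

  IntegerVector out((R_xlen_t)nrec * nt * n_traj);
  std::vector<double> x(ns), a(nr);

  for (int traj = 0; traj < n_traj; ++traj) {
    std::seed_seq sseq{seed, traj};
    std::mt19937_64 rng(sseq);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    for (int s = 0; s < ns; ++s) x[s] = init[s];
    double t = 0.0;
    int g = 0;
    while (g < nt && t_grid[g] <= t) {
      for (int k = 0; k < nrec; ++k)
        out[(R_xlen_t)traj * nt * nrec + (R_xlen_t)g * nrec + k] =
          (int)x[record_sp[k]];
      ++g;
    }
    while (g < nt) {
      double a0 = 0.0;
      for (int r = 0; r < nr; ++r) {
        double v = rate[r];
        for (size_t q = 0; q < ord[r].size(); ++q)
          v *= falling_factorial(x[ord[r][q].first], ord[r][q].second);
        if (kind[r] == 1) {
          double sub = x[mm_sub[r]];
          v *= sub / (mm_K[r] + sub);
        }
        if (v < 0.0)
          stop("negative propensity in reaction %d", r + 1);
        a[r] = v;
        a0 += v;
      }
      if (a0 <= 0.0) {
        for (; g < nt; ++g)
          for (int k = 0; k < nrec; ++k)
            out[(R_xlen_t)traj * nt * nrec + (R_xlen_t)g * nrec + k] =
              (int)x[record_sp[k]];
        break;
      }
      double u = unif(rng);
      if (u <= 0.0) u = 1e-300;
      double t_next = t - std::log(u) / a0;
      while (g < nt && t_grid[g] <= t_next) {
        for (int k = 0; k < nrec; ++k)
          out[(R_xlen_t)traj * nt * nrec + (R_xlen_t)g * nrec + k] =
            (int)x[record_sp[k]];
        ++g;
      }
      if (g >= nt) break;
      // choose the reaction channel
      double target = unif(rng) * a0, acc = 0.0;
      int rsel = nr - 1;
      for (int r = 0; r < nr; ++r) {
        acc += a[r];
        if (target <= acc) { rsel = r; break; }
      }
      for (size_t q = 0; q < sto[rsel].size(); ++q)
        x[sto[rsel][q].first] += sto[rsel][q].second;
      if (burst_sp[rsel] >= 0 && burst_p[rsel] > 0.0) {
        std::geometric_distribution<int> geo(1.0 - burst_p[rsel]);
        x[burst_sp[rsel]] += geo(rng);
      }
      for (size_t q = 0; q < sto[rsel].size(); ++q)
        if (x[sto[rsel][q].first] < 0)
          stop("negative count after reaction %d", rsel + 1);
      t = t_next;
    }
  }
  out.attr("dim") = IntegerVector::create(nrec, nt, n_traj);
  return out;
}

// [[Rcpp::export(name = ".sample_geometric")]]
IntegerVector sample_geometric(int n, double p, int seed) {
  std::seed_seq sseq{seed, 0};
  std::mt19937_64 rng(sseq);
  IntegerVector out(n);
  if (p <= 0.0) return out;
  std::geometric_distribution<int> geo(1.0 - p);
  for (int i = 0; i < n; ++i) out[i] = geo(rng);
  return out;
}
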