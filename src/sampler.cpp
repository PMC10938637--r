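// Metropolis Monte Carlo sampler for lambda-parameterized harmonic toy
// systems. Terms are either per-bead tethers, 1/2 k(lam) |r_i - c(lam)|^2,
// or pair distance restraints, 1/2 k(lam) (|r_i - r_j| - b0(lam))^2, with
// k and (c or b0) linearly interpolated between the A and B endpoints.
// Uses R's RNG (unif_rand / norm_rand) so set.seed() in R gives bitwise
// reproducible chains.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct ToyTerms {
  // tethers
  std::vector<int> t_bead;               // 0-based
  NumericMatrix t_cA, t_cB;              // centers, n_teth x dim
  std::vector<double> t_kA, t_kB;
  // pairs
  std::vector<int> p_i, p_j;             // 0-based
  std::vector<double> p_b0A, p_b0B, p_kA, p_kB;
  int dim;
};

static inline double dist(const std::vector<double>& x, int a, int b, int dim) {
  double s = 0.0;
  for (int d = 0; d < dim; ++d) {
    double diff = x[a * dim + d] - x[b * dim + d];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// energy of all terms touching no bead (i.e. total), at lambda lam
static double total_energy(const std::vector<double>& x, const ToyTerms& T,
                           double lam) {
  double e = 0.0;
  const int dim = T.dim;
  for (size_t t = 0; t < T.t_bead.size(); ++t) {
    double k = (1 - lam) * T.t_kA[t] + lam * T.t_kB[t];
    double s = 0.0;
    for (int d = 0; d < dim; ++d) {
      double c = (1 - lam) * T.t_cA(t, d) + lam * T.t_cB(t, d);
      double diff = x[T.t_bead[t] * dim + d] - c;
      s += diff * diff;
    }
    e += 0.5 * k * s;
  }
  for (size_t t = 0; t < T.p_i.size(); ++t) {
    double k = (1 - lam) * T.p_kA[t] + lam * T.p_kB[t];
    double b0 = (1 - lam) * T.p_b0A[t] + lam * T.p_b0B[t];
    double d0 = dist(x, T.p_i[t], T.p_j[t], dim) - b0;
    e += 0.5 * k * d0 * d0;
  }
  return e;
}

// dH/dlambda at lam
static double total_dhdl(const std::vector<double>& x, const ToyTerms& T,
                         double lam) {
  double e = 0.0;
  const int dim = T.dim;
  for (size_t t = 0; t < T.t_bead.size(); ++t) {
    double k = (1 - lam) * T.t_kA[t] + lam * T.t_kB[t];
    double dk = T.t_kB[t] - T.t_kA[t];
    double s = 0.0, sc = 0.0;
    for (int d = 0; d < dim; ++d) {
      double c = (1 - lam) * T.t_cA(t, d) + lam * T.t_cB(t, d);
      double dc = T.t_cB(t, d) - T.t_cA(t, d);
      double diff = x[T.t_bead[t] * dim + d] - c;
      s += diff * diff;
      sc += diff * dc;
    }
    e += 0.5 * dk * s - k * sc;
  }
  for (size_t t = 0; t < T.p_i.size(); ++t) {
    double k = (1 - lam) * T.p_kA[t] + lam * T.p_kB[t];
    double dk = T.p_kB[t] - T.p_kA[t];
    double b0 = (1 - lam) * T.p_b0A[t] + lam * T.p_b0B[t];
    double db0 = T.p_b0B[t] - T.p_b0A[t];
    double disp = dist(x, T.p_i[t], T.p_j[t], dim) - b0;
    e += 0.5 * dk * disp * disp - k * disp * db0;
  }
  return e;
}

// energy of the terms touching bead b only
static double bead_energy(const std::vector<double>& x, const ToyTerms& T,
                          double lam, int b,
                          const std::vector<std::vector<int> >& teth_of,
                          const std::vector<std::vector<int> >& pair_of) {
  double e = 0.0;
  const int dim = T.dim;
  for (size_t q = 0; q < teth_of[b].size(); ++q) {
    int t = teth_of[b][q];
    double k = (1 - lam) * T.t_kA[t] + lam * T.t_kB[t];
    double s = 0.0;
    for (int d = 0; d < dim; ++d) {
      double c = (1 - lam) * T.t_cA(t, d) + lam * T.t_cB(t, d);
      double diff = x[b * dim + d] - c;
      s += diff * diff;
    }
    e += 0.5 * k * s;
  }
  for (size_t q = 0; q < pair_of[b].size(); ++q) {
    int t = pair_of[b][q];
    double k = (1 - lam) * T.p_kA[t] + lam * T.p_kB[t];
    double b0 = (1 - lam) * T.p_b0A[t] + lam * T.p_b0B[t];
    double d0 = dist(x, T.p_i[t], T.p_j[t], dim) - b0;
    e += 0.5 * k * d0 * d0;
  }
  return e;
}

// [[Rcpp::export(name = ".mc_sample_cpp")]]
List mc_sample_cpp(NumericMatrix pos0, int dim,
                   IntegerVector t_bead, NumericMatrix t_cA, NumericMatrix t_cB,
                   NumericVector t_kA, NumericVector t_kB,
                   IntegerVector p_i, IntegerVector p_j,
                   NumericVector p_b0A, NumericVector p_b0B,
                   NumericVector p_kA, NumericVector p_kB,
                   double lam, NumericVector neighbor_lams, double beta,
                   int n_samples, int burn_in, int stride, double step_size,
                   bool tune, bool record_dhdl, bool record_positions) {
  const int n_beads = pos0.nrow();
  ToyTerms T;
  T.dim = dim;
  T.t_bead.assign(t_bead.begin(), t_bead.end());
  T.t_cA = t_cA; T.t_cB = t_cB;
  T.t_kA.assign(t_kA.begin(), t_kA.end());
  T.t_kB.assign(t_kB.begin(), t_kB.end());
  T.p_i.assign(p_i.begin(), p_i.end());
  T.p_j.assign(p_j.begin(), p_j.end());
  T.p_b0A.assign(p_b0A.begin(), p_b0A.end());
  T.p_b0B.assign(p_b0B.begin(), p_b0B.end());
  T.p_kA.assign(p_kA.begin(), p_kA.end());
  T.p_kB.assign(p_kB.begin(), p_kB.end());

  std::vector<std::vector<int> > teth_of(n_beads), pair_of(n_beads);
  for (size_t t = 0; t < T.t_bead.size(); ++t) teth_of[T.t_bead[t]].push_back(t);
  for (size_t t = 0; t < T.p_i.size(); ++t) {
    pair_of[T.p_i[t]].push_back(t);
    pair_of[T.p_j[t]].push_back(t);
  }

  std::vector<double> x(n_beads * dim);
  for (int b = 0; b < n_beads; ++b)
    for (int d = 0; d < dim; ++d) x[b * dim + d] = pos0(b, d);

  const int n_neigh = neighbor_lams.size();
  NumericMatrix works(n_samples, n_neigh);
  NumericVector dhdl(record_dhdl ? n_samples : 0);
  NumericMatrix traj(record_positions ? n_samples : 0,
                     record_positions ? n_beads * dim : 0);

  RNGScope scope;
  long accepted = 0, attempted = 0;
  long tune_acc = 0, tune_att = 0;
  std::vector<double> prop(dim);

  const long total_sweeps = (long)burn_in + (long)n_samples * stride;

  long sweep = 0;
  int recorded = 0;
  for (sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int u = 0; u < n_beads; ++u) {
      int b = (int)(unif_rand() * n_beads);
      if (b == n_beads) b = n_beads - 1;
      double e_old = bead_energy(x, T, lam, b, teth_of, pair_of);
      for (int d = 0; d < dim; ++d) {
        prop[d] = x[b * dim + d];
        x[b * dim + d] += step_size * norm_rand();
      }
      double e_new = bead_energy(x, T, lam, b, teth_of, pair_of);
      double dU = e_new - e_old;
      bool accept = dU <= 0.0 || unif_rand() < std::exp(-beta * dU);
      if (!accept) {
        for (int d = 0; d < dim; ++d) x[b * dim + d] = prop[d];
      }
      if (sweep < burn_in) {
        if (tune) {
          tune_att++;
          if (accept) tune_acc++;
          if (tune_att == 100) {
            double rate = (double)tune_acc / tune_att;
            if (rate < 0.30) step_size *= 0.8;
            else if (rate > 0.60) step_size *= 1.25;
            tune_acc = 0; tune_att = 0;
          }
        }
      } else {
        attempted++;
        if (accept) accepted++;
      }
    }
    if (sweep >= burn_in && ((sweep - burn_in + 1) % stride == 0)) {
      double e_here = total_energy(x, T, lam);
      for (int q = 0; q < n_neigh; ++q) {
        works(recorded, q) = total_energy(x, T, neighbor_lams[q]) - e_here;
      }
      if (record_dhdl) dhdl[recorded] = total_dhdl(x, T, lam);
      if (record_positions) {
        for (int b = 0; b < n_beads; ++b)
          for (int d = 0; d < dim; ++d)
            traj(recorded, b * dim + d) = x[b * dim + d];
      }
      recorded++;
      if (recorded == n_samples) break;
    }
  }

  NumericMatrix final_pos(n_beads, dim);
  for (int b = 0; b < n_beads; ++b)
    for (int d = 0; d < dim; ++d) final_pos(b, d) = x[b * dim + d];

  return List::create(
    _["works"] = works,
    _["dhdl"] = dhdl,
    _["positions"] = traj,
    _["final"] = final_pos,
    _["acceptance_rate"] = attempted > 0 ? (double)accepted / attempted : NA_REAL,
    _["step_size"] = step_size
  );
}
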