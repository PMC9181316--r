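#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One amplification cycle of the expected repeat-length distribution.
// f is indexed by repeat count 1..n (index 0 == one repeat unit).
// A molecule duplicates with probability e; the fresh copy slips with
// probability s, removing one unit with probability q, else adding one.
// Mass that would slip below one unit is clipped to one unit; mass at the
// top of the support is capped there so every cycle conserves probability.
static void propagate_cycle(std::vector<double>& f, double e, double s, double q) {
  const int n = (int)f.size();
  const double stay = 1.0 + e * (1.0 - s);
  const double dn = e * s * q;
  const double up = e * s * (1.0 - q);
  const double z = 1.0 + e;
  std::vector<double> g(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double m = stay * f[i];
    if (i + 1 < n) m += dn * f[i + 1];
    if (i > 0)     m += up * f[i - 1];
    g[i] = m;
  }
  g[0]     += dn * f[0];
  g[n - 1] += up * f[n - 1];
  for (int i = 0; i < n; ++i) f[i] = g[i] / z;
}

// [[Rcpp::export]]
NumericVector cpp_stutter_distribution(int allele, int cycles, double e,
                                       double s, double q, int max_len) {
  std::vector<double> f(max_len, 0.0);
  f[allele - 1] = 1.0;
  for (int c = 0; c < cycles; ++c) propagate_cycle(f, e, s, q);
  return NumericVector(f.begin(), f.end());
}

// Column j holds the distribution for (alleles[j], cycles[j]); rows are
// repeat counts 1..max_len.
// [[Rcpp::export]]
NumericMatrix cpp_stutter_batch(IntegerVector alleles, IntegerVector cycles,
                                double e, double s, double q, int max_len) {
  const int m = alleles.size();
  NumericMatrix out(max_len, m);
  for (int j = 0; j < m; ++j) {
    std::vector<double> f(max_len, 0.0);
    f[alleles[j] - 1] = 1.0;
    for (int c = 0; c < cycles[j]; ++c) propagate_cycle(f, e, s, q);
    for (int i = 0; i < max_len; ++i) out(i, j) = f[i];
  }
  return out;
}

struct Cand {
  double score;
  int n_alleles, cycles, sep, a1, a2;
  double w;
  bool set;
  Cand() : score(-2.0), n_alleles(0), cycles(0), sep(0), a1(0), a2(0),
           w(1.0), set(false) {}
};

// Tie order at equal score (tolerance 1e-9): fewer alleles, lower cycles,
// smaller a2-a1, lower a1.
static bool better(double score, int n_all, int cyc, int sep, int a1,
                   const Cand& b) {
  if (!b.set) return true;
  if (score > b.score + 1e-9) return true;
  if (score < b.score - 1e-9) return false;
  if (n_all != b.n_alleles) return n_all < b.n_alleles;
  if (cyc != b.cycles) return cyc < b.cycles;
  if (sep != b.sep) return sep < b.sep;
  return a1 < b.a1;
}

static void take(Cand& b, double score, int n_all, int cyc, int sep,
                 int a1, int a2, double w) {
  b.score = score; b.n_alleles = n_all; b.cycles = cyc; b.sep = sep;
  b.a1 = a1; b.a2 = a2; b.w = w; b.set = true;
}

// Pearson correlation from precomputed sums; nw = window length.
static double pearson(double Sm, double Smm, double Smo, double So,
                      double Soo, int nw, bool& degen) {
  const double vm = nw * Smm - Sm * Sm;
  const double vo = nw * Soo - So * So;
  degen = false;
  if (vm <= 1e-12 * std::max(1.0, Smm * nw) ||
      vo <= 1e-12 * std::max(1.0, Soo * nw)) {
    degen = true;
    return 0.0;
  }
  return (nw * Smo - Sm * So) / std::sqrt(vm * vo);
}

// Grid fit of one- and two-allele stutter mixtures to an observed
// repeat-number histogram by Pearson correlation over a fixed window.
//
// obs:     read counts over the window win_lo .. win_lo + nw - 1
// alleles: candidate allele repeat counts (sorted ascending, >= 1)
// cycles_grid: sorted ascending, non-negative
// w_grid:  candidate weights of the SHORTER allele, in (0, 1)
//
// Returns the best candidate plus the best one-allele and best two-allele
// scores (the gap between them is the homozygote/heterozygote ambiguity).
// [[Rcpp::export]]
List cpp_fit_genotype(NumericVector obs, int win_lo,
                      IntegerVector alleles, IntegerVector cycles_grid,
                      NumericVector w_grid, double e, double s, double q) {
  const int nw = obs.size();
  const int na = alleles.size();
  const int nc = cycles_grid.size();
  const int nwg = w_grid.size();
  const int win_hi = win_lo + nw - 1;
  // propagate over a padded support so the top cap cannot distort the window
  const int max_len = win_hi + 30;

  // snapshot window slices of each allele's distribution at each grid cycle
  std::vector<double> D((size_t)na * nc * nw);
  std::vector<double> Su((size_t)na * nc), Suu((size_t)na * nc),
      Suo((size_t)na * nc);
  double So = 0.0, Soo = 0.0;
  for (int i = 0; i < nw; ++i) { So += obs[i]; Soo += obs[i] * obs[i]; }
  int obs_argmax = 0;
  for (int i = 1; i < nw; ++i) if (obs[i] > obs[obs_argmax]) obs_argmax = i;
  bool obs_point = true;
  for (int i = 0; i < nw; ++i)
    if (i != obs_argmax && obs[i] > 1e-12 * std::max(1.0, obs[obs_argmax])) {
      obs_point = false; break;
    }

  for (int a = 0; a < na; ++a) {
    std::vector<double> f(max_len, 0.0);
    f[alleles[a] - 1] = 1.0;
    int done = 0;
    for (int c = 0; c < nc; ++c) {
      const int target = cycles_grid[c];
      for (; done < target; ++done) propagate_cycle(f, e, s, q);
      double su = 0.0, suu = 0.0, suo = 0.0;
      double* d = &D[((size_t)a * nc + c) * nw];
      for (int i = 0; i < nw; ++i) {
        const double v = (win_lo + i - 1 < max_len) ? f[win_lo + i - 1] : 0.0;
        d[i] = v;
        su += v; suu += v * v; suo += v * obs[i];
      }
      Su[(size_t)a * nc + c] = su;
      Suu[(size_t)a * nc + c] = suu;
      Suo[(size_t)a * nc + c] = suo;
    }
  }

  Cand best, best1, best2;
  bool degen;

  // single-allele candidates
  for (int a = 0; a < na; ++a) {
    for (int c = 0; c < nc; ++c) {
      const size_t k = (size_t)a * nc + c;
      double r = pearson(Su[k], Suu[k], Suo[k], So, Soo, nw, degen);
      if (degen) {
        // constant vector: score 1 iff both are point masses at the same count
        const double* d = &D[k * nw];
        int am = 0;
        for (int i = 1; i < nw; ++i) if (d[i] > d[am]) am = i;
        bool pm = true;
        for (int i = 0; i < nw; ++i)
          if (i != am && d[i] > 1e-12) { pm = false; break; }
        r = (obs_point && pm && am == obs_argmax) ? 1.0 : 0.0;
      }
      if (better(r, 1, cycles_grid[c], 0, alleles[a], best))
        take(best, r, 1, cycles_grid[c], 0, alleles[a], alleles[a], 1.0);
      if (better(r, 1, cycles_grid[c], 0, alleles[a], best1))
        take(best1, r, 1, cycles_grid[c], 0, alleles[a], alleles[a], 1.0);
    }
  }

  // two-allele mixtures: w on the shorter allele
  for (int a1 = 0; a1 < na; ++a1) {
    for (int a2 = a1 + 1; a2 < na; ++a2) {
      const int sep = alleles[a2] - alleles[a1];
      for (int c = 0; c < nc; ++c) {
        const size_t k1 = (size_t)a1 * nc + c, k2 = (size_t)a2 * nc + c;
        const double* u = &D[k1 * nw];
        const double* v = &D[k2 * nw];
        double Suv = 0.0;
        for (int i = 0; i < nw; ++i) Suv += u[i] * v[i];
        for (int wi = 0; wi < nwg; ++wi) {
          const double w = w_grid[wi], w2 = 1.0 - w;
          const double Sm = w * Su[k1] + w2 * Su[k2];
          const double Smm = w * w * Suu[k1] + 2.0 * w * w2 * Suv +
                             w2 * w2 * Suu[k2];
          const double Smo = w * Suo[k1] + w2 * Suo[k2];
          double r = pearson(Sm, Smm, Smo, So, Soo, nw, degen);
          if (degen) r = 0.0;  // a true two-allele mixture is never a point mass
          if (better(r, 2, cycles_grid[c], sep, alleles[a1], best))
            take(best, r, 2, cycles_grid[c], sep, alleles[a1], alleles[a2], w);
          if (better(r, 2, cycles_grid[c], sep, alleles[a1], best2))
            take(best2, r, 2, cycles_grid[c], sep, alleles[a1], alleles[a2], w);
        }
      }
    }
  }

  return List::create(
      _["a1"] = best.a1,
      _["a2"] = best.n_alleles == 2 ? best.a2 : NA_INTEGER,
      _["w"] = best.w,
      _["cycles"] = best.cycles,
      _["correlation"] = best.score,
      _["n_alleles"] = best.n_alleles,
      _["best_single"] = best1.set ? best1.score : NA_REAL,
      _["best_pair"] = best2.set ? best2.score : NA_REAL);
}
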