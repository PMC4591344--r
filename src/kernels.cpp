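#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binomial pmf written only on its bulk (entries above tol), outward from
// the mode by the multiplicative recurrence; entries outside [lo, hi] are
// left unwritten (mass dropped there is restored by row renormalisation).
// `out` must have capacity n + 1.
static void binom_pmf_bulk(int n, double p, double tol,
                           std::vector<double>& out, int& lo, int& hi) {
  if (n == 0 || p <= 0.0) { out[0] = 1.0; lo = hi = 0; return; }
  if (p >= 1.0) { out[n] = 1.0; lo = hi = n; return; }
  int mode = (int)std::floor((n + 1) * p);
  if (mode > n) mode = n;
  out[mode] = R::dbinom(mode, n, p, 0);
  const double odds = p / (1.0 - p);
  hi = mode;
  for (int k = mode + 1; k <= n; ++k) {
    double v = out[k - 1] * odds * (double)(n - k + 1) / (double)k;
    if (v < tol) break;
    out[k] = v; hi = k;
  }
  lo = mode;
  for (int k = mode - 1; k >= 0; --k) {
    double v = out[k + 1] / odds * (double)(k + 1) / (double)(n - k);
    if (v < tol) break;
    out[k] = v; lo = k;
  }
}

// As binom_pmf_bulk, but restricted to [0, cap]: anchored at min(mode, cap)
// so no work is spent above the cap (mass there is the complement of the
// returned range's sum). An empty range (lo > hi) means essentially all
// mass lies above the cap.
static void binom_pmf_bulk_upto(int n, double p, double tol, int cap,
                                std::vector<double>& out, int& lo, int& hi) {
  if (n == 0 || p <= 0.0) { out[0] = 1.0; lo = hi = 0; return; }
  if (p >= 1.0) {
    if (n <= cap) { out[n] = 1.0; lo = hi = n; } else { lo = 1; hi = 0; }
    return;
  }
  int mode = (int)std::floor((n + 1) * p);
  if (mode > n) mode = n;
  int k0 = mode <= cap ? mode : cap;
  double v0 = R::dbinom(k0, n, p, 0);
  if (v0 < tol) { lo = 1; hi = 0; return; }
  out[k0] = v0;
  const double odds = p / (1.0 - p);
  hi = k0;
  int top = n <= cap ? n : cap;
  for (int k = k0 + 1; k <= top; ++k) {
    double v = out[k - 1] * odds * (double)(n - k + 1) / (double)k;
    if (v < tol) break;
    out[k] = v; hi = k;
  }
  lo = k0;
  for (int k = k0 - 1; k >= 0; --k) {
    double v = out[k + 1] / odds * (double)(k + 1) / (double)(n - k);
    if (v < tol) break;
    out[k] = v; lo = k;
  }
}

static int class_of(int count, const IntegerVector& lower) {
  int k = lower.size(), c = 0;
  while (c + 1 < k && count >= lower[c + 1]) ++c;
  return c; // 0-based
}

// Exact class-level transition tables for one trait triplet.
//
// For each seed-bank class cy, Y is uniform over the class interval
// (top class truncated at its cap); X' ~ Binom(Y, sigma); survivors
// S ~ Binom(Y - X', s); new seeds N ~ Poisson(phi * X') (or the point mass
// round(phi*X') in deterministic mode); Y' = S + N. Probabilities of the
// joint class outcome (class(X'), class(Y')) are accumulated exactly, the
// Poisson part entering through its cdf at the class boundaries (no
// truncation error). Binomial factors below `prune` are dropped and each
// cy row renormalised.
// [[Rcpp::export]]
List exact_kernel_cpp(double sigma, double s, double phi,
                      IntegerVector sb_lower, int sb_cap,
                      IntegerVector em_lower,
                      bool poisson_production, double prune = 1e-14) {
  const int KY = sb_lower.size(), KX = em_lower.size();
  // class intervals for the seed bank (top truncated at cap)
  std::vector<int> lo(KY), hi(KY);
  for (int c = 0; c < KY; ++c) {
    lo[c] = sb_lower[c];
    hi[c] = (c + 1 < KY) ? sb_lower[c + 1] - 1 : sb_cap;
    if (hi[c] < lo[c]) stop("seed-bank cap below the top class lower bound");
  }
  const int maxB = sb_lower[KY - 1] - 1; // largest finite Y'-boundary needed
  const int maxY = hi[KY - 1];

  // Poisson cdf tables per X' (lambda = phi * X'), filled lazily; when the
  // whole cdf up to the last finite boundary is below `prune` the seed rain
  // forces the top class and no table is needed.
  std::vector<std::vector<double>> pois_cdf(maxY + 1);
  std::vector<signed char> pois_state(maxY + 1, 0); // 0 unseen, 1 table, 2 top

  NumericMatrix emergence(KY, KX);
  NumericVector joint(KY * KX * KY); // [cy, cx, cy2] column-major dims (KY,KX,KY)

  std::vector<double> pmfX(maxY + 1), pmfS(maxY + 1);
  std::vector<double> clsN(KY); // per-(Y, X') class accumulator

  for (int cy = 0; cy < KY; ++cy) {
    const double wY = 1.0 / (double)(hi[cy] - lo[cy] + 1);
    for (int Y = lo[cy]; Y <= hi[cy]; ++Y) {
      int x0, x1;
      binom_pmf_bulk(Y, sigma, prune, pmfX, x0, x1);
      for (int X = x0; X <= x1; ++X) {
        const double pX = pmfX[X];
        const int cx = class_of(X, em_lower);
        const int m = Y - X;

        const double* cdf = nullptr;
        bool rain_top = false;
        int detN = 0;
        if (poisson_production && X > 0) {
          if (pois_state[X] == 0) {
            double lam = phi * (double)X;
            if (R::ppois((double)maxB, lam, 1, 0) < prune) {
              pois_state[X] = 2;
            } else {
              pois_state[X] = 1;
              pois_cdf[X].resize(maxB + 1);
              for (int k = 0; k <= maxB; ++k)
                pois_cdf[X][k] = R::ppois((double)k, lam, 1, 0);
            }
          }
          if (pois_state[X] == 2) rain_top = true;
          else cdf = pois_cdf[X].data();
        } else {
          detN = (int)std::llround(phi * (double)X); // includes X == 0
        }

        double* acc = &clsN[0];
        for (int j = 0; j < KY; ++j) acc[j] = 0.0;
        const double wYX = wY * pX;

        if (rain_top) {
          // seed rain alone exceeds the last finite boundary: top class
          acc[KY - 1] += 1.0;
        } else if (!poisson_production && detN > maxB) {
          acc[KY - 1] += 1.0;
        } else if (cdf) {
          // survivor counts above maxB force the top class regardless of N,
          // so the pmf of S is only needed on [0, maxB]; everything else is
          // the complementary mass.
          int s0, sHi;
          binom_pmf_bulk_upto(m, s, prune, maxB, pmfS, s0, sHi);
          double seen = 0.0;
          for (int S = s0; S <= sHi; ++S) {
            const double w = pmfS[S];
            seen += w;
            // P(Y' in class j) = cdf(U_j - S) - cdf(L_j - 1 - S), clamped
            double prev = 0.0;
            for (int j = 0; j + 1 < KY; ++j) {
              int u = sb_lower[j + 1] - 1 - S;
              double cj = (u < 0) ? 0.0 : cdf[u];
              acc[j] += w * (cj - prev);
              prev = cj;
            }
            acc[KY - 1] += w * (1.0 - prev);
          }
          if (seen < 1.0) acc[KY - 1] += 1.0 - seen;
        } else {
          int s0, s1;
          binom_pmf_bulk(m, s, prune, pmfS, s0, s1);
          for (int S = s0; S <= s1; ++S)
            acc[class_of(S + detN, sb_lower)] += pmfS[S];
        }
        for (int j = 0; j < KY; ++j)
          if (acc[j] > 0.0)
            joint[cy + KY * (cx + KX * j)] += wYX * acc[j];
      }
    }
  }

  // marginalise and renormalise per cy row
  for (int cy = 0; cy < KY; ++cy) {
    double tot = 0.0;
    for (int cx = 0; cx < KX; ++cx) {
      double e = 0.0;
      for (int j = 0; j < KY; ++j) e += joint[cy + KY * (cx + KX * j)];
      emergence(cy, cx) = e;
      tot += e;
    }
    if (tot > 0.0)
      for (int cx = 0; cx < KX; ++cx) emergence(cy, cx) /= tot;
  }

  NumericVector bank(KY * KX * KY);
  LogicalMatrix support(KY, KX);
  for (int cy = 0; cy < KY; ++cy)
    for (int cx = 0; cx < KX; ++cx) {
      double tot = 0.0;
      for (int j = 0; j < KY; ++j) tot += joint[cy + KY * (cx + KX * j)];
      if (tot > 0.0) {
        support(cy, cx) = true;
        for (int j = 0; j < KY; ++j)
          bank[cy + KY * (cx + KX * j)] = joint[cy + KY * (cx + KX * j)] / tot;
      } else {
        support(cy, cx) = false;
        for (int j = 0; j < KY; ++j)
          bank[cy + KY * (cx + KX * j)] = 1.0 / (double)KY;
      }
    }
  bank.attr("dim") = IntegerVector::create(KY, KX, KY);

  return List::create(_["emergence"] = emergence, _["bank_update"] = bank,
                      _["support"] = support);
}

// Forward log-likelihood of a batch of independent series under per-action
// kernels. `emergence` has dims (KY, KX, A); `bank` dims (KY, KX, KY, A).
// obs/act are the concatenated series (1-based classes and action indices),
// lens the per-series lengths. A sequence of probability zero contributes
// `floor_loglik`. Returns the per-series log-likelihood vector.
// [[Rcpp::export]]
NumericVector forward_loglik_cpp(NumericVector emergence, NumericVector bank,
                                 NumericVector p0, IntegerVector obs,
                                 IntegerVector act, IntegerVector lens,
                                 double floor_loglik) {
  IntegerVector de = emergence.attr("dim");
  const int KY = de[0], KX = de[1];
  const double* E = emergence.begin();
  const double* B = bank.begin();
  const int n = lens.size();
  NumericVector out(n);
  std::vector<double> alpha(KY), alpha2(KY);
  int pos = 0;
  for (int i = 0; i < n; ++i) {
    const int T = lens[i];
    double logscale = 0.0;
    bool dead = false;
    {
      const int a0 = act[pos] - 1, c1 = obs[pos] - 1;
      const double* Ea = E + (size_t)KY * KX * a0;
      for (int y = 0; y < KY; ++y) alpha[y] = p0[y] * Ea[y + KY * c1];
    }
    for (int t = 1; t < T && !dead; ++t) {
      double tot = 0.0;
      for (int y = 0; y < KY; ++y) tot += alpha[y];
      if (tot <= 0.0) { dead = true; break; }
      logscale += std::log(tot);
      const double inv = 1.0 / tot;
      const int ap = act[pos + t - 1] - 1;  // action a^{t-2} (0-based series slot t-1)
      const int an = act[pos + t] - 1;      // action a^{t-1}
      const int cp = obs[pos + t - 1] - 1;  // observation c_x^{t-1}
      const int cn = obs[pos + t] - 1;      // observation c_x^t
      const double* Ba = B + (size_t)KY * KX * KY * ap;
      const double* Ea = E + (size_t)KY * KX * an;
      for (int y2 = 0; y2 < KY; ++y2) {
        double acc = 0.0;
        for (int y = 0; y < KY; ++y)
          acc += alpha[y] * Ba[y + KY * (cp + KX * y2)];
        alpha2[y2] = acc * Ea[y2 + KY * cn] * inv;
      }
      std::swap(alpha, alpha2);
    }
    double tot = 0.0;
    for (int y = 0; y < KY; ++y) tot += alpha[y];
    out[i] = (dead || tot <= 0.0) ? floor_loglik : logscale + std::log(tot);
    pos += T;
  }
  return out;
}
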