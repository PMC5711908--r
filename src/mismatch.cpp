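// Core numerics for mismatch-distribution demography:
//  - transient pairwise-difference distribution under the sudden-expansion
//    model (equilibrium geometric mixed with a Poisson wave at tau)
//  - least-squares fit of (tau, theta0, theta1) by multistart Nelder-Mead
//  - coalescent simulator with one instantaneous size change, time measured
//    in mutational units (theta = 2Nu), returning the mismatch histogram
//  - the parametric bootstrap loop (simulate -> refit) kept in C++ because
//    B x replicate refits dominate the runtime budget.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double THETA1_MAX = 99999.0;

// Model probabilities for classes 0..d (no tail folding here).
// F_i = Fhat_i(t1) + exp(-tau (t1+1)/t1) * sum_l Pois(l; tau) e^{tau} ... ,
// computed with Poisson pmf scaling for numerical stability.
static void expected_raw(double tau, double t0, double t1, int d,
                         std::vector<double> &F) {
  if (t0 < 0) t0 = 0;
  if (t1 < 1e-12) t1 = 1e-12;
  if (t1 > THETA1_MAX) t1 = THETA1_MAX;
  F.assign(d + 1, 0.0);
  std::vector<double> fh0(d + 1), fh1(d + 1);
  double a0 = 1.0 / (1.0 + t0), a1 = 1.0 / (1.0 + t1);
  fh0[0] = a0; fh1[0] = a1;
  for (int i = 1; i <= d; ++i) {
    fh0[i] = fh0[i - 1] * t0 * a0;
    fh1[i] = fh1[i - 1] * t1 * a1;
  }
  // scaled decay factor: exp(-tau(1+1/t1)) = exp(-tau) * exp(-tau/t1);
  // fold exp(-tau) into the Poisson pmf g_l = e^-tau tau^l / l!
  double decay = std::exp(-tau / t1);
  std::vector<double> g(d + 1);
  g[0] = std::exp(-tau);
  for (int l = 1; l <= d; ++l) g[l] = g[l - 1] * tau / l;
  for (int i = 0; i <= d; ++i) {
    double s = 0.0;
    for (int l = 0; l <= i; ++l) s += g[l] * (fh0[i - l] - fh1[i - l]);
    double v = fh1[i] + decay * s;
    F[i] = v < 0 ? 0.0 : v;
  }
}

// [[Rcpp::export]]
NumericVector expected_mismatch_cpp(double tau, double theta0, double theta1,
                                    int d) {
  std::vector<double> F;
  expected_raw(tau, theta0, theta1, d, F);
  return NumericVector(F.begin(), F.end());
}

// SSD between observed relative frequencies (classes 0..d) and the model
// with tail mass folded into the last class.
static double ssd_obj(const std::vector<double> &x, double tau, double t0,
                      double t1) {
  int d = (int)x.size() - 1;
  std::vector<double> F;
  expected_raw(tau, t0, t1, d, F);
  double cum = 0.0;
  for (int i = 0; i < d; ++i) cum += F[i];
  F[d] = 1.0 - cum;  // fold tail
  if (F[d] < 0) F[d] = 0;
  double s = 0.0;
  for (int i = 0; i <= d; ++i) {
    double e = x[i] - F[i];
    s += e * e;
  }
  return s;
}

// [[Rcpp::export]]
double ssd_cpp(NumericVector x, double tau, double theta0, double theta1) {
  std::vector<double> xx(x.begin(), x.end());
  return ssd_obj(xx, tau, theta0, theta1);
}

// Harpending's raggedness over relative frequencies with a trailing zero
// class appended.
static double raggedness_stat(const std::vector<double> &x) {
  double r = 0.0, prev = x[0];
  for (size_t i = 1; i < x.size(); ++i) {
    double dlt = x[i] - prev;
    r += dlt * dlt;
    prev = x[i];
  }
  r += prev * prev;  // x_{d+1} = 0
  return r;
}

// [[Rcpp::export]]
double raggedness_cpp(NumericVector x) {
  std::vector<double> xx(x.begin(), x.end());
  return raggedness_stat(xx);
}

struct FitResult { double tau, t0, t1, ssd; };

// Nelder-Mead on squared-root-transformed parameters (keeps all >= 0).
static FitResult nelder_mead(const std::vector<double> &x, double tau0,
                             double th00, double th10, int maxeval) {
  const int np = 3;
  auto eval = [&](const double *u) {
    double tau = u[0] * u[0], t0 = u[1] * u[1], t1 = u[2] * u[2];
    if (t1 > THETA1_MAX) t1 = THETA1_MAX;
    return ssd_obj(x, tau, t0, t1);
  };
  double simplex[4][3];
  double fv[4];
  double u0[3] = {std::sqrt(tau0), std::sqrt(th00), std::sqrt(th10)};
  for (int i = 0; i <= np; ++i) {
    for (int j = 0; j < np; ++j) simplex[i][j] = u0[j];
    if (i > 0) {
      double &v = simplex[i][i - 1];
      v = (std::fabs(v) > 1e-3) ? v * 1.1 : v + 0.1;
    }
    fv[i] = eval(simplex[i]);
  }
  int neval = np + 1;
  while (neval < maxeval) {
    // order
    int lo = 0, hi = 0, nh = 0;
    for (int i = 1; i <= np; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    nh = (hi == 0) ? 1 : 0;
    for (int i = 0; i <= np; ++i)
      if (i != hi && fv[i] > fv[nh]) nh = i;
    if (fv[hi] - fv[lo] < 1e-15 * (1.0 + fv[lo])) break;
    double cen[3] = {0, 0, 0};
    for (int i = 0; i <= np; ++i)
      if (i != hi)
        for (int j = 0; j < np; ++j) cen[j] += simplex[i][j] / np;
    double refl[3], exp_[3], con[3];
    for (int j = 0; j < np; ++j) refl[j] = cen[j] + (cen[j] - simplex[hi][j]);
    double fr = eval(refl); ++neval;
    if (fr < fv[lo]) {
      for (int j = 0; j < np; ++j) exp_[j] = cen[j] + 2.0 * (cen[j] - simplex[hi][j]);
      double fe = eval(exp_); ++neval;
      if (fe < fr) { std::copy(exp_, exp_ + 3, simplex[hi]); fv[hi] = fe; }
      else { std::copy(refl, refl + 3, simplex[hi]); fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      std::copy(refl, refl + 3, simplex[hi]); fv[hi] = fr;
    } else {
      for (int j = 0; j < np; ++j) con[j] = cen[j] + 0.5 * (simplex[hi][j] - cen[j]);
      double fc = eval(con); ++neval;
      if (fc < fv[hi]) { std::copy(con, con + 3, simplex[hi]); fv[hi] = fc; }
      else {
        for (int i = 0; i <= np; ++i) {
          if (i == lo) continue;
          for (int j = 0; j < np; ++j)
            simplex[i][j] = simplex[lo][j] + 0.5 * (simplex[i][j] - simplex[lo][j]);
          fv[i] = eval(simplex[i]); ++neval;
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i <= np; ++i) if (fv[i] < fv[lo]) lo = i;
  FitResult r;
  r.tau = simplex[lo][0] * simplex[lo][0];
  r.t0 = simplex[lo][1] * simplex[lo][1];
  r.t1 = simplex[lo][2] * simplex[lo][2];
  if (r.t1 > THETA1_MAX) r.t1 = THETA1_MAX;
  r.ssd = fv[lo];
  return r;
}

static FitResult fit_core(const std::vector<double> &x) {
  int d = (int)x.size() - 1;
  double m = 0.0;
  for (int i = 0; i <= d; ++i) m += i * x[i];
  if (m < 1e-3) {  // degenerate: (nearly) all mass at zero differences
    FitResult r{0.0, 0.0, 0.0, ssd_obj(x, 0, 0, 0)};
    FitResult nm = nelder_mead(x, std::max(m, 1e-4), 1e-4, 1.0, 200);
    return (nm.ssd < r.ssd) ? nm : r;
  }
  double taus[3] = {0.1, std::max(m * 0.5, 0.2), m};
  double th0s[3] = {0.01, 0.5, std::max(m * 0.5, 0.6)};
  double th1s[3] = {1.0, std::max(10.0 * m, 20.0), THETA1_MAX};
  struct Start { double tau, t0, t1, ssd; };
  std::vector<Start> starts;
  for (double a : taus) for (double b : th0s) for (double c : th1s)
    starts.push_back({a, b, c, ssd_obj(x, a, b, c)});
  std::sort(starts.begin(), starts.end(),
            [](const Start &p, const Start &q) {
              return p.ssd < q.ssd ||
                     (p.ssd == q.ssd && p.tau < q.tau);
            });
  FitResult best{0, 0, 0, 1e300};
  int nstart = std::min((size_t)3, starts.size());
  for (int s = 0; s < nstart; ++s) {
    FitResult r = nelder_mead(x, starts[s].tau, starts[s].t0, starts[s].t1, 400);
    if (r.ssd < best.ssd - 1e-15 ||
        (std::fabs(r.ssd - best.ssd) <= 1e-15 && r.tau < best.tau))
      best = r;
  }
  // polish from the winner (an NM restart escapes collapsed simplices)
  {
    FitResult r = nelder_mead(x, std::max(best.tau, 1e-8),
                              std::max(best.t0, 1e-8),
                              std::max(best.t1, 1e-8), 400);
    if (r.ssd < best.ssd) best = r;
  }
  return best;
}

// [[Rcpp::export]]
List fit_mismatch_cpp(NumericVector x) {
  std::vector<double> xx(x.begin(), x.end());
  FitResult r = fit_core(xx);
  return List::create(_["tau"] = r.tau, _["theta0"] = r.t0,
                      _["theta1"] = r.t1, _["ssd"] = r.ssd);
}

// Coalescent with one instantaneous size change at mutational time tau in
// the past (theta1 = present, theta0 = ancestral). Returns the pairwise
// difference matrix condensed to a histogram plus the total mutation count
// (= segregating sites under infinite sites).
struct SimOut { std::vector<int> hist; long total_mut; double kbar; };

static SimOut sim_mismatch(int n, double theta0, double theta1, double tau) {
  std::vector<std::vector<int> > lin(n);
  for (int i = 0; i < n; ++i) lin[i].assign(1, i);
  std::vector<std::vector<int> > dd(n, std::vector<int>(n, 0));
  double nu = 0.0;  // mutational time elapsed
  long total = 0;
  int j = n;
  while (j > 1) {
    double cj = j * (j - 1) / 2.0;
    // waiting time with piecewise theta(nu)
    double E = R::exp_rand();
    double dt;
    double th_now = (nu < tau) ? theta1 : theta0;
    dt = E * th_now / cj;
    if (nu < tau && nu + dt > tau) {
      double used = (tau - nu) * cj / theta1;  // exponential mass consumed
      dt = (tau - nu) + (E - used) * theta0 / cj;
    }
    // mutations on each active lineage: Poisson(dt / 2)
    for (int a = 0; a < j; ++a) {
      int c = (int)R::rpois(dt / 2.0);
      if (c > 0) {
        total += c;
        const std::vector<int> &S = lin[a];
        std::vector<char> inS(n, 0);
        for (int t : S) inS[t] = 1;
        for (int t : S)
          for (int u = 0; u < n; ++u)
            if (!inS[u]) { dd[t][u] += c; dd[u][t] += c; }
      }
    }
    nu += dt;
    // coalesce a uniform pair
    int a = (int)(R::unif_rand() * j); if (a == j) a = j - 1;
    int b = (int)(R::unif_rand() * (j - 1)); if (b == j - 1) b = j - 2;
    if (b >= a) ++b;
    if (a > b) std::swap(a, b);
    lin[a].insert(lin[a].end(), lin[b].begin(), lin[b].end());
    lin[b] = lin[j - 1];
    lin.pop_back();
    --j;
  }
  int dmax = 0;
  for (int i = 0; i < n; ++i)
    for (int k = i + 1; k < n; ++k) dmax = std::max(dmax, dd[i][k]);
  SimOut out;
  out.hist.assign(dmax + 1, 0);
  double s = 0.0; long np = 0;
  for (int i = 0; i < n; ++i)
    for (int k = i + 1; k < n; ++k) {
      out.hist[dd[i][k]] += 1;
      s += dd[i][k]; ++np;
    }
  out.total_mut = total;
  out.kbar = s / np;
  return out;
}

// [[Rcpp::export]]
List sim_mismatch_cpp(int n, double theta0, double theta1, double tau) {
  SimOut o = sim_mismatch(n, theta0, theta1, tau);
  return List::create(_["counts"] = IntegerVector(o.hist.begin(), o.hist.end()),
                      _["S"] = (double)o.total_mut, _["k_bar"] = o.kbar);
}

// Parametric bootstrap: B simulate-and-refit replicates at the fitted
// parameters; returns per-replicate tau_hat, SSD (of the replicate against
// its own refit) and raggedness of the replicate histogram.
// [[Rcpp::export]]
NumericMatrix bootstrap_mismatch_cpp(int B, int n, double tau, double theta0,
                                     double theta1) {
  NumericMatrix out(B, 3);
  colnames(out) = CharacterVector::create("tau", "ssd", "hrag");
  for (int b = 0; b < B; ++b) {
    SimOut o = sim_mismatch(n, theta0, theta1, tau);
    int d = (int)o.hist.size() - 1;
    double tot = 0;
    for (int v : o.hist) tot += v;
    std::vector<double> x(d + 1);
    for (int i = 0; i <= d; ++i) x[i] = o.hist[i] / tot;
    FitResult f = fit_core(x);
    out(b, 0) = f.tau;
    out(b, 1) = f.ssd;
    out(b, 2) = raggedness_stat(x);
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch simulate-and-refit at fixed truth (for recovery experiments):
// returns tau_hat per replicate.
// [[Rcpp::export]]
NumericMatrix simfit_batch_cpp(int reps, int n, double tau, double theta0,
                               double theta1) {
  NumericMatrix out(reps, 4);
  colnames(out) = CharacterVector::create("tau", "theta0", "theta1", "ssd");
  for (int r = 0; r < reps; ++r) {
    SimOut o = sim_mismatch(n, theta0, theta1, tau);
    int d = (int)o.hist.size() - 1;
    double tot = 0;
    for (int v : o.hist) tot += v;
    std::vector<double> x(d + 1);
    for (int i = 0; i <= d; ++i) x[i] = o.hist[i] / tot;
    FitResult f = fit_core(x);
    out(r, 0) = f.tau; out(r, 1) = f.t0; out(r, 2) = f.t1; out(r, 3) = f.ssd;
    if (r % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
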