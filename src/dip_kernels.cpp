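#include <Rcpp.h>
using namespace Rcpp;

// Dip statistic of an ecdf given as unique sorted values u with jump counts
// (lo = counts strictly before each value, hi = counts through it, n total).
//
// Band view: a unimodal CDF within sup-distance d = D/(2n) of the ecdf
// exists iff for some mode position a convex nondecreasing function fits the
// band [F - d, F^- + d] left of the mode and a concave one right of it, with
// junction values in the right order. The convexity/concavity constraints
// reduce to chord conditions over triples of jump points, each linear in D,
// so a lower bound D0 is a direct max/min over chord values; the junction
// condition is then verified at D0 and, where it binds, the smallest
// feasible D is located by bisection (the junction gap is piecewise linear
// and strictly decreasing in D).
//
// "Gap" modes place the mode strictly between adjacent observed values (or
// outside the range); "atom" modes place it on an observed value, whose own
// jump is then split by an atom of the fitted CDF and exempted from the
// two-sided band.

// max over i<j<l (l fixed) of hi[j] - lo[l] + (u[l]-u[j]) * (lo[l]-lo[i])/(u[l]-u[i])
static void trip_left(const std::vector<double>& u, const std::vector<double>& lo,
                      const std::vector<double>& hi, std::vector<double>& out) {
  int m = u.size();
  out.assign(m, R_NegInf);
  for (int l = 2; l < m; ++l) {
    double best = R_NegInf, pmax = R_NegInf;
    for (int j = 1; j < l; ++j) {
      double ri = (lo[l] - lo[j - 1]) / (u[l] - u[j - 1]);
      if (ri > pmax) pmax = ri;
      double v = hi[j] - lo[l] + (u[l] - u[j]) * pmax;
      if (v > best) best = v;
    }
    out[l] = best;
  }
}

// lower bounds at each point forced by convex chords through earlier bands:
// out[p] = max over i<j<p of L[j] + (u[p]-u[j]) * (L[j]-U[i])/(u[j]-u[i])
static void a_ext(const std::vector<double>& u, const std::vector<double>& L,
                  const std::vector<double>& U, std::vector<double>& out) {
  int m = u.size();
  std::vector<double> S(m, R_NegInf);
  for (int j = 1; j < m; ++j) {
    double best = R_NegInf;
    for (int i = 0; i < j; ++i) {
      double s = (L[j] - U[i]) / (u[j] - u[i]);
      if (s > best) best = s;
    }
    S[j] = best;
  }
  out.assign(m, R_NegInf);
  for (int p = 1; p < m; ++p) {
    double best = R_NegInf;
    for (int j = 1; j < p; ++j) {
      double v = L[j] + S[j] * (u[p] - u[j]);
      if (v > best) best = v;
    }
    out[p] = best;
  }
}

struct TripArrays {
  std::vector<double> LeftT, RightT, LeftC, RightC;
};

static void build_trips(const std::vector<double>& u, const std::vector<double>& lo,
                        const std::vector<double>& hi, double n, TripArrays& T) {
  int m = u.size();
  std::vector<double> mtL, mtLr, ur(m), lor(m), hir(m);
  for (int t = 0; t < m; ++t) {
    ur[t] = -u[m - 1 - t];
    lor[t] = n - hi[m - 1 - t];
    hir[t] = n - lo[m - 1 - t];
  }
  trip_left(u, lo, hi, mtL);
  trip_left(ur, lor, hir, mtLr);
  T.LeftT.assign(m, R_NegInf);
  T.RightT.assign(m, R_NegInf);
  double run = R_NegInf;
  for (int t = 0; t < m; ++t) { run = std::max(run, mtL[t]); T.LeftT[t] = run; }
  run = R_NegInf;
  for (int t = 0; t < m; ++t) { run = std::max(run, mtLr[t]); T.RightT[m - 1 - t] = run; }
  T.LeftC.assign(m, 0.0);
  T.RightC.assign(m, 0.0);
  run = R_NegInf;
  for (int t = 0; t < m; ++t) { run = std::max(run, hi[t] - lo[t]); T.LeftC[t] = run; }
  run = R_NegInf;
  for (int t = m - 1; t >= 0; --t) { run = std::max(run, hi[t] - lo[t]); T.RightC[t] = run; }
}

// Minimal junction excess (A - B) over all modes whose chord constraints
// pass at band width D; <= 0 means a unimodal fit exists at D. The excess of
// every mode decreases at rate >= 1 per unit D, so D + excess(D) is an upper
// bound for the smallest feasible D.
static double junction_excess(double D, const std::vector<double>& u,
                              const std::vector<double>& lo, const std::vector<double>& hi,
                              double n, const TripArrays& T, double tol) {
  int m = u.size();
  std::vector<double> L(m), U(m), Aext, Bext, ur(m), Lr(m), Ur(m), Br;
  for (int t = 0; t < m; ++t) { L[t] = hi[t] - D / 2; U[t] = lo[t] + D / 2; }
  a_ext(u, L, U, Aext);
  for (int t = 0; t < m; ++t) {
    ur[t] = -u[m - 1 - t];
    Lr[t] = n - U[m - 1 - t];
    Ur[t] = n - L[m - 1 - t];
  }
  a_ext(ur, Lr, Ur, Br);
  Bext.assign(m, R_PosInf);
  for (int t = 0; t < m; ++t) Bext[t] = n - Br[m - 1 - t];
  double worst = R_PosInf;
  // gap modes p = 0..m (1-based p; arrays 0-based: point p is index p-1)
  for (int p = 0; p <= m; ++p) {
    bool left_ok = (p == 0) ||
      (std::max(T.LeftT[p - 1], T.LeftC[p - 1]) <= D + tol);
    bool right_ok = (p == m) ||
      (std::max(T.RightT[p], T.RightC[p]) <= D + tol);
    if (!left_ok || !right_ok) continue;
    double A = (p == 0) ? R_NegInf : std::max(L[p - 1], Aext[p - 1]);
    double B = (p == m) ? R_PosInf : std::min(U[p], Bext[p]);
    double e = A - B;
    if (e < worst) worst = e;
    if (worst <= 0) return worst;
  }
  // atom modes p = 1..m
  for (int p = 1; p <= m; ++p) {
    bool left_ok = T.LeftT[p - 1] <= D + tol &&
      (p == 1 || T.LeftC[p - 2] <= D + tol);
    bool right_ok = T.RightT[p - 1] <= D + tol &&
      (p == m || T.RightC[p] <= D + tol);
    if (!left_ok || !right_ok) continue;
    double A = std::max(lo[p - 1] - D / 2, Aext[p - 1]);
    double B = std::min(hi[p - 1] + D / 2, Bext[p - 1]);
    double e = A - B;
    if (e < worst) worst = e;
    if (worst <= 0) return worst;
  }
  return worst;
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector u_, NumericVector lo_, NumericVector hi_,
                    double n) {
  std::vector<double> u = as<std::vector<double> >(u_);
  std::vector<double> lo = as<std::vector<double> >(lo_);
  std::vector<double> hi = as<std::vector<double> >(hi_);
  int m = u.size();
  if (m == 1) return 0.0;
  TripArrays T;
  build_trips(u, lo, hi, n, T);
  // lower bound D0 over all modes from the D-linear constraints
  double D0 = R_PosInf;
  for (int p = 0; p <= m; ++p) {
    double left = (p == 0) ? 0.0 : std::max(T.LeftT[p - 1], T.LeftC[p - 1]);
    double right = (p == m) ? 0.0 : std::max(T.RightT[p], T.RightC[p]);
    D0 = std::min(D0, std::max(left, right));
  }
  for (int p = 1; p <= m; ++p) {
    double v = std::max(T.LeftT[p - 1], T.RightT[p - 1]);
    if (p >= 2) v = std::max(v, T.LeftC[p - 2]);
    if (p < m) v = std::max(v, T.RightC[p]);
    D0 = std::min(D0, v);
  }
  double tol = 1e-9 * n;
  double e0 = junction_excess(D0 + tol, u, lo, hi, n, T, tol);
  if (e0 <= tol) return D0 / (2 * n);
  // junction coupling binds: bracket by the excess bound and bisect,
  // shrinking the upper end with each midpoint's own excess bound
  double Dlo = D0, Dhi = D0 + e0 + 2 * tol;
  while (Dhi - Dlo > 1e-5) {
    double Dmid = (Dlo + Dhi) / 2;
    double e = junction_excess(Dmid, u, lo, hi, n, T, tol);
    if (e <= tol) Dhi = Dmid;
    else { Dlo = Dmid; Dhi = std::min(Dhi, Dmid + e + 2 * tol); }
  }
  return Dhi / (2 * n);
}
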