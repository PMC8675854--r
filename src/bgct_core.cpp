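// Compiled core: vector field, Jacobian, multistart Newton root search and
// Euler-Maruyama integrator for the 7-population cortex-basal
// ganglia-thalamus firing-rate model.  The same drift/Jacobian code backs
// the deSolve hooks (bgct_derivs/bgct_jac) and the .Call exports, so there
// is a single definition of the model equations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Parameter vector layout (see bgct_parms_vector() on the R side):
// [0..6] C1..C7, [7..13] R1..R7,
// [14..26] T16,T21,T26,T31,T36,T42,T45,T47,T53,T57,T64,T71,T75,
// [27..33] I1..I7, [34] s, [35] n, [36] Dinput
#define NPAR 37
enum { iC = 0, iR = 7,
       iT16 = 14, iT21, iT26, iT31, iT36, iT42, iT45, iT47, iT53, iT57,
       iT64, iT71, iT75,
       iI = 27, iS = 34, iN = 35, iD = 36 };

static double g_parms[NPAR];   // parameter block used by the deSolve hooks

static inline double hillf(double x, double s, double n) {
  double xn = std::pow(x, n), sn = std::pow(s, n);
  return xn / (sn + xn);
}

// d/dx of the Hill response: n s^n x^(n-1) / (s^n + x^n)^2
static inline double hilld(double x, double s, double n) {
  double xn = std::pow(x, n), sn = std::pow(s, n), den = sn + xn;
  return n * sn * std::pow(x, n - 1.0) / (den * den);
}

static void drift_impl(const double* x, const double* p, double* f) {
  const double s = p[iS], n = p[iN], D = p[iD];
  const double H1 = hillf(x[0], s, n), H2 = hillf(x[1], s, n),
               H3 = hillf(x[2], s, n), H4 = hillf(x[3], s, n),
               H5 = hillf(x[4], s, n), H6 = hillf(x[5], s, n),
               H7 = hillf(x[6], s, n);
  f[0] = (p[iI+0] - x[0]/p[iR+0] + p[iT16]*H6)                             / p[iC+0];
  f[1] = (p[iI+1] - x[1]/p[iR+1] + p[iT21]*H1 + p[iT26]*H6 + D)            / p[iC+1];
  f[2] = (p[iI+2] - x[2]/p[iR+2] + p[iT31]*H1 + p[iT36]*H6 - D)            / p[iC+2];
  f[3] = (p[iI+3] - x[3]/p[iR+3] + p[iT47]*H7 - p[iT42]*H2 - p[iT45]*H5)   / p[iC+3];
  f[4] = (p[iI+4] - x[4]/p[iR+4] + p[iT57]*H7 - p[iT53]*H3)                / p[iC+4];
  f[5] = (p[iI+5] - x[5]/p[iR+5] - p[iT64]*H4)                             / p[iC+5];
  f[6] = (p[iI+6] - x[6]/p[iR+6] + p[iT71]*H1 - p[iT75]*H5)                / p[iC+6];
}

// column-major 7x7
static void jac_impl(const double* x, const double* p, double* J) {
  const double s = p[iS], n = p[iN];
  for (int k = 0; k < 49; ++k) J[k] = 0.0;
  for (int i = 0; i < 7; ++i) J[i + 7*i] = -1.0 / (p[iC+i] * p[iR+i]);
  const double d1 = hilld(x[0], s, n), d2 = hilld(x[1], s, n),
               d3 = hilld(x[2], s, n), d4 = hilld(x[3], s, n),
               d5 = hilld(x[4], s, n), d6 = hilld(x[5], s, n),
               d7 = hilld(x[6], s, n);
  J[0 + 7*5] =  p[iT16]*d6 / p[iC+0];
  J[1 + 7*0] =  p[iT21]*d1 / p[iC+1];
  J[1 + 7*5] =  p[iT26]*d6 / p[iC+1];
  J[2 + 7*0] =  p[iT31]*d1 / p[iC+2];
  J[2 + 7*5] =  p[iT36]*d6 / p[iC+2];
  J[3 + 7*6] =  p[iT47]*d7 / p[iC+3];
  J[3 + 7*1] = -p[iT42]*d2 / p[iC+3];
  J[3 + 7*4] = -p[iT45]*d5 / p[iC+3];
  J[4 + 7*6] =  p[iT57]*d7 / p[iC+4];
  J[4 + 7*2] = -p[iT53]*d3 / p[iC+4];
  J[5 + 7*3] = -p[iT64]*d4 / p[iC+5];
  J[6 + 7*0] =  p[iT71]*d1 / p[iC+6];
  J[6 + 7*4] = -p[iT75]*d5 / p[iC+6];
}

// ---------------------------------------------------------------------------
// deSolve compiled-model hooks
extern "C" {

void bgct_initmod(void (*odeparms)(int*, double*)) {
  int n = NPAR;
  odeparms(&n, g_parms);
}

void bgct_derivs(int* neq, double* t, double* y, double* ydot,
                 double* yout, int* ip) {
  (void)neq; (void)t; (void)yout; (void)ip;
  drift_impl(y, g_parms, ydot);
}

void bgct_jac(int* neq, double* t, double* y, int* ml, int* mu,
              double* pd, int* nrowpd, double* yout, int* ip) {
  (void)neq; (void)t; (void)ml; (void)mu; (void)yout; (void)ip;
  double J[49];
  jac_impl(y, g_parms, J);
  for (int j = 0; j < 7; ++j)
    for (int i = 0; i < 7; ++i)
      pd[i + j * (*nrowpd)] = J[i + 7*j];
}

} // extern "C"

// ---------------------------------------------------------------------------
// .Call exports

// [[Rcpp::export]]
NumericVector bgct_drift_c(NumericVector x, NumericVector parms) {
  if (x.size() != 7) stop("state must have length 7");
  if (parms.size() != NPAR) stop("parameter vector must have length 37");
  NumericVector f(7);
  drift_impl(x.begin(), parms.begin(), f.begin());
  return f;
}

// [[Rcpp::export]]
NumericMatrix bgct_jac_c(NumericVector x, NumericVector parms) {
  if (x.size() != 7) stop("state must have length 7");
  if (parms.size() != NPAR) stop("parameter vector must have length 37");
  NumericMatrix J(7, 7);
  jac_impl(x.begin(), parms.begin(), J.begin());
  return J;
}

// Damped Newton iteration from a single start.  Returns true on
// convergence (max |f| < tol).
static bool newton_one(arma::vec& x, const double* p, double tol,
                       int maxit, bool& singular) {
  arma::vec f(7), dx(7);
  arma::mat J(7, 7);
  singular = false;
  for (int it = 0; it < maxit; ++it) {
    drift_impl(x.memptr(), p, f.memptr());
    double fn = arma::abs(f).max();
    if (!std::isfinite(fn)) return false;
    if (fn < tol) {
      jac_impl(x.memptr(), p, J.memptr());
      singular = arma::rcond(J) < 1e-12;
      return true;
    }
    jac_impl(x.memptr(), p, J.memptr());
    if (!arma::solve(dx, J, f, arma::solve_opts::no_approx)) return false;
    // damped step: backtrack until the residual decreases
    double lam = 1.0;
    arma::vec xn = x - dx;
    for (int k = 0; k < 8; ++k) {
      drift_impl(xn.memptr(), p, f.memptr());
      double fn2 = arma::abs(f).max();
      if (std::isfinite(fn2) && fn2 < fn) break;
      lam *= 0.5;
      xn = x - lam * dx;
    }
    x = xn;
    if (arma::abs(x).max() > 1e5) return false;
  }
  drift_impl(x.memptr(), p, f.memptr());
  return arma::abs(f).max() < tol;
}

// Multistart Newton root search.  starts: n x 7 matrix.  Roots are
// deduplicated by max-abs distance dedup_tol and returned with a
// singular-Jacobian flag per root.
// [[Rcpp::export]]
List bgct_newton_multistart_c(NumericMatrix starts, NumericVector parms,
                              double tol, int maxit, double dedup_tol) {
  if (starts.ncol() != 7) stop("starts must have 7 columns");
  if (parms.size() != NPAR) stop("parameter vector must have length 37");
  const double* p = parms.begin();
  std::vector<arma::vec> roots;
  std::vector<bool> sing;
  for (int i = 0; i < starts.nrow(); ++i) {
    arma::vec x(7);
    for (int j = 0; j < 7; ++j) x(j) = starts(i, j);
    bool is_sing = false;
    if (!newton_one(x, p, tol, maxit, is_sing)) continue;
    bool dup = false;
    for (size_t r = 0; r < roots.size(); ++r) {
      if (arma::abs(roots[r] - x).max() < dedup_tol) { dup = true; break; }
    }
    if (!dup) { roots.push_back(x); sing.push_back(is_sing); }
  }
  NumericMatrix out(roots.size(), 7);
  LogicalVector singular(roots.size());
  NumericVector resid(roots.size());
  for (size_t r = 0; r < roots.size(); ++r) {
    arma::vec f(7);
    drift_impl(roots[r].memptr(), p, f.memptr());
    resid[r] = arma::abs(f).max();
    singular[r] = sing[r];
    for (int j = 0; j < 7; ++j) out(r, j) = roots[r](j);
  }
  return List::create(_["roots"] = out, _["singular"] = singular,
                      _["residual"] = resid);
}

// Single damped-Newton polish from one start; returns the root or NULL.
// [[Rcpp::export]]
SEXP bgct_newton_polish_c(NumericVector x0, NumericVector parms,
                          double tol, int maxit) {
  arma::vec x(7);
  for (int j = 0; j < 7; ++j) x(j) = x0[j];
  bool is_sing = false;
  if (!newton_one(x, parms.begin(), tol, maxit, is_sing)) return R_NilValue;
  NumericVector out(7);
  for (int j = 0; j < 7; ++j) out[j] = x(j);
  out.attr("singular") = is_sing;
  return out;
}

// Euler-Maruyama integrator with additive Gaussian white noise of
// strength D on the equations selected by `applied` (1-based indices):
//   x <- x + f(x) dt + sqrt(2 D dt) eta,   eta ~ N(0,1) i.i.d.
// Uses R's RNG so results are governed by set.seed().  Records the full
// state every `record_every` steps after `burn_steps`.  With
// reflect = true the state is reflected at 0 (optional floor, off by
// default on the R side).
// [[Rcpp::export]]
NumericMatrix bgct_em_c(NumericVector x0, NumericVector parms, double dt,
                        int nsteps, double D, IntegerVector applied,
                        int burn_steps, int record_every, bool reflect) {
  if (x0.size() != 7) stop("state must have length 7");
  if (dt <= 0) stop("dt must be positive");
  bool on[7] = {false, false, false, false, false, false, false};
  for (int k = 0; k < applied.size(); ++k) {
    int j = applied[k];
    if (j < 1 || j > 7) stop("applied indices must be in 1..7");
    on[j - 1] = true;
  }
  const double amp = std::sqrt(2.0 * D * dt);
  double x[7], f[7];
  for (int j = 0; j < 7; ++j) x[j] = x0[j];
  int nrec = (nsteps - burn_steps) / record_every;
  if (nrec < 1) stop("no recorded steps: increase nsteps");
  NumericMatrix out(nrec, 8);
  int r = 0;
  for (int i = 1; i <= nsteps; ++i) {
    drift_impl(x, parms.begin(), f);
    for (int j = 0; j < 7; ++j) {
      x[j] += f[j] * dt;
      if (amp > 0 && on[j]) x[j] += amp * norm_rand();
      if (reflect && x[j] < 0) x[j] = -x[j];
      if (!std::isfinite(x[j]))
        stop("stochastic trajectory diverged at t = %g ms", i * dt);
    }
    if (std::abs(x[0]) > 1e6)
      stop("stochastic trajectory diverged at t = %g ms", i * dt);
    if (i > burn_steps && (i - burn_steps) % record_every == 0 && r < nrec) {
      out(r, 0) = i * dt;
      for (int j = 0; j < 7; ++j) out(r, j + 1) = x[j];
      ++r;
    }
  }
  return out;
}
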