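// Dormand-Prince 5(4) integrator for piecewise-constant linear systems
//   y' = A0 y            outside gallbladder-emptying windows
//   y' = (A0 + Am) y     inside a window
// The matrices are passed as dgCMatrix slots (column pointers p, row
// indices i, values x). Meal-window edges are hard integration breakpoints
// so results do not depend on the output grid; output times are hit
// exactly by step-size capping (the system is mildly stiff, so natural
// steps are far smaller than the 0.1 h reporting grid anyway).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif

using namespace Rcpp;

namespace {

struct CscMat {
  const int *p;
  const int *i;
  const double *x;
  int n;
};

inline void deriv(const CscMat &a0, const CscMat &am, bool meal_on,
                  const std::vector<double> &y, std::vector<double> &f) {
  const int n = a0.n;
  std::fill(f.begin(), f.end(), 0.0);
  for (int col = 0; col < n; ++col) {
    const double yc = y[col];
    if (yc == 0.0) continue;
    for (int k = a0.p[col]; k < a0.p[col + 1]; ++k) f[a0.i[k]] += a0.x[k] * yc;
  }
  if (meal_on) {
    for (int col = 0; col < n; ++col) {
      const double yc = y[col];
      if (yc == 0.0) continue;
      for (int k = am.p[col]; k < am.p[col + 1]; ++k) f[am.i[k]] += am.x[k] * yc;
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".dopri5_lin")]]
List dopri5_lin(NumericVector y0,
                IntegerVector a0p, IntegerVector a0i, NumericVector a0x,
                IntegerVector amp, IntegerVector ami, NumericVector amx,
                NumericVector t_out,
                NumericVector win_start, NumericVector win_end,
                double rtol, double atol, double hmax, double h0,
                double max_steps) {
  // Exponentially decaying tails reach the denormal range (~1e-300) where
  // x86 arithmetic is microcoded and ~50x slower; flush them to zero for
  // the duration of the integration (they are far below atol).
#ifdef __SSE2__
  const unsigned int csr_saved = _mm_getcsr();
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  const int n = y0.size();
  const int nt = t_out.size();
  CscMat A0{a0p.begin(), a0i.begin(), a0x.begin(), n};
  CscMat Am{amp.begin(), ami.begin(), amx.begin(), n};

  // Dormand-Prince coefficients (the system is autonomous within a
  // segment, so the stage abscissae are not needed)
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  // error estimate coefficients (b - bhat)
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  // breakpoints: output times plus window edges inside the horizon
  std::vector<double> targets(t_out.begin(), t_out.end());
  const double t_end = t_out[nt - 1];
  for (int k = 0; k < win_start.size(); ++k) {
    if (win_start[k] > targets.front() && win_start[k] < t_end)
      targets.push_back(win_start[k]);
    if (win_end[k] > targets.front() && win_end[k] < t_end)
      targets.push_back(win_end[k]);
  }
  std::sort(targets.begin(), targets.end());
  targets.erase(std::unique(targets.begin(), targets.end(),
                            [](double a, double b) {
                              return std::abs(a - b) < 1e-12;
                            }),
                targets.end());

  NumericMatrix out(n, nt);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> ytmp(n), ynew(n), err(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);

  double t = t_out[0];
  int iout = 0;
  // record initial condition if it is the first output time
  if (std::abs(targets.front() - t_out[0]) < 1e-12) {
    for (int j = 0; j < n; ++j) out(j, 0) = y[j];
    iout = 1;
  }

  double h = h0;
  long naccept = 0, nreject = 0;
  double steps = 0;

  size_t itgt = 0;
  while (itgt < targets.size() && targets[itgt] <= t + 1e-12) ++itgt;

  while (itgt < targets.size()) {
    const double t_next = targets[itgt];
    // mode for this inter-breakpoint segment
    const double tmid = 0.5 * (t + t_next);
    bool meal_on = false;
    for (int k = 0; k < win_start.size(); ++k) {
      if (tmid >= win_start[k] && tmid < win_end[k]) { meal_on = true; break; }
    }
    while (t < t_next - 1e-12) {
      if (++steps > max_steps) {
#ifdef __SSE2__
        _mm_setcsr(csr_saved);
#endif
        stop("integration exceeded max_steps at t = %f", t);
      }
      double hseg = std::min(h, hmax);
      if (t + hseg > t_next) hseg = t_next - t;

      deriv(A0, Am, meal_on, y, k1);
      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + hseg * a21 * k1[j];
      deriv(A0, Am, meal_on, ytmp, k2);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hseg * (a31 * k1[j] + a32 * k2[j]);
      deriv(A0, Am, meal_on, ytmp, k3);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hseg * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      deriv(A0, Am, meal_on, ytmp, k4);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hseg * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                                 a54 * k4[j]);
      deriv(A0, Am, meal_on, ytmp, k5);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + hseg * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                                 a64 * k4[j] + a65 * k5[j]);
      deriv(A0, Am, meal_on, ytmp, k6);
      for (int j = 0; j < n; ++j)
        ynew[j] = y[j] + hseg * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                                 b5 * k5[j] + b6 * k6[j]);
      deriv(A0, Am, meal_on, ynew, k7);

      double errnorm = 0.0;
      for (int j = 0; j < n; ++j) {
        const double e = hseg * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                 e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double sk =
            atol + rtol * std::max(std::abs(y[j]), std::abs(ynew[j]));
        const double r = e / sk;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / n);

      if (errnorm <= 1.0) {
        t += hseg;
        std::swap(y, ynew);
        ++naccept;
        const double fac =
            std::min(5.0, std::max(0.2, 0.9 * std::pow(
                                            std::max(errnorm, 1e-10), -0.2)));
        h = hseg * fac;
      } else {
        ++nreject;
        h = hseg * std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
        if (h < 1e-10) {
#ifdef __SSE2__
          _mm_setcsr(csr_saved);
#endif
          stop("step size underflow at t = %f (last good state kept)", t);
        }
      }
    }
    t = t_next;
    if (iout < nt && std::abs(t_out[iout] - t) < 1e-12) {
      for (int j = 0; j < n; ++j) out(j, iout) = y[j];
      ++iout;
    }
    ++itgt;
  }
#ifdef __SSE2__
  _mm_setcsr(csr_saved);
#endif
  if (iout != nt) stop("internal error: %d of %d output times filled", iout, nt);

  return List::create(_["y"] = out, _["naccept"] = naccept,
                      _["nreject"] = nreject);
}
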