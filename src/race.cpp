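#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Euler-Maruyama update for the leaky stochastic accumulator
//   x[i+1] = x[i] + (I - k*x[i])*dt + c*xi*sqrt(dt)
// x starts at 0 at stimulus onset; the stored trace holds steps 1..m
// (activation at t = i*dt). Noiseless accumulators (c == 0) consume no
// random numbers, so deterministic paths do not perturb the RNG stream.

static inline double step_acc(double x, double I, double k, double c,
                              double dt, double sdt) {
  double dx = (I - k * x) * dt;
  if (c > 0.0) dx += c * norm_rand() * sdt;
  return x + dx;
}

// [[Rcpp::export]]
List cpp_accumulate(double I, double k, double c, double theta,
                    double dt, int n_max) {
  std::vector<double> trace;
  trace.reserve(n_max < 4096 ? n_max : 4096);
  const double sdt = std::sqrt(dt);
  const bool bounded = R_finite(theta);
  double x = 0.0;
  int crossing = 0;
  for (int i = 1; i <= n_max; ++i) {
    x = step_acc(x, I, k, c, dt, sdt);
    trace.push_back(x);
    if (bounded && x >= theta) { crossing = i; break; }
  }
  return List::create(_["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["crossing"] = crossing);
}

// Race between two accumulators; optionally a second (SMA) pair integrates
// without a threshold alongside and is truncated at the deciding crossing.
// Per-step RNG draw order: congruent, incongruent, sma congruent, sma
// incongruent. A tie at the same sample is broken by a fair coin drawn from
// the same stream.
// [[Rcpp::export]]
List cpp_race_trial(double I1, double k1, double c1,
                    double I2, double k2, double c2,
                    double theta, double dt, int n_max,
                    bool with_sma,
                    double sI1, double sk1, double sc1,
                    double sI2, double sk2, double sc2) {
  const double sdt = std::sqrt(dt);
  std::vector<double> t1, t2, s1, s2;
  size_t res = n_max < 4096 ? n_max : 4096;
  t1.reserve(res); t2.reserve(res);
  if (with_sma) { s1.reserve(res); s2.reserve(res); }
  double x1 = 0.0, x2 = 0.0, y1 = 0.0, y2 = 0.0;
  int winner = 0, crossing = 0;
  for (int i = 1; i <= n_max; ++i) {
    x1 = step_acc(x1, I1, k1, c1, dt, sdt);
    x2 = step_acc(x2, I2, k2, c2, dt, sdt);
    t1.push_back(x1);
    t2.push_back(x2);
    if (with_sma) {
      y1 = step_acc(y1, sI1, sk1, sc1, dt, sdt);
      y2 = step_acc(y2, sI2, sk2, sc2, dt, sdt);
      s1.push_back(y1);
      s2.push_back(y2);
    }
    bool h1 = x1 >= theta, h2 = x2 >= theta;
    if (h1 || h2) {
      crossing = i;
      if (h1 && h2) winner = (unif_rand() < 0.5) ? 1 : 2;
      else winner = h1 ? 1 : 2;
      break;
    }
  }
  List out = List::create(
    _["winner"] = winner,
    _["crossing"] = crossing,
    _["trace1"] = NumericVector(t1.begin(), t1.end()),
    _["trace2"] = NumericVector(t2.begin(), t2.end()));
  if (with_sma) {
    out["sma1"] = NumericVector(s1.begin(), s1.end());
    out["sma2"] = NumericVector(s2.begin(), s2.end());
  }
  return out;
}

// Trace-free batch of races for fitting loops.
// [[Rcpp::export]]
List cpp_race_many(int n, double I1, double k1, double c1,
                   double I2, double k2, double c2,
                   double theta, double dt, int n_max) {
  const double sdt = std::sqrt(dt);
  IntegerVector winner(n), crossing(n);
  for (int r = 0; r < n; ++r) {
    double x1 = 0.0, x2 = 0.0;
    int w = 0, cr = 0;
    for (int i = 1; i <= n_max; ++i) {
      x1 = step_acc(x1, I1, k1, c1, dt, sdt);
      x2 = step_acc(x2, I2, k2, c2, dt, sdt);
      bool h1 = x1 >= theta, h2 = x2 >= theta;
      if (h1 || h2) {
        cr = i;
        if (h1 && h2) w = (unif_rand() < 0.5) ? 1 : 2;
        else w = h1 ? 1 : 2;
        break;
      }
    }
    winner[r] = w;
    crossing[r] = cr;
  }
  return List::create(_["winner"] = winner, _["crossing"] = crossing);
}
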