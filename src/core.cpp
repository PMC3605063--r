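#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Orientation coding: +1 = anti-clockwise (increasing angle), -1 = clockwise.
// Zone codes: 0 none, 1 global, 2 nearest-K, 3 symmetric, 4 forward.

// x mod 2*pi with result in [0, 2*pi), matching R's %% semantics
static inline double mod2pi(double x) {
  double r = x - 2.0 * M_PI * std::floor(x / (2.0 * M_PI));
  if (r >= 2.0 * M_PI) r = 0.0;  // guard against rounding at the boundary
  if (r < 0) r = 0.0;
  return r;
}

static inline double wrap2pi(double x) { return mod2pi(x); }

// signed difference wrapped into (-pi, pi]; mirrors R wrapSigned()
static inline double wrap_signed(double x) {
  double r = mod2pi(x + M_PI) - M_PI;
  if (r <= -M_PI) r = M_PI;
  return r;
}

// |a - b| first, then wrap: exact for small separations (mirrors the R
// implementation so zone-boundary comparisons agree between the two paths)
static inline double ang_sep(double a, double b) {
  double d = mod2pi(std::fabs(a - b));
  return d > M_PI ? 2.0 * M_PI - d : d;
}

static inline bool in_zone(double th_f, int or_f, double th_o, int zone,
                           double R) {
  if (zone == 3) return ang_sep(th_o, th_f) <= R / 2.0;
  double ahead = wrap_signed(th_o - th_f) * or_f;
  return ahead > 0 && ahead <= R;  // zone == 4
}

static const double LOGMIN = -27.631021115928547;  // log(1e-12)

static inline double log_p_turn(double lambda) {   // log logistic(lambda)
  return lambda > 0 ? -std::log1p(std::exp(-lambda))
                    : lambda - std::log1p(std::exp(lambda));
}

// ---------------------------------------------------------------- HMM ----

// Forward-backward for the symmetric two-state Gaussian HMM.
// States: 1 = ACW (mean +mu), 2 = CW (mean -mu); shared sigma and switch
// probability; uniform initial distribution. Log-space recursions.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericVector obs, double p, double mu, double sigma) {
  int T = obs.size();
  NumericMatrix la(T, 2), lb(T, 2), gamma(T, 2);
  NumericMatrix xi(2, 2);
  double lstay = std::log1p(-p), lswitch = std::log(p);
  NumericMatrix le(T, 2);
  for (int t = 0; t < T; ++t) {
    le(t, 0) = R::dnorm(obs[t], mu, sigma, 1);
    le(t, 1) = R::dnorm(obs[t], -mu, sigma, 1);
  }
  const double lhalf = std::log(0.5);
  la(0, 0) = lhalf + le(0, 0);
  la(0, 1) = lhalf + le(0, 1);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < 2; ++j) {
      double a0 = la(t - 1, 0) + (j == 0 ? lstay : lswitch);
      double a1 = la(t - 1, 1) + (j == 1 ? lstay : lswitch);
      double m = std::max(a0, a1);
      la(t, j) = m + std::log(std::exp(a0 - m) + std::exp(a1 - m)) + le(t, j);
    }
  double m = std::max(la(T - 1, 0), la(T - 1, 1));
  double loglik = m + std::log(std::exp(la(T - 1, 0) - m) +
                               std::exp(la(T - 1, 1) - m));
  lb(T - 1, 0) = 0.0;
  lb(T - 1, 1) = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < 2; ++i) {
      double b0 = (i == 0 ? lstay : lswitch) + le(t + 1, 0) + lb(t + 1, 0);
      double b1 = (i == 1 ? lstay : lswitch) + le(t + 1, 1) + lb(t + 1, 1);
      double mm = std::max(b0, b1);
      lb(t, i) = mm + std::log(std::exp(b0 - mm) + std::exp(b1 - mm));
    }
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < 2; ++i)
      gamma(t, i) = std::exp(la(t, i) + lb(t, i) - loglik);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < 2; ++i)
      for (int j = 0; j < 2; ++j)
        xi(i, j) += std::exp(la(t, i) + (i == j ? lstay : lswitch) +
                             le(t + 1, j) + lb(t + 1, j) - loglik);
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding; ties broken toward the previous step's state
// (persistence). Returns +1 (ACW) / -1 (CW) per step.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(NumericVector obs, double p, double mu,
                          double sigma) {
  int T = obs.size();
  NumericMatrix d(T, 2);
  IntegerMatrix back(T, 2);
  double lstay = std::log1p(-p), lswitch = std::log(p);
  const double lhalf = std::log(0.5);
  d(0, 0) = lhalf + R::dnorm(obs[0], mu, sigma, 1);
  d(0, 1) = lhalf + R::dnorm(obs[0], -mu, sigma, 1);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < 2; ++j) {
      double le = R::dnorm(obs[t], j == 0 ? mu : -mu, sigma, 1);
      double from_same = d(t - 1, j) + lstay;
      double from_other = d(t - 1, 1 - j) + lswitch;
      // on a tie keep the same state as the previous step
      if (from_same >= from_other) {
        d(t, j) = from_same + le;
        back(t, j) = j;
      } else {
        d(t, j) = from_other + le;
        back(t, j) = 1 - j;
      }
    }
  IntegerVector path(T);
  int s = d(T - 1, 0) >= d(T - 1, 1) ? 0 : 1;
  path[T - 1] = s == 0 ? 1 : -1;
  for (int t = T - 1; t > 0; --t) {
    s = back(t, s);
    path[t - 1] = s == 0 ? 1 : -1;
  }
  return path;
}

// ------------------------------------------------- neighbour counting ----

static void zone_counts(const NumericMatrix &theta, const IntegerMatrix &state,
                        int t, int i, int zone, double R, int K,
                        int *nneg, int *npos,
                        std::vector<bool> *inz = nullptr) {
  int N = theta.ncol();
  *nneg = 0;
  *npos = 0;
  if (zone == 0) return;
  if (zone == 2) {  // K nearest by angular separation, ties by index
    std::vector<std::pair<double, int> > sep;
    sep.reserve(N - 1);
    for (int j = 0; j < N; ++j)
      if (j != i) sep.push_back(std::make_pair(ang_sep(theta(t, j), theta(t, i)), j));
    std::stable_sort(sep.begin(), sep.end());
    for (int k = 0; k < K && k < (int)sep.size(); ++k) {
      int j = sep[k].second;
      if (state(t, j) != state(t, i)) ++*nneg; else ++*npos;
    }
    return;
  }
  for (int j = 0; j < N; ++j) {
    if (j == i) continue;
    bool in = (zone == 1) ||
      in_zone(theta(t, i), state(t, i), theta(t, j), zone, R);
    if (inz) (*inz)[j] = in;
    if (in) {
      if (state(t, j) != state(t, i)) ++*nneg; else ++*npos;
    }
  }
}

// Per-step negative/positive neighbour counts on decision snapshots
// (frames 0 .. T-2). Used to build sufficient statistics for the
// zone-parameter-free models and for diagnostics.
// [[Rcpp::export(name = ".negcounts_cpp")]]
List negcounts_cpp(NumericMatrix theta, IntegerMatrix state, int zone,
                   double R, int K) {
  int T = theta.nrow(), N = theta.ncol();
  IntegerMatrix nneg(T - 1, N), npos(T - 1, N);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < N; ++i) {
      int a, b;
      zone_counts(theta, state, t, i, zone, R, K, &a, &b);
      nneg(t, i) = a;
      npos(t, i) = b;
    }
  return List::create(_["nNeg"] = nneg, _["nPos"] = npos);
}

// Signed angular separation (positive = ahead along the focal's heading) to
// the nearest opposite-facing individual, per decision snapshot; NaN where
// no opposite-facing individual exists.
// [[Rcpp::export(name = ".nearest_opp_cpp")]]
NumericMatrix nearest_opp_cpp(NumericMatrix theta, IntegerMatrix state) {
  int T = theta.nrow(), N = theta.ncol();
  NumericMatrix out(T - 1, N);
  for (int t = 0; t < T - 1; ++t)
    for (int i = 0; i < N; ++i) {
      double best = NA_REAL, bestabs = R_PosInf;
      for (int j = 0; j < N; ++j) {
        if (j == i || state(t, j) == state(t, i)) continue;
        double s = wrap_signed(theta(t, j) - theta(t, i)) * state(t, i);
        if (std::fabs(s) < bestabs) {
          bestabs = std::fabs(s);
          best = s;
        }
      }
      out(t, i) = best;
    }
  return out;
}

// ----------------------------------------------------------- likelihood ----

// Log-likelihood of the direction-change events under any of the eleven
// models. The probability of an event between frames t and t+1 is computed
// from the frame-t snapshot of all positions and orientations; for memory
// models the per-focal memory state is propagated from the trial start and
// cleared after the focal's own turns. dialect: 0 = per-neighbour trace,
// 1 = aggregate autoregressive.
// [[Rcpp::export(name = ".loglik_cpp")]]
List loglik_cpp(NumericMatrix theta, IntegerMatrix state, IntegerMatrix events,
                int zone, bool usesPos, bool memory, double lambda0,
                double wNeg, double wPos, double R, int K, double alpha,
                int dialect) {
  int T = theta.nrow(), N = theta.ncol();
  double ll = 0.0;
  int clamped = 0;
  double wp = usesPos ? wPos : 0.0;
  std::vector<double> traces(memory ? (size_t)N * N : 0, 0.0);
  std::vector<double> lamPrev(memory ? N : 0, lambda0);
  std::vector<bool> inz(N);
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < N; ++i) {
      double lam;
      if (!memory) {
        int nneg, npos;
        zone_counts(theta, state, t, i, zone, R, K, &nneg, &npos);
        lam = lambda0 + wNeg * nneg + wp * npos;
      } else {
        bool turned = t > 0 && events(t - 1, i) == 1;
        std::fill(inz.begin(), inz.end(), false);
        int nneg, npos;
        zone_counts(theta, state, t, i, zone, R, K, &nneg, &npos, &inz);
        if (dialect == 0) {
          double *tr = &traces[(size_t)i * N];
          if (turned)
            for (int j = 0; j < N; ++j) tr[j] = 0.0;
          double s = 0.0;
          for (int j = 0; j < N; ++j) {
            if (j == i) continue;
            if (inz[j])
              tr[j] = state(t, j) != state(t, i) ? wNeg : wp;
            else
              tr[j] *= alpha;
            s += tr[j];
          }
          lam = lambda0 + s;
        } else {
          double carry = turned ? 0.0 : alpha * (lamPrev[i] - lambda0);
          lam = lambda0 + carry + wNeg * nneg + wp * npos;
          lamPrev[i] = lam;
        }
      }
      double lp;
      if (events(t, i) == 1) {
        lp = log_p_turn(lam);
        if (lp < LOGMIN) { lp = LOGMIN; ++clamped; }
      } else {
        lp = log_p_turn(-lam);
        if (lp < LOGMIN) { lp = LOGMIN; ++clamped; }
      }
      ll += lp;
    }
  }
  return List::create(_["loglik"] = ll, _["clamped"] = clamped);
}

// ------------------------------------------------------------ simulator ----

// Forward simulation of one trial. Initial positions uniform on the ring,
// initial orientations fair coin flips. Per step, agents move in a fresh
// uniformly random order by Gaussian(speedMean*dt, (speedSd*sqrt(dt))^2)
// signed steps along their orientation; turn decisions are then drawn from
// the model intensity evaluated on the post-move positions with all
// orientations frozen at their pre-decision values. Uses R's RNG.
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(int N, int T, double dt, double speedMean, double speedSd,
                  int zone, bool usesPos, bool memory, double lambda0,
                  double wNeg, double wPos, double R, int K, double alpha,
                  int dialect) {
  NumericMatrix theta(T, N);
  IntegerMatrix state(T, N);
  double wp = usesPos ? wPos : 0.0;
  double stepMean = speedMean * dt, stepSd = speedSd * std::sqrt(dt);
  std::vector<double> traces(memory ? (size_t)N * N : 0, 0.0);
  std::vector<double> lamPrev(memory ? N : 0, lambda0);
  std::vector<int> turnedLast(N, 0), order(N), decide(N);
  std::vector<bool> inz(N);
  for (int i = 0; i < N; ++i) {
    theta(0, i) = unif_rand() * 2.0 * M_PI;
    state(0, i) = unif_rand() < 0.5 ? 1 : -1;
  }
  for (int t = 1; t < T; ++t) {
    // fresh random update order for the movement phase (Fisher-Yates)
    for (int i = 0; i < N; ++i) order[i] = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < N; ++k) {
      int i = order[k];
      double step = norm_rand() * stepSd + stepMean;  // may be negative
      theta(t, i) = wrap2pi(theta(t - 1, i) + step * state(t - 1, i));
      state(t, i) = state(t - 1, i);  // frozen until the decision phase
    }
    // synchronous decision phase on the post-move snapshot
    for (int i = 0; i < N; ++i) {
      double lam;
      std::fill(inz.begin(), inz.end(), false);
      int nneg, npos;
      zone_counts(theta, state, t, i, zone, R, K, &nneg, &npos, &inz);
      if (!memory) {
        lam = lambda0 + wNeg * nneg + wp * npos;
      } else if (dialect == 0) {
        double *tr = &traces[(size_t)i * N];
        if (turnedLast[i])
          for (int j = 0; j < N; ++j) tr[j] = 0.0;
        double s = 0.0;
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          if (inz[j])
            tr[j] = state(t, j) != state(t, i) ? wNeg : wp;
          else
            tr[j] *= alpha;
          s += tr[j];
        }
        lam = lambda0 + s;
      } else {
        double carry = turnedLast[i] ? 0.0 : alpha * (lamPrev[i] - lambda0);
        lam = lambda0 + carry + wNeg * nneg + wp * npos;
        lamPrev[i] = lam;
      }
      double pturn = 1.0 / (1.0 + std::exp(-lam));
      decide[i] = unif_rand() < pturn ? 1 : 0;
    }
    for (int i = 0; i < N; ++i) {
      if (decide[i]) state(t, i) = -state(t, i);
      turnedLast[i] = decide[i];
    }
  }
  return List::create(_["theta"] = theta, _["state"] = state);
}
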