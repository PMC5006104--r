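#include <Rcpp.h>
using namespace Rcpp;

// Transfer function r = (a*I - b) / (1 - exp(-d*(a*I - b))) with the
// removable singularity at a*I = b handled by a 2-term Taylor expansion.
static inline double rate_fI(double I, double a, double b, double d) {
  double x = a * I - b;
  if (std::fabs(x) < 1e-6) return 1.0 / d + 0.5 * x;
  return x / (1.0 - std::exp(-d * x));
}

// Fixed-step Euler-Maruyama integration of the coupled two-ensemble
// system.  All stochastic increments (z1, z2, standard normal) are drawn
// by the caller so the function is a pure map from inputs to outputs.
//
// istim1/istim2 cover burn-in and protocol: sample k is the external
// input over [t_k, t_k + dt) with t_k = (k - n_burn) * dt (ms).
// States are recorded from the end of burn-in (t = 0) every
// `record_every` steps, burn-in samples are discarded.
// [[Rcpp::export(name = ".integrate_core")]]
List integrate_core(double dt, int n_burn,
                    NumericVector istim1, NumericVector istim2,
                    NumericVector z1, NumericVector z2,
                    double a, double b, double d,
                    double Js, double Jo,
                    double Io, double sigma, double tau_noise,
                    double gamma, double tau_s,
                    double S1_init, double S2_init,
                    int record_every) {
  const int n_total = istim1.size();
  if (istim2.size() != n_total || z1.size() != n_total ||
      z2.size() != n_total)
    stop("input vectors must have equal length");
  if (n_burn < 0 || n_burn > n_total)
    stop("invalid burn-in length");
  const int n_steps = n_total - n_burn;
  const int n_rec = n_steps / record_every + 1;

  NumericVector oS1(n_rec), oS2(n_rec), oIn1(n_rec), oIn2(n_rec);

  const double dt_s = dt / 1000.0;        // gating equation runs in seconds
  const double tau_s_s = tau_s / 1000.0;
  const double noise_relax = dt / tau_noise;
  const double noise_kick = sigma * std::sqrt(2.0 * dt / tau_noise);

  double S1 = S1_init, S2 = S2_init;
  double In1 = Io, In2 = Io;
  int irec = 0;

  for (int k = 0; k <= n_total; ++k) {
    if (k >= n_burn && (k - n_burn) % record_every == 0 && irec < n_rec) {
      oS1[irec] = S1; oS2[irec] = S2;
      oIn1[irec] = In1; oIn2[irec] = In2;
      ++irec;
    }
    if (k == n_total) break;

    double I1 = Js * S1 - Jo * S2 + istim1[k] + In1;
    double I2 = Js * S2 - Jo * S1 + istim2[k] + In2;
    double r1 = rate_fI(I1, a, b, d);
    double r2 = rate_fI(I2, a, b, d);

    S1 += dt_s * (-S1 / tau_s_s + (1.0 - S1) * gamma * r1);
    S2 += dt_s * (-S2 / tau_s_s + (1.0 - S2) * gamma * r2);

    // numerical overshoot beyond [0,1] by more than 1e-6 indicates a
    // genuine integration problem and is surfaced, never clipped away
    if (!R_finite(S1) || !R_finite(S2))
      stop("integration diverged (non-finite S) at step %d", k + 1);
    if (S1 > 1.0) { if (S1 > 1.0 + 1e-6) stop("S1 overshoot > 1e-6 at step %d", k + 1); S1 = 1.0; }
    if (S2 > 1.0) { if (S2 > 1.0 + 1e-6) stop("S2 overshoot > 1e-6 at step %d", k + 1); S2 = 1.0; }
    if (S1 < 0.0) { if (S1 < -1e-6) stop("S1 undershoot < -1e-6 at step %d", k + 1); S1 = 0.0; }
    if (S2 < 0.0) { if (S2 < -1e-6) stop("S2 undershoot < -1e-6 at step %d", k + 1); S2 = 0.0; }

    In1 += noise_relax * (Io - In1) + noise_kick * z1[k];
    In2 += noise_relax * (Io - In2) + noise_kick * z2[k];
  }

  return List::create(_["S1"] = oS1, _["S2"] = oS2,
                      _["Inoise1"] = oIn1, _["Inoise2"] = oIn2);
}
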