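#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the controller-metabolite system at sensor
// cadence. The cell concentration X and specific growth rate mu are closed
// forms and are supplied precomputed on the grid; only D, S, P (and
// optionally normalized DO) are integrated. Clamping order: derivatives from
// the current state, Euler update, then clamp each state to its feasible set
// (non-negativity; D floored at Dmin during perfusion; DO in [0, 1]).
//
// Two controller drive modes:
//  * analytic (measured_mode = false): the controller sees the model's exact
//    glucose state and the analytic dS/dt (deterministic simulator).
//  * measured (measured_mode = true): raw measurements S + noiseS pass
//    through a causal order-2 lowpass biquad (direct-form II transposed,
//    steady-state initialized) and the controller sees the filtered signal
//    and its finite-difference derivatives — the synthetic-data path, where
//    bubble artifacts induce perfusion-rate spikes emergently.
//
// [[Rcpp::export]]
List euler_core_cpp(NumericVector X, NumericVector mu, NumericVector tgrid,
                    double tsed, double dt,
                    double SI, double Ssp, double Dmin,
                    double Kp, double Ki, double Kd, bool use_pid,
                    double Yxs, double Ypx,
                    bool has_do, double kLa, double Yxc_prime,
                    double S0, double P0, double D0, double C0,
                    double d_ceiling,
                    bool measured_mode,
                    NumericVector noiseS, NumericVector noiseP,
                    NumericVector bcoef, NumericVector acoef) {
  const int n = tgrid.size();
  NumericVector D(n), S(n), P(n);
  NumericVector C(has_do ? n : 0);
  NumericVector Sf(measured_mode ? n : 0), Pf(measured_mode ? n : 0);

  double b0 = 0, b1 = 0, b2 = 0, a1 = 0, a2 = 0;
  if (measured_mode) {
    b0 = bcoef[0]; b1 = bcoef[1]; b2 = bcoef[2];
    a1 = acoef[1]; a2 = acoef[2];  // acoef[0] normalized to 1
  }
  // biquad states (direct-form II transposed) for S and P channels
  double zs1 = 0, zs2 = 0, zp1 = 0, zp2 = 0;

  double Dk = D0, Sk = S0, Pk = P0, Ck = C0;
  double sf_prev = 0, sf_prev2 = 0;       // filtered glucose history
  double dSdt_prev = 0;                   // analytic-mode derivative history
  bool have_prev = false, have_prev2 = false;
  int bad_k = -1;

  for (int k = 0; k < n; ++k) {
    const bool H = tgrid[k] >= tsed;
    if (H && Dk < Dmin) Dk = Dmin;        // hardware floor during perfusion
    if (!H) Dk = 0.0;

    if (!(R_finite(Dk) && R_finite(Sk) && R_finite(Pk)) ||
        std::abs(Dk) > d_ceiling) {
      bad_k = k;
      break;
    }

    D[k] = Dk; S[k] = Sk; P[k] = Pk;
    if (has_do) C[k] = Ck;

    // measurement channel: raw = true + noise, then causal lowpass
    double sf = 0, pf = 0;
    if (measured_mode) {
      double sraw = Sk + noiseS[k];
      double praw = Pk + noiseP[k];
      if (k == 0) {
        // steady-state init: constant input passes through unchanged
        zs2 = (b2 - a2) * sraw; zs1 = (b1 - a1) * sraw + zs2;
        zp2 = (b2 - a2) * praw; zp1 = (b1 - a1) * praw + zp2;
      }
      sf = b0 * sraw + zs1;
      zs1 = b1 * sraw - a1 * sf + zs2;
      zs2 = b2 * sraw - a2 * sf;
      pf = b0 * praw + zp1;
      zp1 = b1 * praw - a1 * pf + zp2;
      zp2 = b2 * praw - a2 * pf;
      Sf[k] = sf; Pf[k] = pf;
    }
    if (k == n - 1) break;

    // physical right-hand sides at the current state
    const double cons = mu[k] * X[k] / Yxs;            // glucose consumption
    const double dSdt = (H ? Dk * (SI - Sk) : 0.0) - cons;
    const double dPdt = Ypx * mu[k] * X[k] - (H ? Dk * Pk : 0.0);

    // controller input: filtered measurement or exact state
    double S_ctrl, dS_ctrl, d2S_ctrl = 0;
    if (measured_mode) {
      S_ctrl = sf;
      dS_ctrl = have_prev ? (sf - sf_prev) / dt : 0.0;
      if (use_pid && have_prev2)
        d2S_ctrl = (sf - 2.0 * sf_prev + sf_prev2) / (dt * dt);
      sf_prev2 = sf_prev; sf_prev = sf;
      have_prev2 = have_prev; have_prev = true;
    } else {
      S_ctrl = Sk;
      dS_ctrl = dSdt;
      if (use_pid && have_prev) d2S_ctrl = (dSdt - dSdt_prev) / dt;
      dSdt_prev = dSdt; have_prev = true;
    }

    double dDdt = 0.0;
    if (H) {
      dDdt = -Kp * dS_ctrl + Ki * (Ssp - S_ctrl);
      if (use_pid) dDdt -= Kd * d2S_ctrl;
    }

    double Dn = Dk + dt * dDdt;
    double Sn = Sk + dt * dSdt;
    double Pn = Pk + dt * dPdt;

    if (Dn < 0) Dn = 0;
    if (Sn < 0) Sn = 0;
    if (Pn < 0) Pn = 0;

    if (has_do) {
      double dCdt = ((H ? Dk : 0.0) + kLa) * (1.0 - Ck) -
                    mu[k] * X[k] / Yxc_prime;
      Ck += dt * dCdt;
      if (Ck < 0) Ck = 0;
      if (Ck > 1) Ck = 1;
    }

    Dk = Dn; Sk = Sn; Pk = Pn;
  }

  return List::create(_["D"] = D, _["S"] = S, _["P"] = P, _["C"] = C,
                      _["Sf"] = Sf, _["Pf"] = Pf, _["bad_k"] = bad_k);
}
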