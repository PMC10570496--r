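#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the three-population neural mass model
// with optional delayed-feedback stimulation.
//
// Channel order (fixed): stn1 (GPe->STN), stn2 (Cor->STN), stn3 (PPN->STN),
// gpe1 (STN->GPe), gpe2 (GPe->GPe), gpe3 (Str->GPe), ppn1 (GPi->PPN),
// ppn2 (STN->PPN).
//
// noise: N x 3 matrix of standard-normal draws (columns Cor, Str, GPi);
// pops: Hs, xs, rs, ys, Hg, xg, rg, yg, Hp, xp, rp, yp;
// lambda: the five pathway gains; input_mean/input_sd: Cor, Str, GPi stats;
// target/source: 0 = none, 1 = STN, 2 = GPe, 3 = PPN;
// delay_steps = round(tau/dt); onset_step: first 1-based step index with
// stimulation active.
//
// The LFPs are recorded at the state current at each step (t_i = (i-1)*dt),
// and the feedback signal is computed from that same grid, so the signal
// enters the sigmoid at the step it is computed.
// [[Rcpp::export]]
List sim_core(NumericMatrix noise, NumericVector pops, NumericVector lambda,
              NumericVector input_mean, NumericVector input_sd,
              double dt, int target, int source, double K,
              int delay_steps, int onset_step) {
  const int N = noise.nrow();
  const double Hs = pops[0], xs = pops[1], rs = pops[2], ys = pops[3];
  const double Hg = pops[4], xg = pops[5], rg = pops[6], yg = pops[7];
  const double Hp = pops[8], xp = pops[9], rp = pops[10], yp = pops[11];

  double gain[8] = {lambda[0] * Hs, Hs, lambda[4] * Hs,
                    lambda[1] * Hg, lambda[2] * Hg, Hg,
                    Hp, lambda[3] * Hp};
  double tc[8] = {xs, xs, xs, xg, xg, xg, xp, xp};
  double v[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  double z[8] = {0, 0, 0, 0, 0, 0, 0, 0};

  NumericVector vs(N), vg(N), vp(N), w(N);

  for (int i = 0; i < N; ++i) {
    const double vstn = v[2] + v[1] - v[0];
    const double vgpe = v[3] - v[4] - v[5];
    const double vppn = v[7] - v[6];
    vs[i] = vstn; vg[i] = vgpe; vp[i] = vppn;

    double wi = 0.0;
    if (target > 0 && (i + 1) >= onset_step) {
      const int j = i - delay_steps;
      if (j < 0) stop("delay exceeds available history at step %d", i + 1);
      const double cur = (source == 1) ? vstn : (source == 2) ? vgpe : vppn;
      const double past = (source == 1) ? vs[j] : (source == 2) ? vg[j] : vp[j];
      wi = K * (past - cur);
    }
    w[i] = wi;

    const double ws = (target == 1) ? wi : 0.0;
    const double wg_ = (target == 2) ? wi : 0.0;
    const double wp_ = (target == 3) ? wi : 0.0;
    const double uS = rs / (1.0 + std::exp(-ys * (vstn + ws)));
    const double uG = rg / (1.0 + std::exp(-yg * (vgpe + wg_)));
    const double uP = rp / (1.0 + std::exp(-yp * (vppn + wp_)));
    const double uCor = input_mean[0] + input_sd[0] * noise(i, 0);
    const double uStr = input_mean[1] + input_sd[1] * noise(i, 1);
    const double uGpi = input_mean[2] + input_sd[2] * noise(i, 2);

    const double u[8] = {uG, uCor, uP, uS, uG, uStr, uGpi, uS};

    double check = 0.0;
    for (int k = 0; k < 8; ++k) {
      const double dz = (gain[k] / tc[k]) * u[k] - (2.0 / tc[k]) * z[k]
                        - v[k] / (tc[k] * tc[k]);
      v[k] += dt * z[k];
      z[k] += dt * dz;
      check += v[k] + z[k];
    }
    if (!std::isfinite(check)) {
      stop("simulation diverged (non-finite state) at step %d of %d",
           i + 1, N);
    }
  }

  return List::create(_["v_stn"] = vs, _["v_gpe"] = vg, _["v_ppn"] = vp,
                      _["w"] = w);
}
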