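#include <Rcpp.h>
#include "tt06.h"
using namespace Rcpp;

// Single-cell pacing driver: fixed-step forward Euler / Rush-Larsen at dt,
// stimulus applied at the start of each cycle. Records V from `record_from`
// (ms) onward at `sample_dt` intervals.
// [[Rcpp::export(name = ".cpp_simulate_single_cell")]]
List cpp_simulate_single_cell(int celltype, double gto_mult, double gks_mult,
                              double gkr_mult, double dt, double bcl,
                              int nbeats, double stim_amp, double stim_dur,
                              double sample_dt, double record_from,
                              Nullable<NumericVector> init_state_ = R_NilValue) {
  tt06::LUT lut;
  lut.build(dt, dt);
  tt06::SoA s;
  s.init(1);
  if (init_state_.isNotNull()) {
    NumericVector y(init_state_);
    if (y.size() != tt06::NSTATE) stop("init state must have %d entries", tt06::NSTATE);
    s.V[0] = y[0]; s.m[0] = y[1]; s.h[0] = y[2]; s.j[0] = y[3];
    s.xr1[0] = y[4]; s.xr2[0] = y[5]; s.xs[0] = y[6]; s.r[0] = y[7];
    s.s[0] = y[8]; s.d[0] = y[9]; s.f[0] = y[10]; s.f2[0] = y[11];
    s.fcass[0] = y[12]; s.rr[0] = y[13]; s.cai[0] = y[14]; s.casr[0] = y[15];
    s.cass[0] = y[16]; s.nai[0] = y[17]; s.ki[0] = y[18];
    s.refresh_reversals();
  }
  tt06::CellCond cc;
  cc.ct = celltype;
  cc.Gto = tt06::Gto_base(celltype) * gto_mult;
  cc.Gks = tt06::Gks_base(celltype) * gks_mult;
  cc.Gkr = tt06::GKr * gkr_mult;

  const double t_end = bcl * nbeats;
  const long nsteps = (long)std::llround(t_end / dt);
  const long sample_every = std::max(1L, (long)std::llround(sample_dt / dt));
  std::vector<double> tv, vv;
  tv.reserve(nsteps / sample_every + 2);
  vv.reserve(nsteps / sample_every + 2);

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    if (k % sample_every == 0 && t >= record_from - 1e-9) {
      tv.push_back(t);
      vv.push_back(s.V[0]);
    }
    double tc = t - bcl * std::floor(t / bcl);
    double istim = (tc < stim_dur - 1e-9) ? stim_amp : 0.0;
    s.refresh_reversals();
    double dv = tt06::cell_step(s, cc, lut, 0, dt, true, istim);
    s.V[0] += dt * dv;
    if (std::fabs(s.V[0]) > 200.0)
      stop("single-cell integration diverged (|V| > 200 mV at t = %.3f ms)", t);
  }
  tv.push_back(t_end);
  vv.push_back(s.V[0]);

  NumericVector fin(tt06::NSTATE);
  fin[0] = s.V[0]; fin[1] = s.m[0]; fin[2] = s.h[0]; fin[3] = s.j[0];
  fin[4] = s.xr1[0]; fin[5] = s.xr2[0]; fin[6] = s.xs[0]; fin[7] = s.r[0];
  fin[8] = s.s[0]; fin[9] = s.d[0]; fin[10] = s.f[0]; fin[11] = s.f2[0];
  fin[12] = s.fcass[0]; fin[13] = s.rr[0]; fin[14] = s.cai[0];
  fin[15] = s.casr[0]; fin[16] = s.cass[0]; fin[17] = s.nai[0]; fin[18] = s.ki[0];

  return List::create(_["time"] = wrap(tv), _["V"] = wrap(vv),
                      _["state"] = fin);
}
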