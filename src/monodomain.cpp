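// Anisotropic monodomain reaction-diffusion solver on a structured voxel grid.
// Godunov operator splitting: TT06 reaction step (Rush-Larsen) followed by a
// conservative finite-volume diffusion step with face-averaged tensors and
// no-flux boundaries. Adaptive time step: dt_min whenever any voxel has
// |dV/dt| > 1 mV/ms, else dt_max.
#include <Rcpp.h>
#include <cstring>
#include "tt06.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_run_tissue")]]
List cpp_run_tissue(IntegerVector dims, double dx,
                    IntegerVector tissue_idx,      // 0-based linear full-grid index
                    NumericMatrix tensors,         // n x 6: xx,yy,zz,xy,xz,yz
                    IntegerVector celltype,        // 0 ENDO, 1 MCELL, 2 EPI
                    NumericVector gto_mult, NumericVector gks_mult,
                    NumericVector gkr_mult,
                    List stim_voxels,              // list of 0-based tissue-index vectors
                    NumericVector stim_onset, NumericVector stim_dur,
                    NumericVector stim_amp,
                    double dt_min, double dt_max, double t_end,
                    NumericVector snapshot_times,  // ascending, on dt grid
                    IntegerVector record_idx,      // 0-based tissue indices (empty = all)
                    double window_start, double stop_margin,
                    bool passive, double refresh_ms, bool local_adaptive,
                    double upstroke_thr,
                    Nullable<NumericVector> v_init_ = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nfull = (size_t)nx * ny * nz;
  const size_t n = tissue_idx.size();
  if ((size_t)tensors.nrow() != n) stop("tensor rows must match tissue voxels");

  // full-grid -> tissue map and neighbor table
  std::vector<int> full2tis(nfull, -1);
  for (size_t v = 0; v < n; ++v) {
    int fi = tissue_idx[v];
    if (fi < 0 || (size_t)fi >= nfull) stop("tissue index out of range");
    full2tis[fi] = (int)v;
  }
  const int sx = 1, sy = nx, sz = nx * ny;
  std::vector<int> nb(n * 6, -1);  // x-,x+,y-,y+,z-,z+
  for (size_t v = 0; v < n; ++v) {
    int fi = tissue_idx[v];
    int i = fi % nx, j = (fi / nx) % ny, k = fi / (nx * ny);
    if (i > 0) nb[v * 6 + 0] = full2tis[fi - sx];
    if (i < nx - 1) nb[v * 6 + 1] = full2tis[fi + sx];
    if (j > 0) nb[v * 6 + 2] = full2tis[fi - sy];
    if (j < ny - 1) nb[v * 6 + 3] = full2tis[fi + sy];
    if (k > 0) nb[v * 6 + 4] = full2tis[fi - sz];
    if (k < nz - 1) nb[v * 6 + 5] = full2tis[fi + sz];
  }

  // flat copy of tensors for the hot loop
  std::vector<double> T6(n * 6);
  for (size_t v = 0; v < n; ++v)
    for (int c = 0; c < 6; ++c) T6[v * 6 + c] = tensors(v, c);

  tt06::LUT lut;
  lut.build(dt_min, dt_max);
  tt06::SoA s;
  s.init(n);
  if (v_init_.isNotNull()) {
    NumericVector vi(v_init_);
    if ((size_t)vi.size() != n) stop("v_init length must match tissue voxels");
    for (size_t v = 0; v < n; ++v) s.V[v] = vi[v];
  }
  std::vector<tt06::CellCond> cond(n);
  for (size_t v = 0; v < n; ++v) {
    cond[v].ct = celltype[v];
    cond[v].Gto = tt06::Gto_base(celltype[v]) * gto_mult[v];
    cond[v].Gks = tt06::Gks_base(celltype[v]) * gks_mult[v];
    cond[v].Gkr = tt06::GKr * gkr_mult[v];
  }

  // stimulus bookkeeping
  const int nev = stim_onset.size();
  std::vector<std::vector<int>> ev_vox(nev);
  for (int e = 0; e < nev; ++e) {
    IntegerVector iv = stim_voxels[e];
    ev_vox[e].assign(iv.begin(), iv.end());
    for (int q : ev_vox[e])
      if (q < 0 || (size_t)q >= n) stop("stimulus voxel index out of range");
  }
  std::vector<double> istim(n, 0.0);
  long active_sig = -1;

  // recording setup
  std::vector<int> rec;
  if (record_idx.size() == 0) {
    rec.resize(n);
    for (size_t v = 0; v < n; ++v) rec[v] = (int)v;
  } else {
    rec.assign(record_idx.begin(), record_idx.end());
  }
  const size_t nrec = rec.size();
  const int nsnap = snapshot_times.size();
  NumericMatrix Vrec(nrec, nsnap);
  int snap_ptr = 0;

  // activation tracking (within [window_start, end])
  std::vector<double> act_time(n, NA_REAL), max_dvdt(n, 0.0);
  // a voxel counts as activated only after an upward crossing of -20 mV from
  // a repolarized state (below -60 mV) within the analysis window, so tissue
  // still depolarized from a previous beat is not mistaken for activation
  std::vector<char> crossed(n, 0), armed(n, 0);
  for (size_t v = 0; v < n; ++v) armed[v] = s.V[v] < -60.0;
  size_t n_crossed = 0;
  bool window_open = (window_start <= 1e-12);

  std::vector<double> vold(n), dvd(n);
  // per-cell adaptive reaction stepping: quiescent cells re-evaluate their
  // ionic currents only every dt_max, advancing V with the cached derivative
  std::vector<double> cached_dvr(n, 0.0), acc_ms(n, 0.0);
  std::vector<char> fast(n, 1);
  const double inv_dx = 1.0 / dx;
  const double eps = 1e-9;
  double t = 0.0, t_stop = t_end;
  double prev_max_dvdt = 1e9;  // start at dt_min
  long refresh_every = std::max(1L, (long)std::llround(refresh_ms / dt_min));
  long step = 0;

  while (t < t_stop - eps) {
    // time-step selection: boundaries are event on/off times and snapshots
    double next_bound = t_stop;
    for (int e = 0; e < nev; ++e) {
      if (stim_onset[e] > t + eps) next_bound = std::min(next_bound, stim_onset[e]);
      double off = stim_onset[e] + stim_dur[e];
      if (off > t + eps) next_bound = std::min(next_bound, off);
    }
    if (snap_ptr < nsnap && snapshot_times[snap_ptr] > t + eps)
      next_bound = std::min(next_bound, (double)snapshot_times[snap_ptr]);
    if (!window_open && window_start > t + eps)
      next_bound = std::min(next_bound, window_start);
    bool slow = prev_max_dvdt > upstroke_thr;
    double dt;
    bool useA;
    if (!slow && t + dt_max <= next_bound + eps) {
      dt = dt_max; useA = false;
    } else {
      dt = dt_min; useA = true;
      if (t + dt > next_bound + eps) dt = next_bound - t;  // sub-grid guard
    }

    // stimulus activity signature
    long sig = 0;
    bool any_active = false;
    for (int e = 0; e < nev; ++e) {
      if (t >= stim_onset[e] - eps && t < stim_onset[e] + stim_dur[e] - eps) {
        sig = sig * 131 + e + 1;
        any_active = true;
      }
    }
    if (sig != active_sig) {
      std::memset(istim.data(), 0, n * sizeof(double));
      for (int e = 0; e < nev; ++e)
        if (t >= stim_onset[e] - eps && t < stim_onset[e] + stim_dur[e] - eps)
          for (int q : ev_vox[e]) istim[q] += stim_amp[e];
      active_sig = sig;
    }

    if (step % refresh_every == 0 && !passive) s.refresh_reversals();
    std::memcpy(vold.data(), s.V.data(), n * sizeof(double));

    // reaction
    if (!passive && !local_adaptive) {
      for (size_t v = 0; v < n; ++v) {
        double dv = tt06::cell_step(s, cond[v], lut, v, dt, useA, istim[v]);
        s.V[v] += dt * dv;
      }
    } else if (!passive) {
      for (size_t v = 0; v < n; ++v) {
        acc_ms[v] += dt;
        bool due = fast[v] || istim[v] != 0.0 ||
                   acc_ms[v] >= dt_max - eps;
        if (due) {
          bool gatesA = acc_ms[v] < dt_max - eps;
          double dv = tt06::cell_step(s, cond[v], lut, v, acc_ms[v], gatesA,
                                      istim[v]);
          cached_dvr[v] = dv;
          acc_ms[v] = 0.0;
          s.V[v] += dt * dv;
        } else {
          s.V[v] += dt * cached_dvr[v];
        }
      }
    } else if (any_active) {
      for (size_t v = 0; v < n; ++v) s.V[v] += dt * (-istim[v]);
    }

    // diffusion (conservative face fluxes)
    std::memset(dvd.data(), 0, n * sizeof(double));
    const double *V = s.V.data();
    for (size_t v = 0; v < n; ++v) {
      const int *nbv = &nb[v * 6];
      double Vv = V[v];
      // tangential derivative helper via reflection
      for (int a = 0; a < 3; ++a) {
        int w = nbv[2 * a + 1];
        if (w < 0) continue;  // no-flux face
        const int *nbw = &nb[(size_t)w * 6];
        double Dn, Dt1, Dt2;
        int t1m_v, t1p_v, t2m_v, t2p_v, t1m_w, t1p_w, t2m_w, t2p_w;
        if (a == 0) {        // +x face: normal xx, tangential y (xy), z (xz)
          Dn = 0.5 * (T6[v * 6 + 0] + T6[(size_t)w * 6 + 0]);
          Dt1 = 0.5 * (T6[v * 6 + 3] + T6[(size_t)w * 6 + 3]);
          Dt2 = 0.5 * (T6[v * 6 + 4] + T6[(size_t)w * 6 + 4]);
          t1m_v = nbv[2]; t1p_v = nbv[3]; t2m_v = nbv[4]; t2p_v = nbv[5];
          t1m_w = nbw[2]; t1p_w = nbw[3]; t2m_w = nbw[4]; t2p_w = nbw[5];
        } else if (a == 1) { // +y face: normal yy, tangential x (xy), z (yz)
          Dn = 0.5 * (T6[v * 6 + 1] + T6[(size_t)w * 6 + 1]);
          Dt1 = 0.5 * (T6[v * 6 + 3] + T6[(size_t)w * 6 + 3]);
          Dt2 = 0.5 * (T6[v * 6 + 5] + T6[(size_t)w * 6 + 5]);
          t1m_v = nbv[0]; t1p_v = nbv[1]; t2m_v = nbv[4]; t2p_v = nbv[5];
          t1m_w = nbw[0]; t1p_w = nbw[1]; t2m_w = nbw[4]; t2p_w = nbw[5];
        } else {             // +z face: normal zz, tangential x (xz), y (yz)
          Dn = 0.5 * (T6[v * 6 + 2] + T6[(size_t)w * 6 + 2]);
          Dt1 = 0.5 * (T6[v * 6 + 4] + T6[(size_t)w * 6 + 4]);
          Dt2 = 0.5 * (T6[v * 6 + 5] + T6[(size_t)w * 6 + 5]);
          t1m_v = nbv[0]; t1p_v = nbv[1]; t2m_v = nbv[2]; t2p_v = nbv[3];
          t1m_w = nbw[0]; t1p_w = nbw[1]; t2m_w = nbw[2]; t2p_w = nbw[3];
        }
        double Vw = V[w];
        double g1v = 0.5 * ((t1p_v >= 0 ? V[t1p_v] : Vv) - (t1m_v >= 0 ? V[t1m_v] : Vv));
        double g1w = 0.5 * ((t1p_w >= 0 ? V[t1p_w] : Vw) - (t1m_w >= 0 ? V[t1m_w] : Vw));
        double g2v = 0.5 * ((t2p_v >= 0 ? V[t2p_v] : Vv) - (t2m_v >= 0 ? V[t2m_v] : Vv));
        double g2w = 0.5 * ((t2p_w >= 0 ? V[t2p_w] : Vw) - (t2m_w >= 0 ? V[t2m_w] : Vw));
        double flux = Dn * (Vw - Vv) * inv_dx +
                      Dt1 * 0.5 * (g1v + g1w) * inv_dx +
                      Dt2 * 0.5 * (g2v + g2w) * inv_dx;
        dvd[v] += flux * inv_dx;
        dvd[w] -= flux * inv_dx;
      }
    }
    double maxdv = 0.0;
    for (size_t v = 0; v < n; ++v) {
      s.V[v] += dt * dvd[v];
      double dvtot = (s.V[v] - vold[v]) / dt;
      double ad = std::fabs(dvtot);
      if (ad > maxdv) maxdv = ad;
      fast[v] = ad > upstroke_thr;
      if (window_open) {
        if (dvtot > max_dvdt[v]) { max_dvdt[v] = dvtot; act_time[v] = t; }
        if (!armed[v] && s.V[v] < -60.0) armed[v] = 1;
        if (armed[v] && !crossed[v] && s.V[v] > -20.0) { crossed[v] = 1; ++n_crossed; }
      }
    }
    prev_max_dvdt = maxdv;
    if (maxdv * dt_min > 200.0 || std::fabs(s.V[0]) > 1e6)
      stop("monodomain solution diverging at t = %.3f ms (max |dV/dt| = %.1f)", t, maxdv);
    for (size_t v = 0; v < n; ++v)
      if (std::fabs(s.V[v]) > 200.0)
        stop("monodomain instability at tissue voxel %d, t = %.3f ms, dt = %.3f "
             "(|V| > 200 mV)", (int)v + 1, t, dt);

    t += dt;
    ++step;

    // window opening resets activation trackers
    if (!window_open && t >= window_start - eps) {
      window_open = true;
      std::fill(max_dvdt.begin(), max_dvdt.end(), 0.0);
      std::fill(act_time.begin(), act_time.end(), NA_REAL);
      std::fill(crossed.begin(), crossed.end(), 0);
      for (size_t v = 0; v < n; ++v) armed[v] = s.V[v] < -60.0;
      n_crossed = 0;
    }
    // snapshot
    while (snap_ptr < nsnap && t >= snapshot_times[snap_ptr] - eps) {
      for (size_t q = 0; q < nrec; ++q) Vrec(q, snap_ptr) = s.V[rec[q]];
      ++snap_ptr;
    }
    // early stop after full activation
    if (stop_margin >= 0 && window_open && n_crossed == n && t_stop == t_end)
      t_stop = std::min(t_end, t + stop_margin);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["times"] = snapshot_times[Range(0, std::max(0, snap_ptr - 1))],
      _["n_snapshots"] = snap_ptr,
      _["V"] = Vrec,
      _["act_time"] = wrap(act_time),
      _["max_dvdt"] = wrap(max_dvdt),
      _["activated"] = wrap(std::vector<int>(crossed.begin(), crossed.end())),
      _["V_final"] = wrap(s.V),
      _["t_final"] = t,
      _["steps"] = (double)step);
}
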