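#' Assemble the anisotropic diffusion tensor field
#'
#' D = D_perp I + (D_par - D_perp) A A^T per tissue voxel, where A is the
#' unit fiber vector: axially symmetric anisotropy with longitudinal
#' coefficient `d_par` along fibers and transverse coefficient `d_perp`
#' orthogonal to them. Defaults: D_par = 0.18 mm^2/ms (conduction velocity
#' ~70 cm/s along fibers) and a 4:1 anisotropy ratio.
#'
#' @param fibers n x 3 matrix of unit fiber vectors.
#' @param d_par Longitudinal diffusion coefficient, mm^2/ms.
#' @param d_perp Transverse diffusion coefficient, mm^2/ms.
#' @return An `ecgi_diffusion` object: n x 6 matrix with columns
#'   xx, yy, zz, xy, xz, yz plus `d_par`/`d_perp` attributes.
#' @export
assemble_diffusion <- function(fibers, d_par = 0.18, d_perp = 0.18 / 4) {
  fibers <- as.matrix(fibers)
  if (ncol(fibers) != 3) stop("fibers must be an n x 3 matrix")
  nrm <- sqrt(rowSums(fibers^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("fiber vectors must be unit length (max deviation ",
         format(max(abs(nrm - 1))), ")")
  dd <- d_par - d_perp
  tens <- cbind(d_perp + dd * fibers[, 1]^2,
                d_perp + dd * fibers[, 2]^2,
                d_perp + dd * fibers[, 3]^2,
                dd * fibers[, 1] * fibers[, 2],
                dd * fibers[, 1] * fibers[, 3],
                dd * fibers[, 2] * fibers[, 3])
  colnames(tens) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  structure(tens, d_par = d_par, d_perp = d_perp, class = "ecgi_diffusion")
}

#' Conduction-velocity-matched diffusion coefficients for coarse grids
#'
#' Explicit finite differences underestimate conduction velocity when the
#' upstroke spans few voxels, so coarse desk-scale grids need rescaled
#' diffusion coefficients to propagate at the speeds of the 0.5 mm study
#' resolution (68.5 cm/s along fibers, 22.8 cm/s transverse, measured on the
#' 1D cable with D_par = 0.18 mm^2/ms and a 4:1 anisotropy ratio). The
#' values shipped here were calibrated once by bisection on cable
#' simulations at each resolution; intermediate resolutions are
#' log-interpolated.
#'
#' @param dx Grid resolution, mm (supported range 0.5 to 4/3).
#' @return List with `d_par` and `d_perp` (mm^2/ms).
#' @export
cv_matched_diffusion <- function(dx) {
  cal <- cbind(dx = c(0.5, 1.0, 4 / 3),
               d_par = c(0.18, 0.2866, 0.3654),
               d_perp = c(0.045, 0.0916, 0.1277))
  if (dx < min(cal[, 1]) - 1e-9 || dx > max(cal[, 1]) + 1e-9)
    stop("cv_matched_diffusion calibrated for resolutions in [0.5, 4/3] mm")
  list(d_par = exp(stats::approx(cal[, 1], log(cal[, 2]), dx, rule = 2)$y),
       d_perp = exp(stats::approx(cal[, 1], log(cal[, 3]), dx, rule = 2)$y))
}

#' Solver options for the monodomain model
#'
#' The explicit solver uses Godunov operator splitting (reaction then
#' diffusion) with an adaptive step: dt_min whenever any voxel's |dV/dt|
#' exceeds 1 mV/ms (an upstroke anywhere in the tissue), dt_max otherwise.
#'
#' @param dt_min Minimum time step, ms.
#' @param dt_max Maximum time step, ms.
#' @param sample_dt Snapshot interval for recorded voltages, ms.
#' @param refresh_ms Interval at which slowly varying reversal potentials are
#'   recomputed from the ionic concentrations, ms.
#' @param upstroke_thr |dV/dt| threshold (mV/ms) above which a voxel counts
#'   as active, forcing `dt_min`.
#' @param local_adaptive Additionally let each quiescent cell (|dV/dt| below
#'   the threshold, unstimulated) re-evaluate its ionic currents only every
#'   `dt_max`, advancing its voltage with the cached reaction derivative in
#'   between; cells on the wavefront are always evaluated every step. Off by
#'   default; used by the experiment drivers at desk scale.
#' @return An `ecgi_solver_options` object.
#' @export
solver_options <- function(dt_min = 0.02, dt_max = 0.2, sample_dt = 1,
                           refresh_ms = 0.5, local_adaptive = FALSE,
                           upstroke_thr = 0.5) {
  if (dt_min <= 0 || dt_max < dt_min) stop("need 0 < dt_min <= dt_max")
  structure(list(dt_min = dt_min, dt_max = dt_max, sample_dt = sample_dt,
                 refresh_ms = refresh_ms,
                 local_adaptive = isTRUE(local_adaptive),
                 upstroke_thr = upstroke_thr),
            class = "ecgi_solver_options")
}

#' Run the monodomain tissue simulation
#'
#' Solves dV/dt = div(D grad V) - I_ion / C_m on the tissue voxels of a
#' labeled grid with no-flux boundaries, the TT06 reaction term, and the
#' stimuli of a schedule. Per-voxel regional parameters are derived from the
#' grid's cell-type and apico-basal fields.
#'
#' @param grid A labeled `ecgi_grid` (with `celltype` and `f_ab`; see
#'   [build_labeled_geometry()]).
#' @param diffusion An `ecgi_diffusion` from [assemble_diffusion()].
#' @param schedule An `ecgi_schedule` from the protocol constructors.
#' @param opts An `ecgi_solver_options`.
#' @param t_end End of simulation, ms (default: schedule window).
#' @param short_ap Use the short-action-potential cell variant everywhere.
#' @param record Optional indices (into the tissue voxel enumeration) to
#'   record; default records all tissue voxels.
#' @param window_start Start of the activation-analysis window, ms
#'   (activation times and snapshots are only meaningful from here on).
#' @param stop_margin If >= 0, stop this many ms after every tissue voxel has
#'   activated within the analysis window (saves the quiescent tail).
#' @param snapshot_times Explicit snapshot times, ms (overrides `sample_dt`).
#' @param passive Disable the ionic model (linear diffusion only; used for
#'   conservation tests).
#' @param v_init Optional initial voltage per tissue voxel, mV.
#' @return An `ecgi_recordings` object: list with `times`, `V` (voxels x
#'   times), `act_time`, `max_dvdt`, `activated`, `record` (recorded voxel
#'   indices), `grid_ref` (dims/dx/origin/tissue_idx) and `t_final`.
#' @export
run_tissue <- function(grid, diffusion, schedule, opts = solver_options(),
                       t_end = NULL, short_ap = FALSE, record = NULL,
                       window_start = 0, stop_margin = -1,
                       snapshot_times = NULL, passive = FALSE, v_init = NULL) {
  stopifnot(inherits(grid, "ecgi_grid"))
  n <- length(grid$tissue_idx)
  if (!passive) {
    if (is.null(grid$celltype) || is.null(grid$f_ab))
      stop("grid needs celltype and f_ab fields (see build_labeled_geometry)")
    cp <- tissue_cell_multipliers(grid, short_ap)
  } else {
    cp <- list(celltype = integer(n), gto = rep(1, n), gks = rep(1, n),
               gkr = rep(1, n))
  }
  if (nrow(diffusion) != n) stop("diffusion rows must match tissue voxels")
  stopifnot(inherits(schedule, "ecgi_schedule"))
  if (is.null(t_end)) t_end <- schedule$window
  # snap event times to the dt_max grid so adaptive stepping stays aligned
  onsets <- round(schedule$onset / opts$dt_max) * opts$dt_max
  durs <- pmax(round(schedule$duration / opts$dt_min) * opts$dt_min, opts$dt_min)
  if (any(onsets + durs > t_end))
    stop("schedule events extend beyond the simulation window")
  stim_vox <- schedule_voxels(grid, schedule)
  if (is.null(snapshot_times))
    snapshot_times <- seq(max(opts$sample_dt, window_start), t_end,
                          by = opts$sample_dt)
  snapshot_times <- round(snapshot_times / opts$dt_max) * opts$dt_max

  res <- .cpp_run_tissue(as.integer(grid$dims), grid$dx,
                         as.integer(grid$tissue_idx - 1L),
                         unclass(diffusion)[, , drop = FALSE],
                         as.integer(cp$celltype), cp$gto, cp$gks, cp$gkr,
                         lapply(stim_vox, function(v) as.integer(v - 1L)),
                         onsets, durs, schedule$amplitude,
                         opts$dt_min, opts$dt_max, t_end,
                         snapshot_times,
                         if (is.null(record)) integer(0) else as.integer(record - 1L),
                         window_start, stop_margin, passive, opts$refresh_ms,
                         opts$local_adaptive, opts$upstroke_thr, v_init)
  ns <- res$n_snapshots
  act <- res$act_time
  act[res$activated == 0L] <- NA_real_
  structure(list(times = snapshot_times[seq_len(ns)],
                 V = res$V[, seq_len(ns), drop = FALSE],
                 act_time = act,
                 max_dvdt = res$max_dvdt,
                 activated = res$activated == 1L,
                 record = if (is.null(record)) seq_len(n) else record,
                 V_final = res$V_final,
                 t_final = res$t_final,
                 steps = res$steps,
                 grid_ref = list(dims = grid$dims, dx = grid$dx,
                                 origin = grid$origin,
                                 tissue_idx = grid$tissue_idx)),
            class = "ecgi_recordings")
}

#' @noRd
tissue_cell_multipliers <- function(grid, short_ap = FALSE) {
  grad <- 0.5 + 0.5 * grid$f_ab
  gkr <- ifelse(grid$celltype == 2L, 1.6, 1.0)
  gks <- grad
  if (isTRUE(short_ap)) {
    gkr <- gkr * 5
    gks <- gks * 5
  }
  list(celltype = grid$celltype, gto = grad, gks = gks, gkr = gkr)
}

# map schedule events to tissue-voxel index sets (1-based)
#' @noRd
schedule_voxels <- function(grid, schedule) {
  xyz <- grid_coords(grid)
  lapply(seq_len(nrow(schedule$center)), function(e) {
    ctr <- schedule$center[e, ]
    r <- schedule$extent[e] / 2
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    w <- which(d2 <= r^2)
    if (length(w) == 0) {
      # fall back to the nearest tissue voxel so every event captures
      w <- which.min(d2)
    }
    w
  })
}

#' Conduction velocity between two recorded probes
#'
#' Activation time at each probe is the time of maximum dV/dt of its trace;
#' the conduction velocity is the probe separation divided by the activation
#' delay.
#'
#' @param recordings An `ecgi_recordings` object.
#' @param probes Length-2 vector of indices into the recorded voxel set.
#' @param positions 2 x 3 matrix of probe positions, mm (defaults to the
#'   voxel centres of the probes).
#' @return Conduction velocity in cm/s.
#' @export
measure_cv <- function(recordings, probes, positions = NULL) {
  stopifnot(inherits(recordings, "ecgi_recordings"), length(probes) == 2)
  tt <- recordings$times
  act <- numeric(2)
  for (q in 1:2) {
    ridx <- match(probes[q], recordings$record)
    if (is.na(ridx)) stop("probe not in recorded set")
    v <- recordings$V[ridx, ]
    dv <- diff(v) / diff(tt)
    if (max(dv) < 1) stop("probe never activates (no upstroke)")
    act[q] <- tt[which.max(dv)]
  }
  if (is.null(positions)) {
    gr <- recordings$grid_ref
    fake <- structure(list(dims = gr$dims, dx = gr$dx, origin = gr$origin,
                           tissue_idx = gr$tissue_idx), class = "ecgi_grid")
    positions <- grid_coords(fake)[probes, , drop = FALSE]
  }
  dist_mm <- sqrt(sum((positions[2, ] - positions[1, ])^2))
  dt_ms <- act[2] - act[1]
  if (abs(dt_ms) < .Machine$double.eps)
    stop("zero activation delay between probes")
  (dist_mm / abs(dt_ms)) * 100  # mm/ms -> cm/s
}

#' Build a 1D cable fixture
#'
#' A single-fiber strand of `n` voxels at spacing `dx` with fibers along x,
#' uniform cell type and apical parameters; used for conduction-velocity
#' calibration.
#'
#' @param n Number of voxels.
#' @param dx Spacing, mm.
#' @param celltype Cell type for all voxels.
#' @param fiber_axis 1 for propagation along the cable (longitudinal), or a
#'   length-3 fiber vector to set anisotropy relative to the cable direction.
#' @return A minimal labeled `ecgi_grid` of dims c(n, 1, 1).
#' @export
make_cable_grid <- function(n = 100, dx = 0.5, celltype = "EPI",
                            fiber_axis = 1) {
  ct <- celltype_code(celltype)
  if (length(fiber_axis) == 1) {
    fib <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
  } else {
    f <- fiber_axis / sqrt(sum(fiber_axis^2))
    fib <- matrix(rep(f, each = n), ncol = 3)
  }
  structure(list(dims = c(n, 1L, 1L), dx = dx,
                 origin = c(dx / 2, 0, 0),
                 tissue_idx = seq_len(n),
                 mask = array(TRUE, c(n, 1, 1)),
                 cavity = array(FALSE, c(n, 1, 1)),
                 chamber = rep(1L, n),
                 depth = rep(0.5, n),
                 celltype = rep(ct, n),
                 f_ab = rep(1, n),
                 fiber = fib,
                 params = NULL),
            class = "ecgi_grid")
}
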