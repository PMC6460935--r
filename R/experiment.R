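#' Configuration for the mismatch / rate / short-AP studies
#'
#' Desk-scale defaults: a 1.0 mm grid for sinus activation; ectopic studies
#' default to the coarsest grid that still resolves the right-ventricular
#' wall with three voxels (4/3 mm); icosphere level 3 (642-vertex) torso and
#' epicardial surfaces; 128 electrodes; 2 ms snapshots. The full-scale
#' 0.5 mm setting of the source study is supported by setting
#' `resolution = 0.5`.
#'
#' @param variants Geometry variants to simulate.
#' @param sites Ectopic sites (see [ectopic_sites()]).
#' @param bcls Basic cycle lengths for the rate study, ms.
#' @param orders Tikhonov orders.
#' @param resolution Grid resolution for ectopic studies, mm.
#' @param epi_level,torso_level Icosphere subdivision of the surfaces.
#' @param n_electrodes Number of electrodes.
#' @param snapshot_dt Snapshot interval, ms.
#' @param d_par,d_perp Diffusion coefficients, mm^2/ms; NULL (default)
#'   selects the conduction-velocity-matched values for `resolution`
#'   ([cv_matched_diffusion()]).
#' @param source_cell Source-aggregation bin, mm.
#' @param act_window Post-stimulus analysis window, ms.
#' @param ed_window Earliest-activation window for localization error, ms.
#' @param noise_snr_db Optional SNR of added BSP noise (NA = noiseless).
#' @param lambda Lambda selection mode for [reconstruct_timeseries()]
#'   (`"shared"` by default: one L-curve lambda per case, selected on the
#'   snapshot of maximum BSP power, so activation-time derivatives are not
#'   contaminated by snapshot-to-snapshot regularization jumps).
#' @param seed Seed for electrode layout and noise.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return An `ecgi_experiment_config`.
#' @export
experiment_config <- function(variants = c("control", "thick", "dilated"),
                              sites = c("RV-LAT", "LV-LAT"),
                              bcls = c(1000, 300),
                              orders = 0:2,
                              resolution = 4 / 3,
                              epi_level = 3, torso_level = 3,
                              n_electrodes = 128,
                              snapshot_dt = 2,
                              d_par = NULL, d_perp = NULL,
                              source_cell = 2.5,
                              act_window = 230,
                              ed_window = 5,
                              noise_snr_db = NA,
                              lambda = "shared",
                              seed = 1L,
                              out_dir = NULL) {
  variants <- match.arg(variants, c("control", "thick", "dilated"),
                        several.ok = TRUE)
  bad <- setdiff(sites, ectopic_sites())
  if (length(bad)) stop("unknown sites: ", paste(bad, collapse = ", "))
  if (!all(orders %in% 0:2)) stop("orders must be within 0:2")
  if (any(bcls <= 0)) stop("bcls must be positive")
  structure(list(variants = variants, sites = sites, bcls = bcls,
                 orders = orders, resolution = resolution,
                 epi_level = epi_level, torso_level = torso_level,
                 n_electrodes = n_electrodes, snapshot_dt = snapshot_dt,
                 d_par = d_par, d_perp = d_perp,
                 source_cell = source_cell, act_window = act_window,
                 ed_window = ed_window, noise_snr_db = noise_snr_db,
                 lambda = lambda, seed = as.integer(seed), out_dir = out_dir),
            class = "ecgi_experiment_config")
}

#' Build the shared study context
#'
#' Constructs the control geometry, torso, electrode layout, forward system,
#' control epicardial envelope and the Barr transfer matrix that every
#' experiment reuses (the inverse problem is always solved on the control
#' anatomy).
#'
#' @param config An `ecgi_experiment_config`.
#' @return An `ecgi_study_context` (list).
#' @export
build_study_context <- function(config) {
  ctrl_par <- geometry_params(resolution = config$resolution)
  grid <- build_labeled_geometry(ctrl_par)
  torso <- build_torso(level = config$torso_level,
                       n_electrodes = config$n_electrodes,
                       heart_pose = c(0, 30, 40), seed = config$seed)
  system <- assemble_bem(torso)
  # the envelope stands 2 mm off the tissue so that evaluation vertices stay
  # clear of the near field of the aggregated volumetric sources
  epi <- extract_epicardial_surface(grid, level = config$epi_level, pad = 2)
  epi_t <- place_in_torso(torso, epi)
  transfer <- build_transfer_matrix(epi_t, torso$outer)
  Ze <- transfer_at_electrodes(transfer, torso$electrodes)
  structure(list(config = config, control_grid = grid, torso = torso,
                 system = system, epi = epi_t, transfer = transfer,
                 Ze = Ze, cache = new.env(parent = emptyenv())),
            class = "ecgi_study_context")
}

#' @noRd
config_diffusion <- function(cfg) {
  if (is.null(cfg$d_par) || is.null(cfg$d_perp))
    return(cv_matched_diffusion(cfg$resolution))
  list(d_par = cfg$d_par, d_perp = cfg$d_perp)
}

# number of paced beats needed to expose rate effects at a given BCL:
# slow rates (>= 750 ms) reach a fully repolarized state after one beat
#' @noRd
beats_for_bcl <- function(bcl) if (bcl >= 750) 1L else 2L

# simulate one ectopic case and compute forward + true epicardial data
#' @noRd
run_forward_case <- function(ctx, grid, site, bcl = 1000, short_ap = FALSE,
                             n_beats = beats_for_bcl(bcl)) {
  cfg <- ctx$config
  # control-geometry cases are memoized so the rate and short-AP studies can
  # share simulations with the geometry study
  key <- NULL
  if (!is.null(ctx$cache) && identical(grid$params, ctx$control_grid$params)) {
    key <- sprintf("control|%s|%g|%d|%d", site, bcl, as.integer(short_ap),
                   n_beats)
    if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  }
  base <- ectopic_protocol(grid, site, window = cfg$act_window)
  sched <- pacing_schedule(base, bcl, n_beats)
  window_start <- (n_beats - 1) * bcl
  t_end <- window_start + cfg$act_window
  sched$window <- t_end
  dcoef <- config_diffusion(cfg)
  diff_field <- assemble_diffusion(grid$fiber, dcoef$d_par, dcoef$d_perp)
  snaps <- seq(window_start + cfg$snapshot_dt, t_end, by = cfg$snapshot_dt)
  rec <- run_tissue(grid, diff_field, sched,
                    opts = solver_options(local_adaptive = TRUE),
                    t_end = t_end,
                    short_ap = short_ap, window_start = window_start,
                    stop_margin = 20, snapshot_times = snaps)
  src <- compute_sources(rec, diff_field, grid)
  src <- aggregate_sources(src, cfg$source_cell)
  bsp <- compute_bsp(src, ctx$system)
  if (is.finite(cfg$noise_snr_db %||% NA))
    bsp <- add_noise(bsp, cfg$noise_snr_db, seed = cfg$seed)
  phi_true <- forward_potential_at(ctx$system, bsp$phi_surface,
                                   ctx$epi$vertices, src)
  act_true <- activation_map(phi_true, rec$times, mode = "negative")
  out <- list(site = site, bcl = bcl, short_ap = short_ap,
              times = rec$times, act_tissue = rec$act_time,
              bsp = bsp, phi_true = phi_true, act_true = act_true)
  if (!is.null(key)) ctx$cache[[key]] <- out
  out
}

# reconstruct a forward case with one Tikhonov order and compare against a
# reference case (usually itself; the control case for geometry mismatch)
#' @noRd
reconstruct_and_score <- function(ctx, fwd, order, ref = fwd) {
  cfg <- ctx$config
  nt <- min(ncol(fwd$bsp$potentials), ncol(ref$phi_true))
  sol <- reconstruct_timeseries(ctx$Ze, fwd$bsp$potentials[, seq_len(nt), drop = FALSE],
                                order, ctx$epi, lambda = cfg$lambda)
  sm <- snapshot_metrics(sol$X, ref$phi_true[, seq_len(nt), drop = FALSE],
                         fwd$times[seq_len(nt)])
  act_rec <- activation_map(sol$X, fwd$times[seq_len(nt)], mode = "negative")
  ed <- focus_localization_ed(act_rec, ref$act_true, ctx$epi$vertices,
                              window = cfg$ed_window)
  list(solution = sol, metrics = sm, ed = ed, act_rec = act_rec)
}

#' @noRd
summarize_case <- function(sm) {
  c(rms = mean(sm$rms, na.rm = TRUE), rms_sd = stats::sd(sm$rms, na.rm = TRUE),
    rrmse = mean(sm$rrmse, na.rm = TRUE), rrmse_sd = stats::sd(sm$rrmse, na.rm = TRUE),
    pcc = mean(sm$pcc, na.rm = TRUE), pcc_sd = stats::sd(sm$pcc, na.rm = TRUE))
}

#' Geometry-mismatch experiment
#'
#' Simulates ectopic activation on each geometry variant, solves the forward
#' problem on that variant, and reconstructs with the control-geometry
#' transfer matrix only (an out-of-date anatomical scan). Errors are
#' computed against the control-geometry activation of the matched ectopic
#' site, so geometry differences need not be mapped between meshes.
#'
#' @param config An `ecgi_experiment_config`.
#' @param ctx Optional prebuilt [build_study_context()].
#' @return An `ecgi_report` list: `snapshots`, `summary`, `ed`, `manifest`.
#' @export
run_geometry_experiment <- function(config = experiment_config(), ctx = NULL) {
  ctx <- ctx %||% build_study_context(config)
  snapshots <- list()
  summary <- list()
  eds <- list()
  ref_cases <- list()
  for (variant in config$variants) {
    par_v <- apply_variant(geometry_params(resolution = config$resolution),
                           variant)
    grid_v <- if (variant == "control") ctx$control_grid else
      build_labeled_geometry(par_v)
    for (site in config$sites) {
      fwd <- run_forward_case(ctx, grid_v, site)
      if (variant == "control") ref_cases[[site]] <- fwd
      ref <- ref_cases[[site]]
      if (is.null(ref)) stop("control reference case missing for site ", site)
      for (ord in config$orders) {
        sc <- reconstruct_and_score(ctx, fwd, ord, ref = ref)
        key <- sprintf("%s|%s|%d", variant, site, ord)
        snapshots[[key]] <- cbind(variant = variant, site = site, order = ord,
                                  sc$metrics)
        summary[[key]] <- data.frame(variant = variant, site = site,
                                     order = ord, t(summarize_case(sc$metrics)))
        eds[[key]] <- data.frame(variant = variant, site = site, order = ord,
                                 ed = sc$ed)
      }
    }
  }
  finish_report(config, snapshots, summary, eds, "geometry")
}

#' Heart-rate experiment
#'
#' Ectopic pacing of the control geometry at several basic cycle lengths;
#' metrics are computed on the final paced beat against the same case's own
#' forward solution. At BCL 150 ms the short-AP cell variant sustains 1:1
#' capture.
#'
#' @param config An `ecgi_experiment_config`.
#' @param ctx Optional prebuilt context.
#' @return An `ecgi_report`.
#' @export
run_rate_experiment <- function(config = experiment_config(), ctx = NULL) {
  ctx <- ctx %||% build_study_context(config)
  snapshots <- list(); summary <- list(); eds <- list()
  for (bcl in config$bcls) {
    short <- bcl <= 150
    for (site in config$sites) {
      fwd <- run_forward_case(ctx, ctx$control_grid, site, bcl = bcl,
                              short_ap = short)
      for (ord in config$orders) {
        sc <- reconstruct_and_score(ctx, fwd, ord)
        key <- sprintf("%g|%s|%d", bcl, site, ord)
        snapshots[[key]] <- cbind(bcl = bcl, site = site, order = ord,
                                  sc$metrics)
        summary[[key]] <- data.frame(bcl = bcl, site = site, order = ord,
                                     t(summarize_case(sc$metrics)))
        eds[[key]] <- data.frame(bcl = bcl, site = site, order = ord,
                                 ed = sc$ed)
      }
    }
  }
  finish_report(config, snapshots, summary, eds, "rate")
}

#' Short-action-potential mechanism experiment
#'
#' 2 x 2 design (control vs short-AP cells, slow vs rapid pacing) probing
#' whether rate-dependent reconstruction errors stem from the shortened
#' excitation wavelength or from tissue still active from the previous
#' beat: the short-AP model at rapid pacing removes the residual activity
#' while keeping the short wavelength.
#'
#' @param config An `ecgi_experiment_config` (`bcls` should contain the slow
#'   and rapid rates; defaults to 1000 and 300 ms).
#' @param site Ectopic site used for the comparison.
#' @param ctx Optional prebuilt context.
#' @return An `ecgi_report` with a `cell_model` column.
#' @export
run_shortap_experiment <- function(config = experiment_config(), site = "LV-LAT",
                                   ctx = NULL) {
  ctx <- ctx %||% build_study_context(config)
  snapshots <- list(); summary <- list(); eds <- list()
  for (cellmod in c("control", "short")) {
    for (bcl in config$bcls) {
      fwd <- run_forward_case(ctx, ctx$control_grid, site, bcl = bcl,
                              short_ap = cellmod == "short")
      for (ord in config$orders) {
        sc <- reconstruct_and_score(ctx, fwd, ord)
        key <- sprintf("%s|%g|%d", cellmod, bcl, ord)
        snapshots[[key]] <- cbind(cell_model = cellmod, bcl = bcl,
                                  site = site, order = ord, sc$metrics)
        summary[[key]] <- data.frame(cell_model = cellmod, bcl = bcl,
                                     site = site, order = ord,
                                     t(summarize_case(sc$metrics)))
        eds[[key]] <- data.frame(cell_model = cellmod, bcl = bcl, site = site,
                                 order = ord, ed = sc$ed)
      }
    }
  }
  finish_report(config, snapshots, summary, eds, "shortap")
}

#' @noRd
finish_report <- function(config, snapshots, summary, eds, study) {
  rep <- structure(list(study = study,
                        snapshots = do.call(rbind, unname(snapshots)),
                        summary = do.call(rbind, unname(summary)),
                        ed = do.call(rbind, unname(eds)),
                        manifest = report_manifest(config, study)),
                   class = "ecgi_report")
  if (!is.null(config$out_dir)) write_report(rep, config$out_dir)
  rep
}

#' @noRd
report_manifest <- function(config, study) {
  list(study = study,
       config_hash = object_hash(unclass(config)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("ecgisim")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Aggregate localization error across cases
#'
#' Both the mean and the median are reported, since both aggregations appear
#' in the ECGi validation literature.
#'
#' @param report An `ecgi_report`.
#' @param by Grouping columns of the `ed` table (default: condition columns,
#'   i.e. everything except `site` and `ed`).
#' @return data.frame with `ed_mean` and `ed_median` per group.
#' @export
aggregate_ed <- function(report, by = NULL) {
  ed <- report$ed
  if (is.null(by)) by <- setdiff(names(ed), c("site", "ed"))
  out <- stats::aggregate(ed["ed"], ed[by], mean)
  names(out)[names(out) == "ed"] <- "ed_mean"
  out$ed_median <- stats::aggregate(ed["ed"], ed[by], stats::median)$ed
  out
}

#' Write an experiment report to CSV/JSON files
#' @param report An `ecgi_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$snapshots,
                   file.path(dir, paste0(report$study, "_snapshots.csv")),
                   row.names = FALSE)
  utils::write.csv(report$summary,
                   file.path(dir, paste0(report$study, "_summary.csv")),
                   row.names = FALSE)
  utils::write.csv(report$ed, file.path(dir, paste0(report$study, "_ed.csv")),
                   row.names = FALSE)
  jsonlite::write_json(report$manifest,
                       file.path(dir, paste0(report$study, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.ecgi_report <- function(x, ...) {
  cat(sprintf("ecgi_report (%s study): %d cases\n", x$study, nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Total ventricular activation time of a simulation
#'
#' Span from first to last node activation (from the per-voxel maximum
#' dV/dt times of the recordings).
#'
#' @param recordings An `ecgi_recordings`.
#' @return Time span in ms.
#' @export
total_activation_time <- function(recordings) {
  act <- recordings$act_time[recordings$activated]
  if (length(act) == 0) stop("no activated tissue")
  max(act) - min(act)
}

#' Sinus activation of the control geometry
#'
#' Builds the control geometry at the requested resolution, applies the
#' calibrated 28-patch endocardial sinus schedule and runs the monodomain
#' simulation; used to verify the ~65 ms total activation time of normal
#' sinus rhythm.
#'
#' @param resolution Grid resolution, mm (1.0 default).
#' @param d_par,d_perp Diffusion coefficients, mm^2/ms; NULL selects the
#'   conduction-velocity-matched values for the resolution.
#' @param grid Optional prebuilt labeled control grid.
#' @return List with `recordings`, `schedule`, `grid` and
#'   `total_activation` (ms).
#' @export
run_sinus_activation <- function(resolution = 1.0, d_par = NULL,
                                 d_perp = NULL, grid = NULL) {
  if (is.null(grid))
    grid <- build_labeled_geometry(geometry_params(resolution = resolution))
  sched <- sinus_protocol(grid)
  if (is.null(d_par) || is.null(d_perp)) {
    dc <- cv_matched_diffusion(if (is.null(grid$params)) resolution else
      grid$params$resolution)
    d_par <- dc$d_par; d_perp <- dc$d_perp
  }
  diff_field <- assemble_diffusion(grid$fiber, d_par, d_perp)
  rec <- run_tissue(grid, diff_field, sched, t_end = sched$window,
                    stop_margin = 10, record = 1L,
                    snapshot_times = sched$window)
  list(recordings = rec, schedule = sched, grid = grid,
       total_activation = total_activation_time(rec))
}
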