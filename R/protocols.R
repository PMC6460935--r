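#' Stimulus schedules
#'
#' A schedule is a list of localized stimulus events: spherical regions of a
#' given extent (diameter, mm) receiving a transmembrane current of given
#' amplitude (pA/pF) for a given duration (ms) from a given onset (ms).
#'
#' @param center n x 3 matrix of event centres, mm.
#' @param extent Event diameters, mm.
#' @param onset Event onsets, ms.
#' @param duration Event durations, ms (default 1 ms).
#' @param amplitude Event amplitudes, pA/pF (default -52, depolarizing).
#' @param window Total schedule window, ms.
#' @return An `ecgi_schedule` object.
#' @export
stimulus_schedule <- function(center, extent, onset, duration = 1,
                              amplitude = -52, window = NULL) {
  center <- matrix(as.numeric(center), ncol = 3)
  n <- nrow(center)
  extent <- rep_len(as.numeric(extent), n)
  onset <- rep_len(as.numeric(onset), n)
  duration <- rep_len(as.numeric(duration), n)
  amplitude <- rep_len(as.numeric(amplitude), n)
  if (any(onset < 0)) stop("onsets must be >= 0")
  if (any(duration <= 0)) stop("durations must be > 0")
  if (any(extent <= 0)) stop("extents must be > 0")
  if (is.null(window)) window <- max(onset + duration) + 200
  structure(list(center = center, extent = extent, onset = onset,
                 duration = duration, amplitude = amplitude,
                 window = as.numeric(window)),
            class = "ecgi_schedule")
}

#' @export
print.ecgi_schedule <- function(x, ...) {
  cat(sprintf("ecgi_schedule: %d events over %.1f ms (window %.1f ms)\n",
              nrow(x$center), max(x$onset), x$window))
  invisible(x)
}

#' Sinus-rhythm endocardial stimulation protocol
#'
#' Generates 28 localized endocardial patches (diameters 9-12 mm) fired in
#' quick succession: a small septal block initiates the wavefront, after
#' which patches spread from apex to base along both endocardial walls over
#' a linear onset ramp. The ramp default is calibrated so that the total
#' activation time of the control geometry is ~65 ms.
#'
#' Patch centres are chosen deterministically by farthest-point sampling of
#' the endocardial-surface voxels, so the protocol is reproducible and maps
#' consistently across resolutions.
#'
#' @param grid A labeled `ecgi_grid` (needs `depth` and `f_ab`).
#' @param n_patches Number of patches.
#' @param ramp Onset ramp duration, ms.
#' @param n_septal Number of initiating septal patches.
#' @param diameters Range of patch diameters, mm.
#' @return An `ecgi_schedule`.
#' @export
sinus_protocol <- function(grid, n_patches = 28, ramp = 30, n_septal = 4,
                           diameters = c(9, 12)) {
  if (is.null(grid$depth) || is.null(grid$f_ab))
    stop("grid needs depth and f_ab fields")
  endo <- which(grid$depth < 0.15)
  if (length(endo) < n_patches)
    stop("geometry lacks an endocardial surface to place patches on")
  xyz <- grid_coords(grid)

  sep_endo <- endo[grid$chamber[endo] == 3L]
  if (length(sep_endo) == 0) sep_endo <- endo
  # initiating septal patches: the most apical septal endocardium
  ord <- order(-grid$f_ab[sep_endo])
  first <- sep_endo[ord[1]]

  # farthest-point sampling over all endocardial voxels, seeded at the
  # septal initiation site (deterministic)
  pts <- xyz[endo, , drop = FALSE]
  picked <- integer(n_patches)
  picked[1] <- match(first, endo)
  mind <- rowSums(sweep(pts, 2, pts[picked[1], ])^2)
  for (q in 2:n_patches) {
    picked[q] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[picked[q], ])^2))
  }
  sel <- endo[picked]

  # order: septal block first (by apico-basal position), then remaining
  # patches from apex (f_ab = 1) to base (f_ab = 0)
  is_sep <- grid$chamber[sel] == 3L
  sep_sel <- sel[is_sep]
  sep_sel <- sep_sel[order(-grid$f_ab[sep_sel])]
  sep_sel <- utils::head(sep_sel, n_septal)
  rest <- setdiff(sel, sep_sel)
  rest <- rest[order(-grid$f_ab[rest])]
  ordered <- c(sep_sel, rest)

  n <- length(ordered)
  onsets <- numeric(n)
  nsep <- length(sep_sel)
  if (nsep > 0) onsets[seq_len(nsep)] <- seq(0, length.out = nsep, by = 1)
  onsets[(nsep + 1):n] <- seq(2, ramp, length.out = n - nsep)
  diam <- rep(seq(diameters[1], diameters[2], length.out = 4), length.out = n)

  out <- stimulus_schedule(center = xyz[ordered, , drop = FALSE],
                    extent = diam, onset = onsets,
                    window = ramp + 150)
  attr(out, "n_septal") <- nsep
  out
}

# anchor positions of the ectopic sites in geometry-relative coordinates,
# computed from the geometry parameters so the sites are homologous across
# the control, thick-walled and dilated variants
#' @noRd
ectopic_anchor <- function(params, site) {
  le <- params$lv_semi; re <- params$rv_semi; rc <- params$rv_center
  switch(site,
    "RV-LAT" = c(rc[1] + re[1] - params$rv_wall / 2, rc[2], rc[3]),
    "SEP" = c(le[1] - params$lv_wall / 2, 0, 0),
    "LV-LAT" = c(-(le[1] - params$lv_wall / 2), 0, 0),
    "LV-Apex" = c(0, 0, -(le[3] - params$lv_wall / 2)),
    stop(sprintf("unknown ectopic site '%s'; valid sites: %s", site,
                 paste(ectopic_sites(), collapse = ", ")), call. = FALSE))
}

#' Names of the prescribed ectopic stimulus sites
#' @return Character vector of site names.
#' @export
ectopic_sites <- function() c("RV-LAT", "SEP", "LV-LAT", "LV-Apex")

#' Ectopic focal stimulation protocol
#'
#' A single -52 pA/pF, 1 ms stimulus applied over a 5 mm spherical region at
#' one of four prescribed sites: the right ventricular lateral wall
#' (RV-LAT), the intra-ventricular septum (SEP), the left ventricular
#' lateral wall (LV-LAT) or the left ventricular apex (LV-Apex). Anchors are
#' defined relative to the geometry parameters (mid-wall at the equatorial
#' plane for the lateral/septal sites, mid-wall on the long axis for the
#' apex), so the same site maps to homologous positions on all variants.
#'
#' @param grid An `ecgi_grid`.
#' @param site Site name (see [ectopic_sites()]).
#' @param extent Stimulated diameter, mm.
#' @param window Analysis window after the stimulus, ms.
#' @return An `ecgi_schedule`.
#' @export
ectopic_protocol <- function(grid, site, extent = 5, window = 250) {
  stopifnot(inherits(grid, "ecgi_grid"))
  anchor <- ectopic_anchor(grid$params, site)
  stimulus_schedule(center = matrix(anchor, ncol = 3), extent = extent,
                    onset = 0, window = window)
}

#' Repeat a schedule at a fixed pacing rate
#'
#' Replicates the base schedule at multiples of the basic cycle length
#' (BCL); 60000 / BCL gives the rate in beats per minute.
#'
#' @param base An `ecgi_schedule`.
#' @param bcl Basic cycle length, ms.
#' @param n_beats Number of beats (>= 1).
#' @return An `ecgi_schedule` covering all beats.
#' @export
pacing_schedule <- function(base, bcl, n_beats) {
  stopifnot(inherits(base, "ecgi_schedule"))
  if (!is.numeric(bcl) || length(bcl) != 1 || bcl <= 0) stop("bcl must be > 0")
  if (n_beats < 1 || n_beats != round(n_beats))
    stop("n_beats must be a positive integer")
  n_beats <- as.integer(n_beats)
  if (n_beats == 1L) return(base)
  k <- rep(seq_len(n_beats) - 1L, each = nrow(base$center))
  stimulus_schedule(center = base$center[rep(seq_len(nrow(base$center)), n_beats), , drop = FALSE],
                    extent = rep(base$extent, n_beats),
                    onset = rep(base$onset, n_beats) + k * bcl,
                    duration = rep(base$duration, n_beats),
                    amplitude = rep(base$amplitude, n_beats),
                    window = (n_beats - 1) * bcl + base$window)
}
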