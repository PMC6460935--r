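#' Activation map from potential time courses
#'
#' Per node, the activation time is the time of the extremal temporal
#' derivative within the analysis window: maximum negative slope (-dV/dt)
#' for extracellular/epicardial potentials (the default), or maximum
#' positive slope for transmembrane upstrokes. Nodes with a flat trace are
#' marked undefined (NA).
#'
#' @param potentials Nodes x times matrix.
#' @param times Snapshot times, ms.
#' @param mode `"negative"` (extracellular convention) or `"positive"`
#'   (transmembrane upstroke).
#' @param flat_tol Minimum trace range for a defined activation.
#' @return An `ecgi_activation_map`: numeric vector of activation times (ms)
#'   with NA for undefined nodes.
#' @export
activation_map <- function(potentials, times, mode = c("negative", "positive"),
                           flat_tol = 1e-9) {
  mode <- match.arg(mode)
  potentials <- as.matrix(potentials)
  if (ncol(potentials) != length(times)) stop("times must match snapshot columns")
  if (length(times) < 3) stop("need at least 3 time samples")
  dv <- (potentials[, -1, drop = FALSE] - potentials[, -ncol(potentials), drop = FALSE]) /
    rep(diff(times), each = nrow(potentials))
  if (mode == "negative") dv <- -dv
  tm <- (times[-1] + times[-length(times)]) / 2
  idx <- max.col(dv, ties.method = "first")
  out <- tm[idx]
  rng <- apply(potentials, 1, function(r) diff(range(r)))
  out[rng < flat_tol] <- NA_real_
  structure(out, class = "ecgi_activation_map")
}

#' Root-mean-square amplitude
#' @param phi Numeric vector (potentials over mesh elements).
#' @return sqrt(sum(phi^2) / N).
#' @export
rms <- function(phi) {
  if (length(phi) == 0) stop("empty input")
  sqrt(sum(phi^2) / length(phi))
}

#' Relative root-mean-square error between two fields
#'
#' rRMSe = ||phi' - phi|| / ||phi'|| with phi' the reference (original
#' simulated) field.
#'
#' @param phi Reconstructed/compared field.
#' @param phi_ref Reference field.
#' @return Non-negative scalar.
#' @export
rrmse <- function(phi, phi_ref) {
  if (length(phi) != length(phi_ref)) stop("length mismatch")
  denom <- sqrt(sum(phi_ref^2))
  if (denom == 0) stop("reference field is identically zero")
  sqrt(sum((phi_ref - phi)^2)) / denom
}

#' Pearson correlation coefficient between two fields
#' @param phi,phi_ref Numeric vectors.
#' @return Correlation in [-1, 1].
#' @export
pcc <- function(phi, phi_ref) {
  if (length(phi) != length(phi_ref)) stop("length mismatch")
  if (stats::sd(phi) == 0 || stats::sd(phi_ref) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(phi, phi_ref)
}

#' Euclidean distance between earliest-activation centroids
#'
#' Localization error of a focal source: the Euclidean distance between the
#' centroids of the earliest-activated node sets (nodes within `window` ms
#' of each map's minimum activation time) of two activation maps.
#'
#' @param map,map_ref Activation maps (numeric vectors, NA = undefined).
#' @param positions,positions_ref Node positions (n x 3, mm).
#' @param window Earliest-activation window, ms.
#' @return Distance in mm.
#' @export
focus_localization_ed <- function(map, map_ref, positions,
                                  positions_ref = positions, window = 5) {
  centroid <- function(m, pos) {
    ok <- !is.na(m)
    if (!any(ok)) stop("activation map has no defined nodes")
    t0 <- min(m[ok])
    sel <- ok & m <= t0 + window
    colMeans(pos[sel, , drop = FALSE])
  }
  c1 <- centroid(as.numeric(map), as.matrix(positions))
  c2 <- centroid(as.numeric(map_ref), as.matrix(positions_ref))
  sqrt(sum((c1 - c2)^2))
}

#' Add white noise to a BSP series at a given signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise with standard deviation set so that the
#' power ratio of the clean series to the noise equals the requested SNR in
#' dB. Reproducible for a fixed seed; `snr_db = Inf` returns the input.
#'
#' @param bsp Electrodes x times matrix (or `ecgi_bsp`).
#' @param snr_db Signal-to-noise ratio, dB.
#' @param seed RNG seed.
#' @return Noisy matrix (or `ecgi_bsp`) of the same shape.
#' @export
add_noise <- function(bsp, snr_db, seed = 1L) {
  obj <- NULL
  if (inherits(bsp, "ecgi_bsp")) { obj <- bsp; bsp <- bsp$potentials }
  if (!is.finite(snr_db)) {
    if (is.null(obj)) return(bsp)
    return(obj)
  }
  p_sig <- mean(bsp^2)
  if (p_sig <= 0) stop("cannot scale noise to a zero-power signal")
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  set.seed(seed)
  noisy <- bsp + matrix(rnorm(length(bsp), sd = sd_n), nrow(bsp))
  if (is.null(obj)) return(noisy)
  obj$potentials <- noisy
  obj
}

#' Per-snapshot comparison metrics between two potential series
#'
#' @param X Reconstructed nodes x times matrix.
#' @param X_ref Reference nodes x times matrix.
#' @param times Snapshot times.
#' @return data.frame with columns `time`, `rms`, `rms_ref`, `rrmse`, `pcc`.
#' @export
snapshot_metrics <- function(X, X_ref, times) {
  stopifnot(ncol(X) == ncol(X_ref), ncol(X) == length(times))
  out <- data.frame(time = times, rms = NA_real_, rms_ref = NA_real_,
                    rrmse = NA_real_, pcc = NA_real_)
  for (j in seq_len(ncol(X))) {
    out$rms[j] <- rms(X[, j])
    out$rms_ref[j] <- rms(X_ref[, j])
    if (sum(X_ref[, j]^2) > 0) out$rrmse[j] <- rrmse(X[, j], X_ref[, j])
    if (stats::sd(X[, j]) > 0 && stats::sd(X_ref[, j]) > 0)
      out$pcc[j] <- pcc(X[, j], X_ref[, j])
  }
  out
}
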