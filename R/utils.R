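# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
normalize_rows <- function(m, tol = 1e-12) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < tol] <- 1
  m / nrm
}

#' @noRd
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# shift a 3D array by one voxel along an axis, padding with NA
#' @noRd
shift_array <- function(a, axis, by) {
  d <- dim(a)
  out <- array(NA_real_, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# deterministic 64-bit-ish FNV hash of a serialized R object, as hex
#' @noRd
object_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 17
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 1073741789
  sprintf("%08x", as.integer(h))
}

#' @noRd
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
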