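#' Parameters of the idealized bi-ventricle geometry
#'
#' The left ventricle (LV) is a thick-walled truncated ellipsoid centred at
#' the origin; the right ventricle (RV) is a thin-walled truncated ellipsoid
#' offset towards +x whose wall attaches to the LV epicardium, forming the
#' septum. Both are cut by the basal plane `z = z_base`; `z` increases from
#' apex to base. Endocardial semi-axes are derived as epicardial semi-axes
#' minus the wall thickness, so the mid-free-wall thickness measured along
#' the short axis equals the requested value exactly.
#'
#' The default semi-axes give a control geometry with an LV wall thickness of
#' 12 mm, an RV wall thickness of 4 mm, and an LV wall volume of 196.6 mL,
#' inside the normal human ranges (12-15 mm, 3-5 mm, ~150-210 mL).
#'
#' @param lv_semi Epicardial LV semi-axes (x, y, z), mm.
#' @param rv_semi Epicardial RV semi-axes (x, y, z), mm.
#' @param rv_center Centre of the RV ellipsoids, mm.
#' @param lv_wall LV wall thickness, mm.
#' @param rv_wall RV wall thickness, mm (0 drops the RV entirely).
#' @param z_base Height of the basal truncation plane, mm.
#' @param smooth_width Width of fiber smoothing at the RV-septum junction, mm.
#' @param resolution Isotropic voxel edge length, mm.
#' @return An object of class `ecgi_geometry_params`.
#' @export
geometry_params <- function(lv_semi = c(42, 42, 68),
                            rv_semi = c(54, 38, 60),
                            rv_center = c(12, 0, 0),
                            lv_wall = 12, rv_wall = 4,
                            z_base = 19,
                            smooth_width = 2,
                            resolution = 0.5) {
  stopifnot(length(lv_semi) == 3, length(rv_semi) == 3, length(rv_center) == 3)
  stopifnot_scalar_pos(lv_wall, "lv_wall")
  stopifnot_scalar_pos(z_base, "z_base")
  stopifnot_scalar_pos(resolution, "resolution")
  if (any(lv_semi <= 0) || any(rv_semi <= 0))
    stop("semi-axes must be positive")
  if (rv_wall < 0) stop("rv_wall must be >= 0")
  if (lv_wall >= min(lv_semi)) stop("LV wall thickness must be smaller than the LV semi-axes")
  if (rv_wall >= min(rv_semi)) stop("RV wall thickness must be smaller than the RV semi-axes")
  structure(list(lv_semi = as.numeric(lv_semi), rv_semi = as.numeric(rv_semi),
                 rv_center = as.numeric(rv_center),
                 lv_wall = as.numeric(lv_wall), rv_wall = as.numeric(rv_wall),
                 z_base = as.numeric(z_base),
                 smooth_width = as.numeric(smooth_width),
                 resolution = as.numeric(resolution)),
            class = "ecgi_geometry_params")
}

#' Derive a geometry variant from control parameters
#'
#' `"thick"` increases both wall thicknesses by 50% (hypertrophy);
#' `"dilated"` increases the short-axis diameter (the anterior-posterior
#' epicardial semi-axis of both ventricles) by 50% while keeping the wall
#' thicknesses unchanged, enlarging the LV wall volume from 196.6 to
#' ~263 mL; `"control"` returns the parameters untouched.
#'
#' @param params An `ecgi_geometry_params` object.
#' @param variant One of `"control"`, `"thick"`, `"dilated"`.
#' @return Modified `ecgi_geometry_params`.
#' @export
apply_variant <- function(params, variant = c("control", "thick", "dilated")) {
  stopifnot(inherits(params, "ecgi_geometry_params"))
  variant <- match.arg(variant)
  if (variant == "thick") {
    params$lv_wall <- params$lv_wall * 1.5
    params$rv_wall <- params$rv_wall * 1.5
  } else if (variant == "dilated") {
    params$lv_semi[2] <- params$lv_semi[2] * 1.5
    params$rv_semi[2] <- params$rv_semi[2] * 1.5
    params$rv_center[2] <- params$rv_center[2] * 1.5
  }
  params
}

#' Voxelize the bi-ventricle geometry
#'
#' Builds a regular voxel grid at the requested resolution, labels tissue
#' voxels by chamber (LV free wall, RV free wall, septum), and records the
#' LV and RV cavity masks used downstream for transmural-depth computation
#' and epicardial-envelope extraction.
#'
#' @param params An `ecgi_geometry_params` object.
#' @return An object of class `ecgi_grid` with elements `dims`, `dx`,
#'   `origin` (physical position of the first voxel centre), `tissue_idx`
#'   (linear indices of tissue voxels), `mask` and `cavity` (full logical
#'   arrays), `chamber` (per-tissue-voxel labels 1 = LV, 2 = RV, 3 = septum)
#'   and the originating `params`.
#' @export
build_biventricle <- function(params) {
  stopifnot(inherits(params, "ecgi_geometry_params"))
  dx <- params$resolution
  if (params$rv_wall > 0 && params$rv_wall / dx < 3)
    stop(sprintf(paste("resolution %.3g mm is too coarse to resolve the RV wall",
                       "(%.3g mm; fewer than 3 voxels across)"), dx, params$rv_wall))
  if (params$lv_wall / dx < 3)
    stop("resolution too coarse to resolve the LV wall (fewer than 3 voxels across)")

  le <- params$lv_semi
  ln <- le - params$lv_wall
  re <- params$rv_semi
  rn <- re - params$rv_wall
  rc <- params$rv_center
  z0 <- params$z_base
  pad <- 2 * dx
  has_rv <- params$rv_wall > 0

  xmin <- min(-le[1], if (has_rv) rc[1] - re[1] else Inf) - pad
  xmax <- max(le[1], if (has_rv) rc[1] + re[1] else -Inf) + pad
  ymin <- min(-le[2], if (has_rv) rc[2] - re[2] else Inf) - pad
  ymax <- max(le[2], if (has_rv) rc[2] + re[2] else -Inf) + pad
  zmin <- -le[3] - pad
  zmax <- z0 + pad

  # voxel centres on a grid aligned so that +/- dx/2 straddles the origin
  gridax <- function(lo, hi) {
    i0 <- floor(lo / dx - 0.5)
    i1 <- ceiling(hi / dx + 0.5)
    (seq.int(i0, i1) + 0.5) * dx
  }
  xs <- gridax(xmin, xmax); ys <- gridax(ymin, ymax); zs <- gridax(zmin, zmax)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)

  # ellipsoid membership via separable quadratic forms
  quad3 <- function(ctr, semi) {
    qx <- (xs - ctr[1])^2 / semi[1]^2
    qy <- (ys - ctr[2])^2 / semi[2]^2
    qz <- (zs - ctr[3])^2 / semi[3]^2
    outer(outer(qx, qy, "+"), qz, "+")
  }
  below <- outer(outer(rep(TRUE, nx), rep(TRUE, ny), "&"),
                 zs <= z0 + 1e-9, "&")

  in_lv_epi <- (quad3(c(0, 0, 0), le) <= 1) & below
  in_lv_endo <- (quad3(c(0, 0, 0), ln) <= 1) & below
  lv_wall <- in_lv_epi & !in_lv_endo
  lv_cav <- in_lv_endo

  if (has_rv) {
    in_rv_epi <- (quad3(rc, re) <= 1) & below
    in_rv_endo <- (quad3(rc, rn) <= 1) & below
    rv_wall <- in_rv_epi & !in_rv_endo & !in_lv_epi
    rv_cav <- in_rv_endo & !in_lv_epi
    xpos <- outer(outer(xs > 0, rep(TRUE, ny), "&"), rep(TRUE, nz), "&")
    septum <- lv_wall & in_rv_endo & xpos
    rm(in_rv_epi, in_rv_endo, xpos)
  } else {
    rv_wall <- array(FALSE, dim = c(nx, ny, nz))
    rv_cav <- rv_wall
    septum <- rv_wall
  }
  mask <- lv_wall | rv_wall
  cavity <- (lv_cav | rv_cav) & !mask

  tissue_idx <- which(mask)
  chamber <- integer(length(tissue_idx))
  chamber[] <- 1L
  chamber[rv_wall[tissue_idx]] <- 2L
  chamber[septum[tissue_idx]] <- 3L

  structure(list(dims = c(nx, ny, nz), dx = dx,
                 origin = c(xs[1], ys[1], zs[1]),
                 tissue_idx = tissue_idx,
                 mask = mask, cavity = cavity,
                 chamber = chamber,
                 params = params),
            class = "ecgi_grid")
}

#' @export
print.ecgi_grid <- function(x, ...) {
  cat(sprintf("ecgi_grid: %d x %d x %d voxels at %.3g mm, %d tissue voxels\n",
              x$dims[1], x$dims[2], x$dims[3], x$dx, length(x$tissue_idx)))
  cat(sprintf("  chambers: LV %d, RV %d, septum %d\n",
              sum(x$chamber == 1L), sum(x$chamber == 2L), sum(x$chamber == 3L)))
  if (!is.null(x$depth)) cat("  transmural depth: computed\n")
  if (!is.null(x$celltype)) cat("  cell types: assigned\n")
  if (!is.null(x$fiber)) cat("  fibers: assigned\n")
  invisible(x)
}

# physical coordinates (mm) of tissue voxels (n x 3)
#' Voxel-centre coordinates of the tissue voxels
#' @param grid An `ecgi_grid`.
#' @param idx Optional linear full-grid indices (defaults to tissue voxels).
#' @return n x 3 matrix of coordinates (mm).
#' @export
grid_coords <- function(grid, idx = grid$tissue_idx) {
  d <- grid$dims
  i <- (idx - 1L) %% d[1]
  j <- ((idx - 1L) %/% d[1]) %% d[2]
  k <- (idx - 1L) %/% (d[1] * d[2])
  cbind(grid$origin[1] + i * grid$dx,
        grid$origin[2] + j * grid$dx,
        grid$origin[3] + k * grid$dx)
}

#' Measure wall thickness by ray casting through the mid free wall
#'
#' Casts a ray along the x axis through the equatorial plane (z = 0) of the
#' ventricles and reports the contiguous tissue span containing the outermost
#' voxel: the LV free wall on the -x side, the RV free wall on the +x side.
#'
#' @param grid An `ecgi_grid`.
#' @param chamber `"lv"` or `"rv"`.
#' @return Thickness in mm.
#' @export
measure_wall_thickness <- function(grid, chamber = c("lv", "rv")) {
  chamber <- match.arg(chamber)
  d <- grid$dims
  j <- which.min(abs(grid$origin[2] + (seq_len(d[2]) - 1) * grid$dx))
  k <- which.min(abs(grid$origin[3] + (seq_len(d[3]) - 1) * grid$dx))
  row <- grid$mask[, j, k]
  if (!any(row)) stop("no tissue found on the equatorial x ray")
  runs <- rle(row)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  tis <- which(runs$values)
  if (chamber == "lv") {
    r <- tis[1]                     # leftmost run: LV free wall
  } else {
    if (sum(runs$values) < 2) stop("no RV free wall on the equatorial x ray")
    r <- tis[length(tis)]           # rightmost run: RV free wall
  }
  runs$lengths[r] * grid$dx
}

#' Chamber wall volumes
#' @param grid An `ecgi_grid`.
#' @return Named vector (mL): `lv` (free wall + septum), `rv`, `total`.
#' @export
wall_volumes <- function(grid) {
  vox_ml <- grid$dx^3 / 1000
  lv <- sum(grid$chamber %in% c(1L, 3L)) * vox_ml
  rv <- sum(grid$chamber == 2L) * vox_ml
  c(lv = lv, rv = rv, total = lv + rv)
}

#' Normalized transmural depth
#'
#' Computes d = dist_endo / (dist_endo + dist_epi) per tissue voxel from
#' Euclidean distance transforms seeded at the cavity (endocardial) and
#' external (epicardial) voxels. d is 0 on the endocardial surface and 1 on
#' the epicardial surface. Voxels exposed only at the basal cut plane are
#' excluded from the epicardial seed set.
#'
#' @param grid An `ecgi_grid`.
#' @return The grid with a `depth` element (per tissue voxel, in [0, 1]).
#' @export
compute_transmural_depth <- function(grid) {
  stopifnot(inherits(grid, "ecgi_grid"))
  d <- grid$dims
  dx <- grid$dx
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * dx
  below <- rep(zs <= grid$params$z_base + 1e-9, each = d[1] * d[2])
  exterior <- !grid$mask & !grid$cavity & array(below, d)

  de2 <- .cpp_edt3d(as.vector(grid$cavity), as.integer(d))
  dp2 <- .cpp_edt3d(as.vector(exterior), as.integer(d))
  de <- pmax(sqrt(de2[grid$tissue_idx]) - 1, 0) * dx
  dp <- pmax(sqrt(dp2[grid$tissue_idx]) - 1, 0) * dx
  tot <- de + dp
  depth <- ifelse(tot > 0, de / tot, NA_real_)
  if (anyNA(depth))
    warning(sprintf("%d tissue voxels unreachable from both surfaces", sum(is.na(depth))))
  grid$depth <- pmin(pmax(depth, 0), 1)
  grid
}

#' Segment tissue into transmural cell types
#'
#' Assigns ENDO / MCELL / EPI labels by transmural-depth bands covering 40%,
#' 30% and 30% of the depth range: ENDO d in [0, 0.4), MCELL [0.4, 0.7),
#' EPI [0.7, 1] (half-open towards the epicardium).
#'
#' @param grid An `ecgi_grid` with computed `depth`.
#' @return The grid with a `celltype` element (0 = ENDO, 1 = MCELL, 2 = EPI).
#' @export
segment_cell_types <- function(grid) {
  if (is.null(grid$depth)) stop("compute_transmural_depth() first")
  ct <- integer(length(grid$depth))
  ct[grid$depth >= 0.4] <- 1L
  ct[grid$depth >= 0.7] <- 2L
  grid$celltype <- ct
  grid
}

#' Parameters of the rule-based fiber model
#'
#' The helix angle is `alpha = R * (1 - 2 d)^n`, rotating from +R at the
#' endocardium (d = 0) through 0 at mid-wall to -R at the epicardium (d = 1).
#' The transverse angle is fixed at 0.
#'
#' @param rotation Transmural rotation R in degrees (default 60, for a total
#'   endo-to-epi rotation of 120 degrees).
#' @param exponent Transmural variation exponent n (1 = linear).
#' @return An object of class `ecgi_fiber_rule`.
#' @export
fiber_rule <- function(rotation = 60, exponent = 1) {
  if (exponent < 1) stop("exponent must be >= 1")
  structure(list(rotation = rotation, exponent = exponent, transverse = 0),
            class = "ecgi_fiber_rule")
}

#' Helix angle as a function of transmural depth
#' @param d Normalized transmural depth in [0, 1].
#' @param rule An `ecgi_fiber_rule`.
#' @return Helix angle in degrees.
#' @export
helix_angle <- function(d, rule = fiber_rule()) {
  u <- 1 - 2 * d
  rule$rotation * sign(u) * abs(u)^rule$exponent
}

#' Apico-basal gradient factor
#'
#' f_AB = (z - z_base) / (z_apex - z_base), linear in z, equal to 1 at the
#' apex and 0 at the base. The apex coordinate is the lowest tissue voxel
#' centre; the base coordinate is the truncation plane.
#'
#' @param grid An `ecgi_grid`.
#' @return The grid with an `f_ab` element per tissue voxel.
#' @export
compute_apicobasal_factor <- function(grid) {
  stopifnot(inherits(grid, "ecgi_grid"))
  xyz <- grid_coords(grid)
  z_apex <- min(xyz[, 3])
  z_base <- grid$params$z_base
  f <- (xyz[, 3] - z_base) / (z_apex - z_base)
  grid$f_ab <- pmin(pmax(f, 0), 1)
  grid
}

#' Assign the rule-based fiber field
#'
#' Builds a local wall frame per voxel (transmural axis = normalized depth
#' gradient; apico-basal axis = global z projected orthogonal to it;
#' circumferential axis = their cross product), applies the helix-angle rule,
#' and smooths fiber directions near the RV-septum junction with two
#' neighbor-averaging passes blended over the configured smoothing width.
#' Voxels with a degenerate frame (apex pole, flat depth gradient) receive a
#' fallback frame built from the x axis; their count is recorded in the
#' `fiber_fallback` attribute.
#'
#' @param grid An `ecgi_grid` with computed `depth`.
#' @param rule An `ecgi_fiber_rule`.
#' @return The grid with `fiber` (n x 3 unit vectors) and `junction_dist`
#'   (distance to the RV-septum junction, mm) elements.
#' @export
assign_fibers <- function(grid, rule = fiber_rule()) {
  if (is.null(grid$depth)) stop("compute_transmural_depth() first")
  d <- grid$dims
  dx <- grid$dx
  full <- array(NA_real_, d)
  full[grid$tissue_idx] <- grid$depth

  grad_axis <- function(axis) {
    p <- shift_array(full, axis, -1L)  # value at +1 neighbor
    m <- shift_array(full, axis, +1L)  # value at -1 neighbor
    p <- ifelse(is.na(p), full, p)
    m <- ifelse(is.na(m), full, m)
    (p - m) / (2 * dx)
  }
  g <- cbind(grad_axis(1L)[grid$tissue_idx],
             grad_axis(2L)[grid$tissue_idx],
             grad_axis(3L)[grid$tissue_idx])
  gn <- sqrt(rowSums(g^2))
  flat <- gn < 1e-8
  et <- g
  et[flat, ] <- rep(c(1, 0, 0), each = sum(flat))
  et <- normalize_rows(et)

  zhat <- matrix(rep(c(0, 0, 1), each = nrow(et)), ncol = 3)
  eab <- zhat - et * et[, 3]
  abn <- sqrt(rowSums(eab^2))
  degen <- abn < 1e-3 | flat
  if (any(degen)) {
    xhat <- matrix(rep(c(1, 0, 0), each = sum(degen)), ncol = 3)
    sub <- xhat - et[degen, , drop = FALSE] * et[degen, 1]
    bad2 <- sqrt(rowSums(sub^2)) < 1e-3
    if (any(bad2)) {
      # project the y axis instead when the x axis is parallel to e_t
      ety <- et[degen, , drop = FALSE][bad2, , drop = FALSE]
      yhat <- matrix(rep(c(0, 1, 0), each = sum(bad2)), ncol = 3)
      sub[bad2, ] <- yhat - ety * ety[, 2]
    }
    eab[degen, ] <- sub
  }
  eab <- normalize_rows(eab)
  ec <- normalize_rows(cross_rows(eab, et))

  alpha <- helix_angle(grid$depth, rule) * pi / 180
  fib <- ec * cos(alpha) + eab * sin(alpha)

  # RV-septum junction smoothing
  jdist <- rep(Inf, length(grid$tissue_idx))
  if (any(grid$chamber == 2L) && any(grid$chamber == 3L) && grid$params$smooth_width > 0) {
    lab <- array(0L, d)
    lab[grid$tissue_idx] <- grid$chamber
    rv <- lab == 2L
    near_sep <- array(FALSE, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift_array(lab + 0, ax, s)
      near_sep <- near_sep | (!is.na(sh) & sh == 3L)
    }
    junction <- rv & near_sep
    if (any(junction)) {
      jd2 <- .cpp_edt3d(as.vector(junction), as.integer(d))
      jdist <- sqrt(jd2[grid$tissue_idx]) * dx
      w <- exp(-(jdist / grid$params$smooth_width)^2)
      zone <- jdist <= 2 * grid$params$smooth_width
      if (any(zone)) {
        fib_s <- fib
        for (pass in 1:2) {
          acc <- fib_s
          cnt <- rep(1, nrow(fib_s))
          fullv <- array(NA_integer_, d)
          fullv[grid$tissue_idx] <- seq_along(grid$tissue_idx)
          for (ax in 1:3) for (s in c(-1L, 1L)) {
            nbv <- shift_array(fullv + 0, ax, s)[grid$tissue_idx]
            ok <- !is.na(nbv)
            # align sign before averaging: fibers are axial (A and -A equivalent)
            dotp <- rowSums(fib_s * fib_s[ifelse(ok, nbv, 1), , drop = FALSE])
            sgn <- ifelse(dotp >= 0, 1, -1)
            acc[ok, ] <- acc[ok, , drop = FALSE] +
              fib_s[nbv[ok], , drop = FALSE] * sgn[ok]
            cnt[ok] <- cnt[ok] + 1
          }
          fib_s <- normalize_rows(acc / cnt)
        }
        fib[zone, ] <- normalize_rows((1 - w[zone]) * fib[zone, , drop = FALSE] +
                                        w[zone] * fib_s[zone, , drop = FALSE])
      }
    }
  }
  grid$fiber <- normalize_rows(fib)
  grid$junction_dist <- jdist
  attr(grid$fiber, "fiber_fallback") <- sum(degen)
  grid
}

#' Build a fully labeled geometry in one call
#'
#' Convenience wrapper chaining [build_biventricle()],
#' [compute_transmural_depth()], [segment_cell_types()],
#' [compute_apicobasal_factor()] and [assign_fibers()].
#'
#' @param params An `ecgi_geometry_params`.
#' @param rule An `ecgi_fiber_rule`.
#' @param fibers Compute the fiber field (set `FALSE` to skip the most
#'   memory-hungry step when only masks and labels are needed).
#' @return A fully populated `ecgi_grid`.
#' @export
build_labeled_geometry <- function(params, rule = fiber_rule(), fibers = TRUE) {
  g <- build_biventricle(params)
  g <- compute_transmural_depth(g)
  g <- segment_cell_types(g)
  g <- compute_apicobasal_factor(g)
  if (fibers) g <- assign_fibers(g, rule)
  g
}
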