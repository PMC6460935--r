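#' Equivalent volumetric current-dipole sources from a voltage field
#'
#' Computes the per-voxel current-dipole density p = -D grad(V) (scaled by
#' the voxel volume and a calibration constant) from transmembrane voltage
#' snapshots on the tissue grid, using central differences with reflection
#' at tissue boundaries. Body-surface potentials are used comparatively, so
#' the absolute scale constant is arbitrary and defaults to 1.
#'
#' @param recordings An `ecgi_recordings` (or a voxels x times matrix with a
#'   matching `grid`).
#' @param diffusion An `ecgi_diffusion` tensor field.
#' @param grid The `ecgi_grid` the voltages live on.
#' @param scale Calibration constant multiplying all moments.
#' @return An `ecgi_sources` object: list with `positions` (n x 3, heart
#'   frame, mm) and `moments` (3n x times matrix; per-voxel moment vectors
#'   stacked).
#' @export
compute_sources <- function(recordings, diffusion, grid, scale = 1) {
  V <- if (inherits(recordings, "ecgi_recordings")) recordings$V else as.matrix(recordings)
  n <- length(grid$tissue_idx)
  if (nrow(V) != n)
    stop("voltage rows must match tissue voxels (record all voxels for the forward problem)")
  if (nrow(diffusion) != n) stop("diffusion rows must match tissue voxels")
  d <- grid$dims
  dx <- grid$dx
  full2tis <- integer(prod(d))
  full2tis[grid$tissue_idx] <- seq_len(n)
  s <- c(1L, d[1], d[1] * d[2])
  nb <- matrix(0L, n, 6)
  ijk <- cbind((grid$tissue_idx - 1L) %% d[1],
               ((grid$tissue_idx - 1L) %/% d[1]) %% d[2],
               (grid$tissue_idx - 1L) %/% (d[1] * d[2]))
  for (ax in 1:3) {
    ok_m <- ijk[, ax] > 0L
    ok_p <- ijk[, ax] < d[ax] - 1L
    idx_m <- integer(n)
    idx_m[ok_m] <- full2tis[grid$tissue_idx[ok_m] - s[ax]]
    idx_p <- integer(n)
    idx_p[ok_p] <- full2tis[grid$tissue_idx[ok_p] + s[ax]]
    nb[, 2 * ax - 1] <- idx_m
    nb[, 2 * ax] <- idx_p
  }
  nt <- ncol(V)
  mom <- matrix(0, 3 * n, nt)
  self <- seq_len(n)
  for (ax in 1:3) {
    im <- nb[, 2 * ax - 1]; ip <- nb[, 2 * ax]
    rm_ <- ifelse(im > 0L, im, self)
    rp_ <- ifelse(ip > 0L, ip, self)
    g <- (V[rp_, , drop = FALSE] - V[rm_, , drop = FALSE]) / (2 * dx)
    # one voxel of separation when a side is missing
    half <- (im == 0L) | (ip == 0L)
    g[half, ] <- g[half, , drop = FALSE] * 2
    both <- (im == 0L) & (ip == 0L)
    g[both, ] <- 0
    # p_c = -sum_ax D[c,ax] * gax ; accumulate per component
    cols <- list(c(1, 4, 5), c(4, 2, 6), c(5, 6, 3))  # tensor col for (c,ax)
    for (cc in 1:3) {
      rows <- seq.int(cc, by = 3, length.out = n)
      mom[rows, ] <- mom[rows, ] - diffusion[, cols[[cc]][ax]] * g
    }
  }
  mom <- mom * (scale * dx^3)
  xyz <- grid_coords(grid)
  structure(list(positions = xyz, moments = mom, dx = dx),
            class = "ecgi_sources")
}

#' Aggregate dipole sources to a coarser grid
#'
#' Sums voxel dipole moments within cubic bins to keep dense forward
#' products tractable; bin positions are the moment-unweighted centroids of
#' the member voxels.
#'
#' @param sources An `ecgi_sources`.
#' @param cell Bin edge length, mm (default 2).
#' @return An `ecgi_sources` with fewer source sites.
#' @export
aggregate_sources <- function(sources, cell = 2) {
  pos <- sources$positions
  key <- paste(floor(pos[, 1] / cell), floor(pos[, 2] / cell),
               floor(pos[, 3] / cell))
  grp <- match(key, unique(key))
  ng <- max(grp)
  n <- nrow(pos)
  newpos <- apply(pos, 2, function(col) rowsum(col, grp)[, 1] / tabulate(grp, ng))
  nt <- ncol(sources$moments)
  newmom <- matrix(0, 3 * ng, nt)
  for (cc in 1:3) {
    rows <- seq.int(cc, by = 3, length.out = n)
    agg <- rowsum(sources$moments[rows, , drop = FALSE], grp)
    newmom[seq.int(cc, by = 3, length.out = ng), ] <- agg
  }
  structure(list(positions = newpos, moments = newmom, dx = cell),
            class = "ecgi_sources")
}

# lumped (vertex-collocated) signed solid-angle matrix: obs x vertices(mesh)
#' @noRd
lumped_solid_angle <- function(mesh, obs) {
  om <- .cpp_solid_angle(mesh$vertices, mesh$triangles - 1L, as.matrix(obs))
  lump_to_vertices(om, mesh)
}

#' @noRd
lumped_single_layer <- function(mesh, obs) {
  sl <- .cpp_single_layer(mesh$vertices, mesh$triangles - 1L, as.matrix(obs))
  lump_to_vertices(sl, mesh)
}

#' @noRd
lump_to_vertices <- function(per_tri, mesh) {
  nv <- nrow(mesh$vertices)
  nt <- nrow(mesh$triangles)
  inc <- matrix(0, nt, nv)
  for (c in 1:3) {
    ij <- cbind(seq_len(nt), mesh$triangles[, c])
    inc[ij] <- inc[ij] + 1 / 3
  }
  per_tri %*% inc
}

#' Assemble the heterogeneous boundary-element forward system
#'
#' Builds the dense vertex-collocated double-layer system for the potential
#' on all compartment surfaces of a torso model given volumetric dipole
#' sources in an unbounded medium: sigma_bar(y) phi(y) - (1/4pi) sum_l
#' (sigma_in - sigma_out)_l W_l phi = s(y), with analytic triangle solid
#' angles, diagonal correction enforcing the closed-surface identity, and
#' rank-one deflation of the Neumann nullspace (zero area-weighted mean on
#' the outer surface).
#'
#' @param torso An `ecgi_torso`.
#' @return An `ecgi_bem` object with the factorizable dense matrix and
#'   bookkeeping (surface offsets, conductivities, electrode rows).
#' @export
assemble_bem <- function(torso) {
  stopifnot(inherits(torso, "ecgi_torso"))
  surfaces <- c(list(torso$outer), unname(torso$organs))
  sig_in <- c(torso$sigma, vapply(torso$organs, function(o) attr(o, "conductivity"), 0))
  sig_out <- c(0, rep(torso$sigma, length(torso$organs)))
  for (s in surfaces) {
    fg <- mesh_face_geometry(s)
    if (any(fg$areas <= 1e-12))
      stop("degenerate (zero-area) triangle in surface", if (!is.null(s$tag)) paste0(" '", s$tag, "'"))
    wt <- is_watertight(s)
    if (!isTRUE(wt))
      stop("surface", if (!is.null(s$tag)) paste0(" '", s$tag, "'"),
           " is not watertight: ", attr(wt, "reason"))
  }
  nv <- vapply(surfaces, function(s) nrow(s$vertices), 0L)
  off <- cumsum(c(0L, nv))
  ntot <- sum(nv)
  obs <- do.call(rbind, lapply(surfaces, function(s) s$vertices))

  A <- diag((sig_in + sig_out)[rep(seq_along(surfaces), nv)] / 2)
  for (l in seq_along(surfaces)) {
    W <- lumped_solid_angle(surfaces[[l]], obs)
    rows_l <- (off[l] + 1):(off[l] + nv[l])
    # enforce the on-surface principal-value identity (row sum = 2 pi)
    rs <- rowSums(W[rows_l, , drop = FALSE])
    W[cbind(rows_l, seq_len(nv[l]))] <-
      W[cbind(rows_l, seq_len(nv[l]))] + (2 * pi - rs)
    dsig <- sig_in[l] - sig_out[l]
    cols_l <- (off[l] + 1):(off[l] + nv[l])
    A[, cols_l] <- A[, cols_l] - dsig / (4 * pi) * W
  }
  # deflation: fix the additive constant via the outer-surface area mean
  w <- numeric(ntot)
  fg <- mesh_face_geometry(surfaces[[1]])
  va <- numeric(nv[1])
  for (c in 1:3) va <- va + tapply_add(surfaces[[1]]$triangles[, c],
                                       fg$areas / 3, nv[1])
  w[1:nv[1]] <- va / sum(va)
  scale <- mean(abs(diag(A)))
  Ad <- A + scale * outer(rep(1, ntot), w)

  structure(list(A = Ad, obs = obs, offsets = off, nv = nv,
                 deflation = list(w = w, scale = scale),
                 sig_in = sig_in, sig_out = sig_out,
                 sigma_bg = torso$sigma,
                 surfaces = surfaces,
                 electrodes = torso$electrodes,
                 heart_pose = torso$heart_pose),
            class = "ecgi_bem")
}

#' Body-surface potentials from dipole sources
#'
#' Evaluates the infinite-medium source potential at all surface vertices,
#' solves the boundary-element system for every snapshot, and returns the
#' electrode potentials, mean-referenced over electrodes per snapshot.
#'
#' @param sources An `ecgi_sources` (heart frame; the torso's heart pose is
#'   applied).
#' @param system An `ecgi_bem` from [assemble_bem()].
#' @param electrodes Electrode vertex indices (default: the torso layout).
#' @return An `ecgi_bsp` object: list with `potentials` (electrodes x
#'   times), `electrodes`, `phi_surface` (all vertices x times).
#' @export
compute_bsp <- function(sources, system, electrodes = NULL) {
  stopifnot(inherits(sources, "ecgi_sources"), inherits(system, "ecgi_bem"))
  if (is.null(electrodes)) electrodes <- system$electrodes
  pos <- sweep(sources$positions, 2, system$heart_pose, "+")
  inside <- points_inside_mesh(system$surfaces[[1]],
                               pos[sample_rows(nrow(pos), 64), , drop = FALSE])
  if (!all(inside)) stop("source positions fall outside the torso surface")
  s <- .cpp_dipole_potential_series(system$obs, pos, sources$moments)
  phi <- solve(system$A, s)
  bsp <- phi[electrodes, , drop = FALSE]
  bsp <- sweep(bsp, 2, colMeans(bsp))
  structure(list(potentials = bsp, electrodes = electrodes,
                 phi_surface = phi),
            class = "ecgi_bsp")
}

#' @noRd
sample_rows <- function(n, k) {
  if (n <= k) seq_len(n) else unique(round(seq(1, n, length.out = k)))
}

#' Potential at interior points from a solved forward problem
#'
#' Representation formula for points inside the torso (in the background
#' compartment): sigma_bg phi(y) = s(y) + (1/4pi) sum_l (sigma_in -
#' sigma_out)_l W_l(y) phi_l. Used to evaluate the "true" extracellular
#' potential on the epicardial envelope.
#'
#' @param system An `ecgi_bem`.
#' @param phi_surface All-vertex surface potentials from [compute_bsp()].
#' @param points n x 3 interior points (torso frame).
#' @param sources The `ecgi_sources` used for the solve.
#' @return n x times potential matrix.
#' @export
forward_potential_at <- function(system, phi_surface, points, sources) {
  pos <- sweep(sources$positions, 2, system$heart_pose, "+")
  s <- .cpp_dipole_potential_series(as.matrix(points), pos, sources$moments)
  acc <- s
  for (l in seq_along(system$surfaces)) {
    rows_l <- (system$offsets[l] + 1):(system$offsets[l] + system$nv[l])
    W <- lumped_solid_angle(system$surfaces[[l]], as.matrix(points))
    dsig <- system$sig_in[l] - system$sig_out[l]
    acc <- acc + dsig / (4 * pi) * (W %*% phi_surface[rows_l, , drop = FALSE])
  }
  acc / system$sigma_bg
}
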