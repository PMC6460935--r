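#' Default compartment conductivities (S/m)
#'
#' Standard literature values for the passive conductivities of the torso
#' and its major compartments; all are configurable per torso model.
#'
#' @return Named numeric vector.
#' @export
default_conductivities <- function() {
  c(torso = 0.22, lungs = 0.05, blood = 0.7, liver = 0.15, bone = 0.02)
}

#' Build a synthetic torso volume-conductor model
#'
#' Generates a closed outer torso surface (an ellipsoid by default, or a
#' sphere for analytic fixtures) as a mapped icosphere, optional nested
#' organ compartments (ellipsoids), a quasi-uniform electrode layout and a
#' heart pose. The forward problem may use the full heterogeneous model; the
#' inverse transfer matrix only ever sees the homogeneous outer surface.
#'
#' @param shape `"ellipsoid"` or `"sphere"`.
#' @param semi_axes Torso semi-axes, mm (ellipsoid shape).
#' @param radius Sphere radius, mm (sphere shape).
#' @param center Torso centre, mm.
#' @param level Icosphere subdivision level of the outer surface.
#' @param organs Optional list of organ descriptors, each a list with
#'   `name`, `center`, `semi_axes`, `conductivity` (S/m) and optional
#'   `level`.
#' @param conductivity Background torso conductivity, S/m.
#' @param heart_pose Translation applied to heart-derived sources/surfaces,
#'   mm.
#' @param n_electrodes Number of body-surface electrodes.
#' @param seed Seed for the deterministic electrode layout.
#' @return An `ecgi_torso` object with elements `outer` (mesh), `organs`
#'   (list of meshes with `conductivity` attributes), `sigma`,
#'   `electrodes` (vertex indices of the outer mesh), `heart_pose`.
#' @export
build_torso <- function(shape = c("ellipsoid", "sphere"),
                        semi_axes = c(170, 120, 280), radius = 150,
                        center = c(0, 0, 0), level = 3,
                        organs = list(),
                        conductivity = default_conductivities()[["torso"]],
                        heart_pose = c(0, 0, 0),
                        n_electrodes = 128, seed = 1L) {
  shape <- match.arg(shape)
  if (conductivity <= 0) stop("conductivity must be > 0")
  base <- icosphere(level)
  if (shape == "sphere") {
    stopifnot_scalar_pos(radius, "radius")
    verts <- base$vertices * radius
  } else {
    if (any(semi_axes <= 0)) stop("semi_axes must be positive")
    verts <- sweep(base$vertices, 2, semi_axes, "*")
  }
  verts <- sweep(verts, 2, center, "+")
  outer_mesh <- surface_mesh(verts, base$triangles, tag = "torso")

  organ_meshes <- list()
  for (og in organs) {
    lev <- og$level %||% 2
    om <- icosphere(lev)
    ov <- sweep(sweep(om$vertices, 2, og$semi_axes, "*"), 2, og$center, "+")
    m <- surface_mesh(ov, om$triangles, tag = og$name)
    if (!all(points_inside_mesh(outer_mesh, m$vertices)))
      stop(sprintf("organ '%s' extends outside the torso surface", og$name))
    attr(m, "conductivity") <- og$conductivity
    organ_meshes[[og$name]] <- m
  }

  el <- layout_electrodes_mesh(outer_mesh, n_electrodes, seed)
  structure(list(outer = outer_mesh, organs = organ_meshes,
                 sigma = conductivity, electrodes = el,
                 heart_pose = as.numeric(heart_pose),
                 shape = shape),
            class = "ecgi_torso")
}

#' @export
print.ecgi_torso <- function(x, ...) {
  cat(sprintf("ecgi_torso (%s): %d surface vertices, %d electrodes, %d organ(s)\n",
              x$shape, nrow(x$outer$vertices), length(x$electrodes),
              length(x$organs)))
  invisible(x)
}

# deterministic quasi-uniform electrode selection by farthest-point sampling
#' @noRd
layout_electrodes_mesh <- function(mesh, n, seed = 1L) {
  nv <- nrow(mesh$vertices)
  if (n < 4) stop("need at least 4 electrodes")
  if (n > nv) stop("more electrodes than surface vertices")
  if (n == nv) return(seq_len(nv))
  set.seed(seed)
  start <- sample.int(nv, 1)
  picked <- integer(n)
  picked[1] <- start
  d2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[start, ])^2)
  for (q in 2:n) {
    picked[q] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(mesh$vertices, 2, mesh$vertices[picked[q], ])^2))
  }
  sort(picked)
}

#' Quasi-uniform electrode layout on the torso surface
#'
#' Deterministic farthest-point sampling of outer-surface vertices given the
#' seed; repeated calls with the same seed return the same layout.
#'
#' @param torso An `ecgi_torso`.
#' @param n Number of electrodes.
#' @param seed Seed.
#' @return Sorted vertex indices into the outer mesh.
#' @export
layout_electrodes <- function(torso, n, seed = 1L) {
  layout_electrodes_mesh(torso$outer, n, seed)
}

#' Extract the closed epicardial envelope of a voxel heart
#'
#' Builds a watertight triangulated envelope of the heart (tissue plus
#' cavities, basal truncation capped) by casting rays from an interior
#' centre through an icosphere tessellation and taking, per direction, the
#' outermost filled-voxel crossing (star-shaped envelope extraction),
#' followed by a containment-repair pass that locally inflates any facet
#' with a tissue voxel centre outside it. The result contains every tissue
#' voxel and tracks the voxel volume to within a few percent.
#'
#' @param grid An `ecgi_grid`.
#' @param level Icosphere subdivision level (3 gives 642 vertices, the
#'   default working resolution of the inverse problem).
#' @param pad Outward padding, mm.
#' @return An `ecgi_mesh` tagged `"epicardium"`.
#' @export
extract_epicardial_surface <- function(grid, level = 3, pad = NULL) {
  stopifnot(inherits(grid, "ecgi_grid"))
  if (is.null(pad)) pad <- grid$dx * 0.25
  filled <- grid$mask | grid$cavity
  idx <- which(filled)
  if (length(idx) == 0) stop("empty tissue mask; cannot close a surface")
  xyz <- grid_coords(grid, idx)
  ctr <- colMeans(xyz)

  sph <- icosphere(level)
  # per direction, march along the ray from the interior centre and take the
  # outermost filled-voxel crossing
  d <- grid$dims
  step <- grid$dx / 4
  t_max <- max(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) + grid$dx
  tgrid <- seq(grid$dx, t_max, by = step)
  nv <- nrow(sph$vertices)
  rmax <- rep(NA_real_, nv)
  for (vtx in seq_len(nv)) {
    pts <- outer(tgrid, sph$vertices[vtx, ]) + rep(ctr, each = length(tgrid))
    i <- round((pts[, 1] - grid$origin[1]) / grid$dx) + 1
    j <- round((pts[, 2] - grid$origin[2]) / grid$dx) + 1
    k <- round((pts[, 3] - grid$origin[3]) / grid$dx) + 1
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    hit <- logical(length(tgrid))
    hit[ok] <- filled[cbind(i[ok], j[ok], k[ok])]
    if (any(hit)) rmax[vtx] <- tgrid[max(which(hit))]
  }
  if (anyNA(rmax)) stop("mask is not closable from the interior centre")
  rmax <- rmax + pad

  # two umbrella-smoothing passes of the radius field: raw per-direction ray
  # casts carry voxelization noise that would roughen the mesh (and with it
  # the Laplacian regularizer built on it); containment is restored below
  ed <- rbind(sph$triangles[, 1:2], sph$triangles[, 2:3],
              sph$triangles[, c(3, 1)])
  ed <- unique(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  from <- c(ed[, 1], ed[, 2])
  to <- c(ed[, 2], ed[, 1])
  deg <- tabulate(from, nv)
  sums <- numeric(nv)
  agg <- rowsum(rmax[to], from)
  sums[as.integer(rownames(agg))] <- agg
  rmax <- (rmax + sums) / (1 + deg)

  # containment repair: facets chord below the true surface on slanted
  # regions, so inflate the supporting vertices of any face with a tissue
  # voxel centre outside until the envelope contains them all
  mesh <- surface_mesh(sweep(sph$vertices * rmax, 2, ctr, "+"),
                       sph$triangles, tag = "epicardium")
  rel_all <- sweep(xyz, 2, ctr)
  rad_all <- sqrt(rowSums(rel_all^2))
  # only voxels near the local surface radius can possibly protrude: compare
  # with the radius of the best-aligned mesh direction, chunked to bound memory
  r_loc <- numeric(nrow(xyz))
  chunk <- 20000L
  for (i0 in seq(1, nrow(xyz), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(xyz))
    sim <- (rel_all[i0:i1, , drop = FALSE] / rad_all[i0:i1]) %*% t(sph$vertices)
    r_loc[i0:i1] <- rmax[max.col(sim)]
  }
  near <- rad_all > r_loc - 3 * grid$dx
  tris <- sph$triangles
  for (it in 1:20) {
    out <- !points_inside_mesh(mesh, xyz[near, , drop = FALSE])
    if (!any(out)) break
    w <- which(near)[out]
    dirs <- rel_all[w, , drop = FALSE] / rad_all[w]
    sim <- dirs %*% t(sph$vertices)
    for (q in seq_along(w)) {
      # locate the face the ray crosses (among faces adjacent to the
      # best-aligned vertices) and scale its corners so the facet plane
      # clears the voxel centre
      top <- order(sim[q, ], decreasing = TRUE)[1:3]
      cand <- which(tris[, 1] %in% top | tris[, 2] %in% top | tris[, 3] %in% top)
      u <- dirs[q, ]
      for (f in cand) {
        vids <- tris[f, ]
        B <- t(sph$vertices[vids, , drop = FALSE])
        bc <- tryCatch(solve(B, u), error = function(e) NULL)
        if (is.null(bc) || any(bc < -1e-9)) next
        p1 <- sph$vertices[vids[1], ] * rmax[vids[1]]
        p2 <- sph$vertices[vids[2], ] * rmax[vids[2]]
        p3 <- sph$vertices[vids[3], ] * rmax[vids[3]]
        nrm <- c((p2 - p1)[2] * (p3 - p1)[3] - (p2 - p1)[3] * (p3 - p1)[2],
                 (p2 - p1)[3] * (p3 - p1)[1] - (p2 - p1)[1] * (p3 - p1)[3],
                 (p2 - p1)[1] * (p3 - p1)[2] - (p2 - p1)[2] * (p3 - p1)[1])
        t_cross <- sum(nrm * p1) / sum(nrm * u)
        fac <- (rad_all[w[q]] + 0.1) / t_cross
        if (is.finite(fac) && fac > 1)
          rmax[vids] <- rmax[vids] * fac
        break
      }
    }
    mesh$vertices <- sweep(sph$vertices * rmax, 2, ctr, "+")
  }
  mesh
}

#' Apply the torso's heart pose to heart-frame coordinates
#' @param torso An `ecgi_torso`.
#' @param x n x 3 matrix (or `ecgi_mesh`) in the heart frame.
#' @return Translated copy.
#' @export
place_in_torso <- function(torso, x) {
  if (inherits(x, "ecgi_mesh")) {
    x$vertices <- sweep(x$vertices, 2, torso$heart_pose, "+")
    return(x)
  }
  sweep(as.matrix(x), 2, torso$heart_pose, "+")
}
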