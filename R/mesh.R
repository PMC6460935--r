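#' Triangulated surface meshes
#'
#' Minimal closed-surface container: vertices (mm), oriented triangles
#' (1-based vertex indices, outward right-handed), an optional compartment
#' tag and optional per-vertex potentials.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of vertex indices.
#' @param tag Optional compartment name.
#' @return An `ecgi_mesh` object.
#' @export
surface_mesh <- function(vertices, triangles, tag = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles, tag = tag),
            class = "ecgi_mesh")
}

#' @export
print.ecgi_mesh <- function(x, ...) {
  cat(sprintf("ecgi_mesh%s: %d vertices, %d triangles, area %.1f, volume %.1f\n",
              if (is.null(x$tag)) "" else paste0(" [", x$tag, "]"),
              nrow(x$vertices), nrow(x$triangles),
              mesh_area(x), mesh_volume(x)))
  invisible(x)
}

#' Total surface area of a mesh
#' @param mesh An `ecgi_mesh`.
#' @return Area (mm^2).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  sum(sqrt(rowSums(cross_rows(a, b)^2))) / 2
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param mesh An `ecgi_mesh`.
#' @return Signed volume (mm^3); positive for outward orientation.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross_rows(p2, p3))) / 6
}

#' Check that a mesh is watertight
#'
#' Every edge must be shared by exactly two triangles with consistent
#' orientation (each undirected edge appears once in each direction).
#'
#' @param mesh An `ecgi_mesh`.
#' @return TRUE/FALSE, with a `reason` attribute when FALSE.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  he <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_dir <- paste(he[, 1], he[, 2])
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  if (any(duplicated(key_dir)))
    return(structure(FALSE, reason = "duplicated directed edge (inconsistent orientation)"))
  cnt <- table(key_und)
  if (any(cnt != 2))
    return(structure(FALSE, reason = "edge not shared by exactly 2 triangles"))
  TRUE
}

#' Triangle centroids and outward normals
#' @param mesh An `ecgi_mesh`.
#' @return List with `centroids` (m x 3), `normals` (m x 3, unit), `areas`.
#' @export
mesh_face_geometry <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  cr <- cross_rows(p2 - p1, p3 - p1)
  areas <- sqrt(rowSums(cr^2)) / 2
  list(centroids = (p1 + p2 + p3) / 3,
       normals = cr / pmax(2 * areas, 1e-300),
       areas = areas)
}

# unit icosphere: subdivided icosahedron (watertight, outward-oriented)
#' Unit icosphere mesh
#' @param level Subdivision level (0 = icosahedron, each level quadruples the
#'   triangle count; level 3 gives 642 vertices).
#' @return An `ecgi_mesh` on the unit sphere.
#' @export
icosphere <- function(level = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1) * 4 + 1, ] <- c(a, ab, ca)
      nf[(t - 1) * 4 + 2, ] <- c(b, bc, ab)
      nf[(t - 1) * 4 + 3, ] <- c(cc, ca, bc)
      nf[(t - 1) * 4 + 4, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  m <- surface_mesh(v, f, tag = "sphere")
  # ensure outward orientation
  if (mesh_volume(m) < 0) m$triangles <- m$triangles[, c(1, 3, 2)]
  m
}

#' Fraction of points inside a closed mesh (winding number)
#'
#' Uses the summed solid angle of all triangles: ~4*pi for interior points,
#' ~0 for exterior.
#'
#' @param mesh An `ecgi_mesh`.
#' @param points n x 3 matrix.
#' @return Logical vector, TRUE for interior points.
#' @export
points_inside_mesh <- function(mesh, points) {
  om <- .cpp_solid_angle(mesh$vertices, mesh$triangles - 1L,
                         as.matrix(points))
  abs(rowSums(om)) > 2 * pi
}

#' Vertex normals (area-weighted average of incident face normals)
#' @param mesh An `ecgi_mesh`.
#' @return n x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  fg <- mesh_face_geometry(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    w <- fg$normals * fg$areas
    for (ax in 1:3) {
      n[, ax] <- n[, ax] + tapply_add(mesh$triangles[, c], w[, ax], nrow(mesh$vertices))
    }
  }
  normalize_rows(n)
}

#' @noRd
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}
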