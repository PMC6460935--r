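#' Write a labeled grid as legacy ASCII VTK structured points
#'
#' Emits the tissue mask, chamber labels and any computed per-voxel fields
#' (cell type, transmural depth, apico-basal factor, fiber vectors) as
#' point-data arrays on the full structured grid.
#'
#' @param grid An `ecgi_grid`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_grid_vtk <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ecgisim labeled bi-ventricle grid",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.10g %.10g %.10g", grid$origin[1], grid$origin[2], grid$origin[3]),
               sprintf("SPACING %.10g %.10g %.10g", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(d))), con)
  emit_scalar <- function(name, values, type = "int") {
    writeLines(sprintf("SCALARS %s %s 1", name, type), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(paste(values, collapse = " "), con)
  }
  full <- function(vals, default = 0) {
    out <- rep(default, prod(d))
    out[grid$tissue_idx] <- vals
    out
  }
  emit_scalar("mask", as.integer(grid$mask))
  emit_scalar("cavity", as.integer(grid$cavity))
  emit_scalar("chamber", full(grid$chamber, 0L))
  if (!is.null(grid$celltype)) emit_scalar("celltype", full(grid$celltype + 1L, 0L))
  if (!is.null(grid$depth))
    emit_scalar("depth", format(full(grid$depth, -1), digits = 6), type = "float")
  if (!is.null(grid$f_ab))
    emit_scalar("f_AB", format(full(grid$f_ab, -1), digits = 6), type = "float")
  if (!is.null(grid$fiber)) {
    writeLines("VECTORS fiber float", con)
    fx <- full(grid$fiber[, 1]); fy <- full(grid$fiber[, 2]); fz <- full(grid$fiber[, 3])
    writeLines(paste(format(fx, digits = 6), format(fy, digits = 6),
                     format(fz, digits = 6), collapse = " "), con)
  }
  invisible(path)
}

#' Read a structured-points VTK grid written by [write_grid_vtk()]
#'
#' @param path VTK file.
#' @return A list with `dims`, `origin`, `spacing` and the per-point data
#'   arrays found in the file.
#' @export
read_grid_vtk <- function(path) {
  lines <- readLines(path)
  getv <- function(prefix) {
    ln <- grep(paste0("^", prefix), lines, value = TRUE)[1]
    as.numeric(strsplit(trimws(sub(prefix, "", ln)), "\\s+")[[1]])
  }
  dims <- as.integer(getv("DIMENSIONS"))
  origin <- getv("ORIGIN")
  spacing <- getv("SPACING")
  np <- prod(dims)
  out <- list(dims = dims, origin = origin, spacing = spacing)
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^SCALARS", lines[i])) {
      name <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- as.numeric(strsplit(trimws(lines[i + 2]), "\\s+")[[1]])
      out[[name]] <- vals[seq_len(np)]
      i <- i + 3
    } else if (grepl("^VECTORS", lines[i])) {
      name <- strsplit(lines[i], "\\s+")[[1]][2]
      vals <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
      out[[name]] <- matrix(vals[seq_len(3 * np)], ncol = 3, byrow = TRUE)
      i <- i + 2
    } else i <- i + 1
  }
  out
}

#' Write a surface mesh as legacy ASCII VTK polydata
#' @param mesh An `ecgi_mesh`.
#' @param path Output file.
#' @param point_data Optional named list of per-vertex numeric vectors.
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0",
               paste("ecgisim surface", mesh$tag %||% ""),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 8), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(paste(format(point_data[[nm]], digits = 6), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Serialize a stimulus schedule to JSON
#' @param schedule An `ecgi_schedule`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(center = schedule$center, extent = schedule$extent,
                            onset = schedule$onset, duration = schedule$duration,
                            amplitude = schedule$amplitude,
                            window = schedule$window),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a stimulus schedule from JSON
#' @param path JSON file written by [write_schedule_json()].
#' @return An `ecgi_schedule`.
#' @export
read_schedule_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_schedule(center = matrix(unlist(j$center), ncol = 3),
                    extent = j$extent, onset = j$onset,
                    duration = j$duration, amplitude = j$amplitude,
                    window = j$window)
}

#' Export single-cell or probe traces as CSV
#' @param trace data.frame with `time` and `V`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
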