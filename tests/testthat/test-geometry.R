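test_that("geometry variants transform wall thickness and axes as prescribed", {
  p <- geometry_params()
  expect_identical(apply_variant(p, "control"), p)
  pt <- apply_variant(p, "thick")
  expect_equal(pt$lv_wall, 18)
  expect_equal(pt$rv_wall, 6)
  expect_equal(pt$lv_semi, p$lv_semi)
  pd <- apply_variant(p, "dilated")
  expect_equal(pd$lv_wall, 12)
  expect_equal(pd$lv_semi[2], p$lv_semi[2] * 1.5)
  expect_error(apply_variant(p, "huge"))
  expect_error(geometry_params(lv_wall = -1))
  expect_error(geometry_params(lv_wall = 50))
})

test_that("voxelized walls reproduce the requested thicknesses within a voxel", {
  for (variant in c("control", "thick", "dilated")) {
    p <- apply_variant(geometry_params(resolution = 1), variant)
    g <- build_biventricle(p)
    expect_lt(abs(measure_wall_thickness(g, "lv") - p$lv_wall), 1 + 1e-9)
    expect_lt(abs(measure_wall_thickness(g, "rv") - p$rv_wall), 1 + 1e-9)
  }
})

test_that("wall volumes follow the hypertrophy/dilation ordering", {
  p <- geometry_params(resolution = 1)
  v0 <- wall_volumes(build_biventricle(p))["lv"]
  vt <- wall_volumes(build_biventricle(apply_variant(p, "thick")))["lv"]
  vd <- wall_volumes(build_biventricle(apply_variant(p, "dilated")))["lv"]
  expect_gt(vt, v0)
  expect_gt(vd, v0)
  expect_gt(vd, vt)   # matches the published size ordering
})

test_that("zero RV thickness gives a pure LV shell matching the closed form", {
  p <- geometry_params(rv_wall = 0, resolution = 0.75)
  g <- build_biventricle(p)
  expect_true(all(g$chamber %in% c(1L, 3L)))
  vol <- sum(g$mask) * p$resolution^3
  trunc_vol <- function(a, b, c, z0) pi * a * b * (z0 - z0^3 / (3 * c^2) + 2 * c / 3)
  le <- p$lv_semi; ln <- le - p$lv_wall
  analytic <- trunc_vol(le[1], le[2], le[3], p$z_base) -
    trunc_vol(ln[1], ln[2], ln[3], p$z_base)
  expect_lt(abs(vol - analytic) / analytic, 0.02)
})

test_that("too-coarse resolutions are rejected with an explicit message", {
  expect_error(build_biventricle(geometry_params(resolution = 2)),
               "RV wall")
})

test_that("transmural depth is 0 at endo, 1 at epi, linear across a slab", {
  g <- compute_transmural_depth(slab_grid(nz_wall = 20, dx = 0.5))
  xyz <- grid_coords(g)
  k <- round((xyz[, 3] - 0.25) / 0.5) + 1  # z layer index
  k_wall <- k - 4                           # 1..20 within the wall
  expected <- (k_wall - 1) / 19
  interior <- xyz[, 1] > 1 & xyz[, 1] < 3.8 & xyz[, 2] > 1 & xyz[, 2] < 3.8
  dev <- abs(g$depth - expected)[interior]
  expect_lt(max(dev), 0.5 / 10)  # one voxel over the wall thickness
  expect_equal(min(g$depth), 0)
  expect_equal(max(g$depth), 1)
})

test_that("depth on the full geometry hits both surfaces and stays in [0,1]", {
  g <- coarse_grid()
  expect_true(all(g$depth >= 0 & g$depth <= 1))
  expect_equal(min(g$depth), 0)
  expect_equal(max(g$depth), 1)
})

test_that("cell-type segmentation uses the 40/30/30 half-open depth bands", {
  g <- coarse_grid()
  expect_true(all(g$celltype[g$depth < 0.4] == 0L))
  expect_true(all(g$celltype[g$depth >= 0.4 & g$depth < 0.7] == 1L))
  expect_true(all(g$celltype[g$depth >= 0.7] == 2L))
  # boundary convention: d = 0.4 exactly is MCELL, 0.7 exactly is EPI
  gg <- g
  gg$depth <- c(0.2, 0.4, 0.7, 1.0)
  gg$tissue_idx <- gg$tissue_idx[1:4]
  gg <- segment_cell_types(gg)
  expect_identical(gg$celltype, c(0L, 1L, 2L, 2L))
})

test_that("the helix-angle rule rotates +R to -R across the wall", {
  rule <- fiber_rule()
  expect_equal(helix_angle(0, rule), 60)
  expect_equal(helix_angle(0.5, rule), 0)
  expect_equal(helix_angle(1, rule), -60)
  expect_equal(helix_angle(0, rule) - helix_angle(1, rule), 120)
  # cubic variation keeps the endpoints and the sign structure
  r3 <- fiber_rule(exponent = 3)
  expect_equal(helix_angle(0, r3), 60)
  expect_equal(helix_angle(0.25, r3), 60 * 0.5^3)
  expect_error(fiber_rule(exponent = 0.5))
})

test_that("stored fiber vectors reproduce the helix-angle rule to < 1 degree", {
  g <- coarse_grid()
  expect_true(all(abs(sqrt(rowSums(g$fiber^2)) - 1) < 1e-6))
  d <- g$dims
  dx <- g$dx
  full <- array(NA_real_, d)
  full[g$tissue_idx] <- g$depth
  idx3 <- cbind((g$tissue_idx - 1) %% d[1],
                ((g$tissue_idx - 1) %/% d[1]) %% d[2],
                (g$tissue_idx - 1) %/% (d[1] * d[2])) + 1
  sel <- which(g$junction_dist > 2 * 2 + dx & g$depth > 0.1 & g$depth < 0.9)
  set.seed(1)
  sel <- sample(sel, 800)
  errs <- vapply(sel, function(v) {
    i <- idx3[v, 1]; j <- idx3[v, 2]; k <- idx3[v, 3]
    if (i <= 1 || j <= 1 || k <= 1 || i >= d[1] || j >= d[2] || k >= d[3]) return(NA_real_)
    gx <- c(full[i + 1, j, k] - full[i - 1, j, k],
            full[i, j + 1, k] - full[i, j - 1, k],
            full[i, j, k + 1] - full[i, j, k - 1]) / (2 * dx)
    if (anyNA(gx) || sqrt(sum(gx^2)) < 1e-6) return(NA_real_)
    et <- gx / sqrt(sum(gx^2))
    eab <- c(0, 0, 1) - et * et[3]
    nn <- sqrt(sum(eab^2))
    if (nn < 1e-3) return(NA_real_)
    eab <- eab / nn
    ec <- c(eab[2] * et[3] - eab[3] * et[2],
            eab[3] * et[1] - eab[1] * et[3],
            eab[1] * et[2] - eab[2] * et[1])
    a_stored <- atan2(sum(g$fiber[v, ] * eab), sum(g$fiber[v, ] * ec)) * 180 / pi
    abs(a_stored - helix_angle(g$depth[v]))
  }, 0)
  expect_lt(stats::quantile(errs, 0.99, na.rm = TRUE), 1)
})

test_that("the apico-basal factor is linear in z between base and apex", {
  g <- coarse_grid()
  xyz <- grid_coords(g)
  z_apex <- min(xyz[, 3])
  z_base <- g$params$z_base
  expected <- pmin(pmax((xyz[, 3] - z_base) / (z_apex - z_base), 0), 1)
  expect_equal(g$f_ab, expected)
  expect_equal(max(g$f_ab), 1)              # apex
  expect_lt(min(g$f_ab), 0.02)              # base (voxel-centre offset only)
  # midway z maps to 0.5
  zmid <- (z_apex + z_base) / 2
  imid <- which.min(abs(xyz[, 3] - zmid))
  expect_lt(abs(g$f_ab[imid] - 0.5), 0.02)
})

test_that("grids round-trip through legacy VTK structured points", {
  g <- coarse_grid()
  path <- tempfile(fileext = ".vtk")
  write_grid_vtk(g, path)
  back <- read_grid_vtk(path)
  expect_equal(back$dims, g$dims)
  expect_equal(back$spacing, rep(g$dx, 3))
  expect_equal(which(back$mask == 1), g$tissue_idx)
  expect_equal(back$depth[g$tissue_idx], g$depth, tolerance = 1e-5)
  unlink(path)
})
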