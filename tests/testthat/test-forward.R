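# tiny labeled block for source computations
source_block <- function(n = 6, dx = 1) {
  g <- make_cable_grid(n * n * n, dx, "EPI")
  mask <- array(TRUE, c(n, n, n))
  structure(list(dims = c(n, n, n), dx = dx, origin = rep(dx / 2, 3),
                 tissue_idx = seq_len(n^3), mask = mask,
                 cavity = array(FALSE, c(n, n, n)),
                 chamber = rep(1L, n^3),
                 fiber = matrix(rep(c(1, 0, 0), each = n^3), ncol = 3),
                 params = NULL),
            class = "ecgi_grid")
}

test_that("equivalent dipole sources follow p = -D grad(V)", {
  g <- source_block()
  diff_iso <- assemble_diffusion(g$fiber, 0.1, 0.1)
  # uniform field: zero sources
  V <- matrix(-80, length(g$tissue_idx), 2)
  src <- compute_sources(V, diff_iso, g)
  expect_equal(max(abs(src$moments)), 0)
  # linear field V = 3x: p = -D * 3 in x everywhere (interior)
  xyz <- grid_coords(g)
  Vlin <- cbind(3 * xyz[, 1])
  src2 <- compute_sources(Vlin, diff_iso, g)
  px <- src2$moments[seq(1, by = 3, length.out = nrow(xyz)), 1]
  expect_equal(px, rep(-0.1 * 3 * g$dx^3, nrow(xyz)), tolerance = 1e-12)
  py <- src2$moments[seq(2, by = 3, length.out = nrow(xyz)), 1]
  expect_equal(max(abs(py)), 0)
  # random smooth field: total moment equals a brute-force finite-difference sum
  set.seed(5)
  Vs <- cbind(sin(xyz[, 1] / 2) + cos(xyz[, 2] / 3) * xyz[, 3] / 5)
  diff_an <- assemble_diffusion(g$fiber, 0.18, 0.045)
  src3 <- compute_sources(Vs, diff_an, g)
  total <- c(sum(src3$moments[seq(1, by = 3, length.out = nrow(xyz)), 1]),
             sum(src3$moments[seq(2, by = 3, length.out = nrow(xyz)), 1]),
             sum(src3$moments[seq(3, by = 3, length.out = nrow(xyz)), 1]))
  # independent oracle: loop over voxels, central/reflected differences
  n <- 6
  arr <- array(Vs, c(n, n, n))
  oracle <- c(0, 0, 0)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    gr <- c(
      (arr[min(i + 1, n), j, k] - arr[max(i - 1, 1), j, k]) /
        ((min(i + 1, n) - max(i - 1, 1)) * g$dx),
      (arr[i, min(j + 1, n), k] - arr[i, max(j - 1, 1), k]) /
        ((min(j + 1, n) - max(j - 1, 1)) * g$dx),
      (arr[i, j, min(k + 1, n)] - arr[i, j, max(k - 1, 1)]) /
        ((min(k + 1, n) - max(k - 1, 1)) * g$dx))
    D <- matrix(c(0.18, 0, 0, 0, 0.045, 0, 0, 0, 0.045), 3)
    oracle <- oracle - as.numeric(D %*% gr) * g$dx^3
  }
  expect_equal(total, oracle, tolerance = 1e-10)
})

test_that("source aggregation preserves the total dipole moment", {
  g <- source_block(8)
  diff_iso <- assemble_diffusion(g$fiber, 0.1, 0.1)
  xyz <- grid_coords(g)
  V <- cbind(sin(xyz[, 1]) * xyz[, 2] / 4)
  src <- compute_sources(V, diff_iso, g)
  agg <- aggregate_sources(src, 2)
  expect_lt(nrow(agg$positions), nrow(src$positions))
  for (c in 1:3) {
    t1 <- sum(src$moments[seq(c, by = 3, length.out = nrow(src$positions)), 1])
    t2 <- sum(agg$moments[seq(c, by = 3, length.out = nrow(agg$positions)), 1])
    expect_equal(t1, t2, tolerance = 1e-12)
  }
})

test_that("solid angles satisfy the Gauss identity on closed surfaces", {
  m <- icosphere(2)
  inner <- matrix(c(0, 0, 0, 0.4, -0.2, 0.3), ncol = 3, byrow = TRUE)
  om <- ecgisim:::.cpp_solid_angle(m$vertices, m$triangles - 1L, inner)
  expect_equal(rowSums(om) / (4 * pi), c(1, 1), tolerance = 1e-6)
  outer_pt <- matrix(c(3, 0, 0), ncol = 3)
  om2 <- ecgisim:::.cpp_solid_angle(m$vertices, m$triangles - 1L, outer_pt)
  expect_lt(abs(sum(om2)), 1e-9)
})

test_that("the assembled forward system satisfies the constant-potential identity", {
  torso <- build_torso(shape = "sphere", radius = 100, level = 2,
                       n_electrodes = 16)
  sys <- assemble_bem(torso)
  # remove the deflation term: the raw operator annihilates constants
  # (the 1/2 jump condition combined with the 2 pi principal-value row sums)
  nv <- nrow(torso$outer$vertices)
  A0 <- sys$A - sys$deflation$scale *
    outer(rep(1, nv), sys$deflation$w)
  expect_lt(max(abs(A0 %*% rep(1, nv))), 1e-10)
})

test_that("degenerate triangles are rejected at assembly", {
  m <- icosphere(1)
  m$triangles[3, ] <- c(1L, 1L, 2L)
  torso <- build_torso(shape = "sphere", radius = 100, level = 1,
                       n_electrodes = 8)
  torso$outer <- m
  expect_error(assemble_bem(torso), "degenerate|watertight")
})

test_that("a dipole in a homogeneous sphere matches the closed form to < 2%", {
  R <- 100; sigma <- 0.22; z0 <- 40
  torso <- build_torso(shape = "sphere", radius = R, level = 3,
                       conductivity = sigma, n_electrodes = 64)
  sys <- assemble_bem(torso)
  src <- structure(list(positions = matrix(c(0, 0, z0), ncol = 3),
                        moments = matrix(c(0, 0, 1), ncol = 1), dx = 1),
                   class = "ecgi_sources")
  bsp <- compute_bsp(src, sys, electrodes = seq_len(nrow(torso$outer$vertices)))
  phi_num <- bsp$phi_surface[, 1]
  vv <- torso$outer$vertices
  theta <- acos(pmin(pmax(vv[, 3] / sqrt(rowSums(vv^2)), -1), 1))
  legendre <- function(l, x) {
    p0 <- rep(1, length(x)); p1 <- x
    if (l == 1) return(p1)
    for (k in 2:l) { p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k; p0 <- p1; p1 <- p2 }
    p1
  }
  phi_ref <- 0
  for (l in 1:80)
    phi_ref <- phi_ref + l * z0^(l - 1) *
      (1 / R^(l + 1) + (l + 1) / (l * R^(l + 1))) * legendre(l, cos(theta))
  phi_ref <- phi_ref / (4 * pi * sigma)
  phi_num <- phi_num - mean(phi_num)
  phi_ref <- phi_ref - mean(phi_ref)
  expect_lt(sqrt(sum((phi_num - phi_ref)^2) / sum(phi_ref^2)), 0.02)
})

test_that("forward accuracy improves monotonically with mesh refinement", {
  R <- 100; sigma <- 1; z0 <- 40
  legendre <- function(l, x) {
    p0 <- rep(1, length(x)); p1 <- x
    if (l == 1) return(p1)
    for (k in 2:l) { p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k; p0 <- p1; p1 <- p2 }
    p1
  }
  src <- structure(list(positions = matrix(c(0, 0, z0), ncol = 3),
                        moments = matrix(c(0, 0, 1), ncol = 1), dx = 1),
                   class = "ecgi_sources")
  errs <- vapply(1:3, function(lev) {
    torso <- build_torso(shape = "sphere", radius = R, level = lev,
                         conductivity = sigma,
                         n_electrodes = min(8, 4 + lev))
    sys <- assemble_bem(torso)
    bsp <- compute_bsp(src, sys)
    vv <- torso$outer$vertices
    theta <- acos(pmin(pmax(vv[, 3] / sqrt(rowSums(vv^2)), -1), 1))
    phi_ref <- 0
    for (l in 1:80)
      phi_ref <- phi_ref + (2 * l + 1) * z0^(l - 1) / R^(l + 1) *
        legendre(l, cos(theta))
    phi_ref <- phi_ref / (4 * pi * sigma)
    got <- bsp$phi_surface[, 1] - mean(bsp$phi_surface[, 1])
    ref <- phi_ref - mean(phi_ref)
    sqrt(sum((got - ref)^2) / sum(ref^2))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("the forward map is linear and mean-referenced", {
  torso <- build_torso(shape = "sphere", radius = 100, level = 2,
                       n_electrodes = 32)
  sys <- assemble_bem(torso)
  mk <- function(mom) structure(list(positions = matrix(c(10, 0, 20), ncol = 3),
                                     moments = matrix(mom, ncol = 1), dx = 1),
                                class = "ecgi_sources")
  b1 <- compute_bsp(mk(c(1, 0, 0)), sys)
  b2 <- compute_bsp(mk(c(0, 2, 1)), sys)
  b12 <- compute_bsp(mk(3 * c(1, 0, 0) + 2 * c(0, 2, 1)), sys)
  expect_equal(b12$potentials, 3 * b1$potentials + 2 * b2$potentials,
               tolerance = 1e-10)
  expect_lt(max(abs(colMeans(b1$potentials))), 1e-12)
  # zero moments give a zero map; opposite co-located dipoles cancel
  b0 <- compute_bsp(mk(c(0, 0, 0)), sys)
  expect_equal(max(abs(b0$potentials)), 0)
  two <- structure(list(positions = matrix(c(10, 0, 20, 10, 0, 20),
                                           ncol = 3, byrow = TRUE),
                        moments = matrix(c(1, 2, 3, -1, -2, -3), ncol = 1),
                        dx = 1),
                   class = "ecgi_sources")
  bt <- compute_bsp(two, sys)
  expect_lt(max(abs(bt$potentials)), 1e-12)
})

test_that("a compartment with background conductivity is a no-op", {
  src <- structure(list(positions = matrix(c(0, 0, 20), ncol = 3),
                        moments = matrix(c(0.3, -0.1, 1), ncol = 1), dx = 1),
                   class = "ecgi_sources")
  plain <- build_torso(shape = "sphere", radius = 100, level = 2,
                       n_electrodes = 32, seed = 2)
  with_organ <- build_torso(shape = "sphere", radius = 100, level = 2,
                            n_electrodes = 32, seed = 2,
                            organs = list(list(name = "lungs",
                                               center = c(40, 0, 0),
                                               semi_axes = c(25, 25, 30),
                                               conductivity = 0.22)))
  b1 <- compute_bsp(src, assemble_bem(plain))
  b2 <- compute_bsp(src, assemble_bem(with_organ))
  rel <- max(abs(b1$potentials - b2$potentials)) / max(abs(b1$potentials))
  expect_lt(rel, 0.001)
  # and a genuinely different conductivity does change the map
  lung_real <- with_organ
  attr(lung_real$organs$lungs, "conductivity") <- 0.05
  b3 <- compute_bsp(src, assemble_bem(lung_real))
  expect_gt(max(abs(b1$potentials - b3$potentials)) / max(abs(b1$potentials)),
            0.01)
})

test_that("interior potential evaluation matches the analytic sphere solution", {
  R <- 100; sigma <- 1; z0 <- 30
  torso <- build_torso(shape = "sphere", radius = R, level = 3,
                       conductivity = sigma, n_electrodes = 32)
  sys <- assemble_bem(torso)
  src <- structure(list(positions = matrix(c(0, 0, z0), ncol = 3),
                        moments = matrix(c(0, 0, 1), ncol = 1), dx = 1),
                   class = "ecgi_sources")
  bsp <- compute_bsp(src, sys)
  # evaluate on an interior ring at r = 70, away from the source
  th <- seq(0.3, pi - 0.3, length.out = 15)
  pts <- cbind(70 * sin(th), 0, 70 * cos(th))
  got <- forward_potential_at(sys, bsp$phi_surface, pts, src)[, 1]
  legendre <- function(l, x) {
    p0 <- rep(1, length(x)); p1 <- x
    if (l == 1) return(p1)
    for (k in 2:l) { p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k; p0 <- p1; p1 <- p2 }
    p1
  }
  r <- 70; ct <- cos(th)
  ref <- 0
  for (l in 1:80) {
    interior <- l * z0^(l - 1) / r^(l + 1)
    image <- (l + 1) * z0^(l - 1) * r^l / (l * R^(2 * l + 1)) * l
    ref <- ref + (interior + image) * legendre(l, ct)
  }
  ref <- ref / (4 * pi * sigma)
  # compare up to the deflation constant
  expect_lt(stats::sd(got - ref) / stats::sd(ref), 0.02)
})
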