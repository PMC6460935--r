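test_that("the transfer matrix reproduces the concentric-spheres harmonic transfer", {
  fx <- spheres_fixture()
  a <- fx$a; b <- fx$b
  Tl <- function(l) (b^l * (2 * l + 1) / (l + 1)) /
    (a^l + l * b^(2 * l + 1) * a^(-l - 1) / (l + 1))
  Z <- fx$transfer$Z
  expect_equal(dim(Z), c(nrow(fx$torso$vertices), nrow(fx$epi$vertices)))
  # uniform epicardial potential maps to the same uniform torso potential
  u <- Z %*% rep(1, ncol(Z))
  expect_lt(max(abs(u - 1)), 0.01)
  # low-order spherical harmonics transfer with the analytic attenuation
  uh1 <- fx$epi$vertices[, 3] / a
  ut1 <- fx$torso$vertices[, 3] / b
  err1 <- sqrt(sum((Z %*% uh1 - Tl(1) * ut1)^2) / sum((Tl(1) * ut1)^2))
  expect_lt(err1, 0.02)
  uh2 <- 0.5 * (3 * (fx$epi$vertices[, 3] / a)^2 - 1)
  ut2 <- 0.5 * (3 * (fx$torso$vertices[, 3] / b)^2 - 1)
  err2 <- sqrt(sum((Z %*% uh2 - Tl(2) * ut2)^2) / sum((Tl(2) * ut2)^2))
  expect_lt(err2, 0.02)
})

test_that("meshes that are open or interpenetrating are rejected", {
  epi <- icosphere(2); epi$vertices <- epi$vertices * 60
  torso <- icosphere(2); torso$vertices <- torso$vertices * 100
  open_mesh <- epi
  open_mesh$triangles <- open_mesh$triangles[-1, , drop = FALSE]
  expect_error(build_transfer_matrix(open_mesh, torso), "watertight")
  big <- epi; big$vertices <- big$vertices * 3  # extends outside the torso
  expect_error(build_transfer_matrix(big, torso), "inside")
})

test_that("regularization operators have the prescribed null spaces", {
  mesh <- icosphere(2)
  r0 <- build_regularizer(0, mesh)
  expect_equal(r0$R, diag(nrow(mesh$vertices)))
  r1 <- build_regularizer(1, mesh)
  expect_lt(max(abs(r1$R %*% rep(1, nrow(mesh$vertices)))), 1e-12)
  r2 <- build_regularizer(2, mesh)
  expect_lt(max(abs(r2$R %*% rep(1, nrow(mesh$vertices)))), 1e-12)
  expect_error(build_regularizer(3, mesh))
  # the Laplacian annihilates linear fields on a symmetric planar patch
  nx <- 9
  gv <- as.matrix(expand.grid(x = 1:nx, y = 1:nx))
  verts <- cbind(gv, 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- NULL
  for (j in 1:(nx - 1)) for (i in 1:(nx - 1)) {
    tris <- rbind(tris, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                  c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  patch <- surface_mesh(verts, tris)
  rl <- build_regularizer(2, patch)
  lin <- 2 * verts[, 1] - 3 * verts[, 2] + 1
  interior <- gv[, 1] > 1 & gv[, 1] < nx & gv[, 2] > 1 & gv[, 2] < nx
  resid <- (rl$R %*% lin)[interior]
  expect_lt(max(abs(resid)), 1e-8 * sqrt(sum(lin^2)))
  # disconnected meshes are rejected for orders 1-2
  disc <- surface_mesh(rbind(verts, verts + 100), tris)
  expect_error(build_regularizer(1, disc), "disconnected")
})

test_that("GSVD-filtered solutions equal dense normal-equation solves", {
  mesh <- icosphere(1)  # 42-vertex operator carrier
  set.seed(11)
  maxerr <- 0
  for (rep in 1:6) {
    Z <- matrix(rnorm(20 * 42), 20, 42)
    y <- rnorm(20)
    for (ord in 0:2) {
      reg <- build_regularizer(ord, mesh)
      for (lam in c(1e-2, 0.5, 5)) {
        x1 <- tikhonov_solve(Z, y, reg, lam)
        x2 <- solve(crossprod(Z) + lam^2 * crossprod(reg$R), crossprod(Z, y))
        maxerr <- max(maxerr, max(abs(x1 - x2)) / max(abs(x2)))
      }
    }
  }
  expect_lt(maxerr, 1e-8)
})

test_that("Tikhonov limits behave as expected", {
  set.seed(12)
  Z <- matrix(rnorm(15 * 15), 15)
  diag(Z) <- diag(Z) + 4
  y <- rnorm(15)
  x0 <- tikhonov_solve(Z, y, diag(15), 0)
  expect_lt(max(abs(x0 - solve(Z, y))), 1e-8)
  xb <- tikhonov_solve(Z, y, diag(15), 1e6)
  expect_lt(sqrt(sum(xb^2)), 1e-4 * sqrt(sum(x0^2)))
  # rank-deficient stacked pair is rejected
  Zr <- matrix(0, 4, 6)
  expect_error(tikhonov_solve(Zr, rep(0, 4), matrix(0, 2, 6), 1),
               "rank")
})

test_that("the L-curve tracks the discrepancy principle on an ill-posed problem", {
  n <- 40
  svec <- seq(-3, 3, length.out = n)
  h <- svec[2] - svec[1]
  K <- h * exp(-outer(svec, svec, function(s, t) (s - t)^2))
  xtrue <- exp(-svec^2) * (1 + 0.5 * cos(2 * svec))
  y0 <- K %*% xtrue
  set.seed(1)
  noise <- rnorm(n)
  noise <- noise / sqrt(sum(noise^2)) * 0.01 * sqrt(sum(y0^2))
  y <- y0 + noise
  grid <- 10^seq(-8, 2, length.out = 60)
  sel <- select_lambda_lcurve(K, y, diag(n), grid)
  expect_true(all(diff(sel$residual) > -1e-12))   # residual nondecreasing
  expect_true(all(diff(sel$seminorm) < 1e-12))    # seminorm nonincreasing
  resid <- vapply(grid, function(l)
    sqrt(sum((K %*% tikhonov_solve(K, y, diag(n), l) - y)^2)), 0)
  lam_dp <- grid[which.min(abs(resid - sqrt(sum(noise^2))))]
  expect_lt(abs(log10(sel$lambda / lam_dp)), 1)
  # degenerate 3-point grid: the single interior candidate is returned
  sel3 <- select_lambda_lcurve(K, y, diag(n), c(1e-6, 1e-2, 10))
  expect_equal(sel3$lambda, 1e-2)
  expect_error(select_lambda_lcurve(K, y, diag(n), c(0.1, 1)), "at least 3")
})

test_that("noiseless reconstructions on the spheres fixture are near-exact", {
  fx <- spheres_fixture()
  y <- fx$Ze %*% fx$phiH
  for (ord in 0:2) {
    sol <- reconstruct_timeseries(fx$Ze, cbind(y), ord, fx$epi)
    expect_gt(pcc(sol$X[, 1], fx$phiH), 0.95)
  }
  # zero BSP reconstructs to zero; identical snapshots give identical output
  z0 <- reconstruct_timeseries(fx$Ze, matrix(0, nrow(fx$Ze), 2), 1, fx$epi)
  expect_equal(max(abs(z0$X)), 0)
  two <- reconstruct_timeseries(fx$Ze, cbind(y, y), 1, fx$epi)
  expect_identical(two$X[, 1], two$X[, 2])
})

test_that("reconstruction error decreases with electrode count (noiseless)", {
  fx <- spheres_fixture()
  # nested quasi-uniform subsets: the first k picks of a farthest-point
  # ordering, so each denser layout contains the sparser one
  nv <- nrow(fx$torso$vertices)
  d2 <- rowSums(sweep(fx$torso$vertices, 2, fx$torso$vertices[1, ])^2)
  fps <- integer(128)
  fps[1] <- 1L
  for (q in 2:128) {
    fps[q] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(fx$torso$vertices, 2,
                                 fx$torso$vertices[fps[q], ])^2))
  }
  errs <- vapply(c(32, 64, 128), function(ne) {
    el <- sort(fps[seq_len(ne)])
    Ze <- transfer_at_electrodes(fx$transfer, el)
    sol <- reconstruct_timeseries(Ze, cbind(Ze %*% fx$phiH), 1, fx$epi)
    rrmse(sol$X[, 1], fx$phiH)
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("forward and inverse formulations are genuinely different operators", {
  # forward: volumetric dipole sources against a compartment BEM system;
  # inverse: two-surface equivalent-potential transfer matrix. Reconstructing
  # forward-generated data must not invert it exactly.
  R <- 100
  torso <- build_torso(shape = "sphere", radius = R, level = 3,
                       n_electrodes = 96, seed = 5)
  sys <- assemble_bem(torso)
  epi <- icosphere(2)
  epi$vertices <- epi$vertices * 50
  tm <- build_transfer_matrix(epi, torso$outer)
  expect_s3_class(sys, "ecgi_bem")
  expect_s3_class(tm, "ecgi_transfer")
  expect_false(identical(dim(sys$A), dim(tm$Z)))
  src <- structure(list(positions = matrix(c(0, 10, 25), ncol = 3),
                        moments = matrix(c(0.5, 0, 1), ncol = 1), dx = 1),
                   class = "ecgi_sources")
  bsp <- compute_bsp(src, sys)
  phi_epi_true <- forward_potential_at(sys, bsp$phi_surface, epi$vertices, src)
  Ze <- transfer_at_electrodes(tm, torso$electrodes)
  sol <- reconstruct_timeseries(Ze, bsp$potentials, 1, epi)
  res <- rrmse(sol$X[, 1] - mean(sol$X[, 1]),
               phi_epi_true[, 1] - mean(phi_epi_true[, 1]))
  expect_gt(res, 1e-6)   # no exact inversion (no "inverse crime")
  expect_gt(pcc(sol$X[, 1], phi_epi_true[, 1]), 0.8)  # but a faithful estimate
})
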