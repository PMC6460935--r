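test_that("diffusion tensors realize axially symmetric anisotropy", {
  # fiber along x: diagonal tensor
  tens <- assemble_diffusion(matrix(c(1, 0, 0), 1), 0.18, 0.045)
  expect_equal(as.numeric(tens[1, ]), c(0.18, 0.045, 0.045, 0, 0, 0))
  # isotropic limit: any fiber gives D_perp * I
  set.seed(2)
  a <- normalize_unit(rnorm(3))
  ti <- assemble_diffusion(matrix(a, 1), 0.1, 0.1)
  expect_equal(as.numeric(ti[1, ]), c(0.1, 0.1, 0.1, 0, 0, 0))
  # random fibers: eigenvalues are {D_par, D_perp, D_perp}
  for (rep in 1:5) {
    a <- normalize_unit(rnorm(3))
    tt <- assemble_diffusion(matrix(a, 1), 0.18, 0.045)
    M <- matrix(c(tt[1, 1], tt[1, 4], tt[1, 5],
                  tt[1, 4], tt[1, 2], tt[1, 6],
                  tt[1, 5], tt[1, 6], tt[1, 3]), 3)
    ev <- sort(eigen(M, symmetric = TRUE)$values)
    expect_equal(ev, c(0.045, 0.045, 0.18), tolerance = 1e-12)
  }
  expect_error(assemble_diffusion(matrix(c(1, 1, 0), 1), 0.18, 0.045),
               "unit")
})

test_that("a uniform resting field stays uniform without stimulation", {
  g <- make_cable_grid(12, 1, "EPI")
  g$dims <- c(12L, 1L, 1L)
  diff_field <- assemble_diffusion(g$fiber, 0.18, 0.045)
  sched <- stimulus_schedule(center = matrix(c(-100, 0, 0), ncol = 3),
                             extent = 0.1, onset = 0, amplitude = 0,
                             window = 120)
  rec <- run_tissue(g, diff_field, sched, t_end = 100,
                    snapshot_times = seq(10, 100, 10))
  expect_lt(max(abs(rec$V - rec$V[1, 1])), 0.1)
})

test_that("passive diffusion conserves the spatial mean under no-flux boundaries", {
  n <- 40
  g <- make_cable_grid(n, 0.5, "EPI")
  diff_field <- assemble_diffusion(g$fiber, 0.18, 0.045)
  sched <- stimulus_schedule(center = matrix(c(-100, 0, 0), ncol = 3),
                             extent = 0.1, onset = 0, amplitude = 0,
                             window = 100)
  v0 <- exp(-((seq_len(n) - n / 2)^2) / 20) * 50 - 80
  rec <- run_tissue(g, diff_field, sched, t_end = 50,
                    snapshot_times = c(25, 50), passive = TRUE, v_init = v0)
  drift <- abs(mean(rec$V[, 2]) - mean(v0)) / abs(mean(v0))
  expect_lt(drift, 1e-6)
})

test_that("the cable propagates at ~70 cm/s along fibers at study settings", {
  cv <- cable_cv(0.5, 0.18, 0.045, len = 50, t_end = 150, extent = 3)
  expect_lt(abs(cv - 70) / 70, 0.05)
})

test_that("transverse propagation matches an equivalent 1D cable and the sqrt(D) law", {
  # a cable with fibers orthogonal to the propagation axis must propagate at
  # the transverse coefficient: identical to a 1D cable run at D_perp
  cv_rot <- cable_cv(0.5, 0.18, 0.045, fiber_axis = c(0, 1, 0),
                     len = 40, t_end = 250)
  cv_1d <- cable_cv(0.5, 0.045, 0.045, len = 40, t_end = 250)
  expect_lt(abs(cv_rot - cv_1d) / cv_1d, 0.02)
  # near the continuum limit the 4:1 coefficient ratio gives a 2:1 velocity
  # ratio (CV proportional to sqrt(D))
  cv_par <- cable_cv(0.1, 0.18, 0.045, len = 30, t_end = 120)
  cv_perp <- cable_cv(0.1, 0.045, 0.045, len = 25, t_end = 220)
  expect_lt(abs(cv_perp / cv_par - 0.5), 0.05)
})

test_that("halving the maximum step changes conduction velocity by < 2%", {
  base <- cable_cv(0.5, 0.18, 0.045, len = 40, t_end = 150, extent = 3)
  n <- 80
  g <- make_cable_grid(n, 0.5, "EPI")
  diff_field <- assemble_diffusion(g$fiber, 0.18, 0.045)
  sched <- stimulus_schedule(center = matrix(c(0.25, 0, 0), ncol = 3),
                             extent = 3, onset = 0, window = 200)
  rec <- run_tissue(g, diff_field, sched, opts = solver_options(dt_max = 0.1),
                    t_end = 150, record = 1L, snapshot_times = 150,
                    stop_margin = 5)
  p1 <- round(0.25 * n); p2 <- round(0.75 * n)
  cv_half <- (p2 - p1) * 0.5 / (rec$act_time[p2] - rec$act_time[p1]) * 100
  expect_lt(abs(cv_half - base) / base, 0.02)
})

test_that("adaptive stepping matches the fixed minimum step to < 0.5 mV", {
  g <- make_cable_grid(60, 0.5, "EPI")
  diff_field <- assemble_diffusion(g$fiber, 0.18, 0.045)
  sched <- stimulus_schedule(center = matrix(c(0.25, 0, 0), ncol = 3),
                             extent = 3, onset = 0, window = 420)
  snaps <- seq(2, 400, by = 2)
  r_fix <- run_tissue(g, diff_field, sched, opts = solver_options(dt_max = 0.02),
                      t_end = 410, snapshot_times = snaps)
  r_ad <- run_tissue(g, diff_field, sched, t_end = 410, snapshot_times = snaps)
  expect_lt(max(abs(r_ad$V - r_fix$V)), 0.5)
  expect_lt(r_ad$steps, r_fix$steps)  # adaptivity actually engages
})

test_that("conduction velocity measurement recovers constructed wave speeds", {
  # two sigmoid upstrokes delayed by exactly 1 ms over 0.7 mm -> 70 cm/s
  tt <- seq(0, 20, by = 0.05)
  up <- function(t0) -80 + 100 / (1 + exp(-(tt - t0) * 4))
  rec <- structure(list(times = tt,
                        V = rbind(up(5), up(6)),
                        record = c(1L, 2L),
                        grid_ref = NULL),
                   class = "ecgi_recordings")
  pos <- rbind(c(0, 0, 0), c(0.7, 0, 0))
  expect_equal(measure_cv(rec, c(1L, 2L), positions = pos), 70, tolerance = 1e-6)
  # identical traces: zero delay is an error
  rec2 <- rec; rec2$V <- rbind(up(5), up(5))
  expect_error(measure_cv(rec2, c(1L, 2L), positions = pos), "delay")
  # a probe that never activates is an error
  rec3 <- rec; rec3$V[2, ] <- -80
  expect_error(measure_cv(rec3, c(1L, 2L), positions = pos), "activate")
  # planar wave train sampled at 0.25 mm: imposed speed recovered to < 1%
  xs <- seq(0, 10, by = 0.25)
  speed <- 0.5  # mm/ms
  recw <- structure(list(times = tt,
                         V = t(sapply(xs, function(x) up(2 + x / speed))),
                         record = seq_along(xs), grid_ref = NULL),
                    class = "ecgi_recordings")
  posw <- cbind(xs, 0, 0)
  cvw <- measure_cv(recw, c(5L, 35L), positions = posw[c(5, 35), ])
  expect_lt(abs(cvw - speed * 100) / (speed * 100), 0.01)
})
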