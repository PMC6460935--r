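# shared fixtures, built once per test run

normalize_unit <- function(v) v / sqrt(sum(v^2))

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# labeled control geometry at the coarse study resolution (4/3 mm)
coarse_grid <- function() {
  fixture("coarse_grid", function()
    build_labeled_geometry(geometry_params(resolution = 4 / 3)))
}

# concentric-spheres inverse fixture: epi sphere a = 60 inside torso sphere
# b = 100, with a 128-electrode subset
spheres_fixture <- function() {
  fixture("spheres", function() {
    a <- 60; b <- 100
    epi <- icosphere(3); epi$vertices <- epi$vertices * a
    torso <- icosphere(3); torso$vertices <- torso$vertices * b
    tm <- build_transfer_matrix(epi, torso)
    set.seed(3)
    el <- sort(sample(nrow(torso$vertices), 128))
    v <- epi$vertices / a
    phiH <- 2 * exp(-((v[, 1] - 0.6)^2 + v[, 2]^2 + (v[, 3] - 0.6)^2) * 3) +
      0.5 * v[, 3]
    list(a = a, b = b, epi = epi, torso = torso, transfer = tm,
         electrodes = el, Ze = transfer_at_electrodes(tm, el), phiH = phiH)
  })
}

# planar slab grid for the transmural-depth closed form: tissue occupying
# z-layers [k0, k1], cavity below, exterior above
slab_grid <- function(nz_wall = 20, dx = 0.5) {
  nx <- 8; ny <- 8
  nz <- nz_wall + 8
  mask <- array(FALSE, c(nx, ny, nz))
  cavity <- array(FALSE, c(nx, ny, nz))
  mask[, , 5:(4 + nz_wall)] <- TRUE
  cavity[, , 1:4] <- TRUE
  structure(list(dims = c(nx, ny, nz), dx = dx,
                 origin = c(dx / 2, dx / 2, dx / 2),
                 tissue_idx = which(mask), mask = mask, cavity = cavity,
                 chamber = rep(1L, sum(mask)),
                 params = list(z_base = Inf)),
            class = "ecgi_grid")
}

cable_cv <- function(dx, d_par, d_perp = d_par, fiber_axis = 1,
                     len = 50, t_end = 300, extent = 6) {
  n <- round(len / dx)
  g <- make_cable_grid(n, dx, "EPI", fiber_axis = fiber_axis)
  diff_field <- assemble_diffusion(g$fiber, d_par, d_perp)
  sched <- stimulus_schedule(center = matrix(c(dx / 2, 0, 0), ncol = 3),
                             extent = extent, onset = 0, window = t_end + 50)
  rec <- run_tissue(g, diff_field, sched, t_end = t_end, record = 1L,
                    snapshot_times = t_end, stop_margin = 5)
  p1 <- round(0.25 * n); p2 <- round(0.75 * n)
  (p2 - p1) * dx / (rec$act_time[p2] - rec$act_time[p1]) * 100
}
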