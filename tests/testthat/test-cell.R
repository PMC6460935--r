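test_that("regional conductance multipliers follow the stated heterogeneities", {
  expect_equal(cell_params("EPI", 1)$gkr_mult, 1.6)
  expect_equal(cell_params("ENDO", 1)$gkr_mult, 1.0)
  expect_equal(cell_params("MCELL", 1)$gkr_mult, 1.0)
  basal <- cell_params("EPI", 0)
  expect_equal(basal$gto_mult, 0.5)
  expect_equal(basal$gks_mult, 0.5)
  apex <- cell_params("EPI", 1)
  expect_equal(apex$gto_mult, 1)
  expect_equal(apex$gks_mult, 1)
  sap <- cell_params("EPI", 1, short_ap = TRUE)
  expect_equal(sap$gkr_mult, 1.6 * 5)
  expect_equal(sap$gks_mult, 5)
  expect_error(cell_params("EPI", 1.2))
  expect_error(cell_params("EPI", -0.1))
})

test_that("the fixed-step integrator matches an adaptive ODE reference", {
  skip_if_not_installed("deSolve")
  # unmodified epicardial cell, one paced beat from standard initial state
  p <- structure(list(celltype = 2L, gto_mult = 1, gks_mult = 1,
                      gkr_mult = 1), class = "ecgi_cell_params")
  tr <- simulate_single_cell(p, bcl = 600, n_beats = 1, sample_dt = 0.1)
  ref <- tt06_reference_beat(celltype = 2, t_end = 600)
  expect_lt(abs(compute_apd(tr) - compute_apd(ref)), 5)
  expect_lt(abs(max(tr$V) - max(ref$V)), 3)
  expect_lt(abs(min(tr$V) - min(ref$V)), 1)
})

test_that("an unstimulated cell settles at the resting potential", {
  tr <- simulate_single_cell(cell_params("EPI"), bcl = 2000, n_beats = 1,
                             stim_amp = 0)
  n <- nrow(tr)
  dv <- abs(diff(tr$V[(n - 100):n])) / 0.1
  expect_lt(max(dv), 0.01)
  expect_lt(abs(tr$V[n] - (-86.2)), 2)
})

test_that("transmural and apico-basal heterogeneity order the APDs correctly", {
  apd <- function(ct, f, sap = FALSE) {
    tr <- simulate_single_cell(cell_params(ct, f, sap), bcl = 1000,
                               n_beats = 15, record_from = 14000)
    compute_apd(tr)
  }
  apd_endo <- apd("ENDO", 1)
  apd_epi <- apd("EPI", 1)
  expect_gt(apd_endo, apd_epi)       # I_Kr 1.0:1.6:1.0 makes ENDO longer
  apd_basal <- apd("EPI", 0)
  expect_gt(apd_basal - apd_epi, 30) # basal cells roughly 50 ms longer
  expect_lt(apd_basal - apd_epi, 70)
  expect_lt(apd("EPI", 1, sap = TRUE), apd_epi)  # short-AP variant shortens
})

test_that("the short-AP variant sustains 1:1 capture at BCL 150 ms", {
  tr <- simulate_single_cell(cell_params("EPI", 1, short_ap = TRUE),
                             bcl = 150, n_beats = 12, record_from = 150 * 8,
                             sample_dt = 0.5)
  # each of the last 4 cycles must contain a full AP (overshoot above 0 mV)
  for (k in 8:11) {
    seg <- tr$V[tr$time >= k * 150 & tr$time < (k + 1) * 150]
    expect_gt(max(seg), 0)
    expect_lt(min(seg), -60)
  }
})

test_that("gate variables stay within [0, 1] across pacing protocols", {
  for (args in list(list(bcl = 1000, n = 3, sap = FALSE),
                    list(bcl = 300, n = 6, sap = FALSE),
                    list(bcl = 150, n = 8, sap = TRUE))) {
    tr <- simulate_single_cell(cell_params("MCELL", 0.5, args$sap),
                               bcl = args$bcl, n_beats = args$n)
    gates <- attr(tr, "state")[2:14]
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(all(attr(tr, "state")[15:19] > 0))  # concentrations positive
  }
})

test_that("APD measurement handles constructed traces exactly", {
  # square pulse of width w
  t <- seq(0, 100, by = 0.1)
  v <- ifelse(t >= 10 & t < 40, 20, -80)
  expect_lt(abs(compute_apd(data.frame(time = t, V = v)) - 30), 0.2)
  # monotone rising trace has no repolarization
  expect_error(compute_apd(data.frame(time = t, V = t)), "crossing|upstroke")
  # triangular AP: rise at t=10 to peak 20, linear fall to -80 at t=110;
  # APD90 crossing of -70 at t = 10 + 90
  t2 <- seq(0, 120, by = 0.5)
  v2 <- ifelse(t2 < 10, -80, ifelse(t2 < 11, -80 + 100 * (t2 - 10),
                                    pmax(20 - (t2 - 11), -80)))
  apd <- compute_apd(data.frame(time = t2, V = v2), level = 0.9)
  expect_lt(abs(apd - (11 - 10.5 + 90)), 1.0)
})
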