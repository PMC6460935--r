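test_that("RMS, rRMSe and PCC match hand-computed values", {
  expect_equal(rms(c(3, 4)), sqrt(25 / 2))
  expect_equal(rms(rep(2, 5)), 2)
  expect_equal(rms(numeric(3)), 0)
  expect_error(rms(numeric(0)))
  expect_equal(rrmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rrmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rrmse(c(0, 2), c(1, 1)), sqrt(2) / sqrt(2))
  expect_error(rrmse(c(1, 2), c(0, 0)), "zero")
  expect_equal(pcc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pcc(c(1, 2, 3), -c(1, 2, 3)), -1)
  expect_equal(round(pcc(c(1, 2, 4), c(1, 2, 3)), 4), 0.9820)
  expect_error(pcc(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("PCC is invariant under positive affine rescaling", {
  set.seed(31)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pcc(2.7 * a + 3, b), pcc(a, b))
  expect_equal(pcc(a, 0.3 * b - 10), pcc(a, b))
})

test_that("activation maps find the extremal-slope time per node", {
  tt <- seq(0, 40, by = 0.5)
  sig <- function(t0) 1 / (1 + exp(-(tt - t0) * 2))
  pots <- rbind(-sig(10), -sig(17.25), rep(0.5, length(tt)))
  am <- activation_map(pots, tt, mode = "negative")
  expect_lt(abs(am[1] - 10), 0.5)
  expect_lt(abs(am[2] - 17.25), 0.5)
  expect_true(is.na(am[3]))                     # flat trace undefined
  expect_equal(am[2] - am[1], 7.25, tolerance = 0.51)  # time shift preserved
  # transmembrane convention: maximum positive slope
  am_up <- activation_map(rbind(sig(12)), tt, mode = "positive")
  expect_lt(abs(am_up[1] - 12), 0.5)
  expect_error(activation_map(pots[, 1:2], tt[1:2]))
})

test_that("focal localization distance is the earliest-centroid separation", {
  pos <- as.matrix(expand.grid(x = seq(0, 20, 2), y = seq(0, 20, 2), z = 0))
  d1 <- sqrt((pos[, 1] - 4)^2 + (pos[, 2] - 10)^2)
  map1 <- 5 + d1  # activation spreading from (4, 10)
  expect_equal(focus_localization_ed(map1, map1, pos), 0)
  # translating the focus by exactly 5 mm translates the centroid by 5 mm
  d2 <- sqrt((pos[, 1] - 9)^2 + (pos[, 2] - 10)^2)
  map2 <- 5 + d2
  ed <- focus_localization_ed(map2, map1, pos, window = 1.9)
  expect_equal(ed, 5, tolerance = 0.3)
  expect_equal(focus_localization_ed(map1, map2, pos, window = 1.9), ed,
               tolerance = 1e-9)  # symmetric
  empty <- rep(NA_real_, nrow(pos))
  expect_error(focus_localization_ed(empty, map1, pos), "no defined nodes")
})

test_that("noise injection is seeded, scaled, and honours the SNR", {
  set.seed(41)
  bsp <- matrix(rnorm(100 * 100), 100)
  n1 <- add_noise(bsp, 20, seed = 9)
  n2 <- add_noise(bsp, 20, seed = 9)
  expect_identical(n1, n2)
  n3 <- add_noise(bsp, 20, seed = 10)
  expect_false(identical(n1, n3))
  expect_identical(add_noise(bsp, Inf), bsp)
  noise <- n1 - bsp
  snr_emp <- 10 * log10(mean(bsp^2) / mean(noise^2))
  expect_lt(abs(snr_emp - 20), 0.5)
  expect_error(add_noise(matrix(0, 4, 4), 10), "zero-power")
})

test_that("noise degrades accuracy but preserves the order ranking", {
  fx <- spheres_fixture()
  y <- cbind(fx$Ze %*% fx$phiH)
  yn <- add_noise(y, 20, seed = 2)
  pcc_clean <- numeric(3); pcc_noisy <- numeric(3)
  err_clean <- numeric(3); err_noisy <- numeric(3)
  for (ord in 0:2) {
    s0 <- reconstruct_timeseries(fx$Ze, y, ord, fx$epi)
    s1 <- reconstruct_timeseries(fx$Ze, yn, ord, fx$epi)
    pcc_clean[ord + 1] <- pcc(s0$X[, 1], fx$phiH)
    pcc_noisy[ord + 1] <- pcc(s1$X[, 1], fx$phiH)
    err_clean[ord + 1] <- rrmse(s0$X[, 1], fx$phiH)
    err_noisy[ord + 1] <- rrmse(s1$X[, 1], fx$phiH)
  }
  expect_lt(mean(pcc_noisy), mean(pcc_clean))
  expect_lt(err_clean[3], err_clean[1])
  expect_lt(err_noisy[3], err_noisy[1])   # order-2 < order-0 maintained
})

test_that("snapshot metrics assemble a per-time comparison table", {
  set.seed(51)
  X <- matrix(rnorm(30), 10)
  Xr <- X + matrix(rnorm(30, sd = 0.1), 10)
  sm <- snapshot_metrics(X, Xr, times = c(2, 4, 6))
  expect_equal(nrow(sm), 3)
  expect_true(all(sm$pcc > 0.8))
  expect_true(all(sm$rrmse >= 0))
  expect_equal(sm$time, c(2, 4, 6))
})
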