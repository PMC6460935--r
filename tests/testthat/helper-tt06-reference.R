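# Independent reference implementation of the ten Tusscher-Panfilov (2006)
# human ventricular model as a plain ODE system integrated with deSolve
# (adaptive lsoda), used as an oracle for the package's fixed-step
# Rush-Larsen integrator. Rapid calcium buffering is expressed through the
# standard beta factors so the algebraic buffering update of the production
# code corresponds to an equivalent ODE here.

tt06_reference_derivs <- function(t, y, p) {
  R <- 8314.472; Temp <- 310; F <- 96485.3415
  RTONF <- R * Temp / F
  CAP <- 0.185
  Vc <- 0.016404; Vsr <- 0.001094; Vss <- 0.00005468
  Bufc <- 0.2; Kbufc <- 0.001; Bufsr <- 10; Kbufsr <- 0.3
  Bufss <- 0.4; Kbufss <- 0.00025
  Vmaxup <- 0.006375; Kup <- 0.00025
  Vrel <- 0.102; k1p <- 0.15; k2p <- 0.045; k3 <- 0.060; k4 <- 0.005
  EC <- 1.5; maxsr <- 2.5; minsr <- 1
  Vleak <- 0.00036; Vxfer <- 0.0038
  Ko <- 5.4; Cao <- 2; Nao <- 140
  GK1 <- 5.405; pKNa <- 0.03; GNa <- 14.838; GbNa <- 0.00029
  KmK <- 1; KmNa <- 40; knak <- 2.724
  GCaL <- 0.00003980; GbCa <- 0.000592
  knaca <- 1000; KmNai <- 87.5; KmCa <- 1.38; ksat <- 0.1; ncax <- 0.35
  GpCa <- 0.1238; KpCa <- 0.0005; GpK <- 0.0146

  V <- y[1]; m <- y[2]; h <- y[3]; j <- y[4]; xr1 <- y[5]; xr2 <- y[6]
  xs <- y[7]; r <- y[8]; s <- y[9]; d <- y[10]; f <- y[11]; f2 <- y[12]
  fcass <- y[13]; rr <- y[14]; cai <- y[15]; casr <- y[16]; cass <- y[17]
  nai <- y[18]; ki <- y[19]

  Ek <- RTONF * log(Ko / ki)
  Ena <- RTONF * log(Nao / nai)
  Eks <- RTONF * log((Ko + pKNa * Nao) / (ki + pKNa * nai))
  Eca <- 0.5 * RTONF * log(Cao / cai)

  Ak1 <- 0.1 / (1 + exp(0.06 * (V - Ek - 200)))
  Bk1 <- (3 * exp(0.0002 * (V - Ek + 100)) + exp(0.1 * (V - Ek - 10))) /
    (1 + exp(-0.5 * (V - Ek)))
  IK1 <- GK1 * Ak1 / (Ak1 + Bk1) * (V - Ek)
  IKr <- p$Gkr * xr1 * xr2 * (V - Ek)
  IKs <- p$Gks * xs^2 * (V - Eks)
  Ito <- p$Gto * r * s * (V - Ek)
  INa <- GNa * m^3 * h * j * (V - Ena)
  IbNa <- GbNa * (V - Ena)
  vm15 <- V - 15
  e1 <- exp(2 * vm15 / RTONF)
  ICaL <- GCaL * d * f * f2 * fcass * 4 * vm15 * (F / RTONF) *
    (0.25 * e1 * cass - Cao) / (e1 - 1)
  IbCa <- GbCa * (V - Eca)
  INaK <- knak * (Ko / (Ko + KmK)) * (nai / (nai + KmNa)) /
    (1 + 0.1245 * exp(-0.1 * V / RTONF) + 0.0353 * exp(-V / RTONF))
  INaCa <- knaca * (1 / (KmNai^3 + Nao^3)) * (1 / (KmCa + Cao)) *
    (1 / (1 + ksat * exp((ncax - 1) * V / RTONF))) *
    (exp(ncax * V / RTONF) * nai^3 * Cao -
       exp((ncax - 1) * V / RTONF) * Nao^3 * cai * 2.5)
  IpCa <- GpCa * cai / (KpCa + cai)
  IpK <- GpK * (V - Ek) / (1 + exp((25 - V) / 5.98))

  Istim <- if (t >= p$stim_start && t < p$stim_start + p$stim_dur) p$stim_amp else 0
  Iion <- INa + IK1 + IKr + IKs + Ito + ICaL + IbNa + IbCa + INaK + INaCa +
    IpCa + IpK
  dV <- -(Iion + Istim)

  # gates
  minf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tm <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.10 / (1 + exp((V - 50) / 200)))
  hinf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V >= -40) {
    ah <- 0; bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
    aj <- 0; bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  } else {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 310000 * exp(0.3485 * V)
    aj <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  }
  th <- 1 / (ah + bh); tj <- 1 / (aj + bj)
  xr1inf <- 1 / (1 + exp((-26 - V) / 7))
  txr1 <- 450 / (1 + exp((-45 - V) / 10)) * 6 / (1 + exp((V + 30) / 11.5))
  xr2inf <- 1 / (1 + exp((V + 88) / 24))
  txr2 <- 3 / (1 + exp((-60 - V) / 20)) * 1.12 / (1 + exp((V - 60) / 20))
  xsinf <- 1 / (1 + exp((-5 - V) / 14))
  txs <- 1400 / sqrt(1 + exp((5 - V) / 6)) / (1 + exp((V - 35) / 15)) + 80
  rinf <- 1 / (1 + exp((20 - V) / 6))
  tr <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  if (p$celltype == 0) {
    sinf <- 1 / (1 + exp((V + 28) / 5))
    ts <- 1000 * exp(-(V + 67)^2 / 1000) + 8
  } else {
    sinf <- 1 / (1 + exp((V + 20) / 5))
    ts <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  }
  dinf <- 1 / (1 + exp((-8 - V) / 7.5))
  td <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) * 1.4 / (1 + exp((V + 5) / 5)) +
    1 / (1 + exp((50 - V) / 20))
  finf <- 1 / (1 + exp((V + 20) / 7))
  tf <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tf2 <- 600 * exp(-(V + 25)^2 / 170) + 31 / (1 + exp((25 - V) / 10)) +
    16 / (1 + exp((V + 30) / 10))
  fcinf <- 0.6 / (1 + (cass / 0.05)^2) + 0.4
  tfc <- 80 / (1 + (cass / 0.05)^2) + 2

  kcasr <- maxsr - (maxsr - minsr) / (1 + (EC / casr)^2)
  k1 <- k1p / kcasr; k2 <- k2p * kcasr
  drr <- k4 * (1 - rr) - k2 * cass * rr
  OO <- k1 * cass^2 * rr / (k3 + k1 * cass^2)
  Irel <- Vrel * OO * (casr - cass)
  Ileak <- Vleak * (casr - cai)
  Iup <- Vmaxup / (1 + Kup^2 / cai^2)
  Ixfer <- Vxfer * (cass - cai)

  beta_c <- 1 / (1 + Bufc * Kbufc / (Kbufc + cai)^2)
  beta_sr <- 1 / (1 + Bufsr * Kbufsr / (Kbufsr + casr)^2)
  beta_ss <- 1 / (1 + Bufss * Kbufss / (Kbufss + cass)^2)
  dcai <- beta_c * ((-(IbCa + IpCa - 2 * INaCa) / (2 * Vc * F) * CAP) -
                      (Iup - Ileak) * (Vsr / Vc) + Ixfer)
  dcasr <- beta_sr * (Iup - Irel - Ileak)
  dcass <- beta_ss * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) -
                        ICaL / (2 * Vss * F) * CAP)
  dnai <- -(INa + IbNa + 3 * INaK + 3 * INaCa) / (Vc * F) * CAP
  dki <- -(Istim + IK1 + Ito + IKr + IKs - 2 * INaK + IpK) / (Vc * F) * CAP

  list(c(dV,
         (minf - m) / tm, (hinf - h) / th, (hinf - j) / tj,
         (xr1inf - xr1) / txr1, (xr2inf - xr2) / txr2, (xsinf - xs) / txs,
         (rinf - r) / tr, (sinf - s) / ts, (dinf - d) / td,
         (finf - f) / tf, (f2inf - f2) / tf2, (fcinf - fcass) / tfc,
         drr, dcai, dcasr, dcass, dnai, dki))
}

tt06_reference_beat <- function(celltype = 2, gkr_mult = 1, gks_mult = 1,
                                gto_mult = 1, t_end = 600,
                                stim_amp = -52, stim_dur = 1) {
  y0 <- c(-86.2, 0, 0.75, 0.75, 0, 1, 0, 0, 1, 0, 1, 1, 1, 1,
          0.00007, 1.3, 0.00007, 7.67, 138.3)
  p <- list(celltype = celltype,
            Gkr = 0.153 * gkr_mult,
            Gks = (if (celltype == 1) 0.098 else 0.392) * gks_mult,
            Gto = (if (celltype == 0) 0.073 else 0.294) * gto_mult,
            stim_start = 0, stim_dur = stim_dur, stim_amp = stim_amp)
  times <- seq(0, t_end, by = 0.1)
  out <- deSolve::lsoda(y0, times, tt06_reference_derivs, p,
                        rtol = 1e-8, atol = 1e-8, hmax = 0.5)
  data.frame(time = out[, 1], V = out[, 2])
}
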