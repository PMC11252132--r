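# Closed-form relaxation equations and spectral densities.

test_that("field context derives the interaction constants correctly", {
  k <- physical_constants()
  expect_equal(k$gammaN, -27.116e6)
  expect_equal(k$rNH, 1.02)
  expect_equal(k$deltaSigma, 172)
  expect_equal(k$theta, 17)
  f <- make_field_context(900, k)
  # Larmor ratio forced by the gyromagnetic ratios
  expect_equal(f$omegaN / f$omegaH, abs(k$gammaN) / k$gammaH)
  expect_equal(f$omegaH, 2 * pi * 900e6)
  # independent hand evaluation of the printed constant expressions
  r3 <- (1.02e-10)^3
  d_hand <- (4 * pi * 1e-7) * 6.62607e-34 * 27.116e6 * 267.522e6 /
    (8 * pi^2 * r3)
  c_hand <- 172e-6 * f$omegaN / sqrt(3)
  expect_equal(f$d, d_hand, tolerance = 1e-12)
  expect_equal(f$c, c_hand, tolerance = 1e-12)
  expect_equal(f$p, d_hand / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(f$deltaN, f$c / sqrt(6), tolerance = 1e-12)
  expect_error(make_field_context(-1), "positive")
})

test_that("isotropic spectral density has the closed-form limits", {
  tau <- 27.8e-9
  expect_equal(jw_isotropic(0, tau), 2 * tau / 5)
  expect_equal(jw_isotropic(1 / tau, tau), tau / 5)
  # direct arithmetic oracle
  w <- 5.73e8
  expect_equal(jw_isotropic(w, tau), 0.4 * tau / (1 + (w * tau)^2))
  expect_error(jw_isotropic(1, -1), "positive")
})

test_that("Woessner axial expansion reproduces the analytic weights", {
  tens <- diffusion_tensor(0.56e7, 0.77e7, alpha = 0, beta = 0)
  # axis vector: A = (1, 0, 0)
  e0 <- expand_axial(tens, c(0, 0, 1))
  expect_equal(e0$weights, cbind(1, 0, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  # perpendicular: A = (1/4, 0, 3/4)
  e90 <- expand_axial(tens, c(1, 0, 0))
  expect_equal(e90$weights, cbind(0.25, 0, 0.75), ignore_attr = TRUE,
               tolerance = 1e-12)
  # correlation times 1/(6 Dperp + k^2 (Dpar - Dperp))
  expect_equal(e0$times,
               1 / (6 * 0.56e7 + (0:2)^2 * (0.77e7 - 0.56e7)))
  expect_error(expand_axial(tens, c(1, 1, 0)), "unit")
})

test_that("weights normalize and the isotropic limit matches exactly", {
  set.seed(42)
  for (i in 1:200) {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    tens <- diffusion_tensor(10^runif(1, 6.5, 7.5), 10^runif(1, 6.5, 7.5),
                             runif(1, 0, 360), runif(1, 0, 180))
    e <- expand_axial(tens, v)
    expect_equal(sum(e$weights), 1, tolerance = 1e-12)
    expect_true(all(e$times > 0))
  }
  # Dpar = Dperp: equals the isotropic form for random (omega, D)
  for (i in 1:200) {
    D <- 10^runif(1, 6, 8); w <- 10^runif(1, 6, 10)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    e <- expand_axial(diffusion_tensor(D, D), v)
    expect_equal(jw_aniso(e, w), jw_isotropic(w, 1 / (6 * D)),
                 tolerance = 1e-12)
  }
})

test_that("axial spectral density matches a rotational-diffusion Monte Carlo oracle", {
  # brute force: propagate anisotropic rotational Brownian motion in the
  # body frame and average P2(u(0).u(t)); compare with sum A_k exp(-t/tau_k)
  Dperp <- 2e7; Dpar <- 6e7          # strong anisotropy, short tau for speed
  u0 <- c(sin(1.1), 0, cos(1.1))     # 63 deg off the symmetry axis
  tens <- diffusion_tensor(Dperp, Dpar, 0, 0)
  e <- expand_axial(tens, u0)
  dt <- 2e-10; nstep <- 40; ntraj <- 4000
  set.seed(7)
  sds <- sqrt(2 * c(Dperp, Dperp, Dpar) * dt)
  corr <- matrix(0, ntraj, nstep)
  for (m in seq_len(ntraj)) {
    R <- diag(3)
    for (s in seq_len(nstep)) {
      phi <- rnorm(3, 0, sds)
      th <- sqrt(sum(phi^2)); ax <- phi / th
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                  3, 3)
      R <- R %*% (diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K)
      cosang <- sum((R %*% u0) * u0)
      corr[m, s] <- 1.5 * cosang^2 - 0.5
    }
  }
  mc <- colMeans(corr)
  t <- dt * seq_len(nstep)
  analytic <- vapply(t, function(tt)
    sum(as.vector(e$weights) * exp(-tt / e$times)), numeric(1))
  expect_lt(max(abs(mc - analytic)), 0.02)
})

test_that("predicted rates obey limits, Eq-7 behaviour and the CCR truncation bound", {
  f9 <- make_field_context(900)
  tau <- 26.5e-9
  jf <- function(w) jw_isotropic(w, tau)
  r <- predict_rates(jf, f9)
  expect_true(r$R1 > 0 && r$R2 > 0 && r$eta_xy > 0 && r$NOE < 1)
  # magic angle zeroes eta_xy (exactly at acos(1/sqrt(3)), and to the
  # rounding of the 4-decimal printed angle)
  kmag <- physical_constants(theta = acos(1 / sqrt(3)) * 180 / pi)
  rmag <- predict_rates(jf, make_field_context(900, kmag))
  expect_lt(abs(rmag$eta_xy), 1e-12 * r$eta_xy)
  k4 <- physical_constants(theta = 54.7356)
  r4 <- predict_rates(jf, make_field_context(900, k4))
  expect_lt(abs(r4$eta_xy), 1e-6 * r$eta_xy)
  # low-frequency approximation: exact 1/6 prefactor on truncated rates;
  # against the full rates the deviation is the high-frequency R1 fraction
  # (about 1.2 percent, weakly dependent on field and tauC)
  for (fmhz in c(800, 900)) {
    fc <- make_field_context(fmhz)
    for (tns in c(10, 20, 26.5, 40)) {
      jt <- function(w) jw_isotropic(w, tns * 1e-9)
      rr <- predict_rates(jt, fc)
      full <- rr$R2 / rr$R1
      eq7 <- r2r1_from_tauc(tns, fc)
      expect_lt(abs(full - eq7) / full, 0.02)
      # truncated-rate ratio equals Eq. 7 exactly
      J0 <- jt(0); JN <- jt(fc$omegaN)
      r1t <- (3 * fc$d^2 / 4 + fc$c^2) * JN
      r2t <- (fc$d^2 / 8 + fc$c^2 / 6) * (4 * J0 + 3 * JN)
      expect_equal(r2t / r1t, eq7, tolerance = 1e-12)
    }
  }
  # high-frequency CCR term below 1 percent for slow tumbling
  for (tns in c(20, 26.5, 35)) {
    JN <- jw_isotropic(f9$omegaN, tns * 1e-9)
    J0 <- jw_isotropic(0, tns * 1e-9)
    expect_lt(100 * 3 * JN / (4 * J0), 1)
  }
  # extreme narrowing: NOE approaches the dipolar closed form
  taus <- 1e-12
  js <- function(w) jw_isotropic(w, taus)
  rs <- predict_rates(js, make_field_context(900))
  k <- physical_constants()
  noe_oracle <- 1 + (f9$d^2 / (4 * rs$R1)) * (k$gammaH / k$gammaN) *
    (6 * js(f9$omegaH + f9$omegaN) - js(f9$omegaH - f9$omegaN))
  expect_equal(rs$NOE, noe_oracle, tolerance = 1e-12)
})

test_that("R2/R1 <-> tauC conversions invert each other and match arithmetic", {
  f9 <- make_field_context(900)
  # printed intercept
  expect_equal(r2r1_from_tauc(1e-9, f9), 7 / 6, tolerance = 1e-3)
  # round trip
  for (tau in c(5, 15, 26.5, 40)) {
    expect_equal(tauc_from_r2r1(r2r1_from_tauc(tau, f9), f9), tau,
                 tolerance = 1e-12)
  }
  # direct arithmetic oracle at the published frequency
  hand <- (2 / 3) * (2 * pi * 91.2239e6 * 26.5e-9)^2 + 7 / 6
  expect_equal(r2r1_from_tauc(26.5, f9), hand, tolerance = 1e-4)
  expect_equal(round(r2r1_from_tauc(26.5, f9)), 155)
  expect_error(tauc_from_r2r1(1.0, f9), "7/6")
})

test_that("tauC from tensor components matches the published pairing", {
  expect_equal(tauc_from_tensor(diffusion_tensor(0.56e7, 0.77e7)),
               26.5, tolerance = 0.05 / 26.5)
  # isotropic identity 6 D tau = 1 => tauC = tau
  D <- 1e7
  expect_equal(tauc_from_tensor(diffusion_tensor(D, D)), 1e9 / (6 * D))
  expect_equal(tauc_from_tensor(diffusion_tensor(1e7, 1e7)), 16.7,
               tolerance = 1e-2)
})

test_that("tauC recovery from eta_xy is accurate to the truncation bound", {
  f9 <- make_field_context(900)
  tau <- 27.8e-9
  r <- predict_rates(function(w) jw_isotropic(w, tau), f9)
  # eta_xy built by the same truncated expression, S2 = 1: < 1% deviation
  expect_lt(abs(tauc_from_etaxy(r$eta_xy, 1, f9) - 27.8) / 27.8, 0.01)
  # suppressing the J(omegaN) term makes the inversion exact
  th <- physical_constants()$theta * pi / 180
  eta_j0 <- f9$p * f9$deltaN * 4 * jw_isotropic(0, tau) *
    (3 * cos(th)^2 - 1)
  expect_equal(tauc_from_etaxy(eta_j0, 1, f9), 27.8, tolerance = 1e-12)
  # S2 scales tauC inversely
  expect_equal(tauc_from_etaxy(r$eta_xy, 0.44, f9),
               2 * tauc_from_etaxy(r$eta_xy, 0.88, f9))
  expect_error(tauc_from_etaxy(-1, 0.88, f9), "positive")
  expect_error(
    tauc_from_etaxy(1, 1, make_field_context(900,
      physical_constants(theta = acos(1 / sqrt(3)) * 180 / pi))), "magic")
})

test_that("Rex extraction is consistent, linear in injected exchange, and propagates errors", {
  f9 <- make_field_context(900)
  r <- predict_rates(function(w) jw_isotropic(w, 26.5e-9), f9)
  out <- rex_from_r2_etaxy(r$R2, r$eta_xy, f9, 0.5, 0.3)
  # consistent pair: residual is only the high-frequency dipolar part of R2
  expect_lt(abs(out$Rex), 1e-3 * r$R2)
  # injected exchange comes back additively
  out5 <- rex_from_r2_etaxy(r$R2 + 5, r$eta_xy, f9, 0.5, 0.3)
  expect_equal(out5$Rex - out$Rex, 5, tolerance = 1e-12)
  # quadrature propagation oracle with the printed bracket factor
  th <- 17 * pi / 180
  fac <- (3 * f9$d^2 + 4 * f9$c^2) /
    (2 * sqrt(3) * f9$c * f9$d * (3 * cos(th)^2 - 1))
  expect_equal(out$sigma, sqrt(0.5^2 + (fac * 0.3)^2), tolerance = 1e-12)
  expect_error(rex_from_r2_etaxy(10, 5, f9, 0, 0.1), "positive")
})
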