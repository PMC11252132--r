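# Residue selection, axial tensor fitting, resampling, S2 calibration,
# Rex profiling and domain comparison.

test_that("the four selection criteria fire in order with a full audit trail", {
  geometry <- data.frame(residue = 1:10,
                         ux = 1, uy = 0, uz = 0,
                         bfactor = c(rep(20, 8), 40, 20))
  ratios <- data.frame(residue = 1:10,
                       ratio = c(rep(150, 7), 150, 150, 400),
                       sigma = c(18, rep(3, 9)))
  cfg <- selection_config(overlap_exclusions = 5)
  out <- select_residues(ratios, geometry, cfg, "r2r1_900")
  aud <- out$audit
  expect_equal(aud$criterion[aud$residue == 1], "relative_error")  # 12%
  expect_equal(aud$criterion[aud$residue == 9], "bfactor")          # 40 A^2
  expect_equal(aud$criterion[aud$residue == 5], "overlap")
  expect_equal(aud$criterion[aud$residue == 10], "sd_trim")         # outlier
  expect_setequal(out$selected, c(2, 3, 4, 6, 7, 8))
  # 12% relative error survives in an 800 MHz set (threshold 15%)
  out800 <- select_residues(ratios, geometry, cfg, "r2r1_800")
  expect_true(1 %in% out800$selected)
  expect_error(select_residues(ratios, geometry, cfg, "nope"), "kind")
})

test_that("noiseless synthetic ratios return the generating tensor to optimizer precision", {
  ds <- simulate_relaxation_dataset(relaxation_sim_spec(seed = 2))
  tab <- ds$tables[["900"]]
  fit <- fit_axial_tensor(ratios_from_table(tab), ds$geometry,
                          make_field_context(900))
  expect_lt(abs(fit$tensor$Dperp - 0.56e7) / 0.56e7, 1e-6)
  expect_lt(abs(fit$tensor$Dpar - 0.77e7) / 0.77e7, 1e-6)
  expect_lt(abs(fit$tensor$alpha - 11), 1e-4)
  expect_lt(abs(fit$tensor$beta - 59), 1e-4)
  expect_true(fit$orientation_defined)
})

test_that("isotropic data yield zeta near 1 with the orientation flagged undefined", {
  iso <- relaxation_sim_spec(tensor = diffusion_tensor(0.63e7, 0.63e7),
                             seed = 3)
  ds <- simulate_relaxation_dataset(iso)
  expect_warning(
    fit <- fit_axial_tensor(ratios_from_table(ds$tables[["900"]]),
                            ds$geometry, make_field_context(900)),
    "isotropic")
  expect_equal(fit$tensor$zeta, 1, tolerance = 0.02)
  expect_false(fit$orientation_defined)
})

test_that("orientation is canonical and symmetric starts converge to one answer", {
  # the tensor axis is defined up to sign: (alpha, beta) and
  # (alpha + 180, 180 - beta) are the same tensor
  t1 <- diffusion_tensor(0.5e7, 0.8e7, alpha = 211, beta = 121)
  expect_equal(t1$beta, 59, tolerance = 1e-9)
  expect_equal(t1$alpha, 31, tolerance = 1e-9)
  expect_true(t1$beta >= 0 && t1$beta <= 90)
  spec <- relaxation_sim_spec(tensor = diffusion_tensor(0.56e7, 0.77e7,
                                                        alpha = 211,
                                                        beta = 121))
  ds <- simulate_relaxation_dataset(spec)
  fit <- fit_axial_tensor(ratios_from_table(ds$tables[["900"]]),
                          ds$geometry, make_field_context(900))
  expect_equal(fit$tensor$alpha, 31, tolerance = 1e-3)
  expect_equal(fit$tensor$beta, 59, tolerance = 1e-3)
})

test_that("CCR pseudo-ratios invert exactly and scale inversely with S2", {
  f9 <- make_field_context(900)
  tab <- data.frame(residue = 1:5,
                    eta_xy = c(38, 40, 42, 44, 46),
                    eta_xy_sigma = rep(2, 5))
  pr <- ccr_to_pseudo_ratios(tab, S2 = 0.88, field = f9)
  # algebraic round trip ratio -> tauC -> eta -> ratio
  tau_back <- tauc_from_r2r1(pr$ratio, f9)
  expect_equal(tau_back, pr$tauC, tolerance = 1e-10)
  th <- 17 * pi / 180
  eta_back <- pr$tauC * 1e-9 * (8 * 0.88 * f9$p * f9$deltaN *
                                  (3 * cos(th)^2 - 1)) / 5
  expect_equal(eta_back, tab$eta_xy, tolerance = 1e-10)
  # doubling S2 halves tauC
  pr2 <- ccr_to_pseudo_ratios(tab, S2 = 0.44, field = f9)
  expect_equal(pr2$tauC, 2 * pr$tauC, tolerance = 1e-12)
  expect_error(ccr_to_pseudo_ratios(
    transform(tab, eta_xy = -eta_xy), 0.88, f9), "positive")
})

test_that("S2 calibration equates the dataset means and recovers a known S2", {
  expect_equal(calibrate_s2(c(26, 27), c(26, 27), 0.88), 0.88)
  # CCR tauC running 10 percent high means S2 was 10 percent low
  expect_equal(calibrate_s2(1.10 * c(26, 27), c(26, 27), 0.88),
               0.88 * 1.10, tolerance = 1e-12)
  # synthetic: generate eta at S2 = 0.88, start from a wrong S2
  f9 <- make_field_context(900)
  ds <- simulate_relaxation_dataset(relaxation_sim_spec(seed = 4))
  tab <- ds$tables[["900"]]
  tau_ref <- tauc_from_r2r1(tab$r2 / tab$r1, f9)
  s2_start <- 0.75
  tau_ccr <- tauc_from_etaxy(tab$eta_xy, s2_start, f9)
  s2_new <- calibrate_s2(tau_ccr, tau_ref, s2_start)
  expect_equal(s2_new, 0.88, tolerance = 0.02)
  expect_error(calibrate_s2(numeric(0), 1, 0.88), "non-empty")
})

test_that("delete-d resampling is seeded, scaled by sqrt(n/d), and covers the truth", {
  spec <- relaxation_sim_spec(
    vectors = 100, seed = 11,
    noise = c(r1 = 0.02, r2 = 0.02, noe = 0, eta_xy = 0,
              volume = 0, intensity = 0))
  ds <- simulate_relaxation_dataset(spec)
  ratios <- ratios_from_table(ds$tables[["900"]])
  f9 <- make_field_context(900)
  cfg <- resampling_config(deletion_fraction = 0.20, repeats = 40,
                           seed = 21)
  r1 <- resample_tensor(ratios, ds$geometry, f9, cfg)
  expect_equal(r1$scale_factor, sqrt(5), tolerance = 1e-12)
  # fixed seed: bit-identical uncertainties across runs
  r2 <- resample_tensor(ratios, ds$geometry, f9, cfg)
  expect_identical(r1$uncertainty, r2$uncertainty)
  expect_equal(nrow(r1$resamples), 40)
  # truth within 3 scaled SD (a loose sanity check on one seed)
  expect_lt(abs(r1$tensor$Dperp - 0.56e7), 3 * r1$uncertainty["Dperp"])
  expect_lt(abs(r1$tensor$Dpar - 0.77e7), 3 * r1$uncertainty["Dpar"])
  expect_error(resampling_config(deletion_fraction = 0.6), "0.5")
})

test_that("Rex profile flags injected exchange at the 5-sigma rule only", {
  f9 <- make_field_context(900)
  r <- predict_rates(function(w) jw_isotropic(w, 26.5e-9), f9)
  tab <- data.frame(residue = 1:4,
                    r2 = c(r$R2, r$R2 + 8, r$R2 + 4.9, NA),
                    r2_sigma = 1,
                    eta_xy = r$eta_xy, eta_xy_sigma = 1e-6)
  out <- rex_profile(tab, f9)
  expect_equal(out$profile$significant, c(FALSE, TRUE, FALSE))
  expect_equal(out$profile$Rex[2] - out$profile$Rex[1], 8,
               tolerance = 1e-10)
  expect_equal(out$skipped, 4)
})

test_that("domain comparison is symmetric and separates distinct tensors", {
  f9 <- make_field_context(900)
  mk <- function(Dperp, Dpar, seed) {
    spec <- relaxation_sim_spec(
      tensor = diffusion_tensor(Dperp, Dpar, 20, 50),
      vectors = 60, seed = seed,
      noise = c(r1 = 0.015, r2 = 0.015, noe = 0, eta_xy = 0,
                volume = 0, intensity = 0))
    ds <- simulate_relaxation_dataset(spec)
    resample_tensor(ratios_from_table(ds$tables[["900"]]), ds$geometry,
                    f9, resampling_config(repeats = 30, seed = seed))
  }
  # the two published domain tensors, with realistic noise
  fa <- mk(0.52e7, 0.78e7, 31)
  fb <- mk(0.62e7, 0.72e7, 32)
  cmp <- compare_domain_tensors(fa, fb)
  expect_equal(cmp$verdict, "distinct")
  swapped <- compare_domain_tensors(fb, fa)
  expect_equal(swapped$scores, cmp$scores)
  same <- compare_domain_tensors(fa, fa)
  expect_true(all(same$scores == 0))
  expect_equal(same$verdict, "indistinguishable")
})

test_that("CCR and R2/R1 pathways agree on tauC for noiseless synthetic data", {
  # the two routes carry opposite-signed truncation biases (the CCR route
  # inherits the +0.3 percent eta_xy truncation, the ratio route the
  # -0.9 percent high-frequency R1 fraction); their combined systematic
  # offset is about 1.2 percent
  f9 <- make_field_context(900)
  ds <- simulate_relaxation_dataset(relaxation_sim_spec(seed = 5))
  tab <- ds$tables[["900"]]
  tau_r2r1 <- tauc_from_r2r1(tab$r2 / tab$r1, f9)
  tau_ccr <- tauc_from_etaxy(tab$eta_xy, 0.88, f9)
  expect_lt(abs(mean(tau_ccr) - mean(tau_r2r1)) / mean(tau_r2r1), 0.02)
  # residue by residue the two routes track each other to the same bound
  expect_lt(max(abs(tau_ccr - tau_r2r1) / tau_r2r1), 0.02)
})
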