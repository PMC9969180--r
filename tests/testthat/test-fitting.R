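# Inversion: static spectral fit, branch unwrapping, global mutarotation
# fit, detection limits. Coarse 71-point wavelength grids keep these quick;
# the full-scale study conditions live in the acceptance suite.

test_that("noiseless static fit recovers the generator dispersion exactly", {
  cfg <- coarse_static_config(52.68, noise_sigma = 0)
  ser <- simulate_static(cfg)
  fit <- fit_static(ser, water = test_water)
  expect_equal(fit$dispersion$amplitudes, cfg$dispersion$amplitudes,
               tolerance = 1e-8)
  expect_lt(fit$residual_rms, 1e-12)
  # result spectra are consistent with the fitted dispersion
  expect_equal(fit$gamma_spectrum,
               gamma_of(fit$dispersion, test_water, cfg$solution,
                        ser$wavelengths) * 180 / pi, tolerance = 1e-10)
})

test_that("noisy static fit recovers the specific rotation closely", {
  err <- vapply(1:5, function(s) {
    ser <- simulate_static(coarse_static_config(52.68, seed = s))
    fit <- fit_static(ser, water = test_water)
    i <- which.min(abs(ser$wavelengths - 589))
    fit$specific_rotation_spectrum[i] / 52.68 - 1
  }, numeric(1))
  # the 71-point grid carries ~10x less information than the full
  # 701-point measurement, so the band is proportionally wider here
  expect_lt(stats::median(abs(err)), 0.01)
})

test_that("static fit objective is invariant to wavelength ordering", {
  cfg <- coarse_static_config(-92.53, seed = 2L)
  ser <- simulate_static(cfg)
  wl <- ser$wavelengths
  data_vec <- function(idx) {
    unlist(lapply(c("m22", "m23", "m32", "m33"),
                  function(nm) ser$elements[idx, 1, nm]), use.names = FALSE)
  }
  a <- cfg$dispersion$amplitudes * 1.01
  perm <- sample(seq_along(wl))
  ssr1 <- muellerpol:::static_ssr(a, 150, data_vec(seq_along(wl)),
                                  c("m22", "m23", "m32", "m33"),
                                  test_water, cfg$solution, wl)
  ssr2 <- muellerpol:::static_ssr(a, 150, data_vec(perm),
                                  c("m22", "m23", "m32", "m33"),
                                  test_water, cfg$solution, wl[perm])
  expect_equal(ssr1, ssr2, tolerance = 1e-12)
})

test_that("unwrapping restores absolute rotation of a concentrated solution", {
  # 3 M fructose-like: true Gamma exceeds pi/2 in the blue, so the
  # principal extraction is wrapped there
  sol3 <- solution_spec(3, 180.156, 50.04, 20)
  disp <- calibrate_gyration(-92.53, sol3, test_water)
  cfg <- simulation_config(solution = sol3, dispersion = disp,
                           wavelengths = coarse_wl, times = 0,
                           noise_sigma = 0, water = test_water)
  ser <- simulate_static(cfg)
  truth <- gamma_of(disp, test_water, sol3, coarse_wl)
  expect_lt(min(truth), -pi / 2)   # wrapped region exists
  principal <- vapply(seq_along(coarse_wl), function(i) {
    extract_state(m4(series_matrix(ser, i)))$gamma
  }, numeric(1))
  fit <- fit_static(ser, water = test_water)
  unwrapped <- unwrap_absolute(principal, fit, water = test_water)
  expect_equal(as.numeric(unwrapped), truth, tolerance = 0.01 * pi / 180)
  expect_true(any(attr(unwrapped, "branch_index") != 0))
  # continuity: adjacent jumps below pi/2
  expect_lt(max(abs(diff(unwrapped))), pi / 2)
})

test_that("unwrapping is a no-op in the small-rotation regime and is
           invariant to fixed k*pi offsets", {
  cfg <- coarse_static_config(52.68, noise_sigma = 0)
  ser <- simulate_static(cfg)
  truth <- gamma_of(cfg$dispersion, test_water, cfg$solution, coarse_wl)
  expect_lt(max(abs(truth)), pi / 4)
  fit <- fit_static(ser, water = test_water)
  u0 <- unwrap_absolute(truth, fit, water = test_water)
  expect_equal(as.numeric(u0), truth, tolerance = 1e-12)
  expect_true(all(attr(u0, "branch_index") == 0))
  for (m in c(-3L, 2L)) {
    um <- unwrap_absolute(truth + m * pi, fit, water = test_water)
    expect_equal(as.numeric(um), truth, tolerance = 1e-12)
    expect_true(all(attr(um, "branch_index") == -m))
  }
})

test_that("noiseless mutarotation fit is exact; noisy fit recovers tau", {
  cfg <- coarse_mutarotation_config(noise_sigma = 0, n_times = 20)
  ser <- simulate_mutarotation(cfg)
  fit <- fit_mutarotation(ser, water = test_water)
  expect_equal(fit$kinetics$tau, cfg$kinetics$tau, tolerance = 1e-6)
  expect_equal(fit$g_alpha$amplitudes, cfg$g_alpha$amplitudes,
               tolerance = 1e-6)
  expect_equal(fit$g_beta$amplitudes, cfg$g_beta$amplitudes,
               tolerance = 1e-6)
  # noisy, single seed on the coarse grid: few-percent recovery
  sern <- simulate_mutarotation(coarse_mutarotation_config(seed = 6L,
                                                           n_times = 20))
  fitn <- fit_mutarotation(sern, water = test_water)
  expect_equal(fitn$kinetics$tau, 2.332e-4, tolerance = 0.05)
  expect_equal(fitn$alpha_specific_rotation_589, 104.66, tolerance = 0.05)
})

test_that("equilibrium-consistency: weighted anomer sum reproduces an
           independently fitted equilibrium dispersion", {
  # full study-condition grids: the pointwise agreement bound assumes the
  # information content of the 701-wavelength, 100-time measurement
  scen <- glucose_mutarotation_scenario(seed = 12L)
  ser <- simulate_mutarotation(scen)
  kfit <- fit_mutarotation(ser)
  # independent equilibrium measurement of the same solution: a static
  # spectrum generated from the equilibrated anomer mixture
  eq_truth <- gyration_dispersion(
    0.36 * scen$g_alpha$amplitudes + 0.64 * scen$g_beta$amplitudes, 150)
  eq <- simulate_static(simulation_config(
    solution = scen$solution, dispersion = eq_truth,
    wavelengths = scen$wavelengths, times = 0, noise_sigma = 0.001,
    seed = 13L, water = scen$water))
  efit <- fit_static(eq)
  wl <- coarse_wl
  g_mix <- 0.36 * gyration(kfit$g_alpha, wl) + 0.64 * gyration(kfit$g_beta, wl)
  g_eq <- gyration(efit$dispersion, wl)
  expect_lt(max(abs(g_mix / g_eq - 1)), 0.025)
})

test_that("mutarotation fit validates its inputs", {
  cfg <- coarse_mutarotation_config(noise_sigma = 0, n_times = 4)
  ser <- simulate_mutarotation(cfg)
  expect_error(fit_mutarotation(ser, water = test_water),
               class = "mp_invalid_argument")
  cfg20 <- coarse_mutarotation_config(noise_sigma = 0, n_times = 20)
  ser20 <- simulate_mutarotation(cfg20)
  expect_error(fit_mutarotation(ser20, fixed_ratio = c(0.4, 0.7),
                                water = test_water),
               class = "mp_invalid_argument")
})

test_that("detection limit scales as documented", {
  sol <- test_glucose_sol
  expect_equal(detection_limit(0, 52.68, sol), 0)
  # inter-sugar ratio matches the ratio of specific rotations
  ratio <- detection_limit(0.001, -92.53, sol) / detection_limit(0.001, 52.68, sol)
  expect_equal(ratio, 52.68 / 92.53, tolerance = 1e-12)
  expect_equal(ratio, 0.568, tolerance = 0.003)
  # doubling the path halves the limit
  sol2 <- solution_spec(0.25, 180.156, 100.08, 20)
  expect_equal(detection_limit(0.001, 52.68, sol2),
               detection_limit(0.001, 52.68, sol) / 2, tolerance = 1e-12)
  expect_error(detection_limit(0.001, 0, sol), class = "mp_invalid_argument")
})
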