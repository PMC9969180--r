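# Independent oracles and small fixtures used across the suite.

# IAPWS (1997 release) formulation of the water refractive index; an
# independent parameterization against which the packaged Sellmeier model
# is cross-checked.
iapws_water_n <- function(lam_nm, Tc = 20, rho_kgm3 = 998.207) {
  lb <- (lam_nm / 1000) / 0.589
  Tb <- (Tc + 273.15) / 273.15
  rb <- rho_kgm3 / 1000
  a <- c(0.244257733, 9.74634476e-3, -3.73234996e-3, 2.68678472e-4,
         1.58920570e-3, 2.45934259e-3, 0.900704920, -1.66626219e-2)
  R <- a[1] + a[2] * rb + a[3] * Tb + a[4] * lb^2 * Tb + a[5] / lb^2 +
    a[6] / (lb^2 - 0.2292020^2) + a[7] / (lb^2 - 5.432937^2) + a[8] * rb^2
  LL <- R * rb
  sqrt((1 + 2 * LL) / (1 - LL))
}

# Cartesian plane-rotation matrix (basis-change oracle for the Jones rotator)
plane_rotation <- function(gamma) {
  rbind(c(cos(gamma), sin(gamma)), c(-sin(gamma), cos(gamma)))
}

# default water model / glucose solution shared by many tests
test_water <- water_index_model()
test_glucose_sol <- solution_spec(0.25, 180.156, 50.04, 20)

# decimated wavelength grid for cheap fits
coarse_wl <- seq(300, 1000, by = 10)

coarse_static_config <- function(sr, seed = 1L, noise_sigma = 0.001,
                                 sol = test_glucose_sol) {
  disp <- calibrate_gyration(sr, sol, test_water)
  simulation_config(solution = sol, dispersion = disp,
                    wavelengths = coarse_wl, times = 0,
                    noise_sigma = noise_sigma, seed = seed,
                    water = test_water)
}

coarse_mutarotation_config <- function(seed = 1L, noise_sigma = 0.001,
                                       n_times = 20, tau = 2.332e-4,
                                       r_alpha = 0.36) {
  fx <- saccharide_defaults()$glucose
  sol <- test_glucose_sol
  g_a <- calibrate_gyration(fx$alpha_specific_rotation_589, sol, test_water,
                            species = "alpha")
  g_b <- calibrate_gyration(fx$beta_specific_rotation_589, sol, test_water,
                            species = "beta")
  km <- kinetic_model(tau, (1 - r_alpha) / r_alpha, sol$molar_concentration,
                      "alpha")
  simulation_config(solution = sol, g_alpha = g_a, g_beta = g_b,
                    kinetics = km, wavelengths = coarse_wl,
                    times = seq(300, 43200, length.out = n_times),
                    noise_sigma = noise_sigma, seed = seed,
                    water = test_water)
}

# strip class/attributes for plain-matrix comparisons
m4 <- function(M) {
  M <- unclass(M)
  attributes(M) <- list(dim = dim(M))
  M
}
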