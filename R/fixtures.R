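# Packaged default study conditions (saccharide constants and instrument
# settings) and convenience builders of the standard simulation scenarios.

#' Default saccharide and instrument constants
#'
#' Loads the packaged defaults: 589 nm specific rotations of equilibrium
#' d-glucose, d-fructose and d-sucrose and of the pure glucose anomers,
#' the glucose mutarotation rate constant and equilibrium ratio at 20 deg C,
#' and the instrument settings (noise floor 0.001, 50.04 mm cuvette,
#' 300-1000 nm in 1 nm steps, first reading at 300 s, 12 h horizon).
#'
#' @return Nested list mirroring `inst/extdata/saccharide_defaults.json`.
#' @export
saccharide_defaults <- function() {
  path <- system.file("extdata", "saccharide_defaults.json",
                      package = "muellerpol")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Standard glucose mutarotation scenario
#'
#' Builds the [simulation_config()] for the default mutarotation study:
#' freshly dissolved 0.25 M alpha-d-glucose in the 50.04 mm cell at 20 deg C,
#' anomer dispersions calibrated to the 589 nm specific rotations of the
#' pure anomers, total rate constant from the packaged defaults, equilibrium
#' ratio 36:64, noise floor 0.001.
#'
#' @param seed RNG seed for the generated noise.
#' @param noise_sigma per-element noise, default the instrument floor.
#' @param n_times number of time points (default 100).
#' @return A [simulation_config()].
#' @export
glucose_mutarotation_scenario <- function(seed = 0L, noise_sigma = NULL,
                                          n_times = NULL) {
  fx <- saccharide_defaults()
  ins <- fx$instrument
  glu <- fx$glucose
  sol <- solution_spec(glu$default_concentration_M, glu$molar_mass,
                       ins$path_length_mm, ins$temperature_C)
  water <- water_index_model()
  g_alpha <- calibrate_gyration(glu$alpha_specific_rotation_589, sol, water,
                                species = "alpha")
  g_beta <- calibrate_gyration(glu$beta_specific_rotation_589, sol, water,
                               species = "beta")
  r <- glu$eq_alpha_fraction
  km <- kinetic_model(glu$tau_s, (1 - r) / r, sol$molar_concentration, "alpha")
  simulation_config(
    solution = sol, g_alpha = g_alpha, g_beta = g_beta, kinetics = km,
    wavelengths = seq(ins$wavelength_min_nm, ins$wavelength_max_nm,
                      by = ins$wavelength_step_nm),
    times = seq(ins$first_measurement_s, ins$last_measurement_s,
                length.out = n_times %||% ins$n_time_points),
    noise_sigma = noise_sigma %||% ins$noise_floor,
    seed = seed, water = water, species = "alpha-d-glucose")
}

#' Standard static equilibrium scenario
#'
#' [simulation_config()] for a static equilibrium spectrum of one of the
#' packaged saccharides at the default 0.25 M concentration (overridable).
#'
#' @param species `"glucose"`, `"fructose"` or `"sucrose"`.
#' @param seed RNG seed.
#' @param concentration_M molar concentration (default 0.25).
#' @param noise_sigma per-element noise, default the instrument floor.
#' @return A [simulation_config()].
#' @export
static_scenario <- function(species = c("glucose", "fructose", "sucrose"),
                            seed = 0L, concentration_M = 0.25,
                            noise_sigma = NULL) {
  species <- match.arg(species)
  fx <- saccharide_defaults()
  ins <- fx$instrument
  sp <- fx[[species]]
  sol <- solution_spec(concentration_M, sp$molar_mass,
                       ins$path_length_mm, ins$temperature_C)
  water <- water_index_model()
  disp <- calibrate_gyration(sp$specific_rotation_589, sol, water,
                             species = species)
  simulation_config(
    solution = sol, dispersion = disp,
    wavelengths = seq(ins$wavelength_min_nm, ins$wavelength_max_nm,
                      by = ins$wavelength_step_nm),
    times = 0,
    noise_sigma = noise_sigma %||% ins$noise_floor,
    seed = seed, water = water, species = species)
}
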