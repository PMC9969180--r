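# Synthetic Mueller-matrix spectra and time series with the statistical
# structure the inversion assumes: forward chiral-rotator matrices driven by
# a Drude gyration dispersion, first-order anomer kinetics, i.i.d. Gaussian
# element noise at the instrument floor, and optional cuvette-stress linear
# birefringence.

#' Simulation configuration
#'
#' Collects everything the generators need. Defaults mirror the broadband
#' transmission ellipsometry of saccharide solutions the package targets:
#' 300-1000 nm in 1 nm steps, 100 time points from the first reading at
#' 300 s to 12 h, and a per-element Gaussian noise floor of 0.001
#' (normalized Mueller units).
#'
#' @param solution A [solution_spec()].
#' @param dispersion A [gyration_dispersion()] for static simulations.
#' @param g_alpha,g_beta Anomer dispersions for mutarotation simulations.
#' @param kinetics A [kinetic_model()] for mutarotation simulations.
#' @param wavelengths wavelength grid, nm.
#' @param times time grid, s (static simulations use only a single instant).
#' @param noise_sigma per-element Gaussian noise standard deviation, >= 0.
#' @param seed integer RNG seed recorded in the manifest.
#' @param water A [water_index_model()].
#' @param species label stored in the manifest.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(solution,
                              dispersion = NULL,
                              g_alpha = NULL, g_beta = NULL,
                              kinetics = NULL,
                              wavelengths = seq(300, 1000, by = 1),
                              times = seq(300, 43200, length.out = 100),
                              noise_sigma = 0.001,
                              seed = 0L,
                              water = water_index_model(),
                              species = "") {
  if (!inherits(solution, "solution_spec")) {
    mp_stop("mp_invalid_argument", "`solution` must be a solution_spec")
  }
  mp_check_finite(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) mp_stop("mp_invalid_argument", "`noise_sigma` must be >= 0")
  if (is.unsorted(wavelengths, strictly = TRUE) ||
      is.unsorted(times, strictly = TRUE)) {
    mp_stop("mp_invalid_argument", "grids must be strictly increasing")
  }
  structure(list(solution = solution, dispersion = dispersion,
                 g_alpha = g_alpha, g_beta = g_beta, kinetics = kinetics,
                 wavelengths = wavelengths, times = times,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 water = water, species = species),
            class = "simulation_config")
}

# Retardation (radians) for a matrix of per-molar gyration values
# (n_lambda x n_time), through the eigenmode-index chain.
gamma_matrix <- function(g_per_molar, water, sol, wavelengths) {
  g_tot <- sol$molar_concentration * g_per_molar
  n <- water_index(water, wavelengths)
  n2 <- n^2
  # cancellation-free form of sqrt(n2 + g) - sqrt(n2 - g)
  dn <- 2 * g_tot / (sqrt(n2 + g_tot) + sqrt(n2 - g_tot))
  d_nm <- sol$path_length_mm * 1e6
  (pi * d_nm / wavelengths) * dn
}

# Forward chiral elements for a retardation matrix; returns named list of
# element matrices (transparent window: gamma_prime = 0).
chiral_elements <- function(Gam) {
  list(m22 = cos(2 * Gam), m23 = sin(2 * Gam),
       m32 = -sin(2 * Gam), m33 = cos(2 * Gam))
}

add_element_noise <- function(elements, sigma, seed) {
  if (sigma > 0) {
    set.seed(seed)
    idx <- setdiff(mueller_element_names(), "m11")
    nrep <- prod(dim(elements)[1:2])
    for (nm in idx) {
      elements[, , nm] <- elements[, , nm] + stats::rnorm(nrep, 0, sigma)
    }
  }
  elements
}

#' Simulate a static Mueller spectrum
#'
#' Forward-models the normalized Mueller matrix of an equilibrium chiral
#' solution at every wavelength of the grid and adds i.i.d. Gaussian noise
#' of `noise_sigma` to each of the 15 normalized elements. Reproducible for
#' a given seed.
#'
#' @param config A [simulation_config()] with `dispersion` set.
#' @return A single-time-point [mueller_series()].
#' @export
simulate_static <- function(config) {
  if (!inherits(config, "simulation_config") || is.null(config$dispersion)) {
    mp_stop("mp_invalid_argument", "config must carry a `dispersion`")
  }
  wl <- config$wavelengths
  Gam <- gamma_matrix(matrix(gyration(config$dispersion, wl), ncol = 1),
                      config$water, config$solution, wl)
  el <- pack_elements(wl, 0, chiral_elements(Gam))
  el <- add_element_noise(el, config$noise_sigma, config$seed)
  mueller_series(wl, 0, el, manifest = list(
    solution = config$solution, species = config$species,
    seed = config$seed, noise_sigma = config$noise_sigma,
    kind = "static"))
}

#' Simulate a mutarotation Mueller series
#'
#' Forward-models the full spectral-temporal Mueller response of a freshly
#' dissolved pure anomer interconverting toward equilibrium: the effective
#' gyration is the concentration-weighted sum of the anomer dispersions at
#' each instant, propagated through the retardation chain, with independent
#' Gaussian element noise across wavelengths and times.
#'
#' @param config A [simulation_config()] with `g_alpha`, `g_beta` and
#'   `kinetics` set.
#' @return A [mueller_series()] over the configured time grid.
#' @export
simulate_mutarotation <- function(config) {
  if (!inherits(config, "simulation_config") ||
      is.null(config$g_alpha) || is.null(config$g_beta) ||
      is.null(config$kinetics)) {
    mp_stop("mp_invalid_argument",
            "config must carry `g_alpha`, `g_beta` and `kinetics`")
  }
  wl <- config$wavelengths; tt <- config$times
  geff <- effective_gyration(config$g_alpha, config$g_beta, config$kinetics,
                             tt, wl)
  geff <- matrix(geff, nrow = length(wl))
  Gam <- gamma_matrix(geff, config$water, config$solution, wl)
  el <- pack_elements(wl, tt, chiral_elements(Gam))
  el <- add_element_noise(el, config$noise_sigma, config$seed)
  mueller_series(wl, tt, el, manifest = list(
    solution = config$solution, species = config$species,
    seed = config$seed, noise_sigma = config$noise_sigma,
    start_species = config$kinetics$start_species,
    kind = "mutarotation"))
}

#' Inject cuvette-stress linear birefringence into a series
#'
#' Emulates residual stress in the cuvette windows as a commuting cascade:
#' every matrix is pre- and post-multiplied by a linear retarder carrying
#' half the given retardance at the given axis. For axis 0 the stress
#' signals appear in elements m24/m42 (zero) and m34/m43 (+/- sin of the
#' retardance) as expected for linear birefringence on the 0/90 deg axes.
#'
#' @param series A [mueller_series()].
#' @param retardance total linear retardance, radians (small, < 0.2 expected).
#' @param axis_deg fast-axis azimuth, degrees.
#' @return The stressed [mueller_series()].
#' @export
inject_cuvette_stress <- function(series, retardance, axis_deg = 0) {
  mp_check_finite(retardance, "retardance")
  if (abs(retardance) >= 0.2) {
    warning("retardance >= 0.2 rad: commuting-cascade approximation is coarse")
  }
  if (retardance == 0) return(series)
  R <- unclass(mueller_linear_retarder(retardance / 2, axis_deg))
  el <- series$elements
  nl <- dim(el)[1]; nt <- dim(el)[2]
  for (j in seq_len(nt)) {
    flat <- matrix(el[, j, ], nrow = nl)   # n_lambda x 16
    # M' = R M R for every wavelength, vectorized over the element index:
    # (R M R)[a,b] = sum_{p,q} R[a,p] M[p,q] R[q,b]
    out <- matrix(0, nl, 16)
    for (a in 1:4) for (b in 1:4) {
      acc <- 0
      for (p in 1:4) for (q in 1:4) {
        w <- R[a, p] * R[q, b]
        if (w != 0) acc <- acc + w * flat[, (p - 1) * 4 + q]
      }
      out[, (a - 1) * 4 + b] <- acc
    }
    el[, j, ] <- out
  }
  series$elements <- el
  series$manifest$cuvette_stress <- list(retardance = retardance,
                                         axis_deg = axis_deg)
  series
}
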