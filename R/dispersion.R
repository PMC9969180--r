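# Wavelength-dependent physics: water refractive index (Sellmeier),
# phenomenological gyration dispersion g11(lambda) (Drude-type), circular
# eigenmode indices, circular retardation and specific rotatory power.
#
# Units, package-wide: wavelengths nm; path length stored in mm, converted to
# dm only inside the specific-rotation definition and to nm inside the
# retardation formula; Gamma in radians internally, degrees at the interface.

#' Solution metadata
#'
#' Concentration, molar mass, optical path and temperature of a measured
#' solution. The derived mass concentration is
#' `rho = molar_concentration * molar_mass / 1000` in g/mL.
#'
#' @param molar_concentration mol/L, > 0.
#' @param molar_mass g/mol, > 0.
#' @param path_length_mm optical path length, mm, > 0.
#' @param temperature_C solution temperature, deg C.
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(molar_concentration, molar_mass,
                          path_length_mm, temperature_C = 20) {
  for (nm in c("molar_concentration", "molar_mass", "path_length_mm")) {
    v <- get(nm)
    mp_check_finite(v, nm)
    if (v <= 0) mp_stop("mp_invalid_argument", sprintf("`%s` must be > 0", nm))
  }
  mp_check_finite(temperature_C, "temperature_C")
  structure(list(molar_concentration = molar_concentration,
                 molar_mass = molar_mass,
                 path_length_mm = path_length_mm,
                 temperature_C = temperature_C),
            class = "solution_spec")
}

#' Mass concentration of a solution
#'
#' @param sol A [solution_spec()].
#' @return Mass concentration in g/mL.
#' @export
mass_concentration <- function(sol) {
  sol$molar_concentration * sol$molar_mass / 1000
}

#' Sellmeier model of the water refractive index
#'
#' Builds a Sellmeier dispersion model `n^2(lambda) = 1 + sum_i A_i lambda^2 /
#' (lambda^2 - B_i)` (lambda in nm, B_i in nm^2). With no arguments the
#' packaged coefficients (Daimon & Masumura 2007 parameterization of pure
#' water at 20 deg C, stored in `inst/extdata/water_sellmeier.json`) are
#' loaded. Pure-water n is used for the solution: for the dilute solutions
#' considered, a few-percent saccharide mass fraction changes the index
#' dispersion by well under a percent.
#'
#' @param amplitudes dimensionless Sellmeier amplitudes A_i.
#' @param resonances resonance terms B_i in nm^2.
#' @return An object of class `water_index_model`.
#' @export
water_index_model <- function(amplitudes = NULL, resonances = NULL) {
  if (is.null(amplitudes) || is.null(resonances)) {
    path <- system.file("extdata", "water_sellmeier.json", package = "muellerpol")
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    amplitudes <- cfg$amplitudes
    resonances <- cfg$resonances_nm2
  }
  mp_check_finite(amplitudes, "amplitudes")
  mp_check_finite(resonances, "resonances")
  if (length(amplitudes) != length(resonances)) {
    mp_stop("mp_invalid_argument", "amplitudes and resonances must pair up")
  }
  structure(list(amplitudes = amplitudes, resonances = resonances),
            class = "water_index_model")
}

#' Water refractive index
#'
#' Evaluates the Sellmeier model at the given wavelengths.
#'
#' @param model A [water_index_model()].
#' @param wavelength nm, within 200-1100.
#' @return Refractive index n (dimensionless), vectorized over `wavelength`.
#' @export
water_index <- function(model, wavelength) {
  mp_check_finite(wavelength, "wavelength")
  if (any(wavelength < 200 | wavelength > 1100)) {
    mp_stop("mp_invalid_argument", "wavelength outside the 200-1100 nm validity window")
  }
  l2 <- wavelength^2
  n2 <- 1 + vapply(l2, function(x) {
    d <- x - model$resonances
    if (any(abs(d) < 1e-9 * x)) {
      mp_stop("mp_invalid_argument", "wavelength at a Sellmeier resonance pole")
    }
    sum(model$amplitudes * x / d)
  }, numeric(1))
  sqrt(n2)
}

#' Drude-type gyration dispersion of one chemical species
#'
#' Phenomenological model of the gyration tensor element,
#' `g11(lambda) = sum_i a_i / (lambda^2 - lambda_i^2)`, with all resonance
#' wavelengths `lambda_i` below the 300-1000 nm measurement window (the
#' electronic CD bands of monosaccharides lie below 190 nm). Amplitudes are
#' stored per unit molar concentration (1 M) and scaled linearly with
#' concentration where the retardation is evaluated; the sign of `a_i`
#' carries the handedness.
#'
#' @param amplitudes a_i, dimensionless * nm^2, per 1 M.
#' @param resonances_nm lambda_i in nm, each < 300.
#' @param species optional species label.
#' @return An object of class `gyration_dispersion`.
#' @export
gyration_dispersion <- function(amplitudes = numeric(0),
                                resonances_nm = numeric(0),
                                species = "") {
  if (length(amplitudes) != length(resonances_nm)) {
    mp_stop("mp_invalid_argument", "amplitudes and resonances must pair up")
  }
  if (length(amplitudes)) {
    mp_check_finite(amplitudes, "amplitudes")
    mp_check_finite(resonances_nm, "resonances_nm")
    if (any(resonances_nm >= 300)) {
      mp_stop("mp_invalid_argument",
              "gyration resonances must lie below the 300 nm window edge")
    }
  }
  structure(list(amplitudes = amplitudes, resonances_nm = resonances_nm,
                 species = species),
            class = "gyration_dispersion")
}

#' Evaluate a gyration dispersion
#'
#' @param disp A [gyration_dispersion()].
#' @param wavelength nm, within 300-1000.
#' @return g11 per unit molar concentration, vectorized over `wavelength`.
#' @export
gyration <- function(disp, wavelength) {
  mp_check_finite(wavelength, "wavelength")
  if (any(wavelength < 300 | wavelength > 1000)) {
    mp_stop("mp_invalid_argument", "wavelength outside the 300-1000 nm window")
  }
  if (!length(disp$amplitudes)) return(rep(0, length(wavelength)))
  if (any(outer(wavelength, disp$resonances_nm, function(l, l0) abs(l - l0) < 1))) {
    mp_stop("mp_invalid_argument", "wavelength within 1 nm of a gyration resonance")
  }
  vapply(wavelength, function(l) {
    sum(disp$amplitudes / (l^2 - disp$resonances_nm^2))
  }, numeric(1))
}

#' Circular eigenmode refractive indices
#'
#' Wave-equation eigenmode indices of an isotropic chiral medium,
#' `n_{L,R} = sqrt(n^2 +/- g11)`, so that `n_L - n_R ~ g11 / n` for small
#' g11. Positive g11 gives `n_L > n_R` (dextrorotatory with the package sign
#' convention).
#'
#' @param n medium refractive index (> 1).
#' @param g11 gyration tensor element, `|g11| << n^2`.
#' @return A list with vectors `n_L` and `n_R`.
#' @export
eigen_indices <- function(n, g11) {
  mp_check_finite(n, "n"); mp_check_finite(g11, "g11")
  if (any(n <= 1)) mp_stop("mp_invalid_argument", "`n` must exceed 1")
  if (any(n^2 - abs(g11) <= 0)) {
    mp_stop("mp_invalid_argument", "|g11| too large: eigenmode index not real")
  }
  list(n_L = sqrt(n^2 + g11), n_R = sqrt(n^2 - g11))
}

#' Circular retardation of a solution
#'
#' Accumulated circular retardation over the optical path,
#' `Gamma = (pi * d / lambda) * (n_L - n_R)` (radians), with the species
#' gyration scaled linearly by the molar concentration of the solution.
#'
#' @param disp A [gyration_dispersion()] (per 1 M).
#' @param water A [water_index_model()].
#' @param sol A [solution_spec()].
#' @param wavelength nm, vectorized.
#' @return Gamma in radians.
#' @export
gamma_of <- function(disp, water, sol, wavelength) {
  g <- sol$molar_concentration * gyration(disp, wavelength)
  n <- water_index(water, wavelength)
  ei <- eigen_indices(n, g)
  # cancellation-free n_L - n_R = 2 g / (n_L + n_R)
  dn <- 2 * g / (ei$n_L + ei$n_R)
  d_nm <- sol$path_length_mm * 1e6
  pi * d_nm / wavelength * dn
}

#' Specific rotatory power
#'
#' Rotation normalized by mass concentration and path length,
#' `[Gamma] = Gamma_deg / (rho[g/mL] * d[dm])` in deg mL g^-1 dm^-1 -- the
#' quantity tabulated for saccharides at the sodium D line.
#'
#' @param gamma_deg rotation in degrees (vectorized).
#' @param sol A [solution_spec()].
#' @return Specific rotation in deg mL g^-1 dm^-1.
#' @export
specific_rotation <- function(gamma_deg, sol) {
  mp_check_finite(gamma_deg, "gamma_deg")
  rho <- mass_concentration(sol)
  d_dm <- sol$path_length_mm / 100
  if (rho <= 0 || d_dm <= 0) {
    mp_stop("mp_invalid_argument", "concentration and path length must be > 0")
  }
  gamma_deg / (rho * d_dm)
}

#' Specific rotation spectrum implied by a dispersion
#'
#' Convenience chain `gamma_of` -> degrees -> [specific_rotation()].
#'
#' @inheritParams gamma_of
#' @return Specific rotation in deg mL g^-1 dm^-1, vectorized.
#' @export
specific_rotation_of <- function(disp, water, sol, wavelength) {
  specific_rotation(gamma_of(disp, water, sol, wavelength) * 180 / pi, sol)
}

#' Calibrate a single-term gyration dispersion to a known specific rotation
#'
#' Solves the retardation chain in closed form for the Drude amplitude `a_1`
#' such that the dispersion reproduces a target specific rotation at a
#' reference wavelength (conventionally 589 nm). Inverting
#' `Gamma = (pi d / lambda) (sqrt(n^2+g) - sqrt(n^2-g))` gives
#' `g = Delta * sqrt(4 n^2 - Delta^2) / 2` with
#' `Delta = Gamma * lambda / (pi d)`.
#'
#' @param target_specific_rotation deg mL g^-1 dm^-1 at `lambda_ref`.
#' @param sol A [solution_spec()] fixing the concentration and path used in
#'   the inversion (the per-molar amplitude is independent of both up to
#'   negligible nonlinearity of the square roots).
#' @param water A [water_index_model()].
#' @param lambda_ref reference wavelength, nm (default 589).
#' @param lambda_zero Drude resonance wavelength, nm (default 150, fixed
#'   below the electronic CD region).
#' @param species species label for the result.
#' @return A single-term [gyration_dispersion()].
#' @export
calibrate_gyration <- function(target_specific_rotation, sol, water,
                               lambda_ref = 589, lambda_zero = 150,
                               species = "") {
  mp_check_finite(target_specific_rotation, "target_specific_rotation")
  rho <- mass_concentration(sol)
  gamma_deg <- target_specific_rotation * rho * (sol$path_length_mm / 100)
  gamma_rad <- gamma_deg * pi / 180
  n <- water_index(water, lambda_ref)
  d_nm <- sol$path_length_mm * 1e6
  delta <- gamma_rad * lambda_ref / (pi * d_nm)
  g_total <- delta * sqrt(4 * n^2 - delta^2) / 2
  a1 <- g_total / sol$molar_concentration * (lambda_ref^2 - lambda_zero^2)
  gyration_dispersion(a1, lambda_zero, species = species)
}
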