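# First-order mutarotation kinetics of the alpha <-> beta anomers of a
# reducing sugar, and the concentration-weighted effective gyration of the
# reacting solution.

#' First-order mutarotation kinetic model
#'
#' Parameterizes the reversible first-order interconversion alpha <-> beta by
#' the observed total rate constant `tau` (the sum of forward and reverse
#' rate constants, the decay rate of the relaxation exponential) and the
#' equilibrium constant `K = C_beta,eq / C_alpha,eq`. Note that for glucose
#' at 20 deg C, K ~ 1.78 so the rate constant of the beta -> alpha step is
#' the smaller of the pair; species-named accessors are provided by
#' [split_rates()] to avoid arrow-direction ambiguity.
#'
#' @param tau total rate constant, s^-1, > 0.
#' @param K equilibrium constant C_beta,eq / C_alpha,eq, > 0.
#' @param C total molar concentration, mol/L, > 0.
#' @param start_species `"alpha"` or `"beta"`: the pure anomer dissolved at t = 0.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(tau, K, C, start_species = c("alpha", "beta")) {
  start_species <- match.arg(start_species)
  for (nm in c("tau", "K", "C")) {
    v <- get(nm)
    mp_check_finite(v, nm)
    if (v <= 0) mp_stop("mp_invalid_argument", sprintf("`%s` must be > 0", nm))
  }
  structure(list(tau = tau, K = K, C = C, start_species = start_species),
            class = "kinetic_model")
}

#' Split the total rate constant into forward and reverse parts
#'
#' From `k_f + k_r = tau` and `k_f / k_r = K` (with `k_f` the alpha -> beta
#' rate): `k_f = tau * K / (1 + K)`, `k_r = tau / (1 + K)`. The sum equals
#' `tau` exactly by construction.
#'
#' @param model A [kinetic_model()].
#' @return Named numeric vector with `rate_alpha_to_beta` and
#'   `rate_beta_to_alpha`, s^-1.
#' @export
split_rates <- function(model) {
  kf <- model$tau * model$K / (1 + model$K)
  c(rate_alpha_to_beta = kf, rate_beta_to_alpha = model$tau - kf)
}

#' Anomer concentration trajectory
#'
#' Closed-form solution of the first-order rate equation with a pure anomer
#' at t = 0: `C_alpha(t) = C_alpha,eq + (C - C_alpha,eq) exp(-tau t)` with
#' `C_alpha,eq = C / (1 + K)` (mirrored when starting from the beta anomer),
#' and `C_beta(t) = C - C_alpha(t)` (mass conservation).
#'
#' @param model A [kinetic_model()].
#' @param times seconds, >= 0, vectorized.
#' @return A list of class `concentration_trajectory` with `times`,
#'   `C_alpha`, `C_beta` (mol/L).
#' @export
concentrations <- function(model, times) {
  mp_check_finite(times, "times")
  if (any(times < 0)) mp_stop("mp_invalid_argument", "`times` must be >= 0")
  C <- model$C
  C_alpha_eq <- C / (1 + model$K)
  C_alpha_0 <- if (model$start_species == "alpha") C else 0
  C_alpha <- C_alpha_eq + (C_alpha_0 - C_alpha_eq) * exp(-model$tau * times)
  structure(list(times = times, C_alpha = C_alpha, C_beta = C - C_alpha),
            class = "concentration_trajectory")
}

#' Effective gyration of a reacting anomer mixture
#'
#' Concentration-weighted gyration of the solution,
#' `g11(lambda, t) = [C_alpha(t) g11_alpha(lambda) + C_beta(t) g11_beta(lambda)] / C`,
#' returned per unit molar concentration so it plugs directly into
#' [gamma_of()] with the solution's total concentration.
#'
#' @param g_alpha,g_beta [gyration_dispersion()] of the pure anomers (per 1 M).
#' @param model A [kinetic_model()].
#' @param t time, s (scalar or vector).
#' @param wavelength nm (scalar or vector).
#' @return Matrix of g11 values, `length(wavelength)` x `length(t)` (dropped
#'   to a vector when `t` is scalar).
#' @export
effective_gyration <- function(g_alpha, g_beta, model, t, wavelength) {
  traj <- concentrations(model, t)
  ga <- gyration(g_alpha, wavelength)
  gb <- gyration(g_beta, wavelength)
  out <- (outer(ga, traj$C_alpha) + outer(gb, traj$C_beta)) / model$C
  if (length(t) == 1L) out[, 1] else out
}
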