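# Inversion: least-squares fits of the dispersion model to Mueller spectra,
# branch unwrapping of the absolute rotation, global spectral-temporal
# mutarotation fitting, and detection limits.

#' Fitting configuration
#'
#' @param use_cd also fit the m14/m41 circular-dichroism pair (default FALSE:
#'   the transparent window has Gamma' = 0).
#' @param lambda_zero fixed Drude resonance wavelength of the fitted
#'   dispersion, nm.
#' @param sr_grid coarse starting grid of candidate specific rotations
#'   (deg mL g^-1 dm^-1) scanned before the local refinement.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param ptol relative parameter tolerance of the optimizer.
#' @param K_max branch search bound for [unwrap_absolute()].
#' @param ambiguity_tol minimal margin (radians) between the best and
#'   second-best branch before unwrapping is declared ambiguous.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(use_cd = FALSE, lambda_zero = 150,
                       sr_grid = seq(-200, 200, by = 1),
                       max_iter = 200, ptol = 1e-10,
                       K_max = 8, ambiguity_tol = 1e-3) {
  structure(list(use_cd = use_cd, lambda_zero = lambda_zero,
                 sr_grid = sr_grid, max_iter = max_iter, ptol = ptol,
                 K_max = K_max, ambiguity_tol = ambiguity_tol),
            class = "fit_config")
}

fit_elements <- function(config) {
  el <- c("m22", "m23", "m32", "m33")
  if (isTRUE(config$use_cd)) el <- c(el, "m14", "m41")
  el
}

# Stack the chosen data elements of one time slice into a residual-ordered
# vector, and the matching model prediction for a retardation vector.
chiral_prediction <- function(Gam, elements) {
  pred <- list(m22 = cos(2 * Gam), m23 = sin(2 * Gam),
               m32 = -sin(2 * Gam), m33 = cos(2 * Gam),
               m14 = 0 * Gam, m41 = 0 * Gam)
  unlist(pred[elements], use.names = FALSE)
}

# SSR of a single-amplitude dispersion against one time slice; used by the
# deterministic coarse-grid start.
static_ssr <- function(a, lambda_zero, data_vec, elements, water, sol, wl) {
  g_pm <- a / (wl^2 - lambda_zero^2)
  Gam <- gamma_matrix(matrix(g_pm, ncol = 1), water, sol, wl)
  sum((data_vec - chiral_prediction(Gam, elements))^2)
}

sr_to_amplitude <- function(sr, sol, water, lambda_ref = 589, lambda_zero = 150) {
  d <- calibrate_gyration(sr, sol, water, lambda_ref = lambda_ref,
                          lambda_zero = lambda_zero)
  d$amplitudes
}

#' Fit the dispersion model to a static Mueller spectrum
#'
#' Least-squares minimization, over all wavelengths simultaneously, of the
#' elementwise difference between the forward chiral Mueller model and the
#' measured m22/m23/m32/m33 spectra (plus m14/m41 when CD fitting is
#' enabled). The free parameter is the Drude amplitude of the single-term
#' gyration dispersion; starting values come from a deterministic coarse
#' grid of candidate specific rotations, refined by Levenberg-Marquardt.
#' Because the fit works in element space, wrapped (|2 Gamma| > pi) spectra
#' are handled naturally and the fitted dispersion pins the absolute branch.
#'
#' @param series A single-time-point [mueller_series()] (or the time slice
#'   `time_index` of a longer one).
#' @param sol A [solution_spec()]; defaults to the series manifest.
#' @param config A [fit_config()].
#' @param water A [water_index_model()].
#' @param time_index which time slice to fit.
#' @return An object of class `static_fit_result` with the fitted
#'   `dispersion` (per 1 M), `gamma_spectrum` (degrees per wavelength),
#'   `specific_rotation_spectrum`, `residual_rms`, `covariance` and
#'   convergence diagnostics.
#' @export
fit_static <- function(series, sol = series$manifest$solution,
                       config = fit_config(), water = water_index_model(),
                       time_index = 1L) {
  wl <- series$wavelengths
  if (any(wl < 300 | wl > 1000)) {
    mp_stop("mp_invalid_argument", "wavelength grid outside 300-1000 nm")
  }
  elements <- fit_elements(config)
  data_vec <- unlist(lapply(elements, function(nm) {
    series$elements[, time_index, nm]
  }), use.names = FALSE)

  cand <- vapply(config$sr_grid, sr_to_amplitude, numeric(1),
                 sol = sol, water = water, lambda_zero = config$lambda_zero)
  ssr <- vapply(cand, static_ssr, numeric(1),
                lambda_zero = config$lambda_zero, data_vec = data_vec,
                elements = elements, water = water, sol = sol, wl = wl)
  a_start <- cand[which.min(ssr)]

  resid_fn <- function(par) {
    g_pm <- par[1] / (wl^2 - config$lambda_zero^2)
    Gam <- gamma_matrix(matrix(g_pm, ncol = 1), water, sol, wl)
    data_vec - chiral_prediction(Gam, elements)
  }
  out <- minpack.lm::nls.lm(
    par = a_start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                         ptol = config$ptol))
  if (out$info == 0 || out$info == 9) {
    mp_stop("mp_fit_failure",
            sprintf("static fit did not converge: %s", out$message))
  }
  a_hat <- out$par[1]
  disp <- gyration_dispersion(a_hat, config$lambda_zero)
  gam_deg <- gamma_of(disp, water, sol, wl) * 180 / pi
  n_res <- length(data_vec)
  sigma2 <- out$deviance / max(1, n_res - 1)
  covariance <- tryCatch(sigma2 * chol2inv(chol(out$hessian / 2)),
                         error = function(e) matrix(NA_real_, 1, 1))
  structure(list(
    dispersion = disp,
    wavelengths = wl,
    gamma_spectrum = gam_deg,
    specific_rotation_spectrum = specific_rotation(gam_deg, sol),
    residual_rms = sqrt(out$deviance / n_res),
    covariance = covariance,
    niter = out$niter,
    converged = TRUE,
    solution = sol
  ), class = "static_fit_result")
}

#' Unwrap a principal-value rotation spectrum to absolute values
#'
#' A single Mueller matrix pins the retardation only modulo pi. The fitted
#' dispersion model breaks the ambiguity: for each wavelength the branch
#' index k in `[-K_max, K_max]` minimizing
#' `|Gamma_principal + k*pi - Gamma_model(lambda)|` is selected, yielding
#' the absolute (2k pi-wise in 2 Gamma) rotation. An error is raised when
#' the best and second-best branches are separated by less than
#' `ambiguity_tol` radians.
#'
#' @param principal numeric vector of principal-value retardations
#'   (radians, one per wavelength), or a list of [chiro_state()].
#' @param fit A `static_fit_result` providing the dispersion.
#' @param config A [fit_config()] (for `K_max` and `ambiguity_tol`).
#' @param water A [water_index_model()].
#' @return Numeric vector of unwrapped retardations (radians) with the
#'   chosen branch indices in attribute `branch_index`.
#' @export
unwrap_absolute <- function(principal, fit, config = fit_config(),
                            water = water_index_model()) {
  if (is.list(principal)) {
    principal <- vapply(principal, function(s) s$gamma, numeric(1))
  }
  mp_check_finite(principal, "principal")
  wl <- fit$wavelengths
  if (length(principal) != length(wl)) {
    mp_stop("mp_invalid_argument",
            "principal spectrum and fitted wavelength grid differ in length")
  }
  g_model <- gamma_of(fit$dispersion, water, fit$solution, wl)
  ks <- seq(-config$K_max, config$K_max)
  k_hat <- integer(length(wl))
  out <- numeric(length(wl))
  for (i in seq_along(wl)) {
    r <- abs(principal[i] + ks * pi - g_model[i])
    o <- order(r)
    if (r[o[2]] - r[o[1]] < config$ambiguity_tol) {
      mp_stop("mp_branch_ambiguity",
              sprintf("branch ambiguous at %g nm (margin %.2g rad)",
                      wl[i], r[o[2]] - r[o[1]]))
    }
    k_hat[i] <- ks[o[1]]
    out[i] <- principal[i] + k_hat[i] * pi
  }
  attr(out, "branch_index") <- k_hat
  out
}

#' Globally fit the spectral-temporal mutarotation model
#'
#' Simultaneous least squares over all wavelengths and time points of the
#' coupled model: anomer concentrations from the first-order rate equation,
#' effective gyration as their concentration-weighted dispersion sum,
#' retardation through the eigenmode chain, and the chiral Mueller elements
#' against the data. Free parameters are the two anomer Drude amplitudes
#' and the total rate constant `tau`; the equilibrium anomer ratio is fixed
#' (default 36:64 alpha:beta for glucose at 20 deg C) because the beta
#' dispersion and the equilibrium concentration are strongly correlated in
#' the model. Starting values are derived deterministically from per-time
#' static fits followed by an exponential regression of the effective
#' amplitude trajectory.
#'
#' @param series A [mueller_series()] with at least 5 time points.
#' @param sol A [solution_spec()]; defaults to the series manifest.
#' @param fixed_ratio equilibrium (alpha, beta) fractions, summing to 1.
#' @param config A [fit_config()].
#' @param water A [water_index_model()].
#' @return An object of class `kinetic_fit_result`: fitted `g_alpha`,
#'   `g_beta` dispersions, `kinetics` ([kinetic_model()] with the fitted
#'   tau), split `rates`, `fixed_equilibrium_ratio`, `residual_rms`,
#'   `covariance`, and the anomer specific rotations at 589 nm.
#' @export
fit_mutarotation <- function(series, sol = series$manifest$solution,
                             fixed_ratio = c(alpha = 0.36, beta = 0.64),
                             config = fit_config(),
                             water = water_index_model()) {
  tt <- series$times
  if (length(tt) < 5) {
    mp_stop("mp_invalid_argument", "at least 5 time points are required")
  }
  if (tt[1] < 0) mp_stop("mp_invalid_argument", "times must be >= 0")
  if (abs(sum(fixed_ratio) - 1) > 1e-8) {
    mp_stop("mp_invalid_argument", "`fixed_ratio` must sum to 1")
  }
  r_alpha <- fixed_ratio[[1]]
  K_fixed <- (1 - r_alpha) / r_alpha
  wl <- series$wavelengths
  elements <- fit_elements(config)
  lz <- config$lambda_zero
  start_species <- series$manifest$start_species %||% "alpha"

  # -- deterministic starting values -----------------------------------
  # per-time effective amplitude trajectory (grid start once, then warm)
  a_eff <- numeric(length(tt))
  slice_fit <- function(j, start) {
    data_vec <- unlist(lapply(elements, function(nm) series$elements[, j, nm]),
                       use.names = FALSE)
    fn <- function(par) {
      Gam <- gamma_matrix(matrix(par[1] / (wl^2 - lz^2), ncol = 1),
                          water, sol, wl)
      data_vec - chiral_prediction(Gam, elements)
    }
    minpack.lm::nls.lm(par = start, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 50))$par[1]
  }
  first <- fit_static(mueller_series(wl, 0,
                                     series$elements[, 1, , drop = FALSE],
                                     series$manifest),
                      sol = sol, config = config, water = water)
  a_eff[1] <- first$dispersion$amplitudes
  for (j in seq_along(tt)[-1]) a_eff[j] <- slice_fit(j, a_eff[j - 1])

  # exponential regression a_eff(t) = a_eq + (a_0 - a_eq) exp(-tau t)
  tau_grid <- exp(seq(log(1e-5), log(2e-3), length.out = 60))
  best <- NULL
  for (tau_c in tau_grid) {
    X <- cbind(1, exp(-tau_c * tt))
    cf <- stats::lm.fit(X, a_eff)
    ss <- sum(cf$residuals^2)
    if (is.null(best) || ss < best$ss) {
      best <- list(ss = ss, tau = tau_c, a_eq = cf$coefficients[1],
                   delta = cf$coefficients[2])
    }
  }
  a0 <- best$a_eq + best$delta
  if (start_species == "alpha") {
    a_alpha0 <- a0
    a_beta0 <- (best$a_eq - r_alpha * a0) / (1 - r_alpha)
  } else {
    a_beta0 <- a0
    a_alpha0 <- (best$a_eq - (1 - r_alpha) * a0) / r_alpha
  }
  par0 <- c(a_alpha = a_alpha0, a_beta = a_beta0, tau = best$tau)

  # -- global refinement ------------------------------------------------
  data_vec <- unlist(lapply(elements, function(nm) series$elements[, , nm]),
                     use.names = FALSE)
  resid_fn <- function(par) {
    km <- kinetic_model(max(par[3], 1e-8), K_fixed, sol$molar_concentration,
                        start_species)
    geff <- effective_gyration(gyration_dispersion(par[1], lz),
                               gyration_dispersion(par[2], lz),
                               km, tt, wl)
    Gam <- gamma_matrix(matrix(geff, nrow = length(wl)), water, sol, wl)
    data_vec - chiral_prediction(Gam, elements)
  }
  out <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                         ptol = config$ptol))
  if (out$info == 0 || out$info == 9) {
    mp_stop("mp_fit_failure",
            sprintf("mutarotation fit did not converge: %s", out$message))
  }
  tau_hat <- out$par[[3]]
  g_alpha <- gyration_dispersion(out$par[[1]], lz, species = "alpha")
  g_beta <- gyration_dispersion(out$par[[2]], lz, species = "beta")
  km <- kinetic_model(tau_hat, K_fixed, sol$molar_concentration, start_species)
  n_res <- length(data_vec)
  sigma2 <- out$deviance / max(1, n_res - 3)
  covariance <- tryCatch(sigma2 * chol2inv(chol(out$hessian / 2)),
                         error = function(e) matrix(NA_real_, 3, 3))
  structure(list(
    g_alpha = g_alpha, g_beta = g_beta,
    kinetics = km,
    rates = split_rates(km),
    fixed_equilibrium_ratio = fixed_ratio,
    residual_rms = sqrt(out$deviance / n_res),
    covariance = covariance,
    niter = out$niter,
    converged = TRUE,
    solution = sol,
    alpha_specific_rotation_589 = specific_rotation_of(g_alpha, water, sol, 589),
    beta_specific_rotation_589 = specific_rotation_of(g_beta, water, sol, 589),
    amplitude_trajectory = a_eff
  ), class = "kinetic_fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polarimetric detection limit for a chiral solute
#'
#' The smallest rotation distinguishable from instrument noise, taking the
#' per-element noise floor of the normalized Mueller matrix and the
#' small-angle relation `m23 ~ sin(2 Gamma) ~ 2 Gamma`:
#' `Gamma_min = noise_floor / 2` radians. The minimal detectable mass
#' concentration follows from the specific rotation:
#' `C_min = Gamma_min[deg] / ([Gamma] * d[dm])` in g/mL. This is the
#' package's own derivation of the limit; only concentration ratios between
#' solutes are instrument-independent.
#'
#' @param noise_floor per-element noise floor, normalized Mueller units.
#' @param specific_rot specific rotation of the solute, deg mL g^-1 dm^-1
#'   (nonzero).
#' @param sol A [solution_spec()] providing the path length.
#' @return Minimal detectable mass concentration, g/mL.
#' @export
detection_limit <- function(noise_floor, specific_rot, sol) {
  mp_check_finite(noise_floor, "noise_floor")
  mp_check_finite(specific_rot, "specific_rot")
  if (noise_floor < 0) mp_stop("mp_invalid_argument", "`noise_floor` must be >= 0")
  if (specific_rot == 0) {
    mp_stop("mp_invalid_argument", "`specific_rot` must be nonzero")
  }
  gamma_min_deg <- (noise_floor / 2) * 180 / pi
  gamma_min_deg / (abs(specific_rot) * sol$path_length_mm / 100)
}
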