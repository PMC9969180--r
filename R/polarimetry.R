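# Jones and Mueller calculus of non-depolarizing isotropic chiral media.
#
# Conventions (fixed package-wide):
#   * circular basis vectors e_L = (1, i)/sqrt(2), e_R = (1, -i)/sqrt(2);
#   * positive circular retardation Gamma = dextrorotatory, i.e. the Cartesian
#     Jones matrix is the plane rotation by +Gamma and the Mueller rotator has
#     m23 = +sin(2*Gamma), m32 = -sin(2*Gamma);
#   * the circular dichroism angle Gamma' enters as m14 = m41 = +tanh(Gamma').

# Stokes-basis transformation matrix A of the Jones-to-Mueller map
.stokes_A <- rbind(
  c(1, 0, 0, 1),
  c(1, 0, 0, -1),
  c(0, 1, 1, 0),
  c(0, 1i, -1i, 0)
)
.stokes_A_inv <- solve(.stokes_A)

# circular -> Cartesian basis change, columns are e_L, e_R
.circ_to_cart <- matrix(c(1, 1i, 1, -1i), 2, 2) / sqrt(2)
.cart_to_circ <- solve(.circ_to_cart)

#' Jones matrix of a circular retarder (optical rotator)
#'
#' Returns the Cartesian Jones matrix of a pure circular retarder, i.e. the
#' amplitude response of a transparent optically active medium that has
#' accumulated a circular retardation `gamma` between its left- and
#' right-circular eigenmodes. `gamma` is the rotation angle of the plane of
#' linear polarization, i.e. half the accumulated L/R phase difference: on
#' the circular eigenbasis the matrix is
#' `diag(exp(+i*gamma), exp(-i*gamma))` up to global phase, and in Cartesian
#' coordinates it is the plane rotation by `gamma` (positive =
#' dextrorotatory). This keeps the whole chain consistent: the Mueller image
#' rotates the (S1, S2) Stokes pair by `2*gamma`.
#'
#' @param gamma Circular retardation in radians (finite scalar).
#' @return A 2x2 complex unitary matrix.
#' @examples
#' jones_rotator(0)          # identity
#' jones_rotator(0.2)        # plane rotation by 0.2 rad
#' @export
jones_rotator <- function(gamma) {
  mp_check_finite(gamma, "gamma")
  J <- .circ_to_cart %*% diag(exp(c(1i, -1i) * gamma)) %*% .cart_to_circ
  structure(J, class = c("jones_matrix", class(J)))
}

#' Jones matrix of a circular diattenuator
#'
#' Amplitude response of a medium that absorbs left- and right-circular
#' polarizations differently (circular dichroism), parameterized by the CD
#' angle `gamma_prime`. On the circular eigenbasis the matrix is
#' `diag(exp(+gamma_prime/2), exp(-gamma_prime/2))`; it is Hermitian positive
#' and commutes with [jones_rotator()] (both are diagonal on that basis).
#' The unit-determinant normalization is used: only normalized Mueller
#' matrices are observable, so a global attenuation factor is immaterial.
#'
#' @param gamma_prime Circular dichroism angle in radians (finite scalar).
#' @return A 2x2 complex Hermitian matrix.
#' @export
jones_circular_diattenuator <- function(gamma_prime) {
  mp_check_finite(gamma_prime, "gamma_prime")
  J <- .circ_to_cart %*% diag(exp(c(1, -1) * gamma_prime / 2)) %*% .cart_to_circ
  structure(J, class = c("jones_matrix", class(J)))
}

#' Jones-to-Mueller transformation
#'
#' Maps a Jones matrix to the corresponding normalized Mueller matrix via the
#' standard Stokes-basis matrix A: `M = A (J x Conj(J)) A^-1`, normalized to
#' element (1,1). The result of this map is always a non-depolarizing Mueller
#' matrix; a residual imaginary part above `1e-10` (numerically impossible for
#' a valid Jones matrix) is an error.
#'
#' @param J A 2x2 complex Jones matrix.
#' @return A 4x4 real `mueller_matrix` normalized so that `M[1,1] == 1`.
#' @export
jones_to_mueller <- function(J) {
  if (!is.matrix(J) || !all(dim(J) == c(2, 2)) || anyNA(J) ||
      any(!is.finite(Re(J))) || any(!is.finite(Im(J)))) {
    mp_stop("mp_invalid_argument", "`J` must be a finite 2x2 matrix")
  }
  M <- .stokes_A %*% (J %x% Conj(J)) %*% .stokes_A_inv
  if (max(abs(Im(M))) > 1e-10) {
    mp_stop("mp_invalid_argument", "Jones-to-Mueller image is not real")
  }
  M <- Re(M)
  if (abs(M[1, 1]) < .Machine$double.eps) {
    mp_stop("mp_degenerate_input", "cannot normalize: Mueller element (1,1) is zero")
  }
  new_mueller(M / M[1, 1])
}

new_mueller <- function(M, wavelength = NA_real_) {
  structure(M, wavelength = wavelength,
            class = c("mueller_matrix", class(M)))
}

#' Mueller matrix of an optical rotator
#'
#' Closed-form normalized Mueller matrix of a pure circular retarder: the
#' block rotation of the (S1, S2) Stokes pair by `2*gamma` (the Stokes-space
#' angle doubling), with `m23 = +sin(2*gamma)` for dextrorotatory positive
#' `gamma`. Equal to `jones_to_mueller(jones_rotator(gamma))`.
#'
#' @param gamma Circular retardation in radians.
#' @return A 4x4 `mueller_matrix`.
#' @export
mueller_rotator <- function(gamma) {
  mp_check_finite(gamma, "gamma")
  c2 <- cos(2 * gamma); s2 <- sin(2 * gamma)
  new_mueller(rbind(
    c(1, 0, 0, 0),
    c(0, c2, s2, 0),
    c(0, -s2, c2, 0),
    c(0, 0, 0, 1)
  ))
}

#' Chiro-optical state at one wavelength
#'
#' Bundles the circular retardation `gamma` (radians), the circular dichroism
#' angle `gamma_prime` (radians, 0 in the transparent window) and the signed
#' integer `branch_index` k of the pi-branch on which `gamma` lives (0 for a
#' principal value; resolved by [unwrap_absolute()]).
#'
#' @param gamma Circular retardation, radians.
#' @param gamma_prime Circular dichroism angle, radians (default 0).
#' @param branch_index Integer branch index k (default 0).
#' @return An object of class `chiro_state`.
#' @export
chiro_state <- function(gamma, gamma_prime = 0, branch_index = 0L) {
  mp_check_finite(gamma, "gamma")
  mp_check_finite(gamma_prime, "gamma_prime")
  structure(list(gamma = gamma, gamma_prime = gamma_prime,
                 branch_index = as.integer(branch_index)),
            class = "chiro_state")
}

#' @export
print.chiro_state <- function(x, ...) {
  cat(sprintf("chiro_state: Gamma = %.6g rad, Gamma' = %.6g rad, branch k = %d\n",
              x$gamma, x$gamma_prime, x$branch_index))
  invisible(x)
}

#' Mueller matrix of an isotropic chiral medium
#'
#' Exact normalized Mueller matrix of a non-depolarizing isotropic chiral
#' medium with circular retardation `gamma` and circular dichroism angle
#' `gamma_prime`:
#' the (S1,S2) rotation block scaled by `1/cosh(gamma_prime)` together with
#' `m14 = m41 = tanh(gamma_prime)`. Reduces exactly to [mueller_rotator()]
#' when `gamma_prime = 0`, and its first-order expansion in `gamma_prime`
#' has `m14 = m41 = gamma_prime` (the small-CD regime).
#'
#' @param state A [chiro_state()] (or a list with `gamma`, `gamma_prime`).
#' @return A 4x4 `mueller_matrix`.
#' @export
mueller_chiral <- function(state) {
  g <- state$gamma; gp <- state$gamma_prime
  mp_check_finite(g, "gamma"); mp_check_finite(gp, "gamma_prime")
  c2 <- cos(2 * g) / cosh(gp); s2 <- sin(2 * g) / cosh(gp); t <- tanh(gp)
  new_mueller(rbind(
    c(1, 0, 0, t),
    c(0, c2, s2, 0),
    c(0, -s2, c2, 0),
    c(t, 0, 0, 1)
  ))
}

#' Mueller matrix of a linear retarder
#'
#' Standard normalized Mueller matrix of a linear retarder with retardance
#' `delta` (radians) and fast-axis azimuth `axis_deg` (degrees). Used to
#' emulate residual linear birefringence of stressed cuvette windows.
#'
#' @param delta Linear retardance, radians.
#' @param axis_deg Fast-axis azimuth, degrees.
#' @return A 4x4 `mueller_matrix`.
#' @export
mueller_linear_retarder <- function(delta, axis_deg = 0) {
  mp_check_finite(delta, "delta"); mp_check_finite(axis_deg, "axis_deg")
  th <- axis_deg * pi / 180
  c <- cos(2 * th); s <- sin(2 * th); cd <- cos(delta); sd <- sin(delta)
  new_mueller(rbind(
    c(1, 0, 0, 0),
    c(0, c^2 + s^2 * cd, c * s * (1 - cd), -s * sd),
    c(0, c * s * (1 - cd), s^2 + c^2 * cd, c * sd),
    c(0, s * sd, -c * sd, cd)
  ))
}

# Gil-Bernabeu non-depolarization index: tr(M^T M) = 4 m11^2 for a
# non-depolarizing matrix. Returns the deviation (0 for pure matrices).
gil_bernabeu_deviation <- function(M) {
  sum(M^2) - 4 * M[1, 1]^2
}

# ---- differential decomposition -------------------------------------------

# Principal matrix logarithm by eigendecomposition. Eigenvalues on (or
# numerically at) the negative real axis make the principal branch ambiguous.
matrix_log_principal <- function(M, imag_tol = 1e-10) {
  e <- eigen(M)
  lam <- e$values
  on_cut <- Re(lam) < 0 & abs(Im(lam)) < 1e-12 * pmax(1, abs(Re(lam)))
  near_cut <- abs(Arg(lam)) > pi - 1e-8
  if (any(on_cut) || any(near_cut)) {
    mp_stop("mp_branch_ambiguity",
            "matrix logarithm eigenvalue on the negative real axis; unwrap the rotation first")
  }
  L <- e$vectors %*% diag(log(lam), nrow = length(lam)) %*% solve(e$vectors)
  if (max(abs(Im(L))) > imag_tol) {
    mp_stop("mp_branch_ambiguity",
            "matrix logarithm has a large complex residual; principal branch unreliable")
  }
  Re(L)
}

#' Differential decomposition of a Mueller matrix
#'
#' Takes the principal matrix logarithm of a non-depolarizing normalized
#' Mueller matrix and arranges it into the six elementary polarimetric
#' measures: linear dichroism LD and LD' (0/90 deg and +/-45 deg axes),
#' circular dichroism CD, linear birefringence LB and LB', and circular
#' birefringence CB. For a pure rotator CB equals `2*gamma` and every other
#' measure vanishes. Only the principal branch is computed; a matrix whose
#' rotation angle reaches pi raises a branch-ambiguity error and must be
#' unwrapped upstream (see [unwrap_absolute()]).
#'
#' @param M A 4x4 normalized non-depolarizing Mueller matrix.
#' @param tol Warn when the Gil-Bernabeu deviation exceeds this value.
#' @return An object of class `differential_matrix`: the 4x4 log-image with
#'   named accessors in `$measures` (LD, LDp, CD, LB, LBp, CB).
#' @export
differential_decompose <- function(M, tol = 1e-6) {
  if (!is.matrix(M) || !all(dim(M) == c(4, 4))) {
    mp_stop("mp_invalid_argument", "`M` must be a 4x4 matrix")
  }
  mp_check_finite(c(unclass(M)), "M")
  if (abs(M[1, 1] - 1) > 1e-8) {
    mp_stop("mp_invalid_argument", "`M` must be normalized to element (1,1) = 1")
  }
  if (abs(gil_bernabeu_deviation(M)) > tol) {
    warning("Mueller matrix deviates from the non-depolarizing condition; ",
            "differential measures are approximate")
  }
  L <- matrix_log_principal(unclass(M))
  measures <- c(
    LD  = (L[1, 2] + L[2, 1]) / 2,
    LDp = (L[1, 3] + L[3, 1]) / 2,
    CD  = (L[1, 4] + L[4, 1]) / 2,
    CB  = (L[2, 3] - L[3, 2]) / 2,
    LB  = (L[3, 4] - L[4, 3]) / 2,
    LBp = (L[4, 2] - L[2, 4]) / 2
  )
  structure(list(log_matrix = L, measures = measures),
            class = "differential_matrix")
}

#' Retrieve the chiro-optical state from a measured Mueller matrix
#'
#' Principal-value estimator of the circular retardation and CD angle from
#' the four central elements and the (1,4)/(4,1) pair of a normalized
#' Mueller matrix. The retardation is the least-squares combination
#' `Gamma = atan2(sbar, cbar) / 2` with `cbar = (m22 + m33)/2` and
#' `sbar = (m23 - m32)/2`, which uses all four elements and averages their
#' noise; the result lies on the principal branch `(-pi/2, pi/2]` and
#' `branch_index` is 0. The CD angle comes from `(m14 + m41)/2` through the
#' small-CD relation (atanh, exact for noiseless chiral matrices).
#'
#' @param M A 4x4 normalized Mueller matrix.
#' @return A [chiro_state()].
#' @export
extract_state <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(4, 4))) {
    mp_stop("mp_invalid_argument", "`M` must be a 4x4 matrix")
  }
  mp_check_finite(c(unclass(M)), "M")
  cbar <- (M[2, 2] + M[3, 3]) / 2
  sbar <- (M[2, 3] - M[3, 2]) / 2
  if (cbar == 0 && sbar == 0) {
    mp_stop("mp_degenerate_input",
            "rotation elements are all zero: retardation is fully ambiguous")
  }
  gamma <- atan2(sbar, cbar) / 2
  # fold (-pi/2, pi/2]: atan2 returns (-pi, pi] so gamma is already in range,
  # except the boundary -pi/2 which maps to +pi/2
  if (gamma <= -pi / 2) gamma <- gamma + pi
  m14 <- (M[1, 4] + M[4, 1]) / 2
  gp <- if (abs(m14) < 1) atanh(m14) else sign(m14) * Inf
  if (!is.finite(gp)) {
    mp_stop("mp_invalid_argument", "CD elements outside the physical range")
  }
  chiro_state(gamma, gp, 0L)
}
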