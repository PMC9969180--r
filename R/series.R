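# MuellerSeries: wavelength x time array of normalized Mueller matrices plus
# solution metadata. Elements are stored as a (n_lambda, n_time, 16) array in
# row-major element order m11, m12, ..., m44.

mueller_element_names <- function() {
  paste0("m", rep(1:4, each = 4), rep(1:4, times = 4))
}

#' Construct a Mueller series container
#'
#' @param wavelengths strictly increasing wavelength grid, nm.
#' @param times strictly increasing time stamps, s.
#' @param elements numeric array `length(wavelengths)` x `length(times)` x 16
#'   holding the normalized Mueller elements m11..m44 (row-major).
#' @param manifest list of provenance metadata: at least `solution`
#'   (a [solution_spec()]); typically also `species`, `seed`, `noise_sigma`.
#' @return An object of class `mueller_series`.
#' @export
mueller_series <- function(wavelengths, times, elements, manifest = list()) {
  mp_check_finite(wavelengths, "wavelengths")
  mp_check_finite(times, "times")
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    mp_stop("mp_invalid_argument", "`wavelengths` must be strictly increasing")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    mp_stop("mp_invalid_argument", "`times` must be strictly increasing")
  }
  if (!is.array(elements) ||
      !all(dim(elements) == c(length(wavelengths), length(times), 16L))) {
    mp_stop("mp_invalid_argument",
            "`elements` must be a wavelengths x times x 16 array")
  }
  dimnames(elements) <- list(NULL, NULL, mueller_element_names())
  structure(list(wavelengths = wavelengths, times = times,
                 elements = elements, manifest = manifest),
            class = "mueller_series")
}

#' @export
print.mueller_series <- function(x, ...) {
  cat(sprintf("mueller_series: %d wavelengths (%g-%g nm) x %d time points\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              length(x$times)))
  if (!is.null(x$manifest$species)) cat("  species:", x$manifest$species, "\n")
  invisible(x)
}

#' Extract one Mueller matrix from a series
#'
#' @param series A [mueller_series()].
#' @param i wavelength index.
#' @param j time index (default 1).
#' @return A 4x4 `mueller_matrix`.
#' @export
series_matrix <- function(series, i, j = 1L) {
  M <- matrix(series$elements[i, j, ], 4, 4, byrow = TRUE)
  new_mueller(M, wavelength = series$wavelengths[i])
}

# Pack per-element matrices (each n_lambda x n_time) into the series array.
# `el` is a named list, e.g. list(m22 = ..., m23 = ...); unnamed elements
# default to the identity pattern.
pack_elements <- function(wavelengths, times, el) {
  nl <- length(wavelengths); nt <- length(times)
  ident <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1)
  arr <- array(rep(ident, each = nl * nt), dim = c(nl, nt, 16L),
               dimnames = list(NULL, NULL, mueller_element_names()))
  for (nm in names(el)) arr[, , nm] <- el[[nm]]
  arr
}
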