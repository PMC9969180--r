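# File formats: delimited-text spectra files (one per time point), a JSON
# manifest tying them together, YAML run configuration, and JSON fit results.
# No standard bio-format covers Mueller spectra, so the dialect is the
# package's own: 16 tab-separated columns (wavelength_nm then the 15
# normalized elements m12..m44 in row-major order), mandatory header line.
# Angles in output tables are degrees; internal values are radians.

series_header <- function() {
  c("wavelength_nm", setdiff(mueller_element_names(), "m11"))
}

#' Write a Mueller series to a directory
#'
#' Writes one `spectra_%04d.tsv` file per time point (16 tab-separated
#' columns, 12 significant digits) and a `manifest.json` with the time
#' stamps, solution metadata and provenance (species, seed, noise level).
#'
#' @param series A [mueller_series()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- setdiff(mueller_element_names(), "m11")
  for (j in seq_along(series$times)) {
    df <- data.frame(wavelength_nm = series$wavelengths)
    for (nm in cols) df[[nm]] <- series$elements[, j, nm]
    path <- file.path(dir, sprintf("spectra_%04d.tsv", j))
    lines <- c(paste(series_header(), collapse = "\t"),
               apply(df, 1, function(r) paste(sprintf("%.12g", r), collapse = "\t")))
    writeLines(lines, path)
  }
  man <- series$manifest
  sol <- man$solution
  manifest <- list(
    times_s = series$times,
    temperature_C = sol$temperature_C,
    path_length_mm = sol$path_length_mm,
    molar_concentration = sol$molar_concentration,
    molar_mass = sol$molar_mass,
    species = man$species %||% "",
    seed = man$seed %||% NA,
    noise_sigma = man$noise_sigma %||% NA,
    start_species = man$start_species %||% NULL,
    kind = man$kind %||% ""
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a Mueller series from a directory
#'
#' Lossless inverse of [write_series()] (values round-trip to 12
#' significant digits). Structural problems raise classed errors:
#' `mp_format_error` (bad header, wrong column count with the offending
#' line number, non-monotone wavelengths) or `mp_consistency_error`
#' (manifest time count differing from the number of spectra files).
#'
#' @param dir directory written by [write_series()].
#' @return A [mueller_series()].
#' @export
read_series <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    mp_stop("mp_missing_input", sprintf("no manifest.json in %s", dir))
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^spectra_\\d+\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) {
    mp_stop("mp_missing_input", sprintf("no spectra files in %s", dir))
  }
  times <- as.numeric(man$times_s)
  if (length(times) != length(files)) {
    mp_stop("mp_consistency_error",
            sprintf("manifest lists %d times but %d spectra files found",
                    length(times), length(files)))
  }
  header <- series_header()
  slabs <- vector("list", length(files))
  wl_ref <- NULL
  for (f in seq_along(files)) {
    lines <- readLines(files[f])
    got <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (!identical(got, header)) {
      missing <- setdiff(header, got)
      mp_stop("mp_format_error",
              sprintf("%s line 1: bad header%s", basename(files[f]),
                      if (length(missing)) {
                        paste0(", missing column(s): ",
                               paste(missing, collapse = ", "))
                      } else ""))
    }
    body <- strsplit(lines[-1], "\t", fixed = TRUE)
    nfield <- lengths(body)
    bad <- which(nfield != length(header))
    if (length(bad)) {
      mp_stop("mp_format_error",
              sprintf("%s line %d: expected %d columns, found %d",
                      basename(files[f]), bad[1] + 1L, length(header),
                      nfield[bad[1]]))
    }
    vals <- matrix(as.numeric(unlist(body)), ncol = length(header),
                   byrow = TRUE)
    if (anyNA(vals)) {
      mp_stop("mp_format_error",
              sprintf("%s: non-numeric value", basename(files[f])))
    }
    wl <- vals[, 1]
    if (is.unsorted(wl, strictly = TRUE)) {
      mp_stop("mp_format_error",
              sprintf("%s: wavelength column not strictly increasing",
                      basename(files[f])))
    }
    if (is.null(wl_ref)) wl_ref <- wl
    else if (!isTRUE(all.equal(wl, wl_ref))) {
      mp_stop("mp_consistency_error",
              sprintf("%s: wavelength grid differs from first file",
                      basename(files[f])))
    }
    slabs[[f]] <- vals[, -1, drop = FALSE]
  }
  nl <- length(wl_ref)
  el <- array(0, dim = c(nl, length(files), 16L),
              dimnames = list(NULL, NULL, mueller_element_names()))
  el[, , "m11"] <- 1
  cols <- setdiff(mueller_element_names(), "m11")
  for (f in seq_along(files)) {
    for (k in seq_along(cols)) el[, f, cols[k]] <- slabs[[f]][, k]
  }
  sol <- solution_spec(man$molar_concentration, man$molar_mass,
                       man$path_length_mm, man$temperature_C)
  mueller_series(wl_ref, times, el, manifest = list(
    solution = sol, species = man$species, seed = man$seed,
    noise_sigma = man$noise_sigma,
    start_species = if (is.null(man$start_species)) NULL else man$start_species,
    kind = man$kind))
}

#' Write a fit result to JSON
#'
#' Serializes a `static_fit_result` or `kinetic_fit_result` to a documented
#' JSON schema: fitted parameters, covariance, residual RMS, the
#' configuration echo and seed provenance passed in `provenance`.
#'
#' @param fit fit result object.
#' @param path output file.
#' @param provenance optional list echoed into the file (config, seed).
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path, provenance = list()) {
  out <- if (inherits(fit, "static_fit_result")) {
    list(
      type = "static",
      dispersion = fit$dispersion[c("amplitudes", "resonances_nm")],
      specific_rotation_589 = unname(
        fit$specific_rotation_spectrum[which.min(abs(fit$wavelengths - 589))]),
      residual_rms = fit$residual_rms,
      covariance = fit$covariance,
      niter = fit$niter
    )
  } else if (inherits(fit, "kinetic_fit_result")) {
    list(
      type = "mutarotation",
      tau_s = fit$kinetics$tau,
      K = fit$kinetics$K,
      rates = as.list(fit$rates),
      g_alpha = fit$g_alpha[c("amplitudes", "resonances_nm")],
      g_beta = fit$g_beta[c("amplitudes", "resonances_nm")],
      alpha_specific_rotation_589 = fit$alpha_specific_rotation_589,
      beta_specific_rotation_589 = fit$beta_specific_rotation_589,
      fixed_equilibrium_ratio = as.list(fit$fixed_equilibrium_ratio),
      residual_rms = fit$residual_rms,
      covariance = fit$covariance,
      niter = fit$niter
    )
  } else {
    mp_stop("mp_invalid_argument", "unsupported fit result class")
  }
  out$provenance <- provenance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a run configuration
#'
#' Reads and validates the YAML run configuration used by the command-line
#' interface. Recognized keys: `scenario` ("static" or "mutarotation"),
#' `species`, `seed`, `noise_sigma`, `concentration_M`, `n_times`, and an
#' optional `fit` block (`use_cd`, `K_max`, `fixed_ratio_alpha`).
#'
#' @param path YAML file.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    mp_stop("mp_missing_input", sprintf("config file %s not found", path))
  }
  cfg <- yaml::read_yaml(path)
  cfg$scenario <- cfg$scenario %||% "static"
  if (!cfg$scenario %in% c("static", "mutarotation")) {
    mp_stop("mp_format_error", "scenario must be 'static' or 'mutarotation'")
  }
  cfg$species <- cfg$species %||% "glucose"
  cfg$seed <- as.integer(cfg$seed %||% 0L)
  cfg$fit <- cfg$fit %||% list()
  if (!is.null(cfg$fit$fixed_ratio_alpha)) {
    r <- cfg$fit$fixed_ratio_alpha
    if (!is.numeric(r) || r <= 0 || r >= 1) {
      mp_stop("mp_format_error", "fit.fixed_ratio_alpha must be in (0, 1)")
    }
  }
  structure(cfg, class = c("run_config", "list"))
}
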