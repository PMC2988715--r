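#' Quantum catch of a cone mechanism
#'
#' The quantum catch is the trapezoidal integral over 300-800 nm of the
#' pigment absorbance times the photon irradiance of the light field,
#' `Q = integral A(lambda) E(lambda) d lambda`. Both spectra are resampled to
#' the 1 nm computation grid over the requested range. Irradiance must be a
#' photon (quantal) spectrum; no energy-to-quanta conversion is implied (see
#' [energy_to_photons()]).
#'
#' @param absorbance [spectrum] or `pigment_template`.
#' @param irradiance Photon irradiance [spectrum].
#' @param range Integration bounds (nm); default `c(300, 800)`. Both spectra
#'   must cover the range.
#' @return Scalar quantum catch (units follow the irradiance units).
#' @export
quantum_catch <- function(absorbance, irradiance, range = c(300, 800)) {
  if (inherits(absorbance, "pigment_template"))
    absorbance <- absorbance$absorbance
  stopifnot(is_spectrum(absorbance), is_spectrum(irradiance))
  grid <- seq(range[1], range[2], by = 1)
  a <- resample_spectrum(absorbance, grid)
  e <- resample_spectrum(irradiance, grid)
  integrate_spectrum(spectrum(grid, a$value * e$value), range[1], range[2])
}

#' Quantum catch of light reflected from a color pattern
#'
#' Substitutes the irradiance with the product of the sidewelling irradiance
#' and the spectral reflectance of the pattern, then integrates as in
#' [quantum_catch()].
#'
#' @param absorbance [spectrum] or `pigment_template`.
#' @param sidewelling_irradiance Photon irradiance [spectrum] (e.g. measured
#'   horizontally at depth).
#' @param reflectance Reflectance [spectrum], values in \[0, 1\].
#' @param range Integration bounds (nm).
#' @return Scalar quantum catch.
#' @export
reflectance_catch <- function(absorbance, sidewelling_irradiance, reflectance,
                              range = c(300, 800)) {
  stopifnot(is_spectrum(reflectance))
  if (any(reflectance$value < -1e-9) || any(reflectance$value > 1 + 1e-9))
    stop("reflectance must lie in [0, 1]", call. = FALSE)
  grid <- seq(range[1], range[2], by = 1)
  e <- resample_spectrum(sidewelling_irradiance, grid)
  r <- resample_spectrum(reflectance, grid)
  quantum_catch(absorbance, spectrum(grid, e$value * r$value), range = range)
}

#' Normalize quantum catches to percent of the maximum
#'
#' @param catches Numeric vector of non-negative catches, at least one
#'   positive.
#' @return Numeric vector, `100 * Q / max(Q)`.
#' @export
normalize_catches <- function(catches) {
  catches <- as.numeric(catches)
  if (any(catches < 0)) stop("catches must be non-negative", call. = FALSE)
  if (max(catches) == 0) stop("all catches are zero", call. = FALSE)
  100 * catches / max(catches)
}

#' Quantum catches of a set of cone mechanisms under one background
#'
#' Used to verify the design of chromatic-adaptation (isolation) backgrounds:
#' a background is judged by how strongly it drives each candidate mechanism.
#'
#' @param templates List of `pigment_template` objects (or absorbance
#'   spectra), typically the six classes at A2 proportion 0.5.
#' @param background Photon irradiance [spectrum].
#' @param range Integration bounds (nm).
#' @return Named numeric vector of catches, one per template.
#' @export
mechanism_catches <- function(templates, background, range = c(300, 800)) {
  q <- vapply(templates, quantum_catch, numeric(1),
              irradiance = background, range = range)
  if (is.null(names(q)) || any(!nzchar(names(q))))
    names(q) <- seq_along(q)
  q
}

#' Convert an energy irradiance spectrum to photon units
#'
#' Divides by the photon energy `hc / lambda`; never applied implicitly by
#' any other function in the package.
#'
#' @param x Energy irradiance [spectrum] (W cm^-2 nm^-1).
#' @return Photon irradiance [spectrum] (photons cm^-2 s^-1 nm^-1).
#' @export
energy_to_photons <- function(x) {
  stopifnot(is_spectrum(x))
  h <- 6.62607015e-34  # J s
  c0 <- 2.99792458e8   # m s^-1
  photon_energy <- h * c0 / (x$wavelength * 1e-9)
  spectrum(x$wavelength, x$value / photon_energy)
}
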