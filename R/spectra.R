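#' Construct a spectrum
#'
#' A spectrum is the universal carrier for wavelength-indexed quantities in
#' this package: photon irradiance, reflectance, lens transmission, pigment
#' absorbance and linear relative sensitivity all travel as spectra.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   at least two points.
#' @param value Numeric vector of the same length. Units depend on role:
#'   photons cm^-2 s^-1 nm^-1 for irradiance, a fraction in \[0, 1\] for
#'   reflectance/transmission/absorbance, unitless for relative sensitivity.
#' @param bounded If `TRUE`, values are checked to lie in \[0, 1\] (with a
#'   small tolerance), as appropriate for reflectance, transmission and
#'   peak-normalized absorbance.
#' @return An object of class `spectrum`: a data frame with columns
#'   `wavelength` and `value`.
#' @examples
#' s <- spectrum(300:800, rep(1, 501))
#' integrate_spectrum(s, 300, 800)
#' @export
spectrum <- function(wavelength, value, bounded = FALSE) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two wavelengths", call. = FALSE)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have equal length", call. = FALSE)
  if (anyNA(wavelength) || anyNA(value))
    stop("NA in spectrum", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (bounded && (any(value < -1e-6) || any(value > 1 + 1e-6)))
    stop("bounded spectrum values must lie in [0, 1]", call. = FALSE)
  structure(data.frame(wavelength = wavelength, value = value),
            class = c("spectrum", "data.frame"))
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d points, %g-%g nm, values %.4g-%.4g>\n",
              nrow(x), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation is never performed — a grid point
#' outside the source support is an error.
#'
#' @param x A [spectrum].
#' @param grid Numeric vector of target wavelengths (nm), strictly increasing,
#'   within the source range.
#' @return A [spectrum] on `grid`.
#' @export
resample_spectrum <- function(x, grid) {
  stopifnot(is_spectrum(x))
  grid <- as.numeric(grid)
  if (min(grid) < min(x$wavelength) - 1e-9 ||
      max(grid) > max(x$wavelength) + 1e-9)
    stop(sprintf("resampling grid [%g, %g] outside source support [%g, %g]",
                 min(grid), max(grid), min(x$wavelength), max(x$wavelength)),
         call. = FALSE)
  v <- stats::approx(x$wavelength, x$value, xout = grid, rule = 1)$y
  spectrum(grid, v)
}

#' Trapezoidal integral of a spectrum over a wavelength range
#'
#' @param x A [spectrum].
#' @param lo,hi Integration bounds (nm), `lo < hi`, both within the support.
#' @return Scalar integral.
#' @export
integrate_spectrum <- function(x, lo = min(x$wavelength),
                               hi = max(x$wavelength)) {
  stopifnot(is_spectrum(x))
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  if (lo < min(x$wavelength) - 1e-9 || hi > max(x$wavelength) + 1e-9)
    stop(sprintf("integration bounds [%g, %g] outside support [%g, %g]",
                 lo, hi, min(x$wavelength), max(x$wavelength)), call. = FALSE)
  w <- x$wavelength
  keep <- w > lo & w < hi
  grid <- unique(sort(c(lo, w[keep], hi)))
  v <- stats::approx(w, x$value, xout = grid, rule = 1)$y
  sum(diff(grid) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Read a spectrum from delimited text
#'
#' Two columns `wavelength_nm` and `value`, header required, tab or comma
#' delimited (auto-detected), lines starting with `#` ignored.
#'
#' @param path File path.
#' @param bounded Passed to [spectrum()].
#' @return A [spectrum].
#' @export
read_spectrum <- function(path, bounded = FALSE) {
  d <- read_delim_auto(path)
  need <- c("wavelength_nm", "value")
  if (!all(need %in% names(d)))
    stop("spectrum file must have columns wavelength_nm and value",
         call. = FALSE)
  d <- d[order(d$wavelength_nm), , drop = FALSE]
  spectrum(d$wavelength_nm, d$value, bounded = bounded)
}

#' Write a spectrum as tab-separated text
#'
#' Emits header `wavelength_nm\tvalue` with values at 6 significant digits.
#'
#' @param x A [spectrum].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  d <- data.frame(wavelength_nm = x$wavelength,
                  value = signif(x$value, 6))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Auto-detect tab vs comma delimiter; '#' comment lines dropped.
read_delim_auto <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data in ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  utils::read.table(text = lines, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
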