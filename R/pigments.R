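#' Cone pigment classes and their A1 peak wavelengths
#'
#' The six cone pigment classes of Lake Malawi cichlids with the lambda-max of
#' the A1-reconstituted (retinal) visual pigment. RH2a-alpha (519 nm) and
#' RH2a-beta (528 nm) are pooled as RH2a with the averaged peak at 523 nm
#' because of their genetic and spectral similarity.
#'
#' @return Named numeric vector of A1 lambda-max values (nm).
#' @export
pigment_classes <- function() {
  c(SWS1 = 368, SWS2b = 423, SWS2a = 456,
    RH2b = 484, RH2a = 523, LWS = 560)
}

#' Default 1 nm computation grid (300-800 nm)
#' @return Integer wavelength vector.
#' @export
template_grid <- function() 300:800

#' Measurement grid of the spectral-sensitivity protocol (320-700 nm, 20 nm)
#' @return Integer wavelength vector.
#' @export
sensitivity_grid <- function() seq(320L, 700L, by = 20L)

# Govardovskii-style rhodopsin (A1) alpha band. x = lambda_max / lambda.
a1_alpha <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
       exp(-14.9 * (1.104 - x)) + 0.674)
}

# A1 beta band: Gaussian centred on a lambda-max-dependent UV peak.
a1_beta <- function(lambda, lambda_max) {
  lmb <- 189 + 0.315 * lambda_max
  bb <- -40.5 + 0.195 * lambda_max
  0.26 * exp(-((lambda - lmb) / bb)^2)
}

# Porphyropsin (A2) alpha band.
a2_alpha <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  A <- 62.7 + 1.834 * exp((lambda_max - 625) / 54.2)
  a <- 0.875 + 0.0268 * exp((lambda_max - 665) / 40.7)
  1 / (exp(A * (a - x)) + exp(20.85 * (0.9101 - x)) +
       exp(-10.37 * (1.1123 - x)) + 0.5343)
}

# A2 beta band.
a2_beta <- function(lambda, lambda_max) {
  lmb <- 216.7 + 0.287 * lambda_max
  bb <- 317 - 1.149 * lambda_max + 0.00124 * lambda_max^2
  0.26 * exp(-((lambda - lmb) / bb)^2)
}

#' A1 (retinal) visual pigment absorbance template
#'
#' Alpha plus beta band, peak-normalized to 1 on the supplied grid.
#'
#' @param lambda_max Peak wavelength (nm), between 350 and 600.
#' @param grid Wavelength grid (nm); default 1 nm from 300 to 800.
#' @return A [spectrum] of relative absorbance.
#' @export
a1_template <- function(lambda_max, grid = template_grid()) {
  if (lambda_max < 350 || lambda_max > 600)
    stop("lambda_max must be within [350, 600] nm", call. = FALSE)
  v <- a1_alpha(grid, lambda_max) + a1_beta(grid, lambda_max)
  spectrum(grid, v / max(v))
}

#' A2 (3,4-didehydroretinal) visual pigment absorbance template
#'
#' @param lambda_max Peak wavelength (nm) of the A2 pigment.
#' @param grid Wavelength grid (nm).
#' @return A [spectrum] of relative absorbance.
#' @export
a2_template <- function(lambda_max, grid = template_grid()) {
  if (lambda_max < 350 || lambda_max > 700)
    stop("lambda_max must be within [350, 700] nm", call. = FALSE)
  v <- a2_alpha(grid, lambda_max) + a2_beta(grid, lambda_max)
  spectrum(grid, v / max(v))
}

# Quadratic chromophore-shift relation anchored at the two printed pairs
# RH2a 523 -> 560 and LWS 560 -> 626; shift vanishes below the vertex.
a2_shift_params <- local({
  r <- sqrt(66 / 37)
  l0 <- (560 - r * 523) / (1 - r)
  list(l0 = l0, k = 37 / (523 - l0)^2)
})

#' Full-A2 lambda-max for a pigment with a given A1 lambda-max
#'
#' The A1 to A2 chromophore exchange red-shifts the absorbance peak by an
#' amount that grows with wavelength. The relation used here is a monotone
#' quadratic anchored exactly at the RH2a (523 to 560 nm) and LWS (560 to
#' 626 nm) pairs, with zero shift at short wavelengths where A1 and A2 peaks
#' coincide.
#'
#' @param lambda_max_a1 A1 lambda-max (nm).
#' @return Full-A2 lambda-max (nm); always `>= lambda_max_a1`.
#' @examples
#' a2_lambda_max(560) # 626
#' a2_lambda_max(523) # 560
#' @export
a2_lambda_max <- function(lambda_max_a1) {
  p <- a2_shift_params
  ifelse(lambda_max_a1 <= p$l0, lambda_max_a1,
         lambda_max_a1 + p$k * (lambda_max_a1 - p$l0)^2)
}

#' Mixed-chromophore visual pigment template
#'
#' A retina with A2 proportion `a` carries pigment whose absorbance is the
#' mixture (1 - a) * A1 + a * A2, where the A2 component sits at the shifted
#' lambda-max given by [a2_lambda_max()]. The mixture is peak-normalized and
#' the effective lambda-max is read off the curve.
#'
#' @param pigment Pigment class name (one of `names(pigment_classes())`) or a
#'   numeric A1 lambda-max.
#' @param a2_fraction A2 proportion `a` in \[0, 1\].
#' @param grid Wavelength grid (nm).
#' @return An object of class `pigment_template`: list with elements
#'   `pigment`, `lambda_max_a1`, `a2_fraction`, `absorbance` ([spectrum]) and
#'   `effective_lambda_max`.
#' @export
mixed_template <- function(pigment, a2_fraction = 0, grid = template_grid()) {
  if (a2_fraction < 0 || a2_fraction > 1)
    stop("a2_fraction must lie in [0, 1]", call. = FALSE)
  if (is.character(pigment)) {
    cls <- pigment_classes()
    if (!pigment %in% names(cls))
      stop("unknown pigment class: ", pigment, call. = FALSE)
    name <- pigment
    lm1 <- cls[[pigment]]
  } else {
    name <- NA_character_
    lm1 <- as.numeric(pigment)
  }
  v1 <- a1_template(lm1, grid)$value
  v2 <- a2_template(a2_lambda_max(lm1), grid)$value
  v <- (1 - a2_fraction) * v1 + a2_fraction * v2
  abs_sp <- spectrum(grid, v / max(v))
  structure(list(pigment = name,
                 lambda_max_a1 = lm1,
                 a2_fraction = a2_fraction,
                 absorbance = abs_sp,
                 effective_lambda_max = grid[which.max(v)]),
            class = "pigment_template")
}

#' @export
print.pigment_template <- function(x, ...) {
  cat(sprintf("<pigment_template %s: A1 %g nm, a2 %.2f, effective %g nm>\n",
              ifelse(is.na(x$pigment), "(custom)", x$pigment),
              x$lambda_max_a1, x$a2_fraction, x$effective_lambda_max))
  invisible(x)
}

#' Correct a pigment template for ocular (lens) transmission
#'
#' Multiplies the absorbance by the lens transmission spectrum (resampled to
#' the template grid) and renormalizes to peak 1.
#'
#' @param template A `pigment_template`.
#' @param lens A [spectrum] of transmission values in \[0, 1\] covering the
#'   template grid.
#' @return A `pigment_template` with corrected absorbance and updated
#'   effective lambda-max.
#' @export
apply_lens_transmission <- function(template, lens) {
  stopifnot(inherits(template, "pigment_template"), is_spectrum(lens))
  grid <- template$absorbance$wavelength
  tr <- resample_spectrum(lens, grid)$value
  if (any(tr < -1e-9) || any(tr > 1 + 1e-9))
    stop("lens transmission must lie in [0, 1]", call. = FALSE)
  v <- template$absorbance$value * tr
  if (max(v) <= 0) stop("lens annihilates the template", call. = FALSE)
  template$absorbance <- spectrum(grid, v / max(v))
  template$effective_lambda_max <- grid[which.max(v)]
  template
}

#' Build the full lens-corrected template set for one retina
#'
#' @param a2_fraction Shared A2 proportion applied to every class.
#' @param classes Character vector of pigment class names.
#' @param lens Optional lens transmission [spectrum].
#' @param grid Wavelength grid (nm).
#' @return Named list of `pigment_template` objects.
#' @export
template_set <- function(a2_fraction = 0, classes = names(pigment_classes()),
                         lens = NULL, grid = template_grid()) {
  out <- lapply(classes, mixed_template, a2_fraction = a2_fraction,
                grid = grid)
  names(out) <- classes
  if (!is.null(lens)) out <- lapply(out, apply_lens_transmission, lens = lens)
  out
}
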