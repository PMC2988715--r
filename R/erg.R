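#' Fit the Naka-Rushton function to a response-intensity curve
#'
#' Fits `R(I) = Rmax * I / (I + K)` (slope exponent fixed at 1) by least
#' squares to b-wave amplitudes recorded at graded stimulus irradiances. The
#' fit is solved by profiling: for any candidate LogK the optimal `Rmax` is
#' linear and closed-form, so the joint optimum is found by deterministic 1-D
#' minimization of the profiled residual sum of squares over LogK, bounded at
#' the observed irradiance range plus/minus 2 log units.
#'
#' Sensitivity at the tested wavelength is `1/K`.
#'
#' @param log_irradiance Numeric vector, log10 photons cm^-2 s^-1.
#' @param response Numeric vector of b-wave amplitudes (uV), same length.
#' @param fixed_r_max Optional fixed maximum-response parameter (uV); when
#'   given only LogK is fitted (the edge-wavelength rule).
#' @return Object of class `naka_rushton_fit`: list with `r_max`, `log_k`,
#'   `r_squared`, `r_max_constrained`, `converged`, `n`.
#' @export
fit_naka_rushton <- function(log_irradiance, response, fixed_r_max = NULL) {
  x <- as.numeric(log_irradiance)
  y <- as.numeric(response)
  stopifnot(length(x) == length(y))
  if (any(y < 0)) stop("responses must be non-negative", call. = FALSE)
  need <- if (is.null(fixed_r_max)) 3L else 2L
  if (length(x) < need)
    stop(sprintf("need at least %d points", need), call. = FALSE)

  # model response for unit Rmax at log10 irradiance x, half-saturation logk
  unit_resp <- function(logk) 1 / (1 + 10^(logk - x))
  rss <- function(logk) {
    f <- unit_resp(logk)
    rmax <- if (is.null(fixed_r_max)) {
      max(sum(y * f) / sum(f * f), 0)
    } else fixed_r_max
    sum((y - rmax * f)^2)
  }
  lo <- min(x) - 2
  hi <- max(x) + 2
  opt <- stats::optimize(rss, c(lo, hi), tol = 1e-10)
  logk <- opt$minimum
  f <- unit_resp(logk)
  rmax <- if (is.null(fixed_r_max)) max(sum(y * f) / sum(f * f), 0)
          else fixed_r_max
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - opt$objective / sstot else NA_real_
  converged <- rmax > 0 && logk > lo + 1e-6 && logk < hi - 1e-6
  structure(list(r_max = rmax, log_k = logk, r_squared = r2,
                 r_max_constrained = !is.null(fixed_r_max),
                 converged = converged, n = length(x)),
            class = "naka_rushton_fit")
}

#' @export
print.naka_rushton_fit <- function(x, ...) {
  cat(sprintf("<naka_rushton_fit: Rmax %.3g uV%s, LogK %.4f, R2 %.3f%s>\n",
              x$r_max, if (x$r_max_constrained) " (fixed)" else "",
              x$log_k, x$r_squared,
              if (x$converged) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' Fit Naka-Rushton curves for every wavelength of one recording session
#'
#' @param ri Data frame with columns `wavelength_nm`, `log_irradiance`,
#'   `response_uV` (one individual, one background condition).
#' @return Named list of `naka_rushton_fit`, names = wavelengths (nm).
#' @export
fit_ri_curves <- function(ri) {
  need <- c("wavelength_nm", "log_irradiance", "response_uV")
  if (!all(need %in% names(ri)))
    stop("ri needs columns ", paste(need, collapse = ", "), call. = FALSE)
  wls <- sort(unique(ri$wavelength_nm))
  fits <- lapply(wls, function(w) {
    d <- ri[ri$wavelength_nm == w, ]
    fit_naka_rushton(d$log_irradiance, d$response_uV)
  })
  names(fits) <- wls
  fits
}

#' Apply the edge-wavelength maximum-response rule
#'
#' At wavelengths below 360 nm or above 600 nm the response-intensity curve
#' often fails to reach its upper asymptote. Where the fitted `Rmax` exceeds
#' the largest observed response by more than 25% (the asymptote-not-reached
#' criterion), the curve is refitted with `Rmax` fixed to that of the nearest
#' interior neighboring wavelength.
#'
#' @param fits Named list of `naka_rushton_fit` (names = wavelengths).
#' @param ri The response-intensity data frame the fits came from.
#' @param edge_low,edge_high Interior range bounds (nm); default 360 and 600.
#' @param tolerance Allowed fractional excess of fitted `Rmax` over the
#'   maximum observed response before the rule fires (default 0.25).
#' @return The list of fits with edge wavelengths refitted where needed;
#'   refits carry `r_max_constrained = TRUE`.
#' @export
constrain_edge_rmax <- function(fits, ri, edge_low = 360, edge_high = 600,
                                tolerance = 0.25) {
  wls <- as.numeric(names(fits))
  interior <- wls[wls >= edge_low & wls <= edge_high]
  for (i in seq_along(fits)) {
    w <- wls[[i]]
    if (w >= edge_low && w <= edge_high) next
    d <- ri[ri$wavelength_nm == w, ]
    max_obs <- max(d$response_uV)
    if (fits[[i]]$r_max <= (1 + tolerance) * max_obs) next
    if (length(interior) == 0L) {
      warning(sprintf("edge wavelength %g nm has no interior neighbor; dropped", w))
      fits[[i]] <- NULL
      next
    }
    neighbor <- interior[which.min(abs(interior - w))]
    rmax_fixed <- fits[[as.character(neighbor)]]$r_max
    fits[[i]] <- fit_naka_rushton(d$log_irradiance, d$response_uV,
                                  fixed_r_max = rmax_fixed)
  }
  fits
}

#' Build a log relative spectral-sensitivity curve from Naka-Rushton fits
#'
#' Absolute sensitivity at each wavelength is `1/K`; the log relative curve
#' is `log10(1/K)` normalized so its maximum is exactly 0.
#'
#' @param fits Named list of `naka_rushton_fit` (names = wavelengths, nm).
#' @param individual Individual identifier.
#' @param condition Background condition label (e.g. "control", "LW", "SW",
#'   "Dim-SW").
#' @return Object of class `sensitivity_curve`: list with `individual`,
#'   `condition`, `wavelength`, `log_rel_sensitivity`.
#' @export
build_sensitivity_curve <- function(fits, individual = NA_character_,
                                    condition = NA_character_) {
  ok <- vapply(fits, function(f) isTRUE(f$converged) || f$r_max_constrained,
               logical(1))
  if (!any(ok)) stop("all Naka-Rushton fits failed", call. = FALSE)
  fits <- fits[ok]
  if (length(fits) < 5L)
    stop("need fits at >= 5 wavelengths for a sensitivity curve",
         call. = FALSE)
  wl <- as.numeric(names(fits))
  log_s <- -vapply(fits, `[[`, numeric(1), "log_k")  # log10(1/K)
  ord <- order(wl)
  curve <- list(individual = individual, condition = condition,
                wavelength = wl[ord],
                log_rel_sensitivity = unname(log_s[ord] - max(log_s)))
  structure(curve, class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("<sensitivity_curve %s/%s: %d wavelengths, peak at %g nm>\n",
              x$individual, x$condition, length(x$wavelength),
              x$wavelength[which.max(x$log_rel_sensitivity)]))
  invisible(x)
}

#' Convert a log relative sensitivity curve to linear relative sensitivity
#'
#' Transforms log relative sensitivity to the linear scale (`10^log`) and
#' min-max rescales to \[0, 1\], the preprocessing used before template and
#' opponency-model fitting.
#'
#' @param curve A `sensitivity_curve`.
#' @return A [spectrum] with values in \[0, 1\].
#' @export
to_linear_relative <- function(curve) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  lin <- 10^curve$log_rel_sensitivity
  rng <- range(lin)
  if (diff(rng) == 0) return(spectrum(curve$wavelength, rep(0, length(lin))))
  spectrum(curve$wavelength, (lin - rng[1]) / diff(rng))
}

#' Read response-intensity records from delimited text
#'
#' Columns: `individual`, `condition`, `wavelength_nm`, `log_irradiance`,
#' `response_uV`.
#'
#' @param path File path (tab or comma delimited, '#' comments ignored).
#' @return Data frame.
#' @export
read_ri <- function(path) {
  d <- read_delim_auto(path)
  need <- c("individual", "condition", "wavelength_nm",
            "log_irradiance", "response_uV")
  if (!all(need %in% names(d)))
    stop("RI file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d
}

#' Sensitivity curves for every individual/condition in an RI table
#'
#' Runs [fit_ri_curves()], [constrain_edge_rmax()] and
#' [build_sensitivity_curve()] per individual and condition.
#'
#' @param ri Data frame as returned by [read_ri()].
#' @return Nested list: `curves[[individual]][[condition]]`.
#' @export
sensitivity_from_ri <- function(ri) {
  out <- list()
  for (id in unique(ri$individual)) {
    di <- ri[ri$individual == id, ]
    out[[as.character(id)]] <- list()
    for (cond in unique(di$condition)) {
      d <- di[di$condition == cond, ]
      fits <- fit_ri_curves(d)
      fits <- constrain_edge_rmax(fits, d)
      out[[as.character(id)]][[cond]] <-
        build_sensitivity_curve(fits, individual = id, condition = cond)
    }
  }
  out
}
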