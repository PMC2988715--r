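#' Find sensitivity notches delimiting opponency-model segments
#'
#' Notches are strict local minima of the linear relative sensitivity curve
#' (plateau ties resolve to the shorter wavelength); together with the curve
#' ends they bound the spectral segments over which the multiple-cone
#' mechanism model is fitted.
#'
#' @param curve Linear relative sensitivity [spectrum].
#' @return Numeric vector of boundary wavelengths (nm), including both curve
#'   ends.
#' @export
find_notches <- function(curve) {
  stopifnot(is_spectrum(curve))
  if (nrow(curve) < 5L) stop("need at least 5 grid points", call. = FALSE)
  interior <- curve$wavelength[local_minima(curve$value)]
  sort(unique(c(min(curve$wavelength), interior, max(curve$wavelength))))
}

#' Fit one opponency-model segment
#'
#' Fits the multiple-cone mechanism model `S(lambda) = sum_i k_i A_i(lambda)`
#' over one notch-delimited spectral range by unconstrained linear least
#' squares; weights may be positive (excitatory, nonopponent) or negative
#' (inhibitory, opponent).
#'
#' @param curve Linear relative sensitivity [spectrum].
#' @param range Length-2 numeric, the segment bounds (nm).
#' @param templates Named list of `pigment_template`.
#' @param combo Character vector of 1-3 pigment class names (must be in
#'   `names(templates)`).
#' @return Object of class `mcm_segment`: list with `range`, `weights`
#'   (named), `r_squared`, `n_points`.
#' @export
fit_segment <- function(curve, range, templates, combo) {
  stopifnot(is_spectrum(curve), length(range) == 2L)
  if (length(combo) < 1L || length(combo) > 3L)
    stop("combo must have 1-3 pigments", call. = FALSE)
  if (!all(combo %in% names(templates)))
    stop("combo pigments missing from templates", call. = FALSE)
  sel <- curve$wavelength >= range[1] - 1e-9 &
         curve$wavelength <= range[2] + 1e-9
  wl <- curve$wavelength[sel]
  y <- curve$value[sel]
  if (length(y) < length(combo) + 1L)
    stop(sprintf("segment [%g, %g] has %d points; need > %d free parameters",
                 range[1], range[2], length(y), length(combo)),
         call. = FALSE)
  X <- vapply(combo, function(cl)
    resample_spectrum(templates[[cl]]$absorbance, wl)$value,
    numeric(length(wl)))
  X <- matrix(X, ncol = length(combo),
              dimnames = list(NULL, combo))
  k <- stats::lsfit(X, y, intercept = FALSE)$coefficients
  names(k) <- combo
  res <- y - X %*% k
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  structure(list(range = range, weights = k, r_squared = r2,
                 n_points = length(y)),
            class = "mcm_segment")
}

#' @export
print.mcm_segment <- function(x, ...) {
  cat(sprintf("<mcm_segment %g-%g nm: %s; R2 %.3f>\n",
              x$range[1], x$range[2],
              paste(sprintf("%s %+.3f", names(x$weights), x$weights),
                    collapse = ", "),
              x$r_squared))
  invisible(x)
}

#' Select cone interactions for every segment across background conditions
#'
#' For each notch-delimited segment, enumerates every combination of 1 to
#' `max_cones` of the candidate pigments and fits it under every background.
#' Selection follows three criteria: the model must (3) keep the same type of
#' interaction — identical weight signs — under all backgrounds; among
#' sign-consistent candidates the model (1) with the fewest cones whose mean
#' R-squared is within `margin` of the best survivor is chosen, (2)
#' tie-breaking by best mean R-squared. If no combination is sign-consistent
#' the best-fitting one is returned flagged inconsistent.
#'
#' @param curves Named list of linear relative sensitivity [spectrum]
#'   objects, one per background condition.
#' @param segments Numeric vector of boundary wavelengths (from
#'   [find_notches()], typically on the control curve).
#' @param templates Named list of `pigment_template` for the individual's
#'   assigned pigments.
#' @param max_cones Maximum pigments per segment (default 3).
#' @param margin Parsimony margin on mean R-squared (default 0.02).
#' @param exclude_below Optional wavelength; segments entirely below it are
#'   skipped (used to leave beta-band-dominated UV ranges unmodelled).
#' @return Object of class `mcm_model`: list with `segments` (list of
#'   per-segment summaries: range, combo, signs, mean_r2, per-background
#'   weights and R2, consistent, dominant) and `interaction_table` (data
#'   frame of signs per segment and pigment).
#' @export
select_interaction <- function(curves, segments, templates, max_cones = 3,
                               margin = 0.02, exclude_below = NULL) {
  stopifnot(length(curves) >= 1L, length(segments) >= 2L)
  pigs <- names(templates)
  combos <- unlist(lapply(seq_len(min(max_cones, length(pigs))),
                          function(m) utils::combn(pigs, m, simplify = FALSE)),
                   recursive = FALSE)
  seg_out <- list()
  for (s in seq_len(length(segments) - 1L)) {
    rng <- c(segments[s], segments[s + 1L])
    if (!is.null(exclude_below) && rng[2] <= exclude_below) next
    fits <- lapply(combos, function(cb) {
      per_bg <- lapply(curves, function(cv)
        tryCatch(fit_segment(cv, rng, templates, cb), error = function(e) NULL))
      if (any(vapply(per_bg, is.null, logical(1)))) return(NULL)
      signs <- vapply(per_bg, function(f) paste(sign_tol(f$weights),
                                                collapse = ""), character(1))
      list(combo = cb, per_bg = per_bg,
           mean_r2 = mean(vapply(per_bg, `[[`, numeric(1), "r_squared")),
           consistent = length(unique(signs)) == 1L,
           signs = sign_tol(per_bg[[1]]$weights))
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L) next
    surv <- Filter(function(f) f$consistent, fits)
    flagged <- length(surv) == 0L
    pool <- if (flagged) fits else surv
    best_r2 <- max(vapply(pool, `[[`, numeric(1), "mean_r2"))
    ok <- Filter(function(f) f$mean_r2 >= best_r2 - margin, pool)
    sizes <- vapply(ok, function(f) length(f$combo), integer(1))
    ok <- ok[sizes == min(sizes)]
    pick <- ok[[which.max(vapply(ok, `[[`, numeric(1), "mean_r2"))]]

    # dominant pigment: the largest (positive) contribution at the
    # segment's sensitivity peak under the first background
    cv_ref <- curves[[1]]
    sel <- cv_ref$wavelength >= rng[1] - 1e-9 &
           cv_ref$wavelength <= rng[2] + 1e-9
    peak_wl <- cv_ref$wavelength[sel][which.max(cv_ref$value[sel])]
    k_ref <- pick$per_bg[[1]]$weights
    contrib <- vapply(pick$combo, function(cl)
      k_ref[[cl]] * resample_spectrum(templates[[cl]]$absorbance,
                                      c(peak_wl, peak_wl + 1))$value[1],
      numeric(1))
    seg_out[[length(seg_out) + 1L]] <-
      list(range = rng, combo = pick$combo, signs = pick$signs,
           mean_r2 = pick$mean_r2, per_background = pick$per_bg,
           consistent = !flagged,
           dominant = pick$combo[which.max(contrib)])
  }
  itab <- do.call(rbind, lapply(seg_out, function(sg) {
    row <- stats::setNames(rep("", length(pigs)), pigs)
    row[sg$combo] <- ifelse(sg$signs > 0, "+", ifelse(sg$signs < 0, "-", "0"))
    data.frame(lambda1 = sg$range[1], lambda2 = sg$range[2],
               t(row), dominant = sg$dominant, mean_r2 = sg$mean_r2,
               consistent = sg$consistent, check.names = FALSE)
  }))
  structure(list(segments = seg_out, interaction_table = itab),
            class = "mcm_model")
}

sign_tol <- function(k, tol = 1e-8) as.integer(sign(ifelse(abs(k) < tol, 0, k)))

#' @export
print.mcm_model <- function(x, ...) {
  cat("<mcm_model>\n")
  print(x$interaction_table)
  invisible(x)
}

#' Concatenated R-squared of an MCM model across its segments
#'
#' Stitches the per-segment predictions under one background into a single
#' curve and reports the overall variance explained, alongside the
#' per-segment values.
#'
#' @param model An `mcm_model`.
#' @param condition Background condition name (index into the per-background
#'   fits).
#' @param curves The same named list of curves passed to
#'   [select_interaction()].
#' @param templates The same template list.
#' @return List with `concatenated_r2` and `per_segment_r2`.
#' @export
mcm_global_r2 <- function(model, condition, curves, templates) {
  cv <- curves[[condition]]
  yhat <- rep(NA_real_, nrow(cv))
  for (sg in model$segments) {
    sel <- cv$wavelength >= sg$range[1] - 1e-9 &
           cv$wavelength <= sg$range[2] + 1e-9
    X <- vapply(sg$combo, function(cl)
      resample_spectrum(templates[[cl]]$absorbance,
                        cv$wavelength[sel])$value,
      numeric(sum(sel)))
    X <- matrix(X, ncol = length(sg$combo))
    k <- sg$per_background[[condition]]$weights
    yhat[sel] <- X %*% k
  }
  ok <- !is.na(yhat)
  y <- cv$value[ok]
  r2 <- 1 - sum((y - yhat[ok])^2) / sum((y - mean(y))^2)
  list(concatenated_r2 = r2,
       per_segment_r2 = vapply(model$segments, function(sg)
         sg$per_background[[condition]]$r_squared, numeric(1)))
}
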