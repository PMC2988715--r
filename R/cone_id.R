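#' Detect candidate cone-mechanism peaks across background conditions
#'
#' Applies the two identification criteria for functional cone mechanisms:
#' (1) a sensitivity peak must appear (within one 20 nm grid step) under at
#' least two background isolation conditions, and (2) its amplitude must
#' track the background manipulation. The tracking test is decisive in the
#' UV range (340-400 nm), where a bump may be either a UV cone or the
#' beta-band of mid/long-wavelength cones: a UV-range peak is accepted as a
#' cone only when its amplitude is larger under the background that spares
#' the UV mechanism (lowest SWS1 quantum catch) than under the background
#' that adapts it (highest catch); otherwise it is labelled beta-band.
#' Outside the UV range spectrally adjacent mechanisms respond to the
#' background tilts so similarly that relative-amplitude direction is not
#' diagnostic, and presence under two conditions (criterion 1) governs.
#'
#' @param curves List of `sensitivity_curve` objects for one individual, one
#'   per background condition (at least two).
#' @param backgrounds Optional named list of background irradiance spectra
#'   (names matching the curve conditions). When supplied together with
#'   `templates`, criterion 2 is evaluated; otherwise only criterion 1.
#' @param templates Optional named list of `pigment_template` used to rank
#'   backgrounds by mechanism quantum catch (typically [template_set()] at
#'   A2 proportion 0.5, the design convention).
#' @param tol Matching tolerance across conditions in nm (default 20, one
#'   grid step).
#' @return Data frame of peak candidates: `wavelength`, `n_conditions`,
#'   `conditions`, `accepted`, `label` ("cone" or "beta-band" or
#'   "single-condition").
#' @export
detect_peaks <- function(curves, backgrounds = NULL, templates = NULL,
                         tol = 20) {
  if (length(curves) < 2L)
    stop("need curves under at least two background conditions",
         call. = FALSE)
  conds <- vapply(curves, `[[`, character(1), "condition")
  names(curves) <- conds
  lins <- lapply(curves, to_linear_relative)

  # Candidate peaks come from the condition-averaged curve, whose per-point
  # noise is reduced by sqrt(n conditions); criterion 1 then asks in how
  # many single conditions the candidate appears. A candidate "appears"
  # under a condition when, within one grid step, some point stands at or
  # above both its neighbors up to `appear_tol` log units — a peak whose
  # notch is partly filled by measurement noise still appears, while
  # spectral regions sloping monotonically away do not.
  avg <- mean_linear_curve(curves)
  cand_w <- avg$wavelength[local_maxima(avg$value)]

  # A peak whose notch the averaging happens to blur can still be a clear
  # local maximum in individual conditions: wavelengths where at least two
  # conditions show coincident local maxima (greedy vote clustering, one
  # peak per condition per cluster) supplement the averaged-curve
  # candidates.
  pool <- lapply(lins, function(s) s$wavelength[local_maxima(s$value)])
  repeat {
    remaining <- sort(unique(unlist(pool)))
    if (length(remaining) == 0L) break
    props <- lapply(remaining, function(w) {
      sup <- lapply(conds, function(cn) {
        p <- pool[[cn]]
        if (length(p) == 0L) return(NULL)
        d <- abs(p - w)
        if (min(d) <= tol + 1e-9) p[which.min(d)] else NULL
      })
      names(sup) <- conds
      Filter(Negate(is.null), sup)
    })
    ns <- lengths(props)
    best_i <- order(-ns, remaining)[1]
    sup <- props[[best_i]]
    if (ns[best_i] >= 2L &&
        all(abs(cand_w - remaining[best_i]) > tol + 1e-9))
      cand_w <- sort(c(cand_w, remaining[best_i]))
    if (ns[best_i] == 0L) break
    for (cn in names(sup)) pool[[cn]] <- setdiff(pool[[cn]], sup[[cn]])
  }
  if (length(cand_w) == 0L)
    return(data.frame(wavelength = numeric(0), n_conditions = integer(0),
                      conditions = character(0), accepted = logical(0),
                      label = character(0)))
  appear_tol <- 0.1
  appears <- function(curve, w) {
    v <- curve$log_rel_sensitivity
    n <- length(v)
    idx <- which(abs(curve$wavelength - w) <= tol + 1e-9)
    idx <- idx[idx > 1L & idx < n]
    any(vapply(idx, function(i)
      v[i] >= max(v[i - 1L], v[i + 1L]) - appear_tol, logical(1)))
  }
  cand <- lapply(cand_w, function(w) {
    hit <- vapply(curves, appears, logical(1), w = w)
    list(wavelength = w, conditions = conds[hit], n = sum(hit))
  })

  has_q <- !is.null(backgrounds) && !is.null(templates)
  if (has_q) {
    qmat <- vapply(backgrounds, function(bg)
      mechanism_catches(templates, bg), numeric(length(templates)))
    # rows: templates, cols: conditions. Backgrounds are ranked by the
    # mechanism's share of the background's mean drive, so that overall
    # intensity (e.g. the dim variant of a condition) does not mask the
    # spectral tilt; intensity breaks ties between equal shares.
    qshare <- sweep(qmat, 2, colMeans(qmat), "/")
    qflux <- colMeans(qmat)
    eff <- vapply(templates, `[[`, numeric(1), "effective_lambda_max")
  }

  rows <- lapply(cand, function(p) {
    accepted <- p$n >= 2L
    label <- if (accepted) "cone" else "single-condition"
    if (accepted && has_q && p$wavelength <= 400) {
      cls <- names(templates)[which.min(abs(eff - p$wavelength))]
      amp <- vapply(p$conditions, function(cn) {
        s <- lins[[cn]]
        sel <- abs(s$wavelength - p$wavelength) <= tol + 1e-9
        mean(s$value[sel]) / mean(s$value)  # window mean resists noise
      }, numeric(1))
      sh <- qshare[cls, p$conditions]
      fx <- qflux[p$conditions]
      sparing <- p$conditions[order(sh, -fx)][1]
      adapting <- p$conditions[order(-sh, -fx)][1]
      if (!(amp[[sparing]] > amp[[adapting]])) {
        accepted <- FALSE
        label <- "beta-band"
      }
    }
    data.frame(wavelength = p$wavelength, n_conditions = p$n,
               conditions = paste(p$conditions, collapse = ";"),
               accepted = accepted, label = label)
  })
  do.call(rbind, rows)
}

# strict local maxima; plateaus resolve to the shorter wavelength
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(logical(n))
  out <- logical(n)
  for (i in 2:(n - 1L)) {
    if (v[i - 1L] >= v[i]) next  # must rise into i (plateau -> leftmost wins)
    r <- i
    while (r < n && v[r + 1L] == v[i]) r <- r + 1L
    out[i] <- r < n && v[r + 1L] < v[i]
  }
  out
}

# strict local minima; plateaus resolve to the shorter wavelength
local_minima <- function(v) local_maxima(-v)

#' Estimate the retinal A2 proportion from the long-wavelength limb
#'
#' Fits RH2a and LWS mixed-chromophore templates to the sensitivity values
#' long-ward of the longest accepted peak, leaving the A2 proportion and a
#' magnitude coefficient free, and returns the better-fitting pigment with
#' its estimated A2 proportion. The long limb is used because the A1/A2
#' peak shift is largest for long-wavelength pigments and the limb reflects
#' a single cone class, free of opponent interactions. Model selection
#' (which pigment) uses the linear-scale fit; the A2 proportion of the
#' selected pigment is then refined by a log10-scale fit, whose emphasis on
#' the far tail of the limb localizes the chromophore shift much more
#' precisely.
#'
#' @param curve Linear relative sensitivity [spectrum] (values in \[0, 1\]).
#' @param longest_peak Wavelength (nm) of the longest accepted peak.
#' @param lens Optional lens transmission [spectrum] applied to candidate
#'   templates.
#' @param candidates Candidate pigment class names (default RH2a and LWS).
#' @return List: `pigment`, `a2_fraction`, `r_squared`, `ambiguous`,
#'   `fallback`, plus `fits` (per-candidate a2 and r2).
#' @export
estimate_a2_long_limb <- function(curve, longest_peak, lens = NULL,
                                  candidates = c("RH2a", "LWS")) {
  stopifnot(is_spectrum(curve))
  sel <- curve$wavelength >= longest_peak - 1e-9
  if (sum(curve$wavelength > longest_peak + 1e-9) < 3L) {
    warning("long-wavelength limb too short; falling back to A2 = 0.5")
    return(list(pigment = NA_character_, a2_fraction = 0.5,
                r_squared = NA_real_, ambiguous = FALSE, fallback = TRUE,
                fits = NULL))
  }
  sel <- sel & curve$value > 0  # the min-max zero point carries no shape
  wl <- curve$wavelength[sel]
  ylin <- curve$value[sel]
  ylog <- log10(ylin)

  template_at <- function(cls, a) {
    tmpl <- mixed_template(cls, a2_fraction = a)
    if (!is.null(lens)) tmpl <- apply_lens_transmission(tmpl, lens)
    resample_spectrum(tmpl$absorbance, wl)$value
  }
  optimize_a <- function(rss_a) {
    coarse <- seq(0, 1, by = 0.05)
    r <- vapply(coarse, rss_a, numeric(1))
    a0 <- coarse[which.min(r)]
    stats::optimize(rss_a, c(max(0, a0 - 0.05), min(1, a0 + 0.05)),
                    tol = 1e-6)
  }
  fit_one <- function(cls) {
    rss_lin <- function(a) {
      A <- template_at(cls, a)
      m <- sum(ylin * A) / sum(A * A)
      sum((ylin - m * A)^2)
    }
    rss_log <- function(a) {
      A <- log10(pmax(template_at(cls, a), 1e-12))
      off <- mean(ylog - A)  # free magnitude = additive offset in logs
      sum((ylog - A - off)^2)
    }
    lin <- optimize_a(rss_lin)
    lg <- optimize_a(rss_log)
    sstot <- sum((ylin - mean(ylin))^2)
    list(a2 = lg$minimum,
         r2 = if (sstot > 0) 1 - lin$objective / sstot else NA_real_)
  }
  fits <- lapply(candidates, fit_one)
  names(fits) <- candidates
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  tie <- abs(diff(range(r2s))) < 1e-9
  best <- if (tie) candidates[candidates != "LWS"][1] else
    candidates[which.max(r2s)]
  list(pigment = best, a2_fraction = fits[[best]]$a2,
       r_squared = fits[[best]]$r2, ambiguous = tie, fallback = FALSE,
       fits = fits)
}

#' Assign pigment classes to accepted sensitivity peaks
#'
#' For each accepted peak the candidate pigment classes are those whose
#' mixed-template effective lambda-max (at the individual's A2 proportion)
#' lies within `candidate_window` of the peak (falling back to the nearest
#' class if none). A magnitude coefficient per candidate template is fitted
#' by least squares on the grid points within the template's half-maximum
#' window, on the condition where the peak is most prominent, and the class
#' with the best fit R-squared wins, under a uniqueness constraint (greedy
#' by R-squared, distance as tie-break). Fit quality adjudicates rather
#' than raw peak distance because opponent interactions narrow sensitivity
#' peaks and displace them from the template lambda-max — which also means
#' R-squared below 1 is expected even for noise-free data. The fit window
#' is local (the peak plus `candidate_window` on each side) so that
#' neighboring mechanisms' peaks do not leak into the comparison. When the
#' long-wavelength limb fit has already decided between RH2a and LWS, that
#' decision is passed as `anchor` and pins the longest peak's class.
#'
#' @param peaks Data frame from [detect_peaks()] (only `accepted` rows are
#'   used).
#' @param a2_percent A2 proportion for this individual, in percent (0-100).
#' @param curves List of `sensitivity_curve` across conditions.
#' @param lens Optional lens transmission [spectrum].
#' @param individual Individual identifier carried to the output.
#' @param candidate_window Half-width (nm) of the window around a peak
#'   within which pigment classes compete, and of the local fit window
#'   (default 40, two grid steps).
#' @param anchor Optional pigment class name pre-assigned to the longest
#'   accepted peak (typically the winner of [estimate_a2_long_limb()]).
#' @return Object of class `cone_assignment`: list with `individual`,
#'   `a2_percent`, `entries` (data frame: pigment, lambda_max,
#'   peak_wavelength, r_squared), `n_cones`.
#' @export
assign_pigments <- function(peaks, a2_percent, curves, lens = NULL,
                            individual = NA_character_,
                            candidate_window = 40, anchor = NULL) {
  pk <- peaks[peaks$accepted, , drop = FALSE]
  if (nrow(pk) == 0L) stop("no accepted peaks to assign", call. = FALSE)
  tset <- template_set(a2_fraction = a2_percent / 100, lens = lens)
  eff <- vapply(tset, `[[`, numeric(1), "effective_lambda_max")
  s <- mean_linear_curve(curves)

  # template-fit R2 for one peak/class pair on the condition-averaged
  # curve (averaging across backgrounds suppresses measurement noise)
  fit_r2 <- function(peak_wl, cls) {
    tmpl <- tset[[cls]]
    sel <- abs(s$wavelength - peak_wl) <= candidate_window + 1e-9
    A <- resample_spectrum(tmpl$absorbance,
                           pmin(pmax(s$wavelength[sel],
                                     min(tmpl$absorbance$wavelength)),
                                max(tmpl$absorbance$wavelength)))$value
    y <- s$value[sel]
    m <- sum(y * A) / sum(A * A)
    sstot <- sum((y - mean(y))^2)
    if (sstot > 0) 1 - sum((y - m * A)^2) / sstot else NA_real_
  }

  # candidate classes and fit quality per peak
  longest <- which.max(pk$wavelength)
  cand_list <- lapply(seq_len(nrow(pk)), function(i) {
    d <- abs(eff - pk$wavelength[i])
    cand <- names(eff)[d <= candidate_window]
    if (length(cand) == 0L) cand <- names(eff)[which.min(d)]
    if (i == longest && !is.null(anchor) && anchor %in% cand)
      cand <- anchor
    r2 <- vapply(cand, fit_r2, numeric(1), peak_wl = pk$wavelength[i])
    list(cand = cand, r2 = r2, dist = d[cand])
  })
  # exact search over injective peak -> class assignments, maximizing the
  # number of assigned peaks, then the total fit R2 (distance penalty
  # epsilon breaks exact ties toward the nearer lambda-max)
  best <- list(n = -1L, score = -Inf, assign = NULL)
  search <- function(i, taken, assign, score, n) {
    if (i > nrow(pk)) {
      if (n > best$n || (n == best$n && score > best$score))
        best <<- list(n = n, score = score, assign = assign)
      return()
    }
    cl <- cand_list[[i]]
    free <- which(!(cl$cand %in% taken))
    for (k in free)
      search(i + 1L, c(taken, cl$cand[k]),
             c(assign, stats::setNames(cl$cand[k], i)),
             score + cl$r2[k] - 1e-6 * cl$dist[k], n + 1L)
    search(i + 1L, taken, assign, score, n)  # leave peak unassigned
  }
  search(1L, character(0), character(0), 0, 0L)
  assigned <- rep(NA_character_, nrow(pk))
  assigned[as.integer(names(best$assign))] <- best$assign
  assigned_r2 <- vapply(seq_len(nrow(pk)), function(i) {
    if (is.na(assigned[i])) return(NA_real_)
    cl <- cand_list[[i]]
    cl$r2[[match(assigned[i], cl$cand)]]
  }, numeric(1))
  if (anyNA(assigned)) {
    drop <- which(is.na(assigned))
    warning("peak(s) at ", paste(pk$wavelength[drop], collapse = ", "),
            " nm left unassigned (no free pigment class)")
    pk <- pk[-drop, , drop = FALSE]
    assigned <- assigned[-drop]
    assigned_r2 <- assigned_r2[-drop]
  }

  entries <- data.frame(pigment = assigned,
                        lambda_max = vapply(assigned, function(cl)
                          tset[[cl]]$effective_lambda_max, numeric(1)),
                        peak_wavelength = pk$wavelength,
                        r_squared = assigned_r2)
  entries <- entries[order(entries$lambda_max), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(individual = individual, a2_percent = a2_percent,
                 entries = entries, n_cones = nrow(entries)),
            class = "cone_assignment")
}

#' @export
print.cone_assignment <- function(x, ...) {
  cat(sprintf("<cone_assignment %s: %d cones, A2 %.1f%%: %s>\n",
              x$individual, x$n_cones, x$a2_percent,
              paste(x$entries$pigment, collapse = "+")))
  invisible(x)
}

#' Condition-averaged linear relative sensitivity
#'
#' Averages the log relative sensitivity of one individual's curves across
#' background conditions (suppressing per-point measurement noise by the
#' square root of the number of conditions) and returns the min-max scaled
#' linear curve.
#'
#' @param curves List of `sensitivity_curve` on a common grid.
#' @return A [spectrum] with values in \[0, 1\].
#' @export
mean_linear_curve <- function(curves) {
  logs <- vapply(curves, `[[`, numeric(length(curves[[1]]$wavelength)),
                 "log_rel_sensitivity")
  avg <- rowMeans(matrix(logs, ncol = length(curves)))
  avg <- avg - max(avg)
  lin <- 10^avg
  rng <- range(lin)
  spectrum(curves[[1]]$wavelength, (lin - rng[1]) / diff(rng))
}

# [lo, hi] wavelengths where a template first/last crosses half maximum
half_max_span <- function(absorbance) {
  w <- absorbance$wavelength
  v <- absorbance$value
  above <- v >= 0.5
  range(w[above])
}

#' The catalogue of cone pigment subsets
#'
#' The packaged subset catalogue: each row is a subset label within a species
#' context, with presence flags and the reported mean lambda-max of each
#' pigment. Subset labels are species-scoped because the same pigment set may
#' carry different labels in different species (labels 2 and 4), one label may
#' denote different sets across species (label 9), and two labels within one
#' species may share a set and differ only in lambda-max (labels 9 and 10 in
#' P. taeniolatus).
#'
#' @return Data frame with columns `subset`, `species`, `n_cones`, presence
#'   flags `SWS1`..`LWS` and lambda-max columns `lm_SWS1`..`lm_LWS`.
#' @export
subset_catalogue <- function() {
  path <- system.file("extdata", "table1_subsets.tsv",
                      package = "pentachroma", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Match a cone assignment against the subset catalogue
#'
#' Matches the pigment-class set (and species context) against the packaged
#' catalogue. If several catalogue rows share the set, rows of the matching
#' species are preferred, then the row whose lambda-max constellation is
#' nearest (root-mean-square over shared pigments), then the smallest label.
#' A set absent from the catalogue receives a new sequential label.
#'
#' @param assignment A `cone_assignment`, or a character vector of pigment
#'   class names.
#' @param species Optional species context (e.g. "M. zebra").
#' @param catalogue Catalogue data frame; default [subset_catalogue()].
#' @return Subset label (character).
#' @export
canonical_subset <- function(assignment, species = NA_character_,
                             catalogue = subset_catalogue()) {
  pigs <- if (inherits(assignment, "cone_assignment"))
    assignment$entries$pigment else as.character(assignment)
  lms <- if (inherits(assignment, "cone_assignment"))
    stats::setNames(assignment$entries$lambda_max,
                    assignment$entries$pigment) else NULL
  classes <- names(pigment_classes())
  flags <- as.integer(classes %in% pigs)
  hit <- vapply(seq_len(nrow(catalogue)), function(i)
    all(catalogue[i, classes] == flags), logical(1))
  if (!any(hit)) {
    return(as.character(max(as.numeric(catalogue$subset)) + 1))
  }
  rows <- catalogue[hit, , drop = FALSE]
  if (nrow(rows) > 1L && !is.na(species) && any(rows$species == species))
    rows <- rows[rows$species == species, , drop = FALSE]
  if (nrow(rows) > 1L && !is.null(lms)) {
    d <- vapply(seq_len(nrow(rows)), function(i) {
      ref <- as.numeric(rows[i, paste0("lm_", pigs)])
      sqrt(mean((ref - lms[pigs])^2, na.rm = TRUE))
    }, numeric(1))
    rows <- rows[order(d, as.numeric(rows$subset)), , drop = FALSE]
  } else {
    rows <- rows[order(as.numeric(rows$subset)), , drop = FALSE]
  }
  as.character(rows$subset[[1]])
}
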