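#' Default configuration of the synthetic cohort generator
#'
#' The generator emulates the study conditions: three cichlid species with
#' the published per-sex sample sizes, cone-pigment subsets drawn with the
#' published per-species-and-sex frequencies, retinal A2 proportions uniform
#' over 0-65% (the published per-individual range), spectral sensitivity
#' shaped by opponent interactions between spectrally adjacent cones under
#' divisive Weber-style chromatic adaptation, Naka-Rushton
#' response-intensity curves around the simulated sensitivities, and qPCR
#' quantification cycles consistent with target expression fractions.
#'
#' @param n_per_group Named integer vector `species|sex -> n`; defaults to
#'   the study sizes (6/5, 4/7, 5/7 females/males).
#' @param a2_range Uniform range of the A2 proportion.
#' @param opponent_range Magnitude range of the inhibitory weight each cone
#'   receives from a spectrally adjacent cone.
#' @param adaptation_exponent Weber exponent `w`; mechanism gain under a
#'   background is `((Q0 + Q) / (Q0 + Q_control))^(-w)` with a dark-light
#'   constant `Q0` below which a background barely adapts.
#' @param dark_light_fraction `Q0` as a fraction of the mean mechanism catch
#'   under the control background.
#' @param log_sens_sigma SD of the log-normal measurement noise on relative
#'   sensitivity (the SD of its natural log; ~fractional noise for small
#'   values).
#' @param response_sigma Gaussian noise SD on b-wave amplitudes (uV).
#' @param cq_sigma Gaussian noise SD on replicate Cq values (cycles).
#' @param rmax_range Uniform range of per-individual maximum response (uV).
#' @param peak_log_k Log10 irradiance of half response at the most sensitive
#'   wavelength (absolute sensitivity anchor).
#' @param n_levels,level_span Irradiance levels per RI curve and their span
#'   around LogK (log10 units).
#' @param efficiency_range Uniform range of qPCR amplification efficiencies.
#' @param qpcr_total Total template abundance anchor for Cq generation.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = NULL,
                             a2_range = c(0, 0.65),
                             opponent_range = c(0.3, 0.6),
                             adaptation_exponent = 0.25,
                             dark_light_fraction = 0.2,
                             log_sens_sigma = 0.05,
                             response_sigma = 2,
                             cq_sigma = 0.15,
                             rmax_range = c(60, 140),
                             peak_log_k = 9,
                             n_levels = 8,
                             level_span = 2,
                             efficiency_range = c(0.85, 1),
                             qpcr_total = 2^-18) {
  if (is.null(n_per_group))
    n_per_group <- c("M. zebra|Female" = 6L, "M. zebra|Male" = 5L,
                     "M. auratus|Female" = 4L, "M. auratus|Male" = 7L,
                     "P. taeniolatus|Female" = 5L, "P. taeniolatus|Male" = 7L)
  structure(list(
    n_per_group = n_per_group,
    a2_range = a2_range,
    opponent_range = opponent_range,
    adaptation_exponent = adaptation_exponent,
    dark_light_fraction = dark_light_fraction,
    log_sens_sigma = log_sens_sigma,
    response_sigma = response_sigma,
    cq_sigma = cq_sigma,
    rmax_range = rmax_range,
    peak_log_k = peak_log_k,
    n_levels = n_levels,
    level_span = level_span,
    efficiency_range = efficiency_range,
    qpcr_total = qpcr_total,
    lens = synthetic_lens(),
    backgrounds = generate_backgrounds(),
    qpcr_presets = qpcr_presets()
  ), class = "synthetic_config")
}

#' Synthetic ocular-media (lens) transmission curve
#'
#' A smooth UV cutoff with half transmission at 350 nm, emulating the
#' UV-transmissive lens of cichlids; labelled synthetic because no measured
#' lens curve is packaged.
#'
#' @param grid Wavelength grid (nm).
#' @param cutoff Half-transmission wavelength (nm).
#' @param slope Logistic slope (nm).
#' @return A [spectrum] of transmission in \[0, 1\].
#' @export
synthetic_lens <- function(grid = template_grid(), cutoff = 350, slope = 10) {
  spectrum(grid, 1 / (1 + exp(-(grid - cutoff) / slope)))
}

#' Background irradiance spectra of the four isolation conditions
#'
#' Control is spectrally flat. The long-wavelength-isolation background (LW)
#' is short-pass shaped light that adapts the short-wavelength mechanisms
#' and so isolates long-wavelength sensitivity; the short-wavelength
#' isolation backgrounds (SW and the ten-fold dimmer Dim-SW) are long-pass
#' shaped light that adapts the mid/long mechanisms. All intense backgrounds
#' carry equal total photon flux; Dim-SW carries a tenth of the SW flux.
#'
#' @param grid Wavelength grid (nm).
#' @param flux Total photon flux of each intense background
#'   (photons cm^-2 s^-1 over the grid).
#' @param lw_cutoff,sw_cutoff Short-pass / long-pass half-power wavelengths
#'   (nm).
#' @param slope Logistic edge slope (nm).
#' @return Named list of irradiance spectra: `control`, `LW`, `SW`,
#'   `Dim-SW`.
#' @export
generate_backgrounds <- function(grid = template_grid(), flux = 5e14,
                                 lw_cutoff = 490, sw_cutoff = 540,
                                 slope = 10) {
  flat <- spectrum(grid, rep(1, length(grid)))
  shortpass <- spectrum(grid, 1 / (1 + exp((grid - lw_cutoff) / slope)))
  longpass <- spectrum(grid, 1 / (1 + exp(-(grid - sw_cutoff) / slope)))
  scale_to <- function(s, target) {
    tot <- integrate_spectrum(s)
    spectrum(s$wavelength, s$value * target / tot)
  }
  sw <- scale_to(longpass, flux)
  list(control = scale_to(flat, flux),
       LW = scale_to(shortpass, flux),
       SW = sw,
       `Dim-SW` = spectrum(sw$wavelength, 0.1 * sw$value))
}

#' Background conditions used for each species
#'
#' The dim short-wavelength condition replaces the long-wavelength isolation
#' condition in P. taeniolatus.
#'
#' @param species Species name.
#' @return Character vector of condition names.
#' @export
conditions_for_species <- function(species) {
  if (species == "P. taeniolatus") c("Dim-SW", "control", "SW")
  else c("LW", "control", "SW")
}

# Target opsin expression fractions per species and sex. M. auratus sexes
# differ in RH2b/RH2a (the published effect direction pattern); the other
# species' sexes are matched. M. zebra lacks LWS expression.
qpcr_presets <- function() {
  list(
    "M. zebra|Female" = c(SWS1 = 0.20, SWS2b = 0.10, SWS2a = 0.20,
                          RH2b = 0.25, RH2a = 0.25, LWS = 0),
    "M. zebra|Male" = c(SWS1 = 0.20, SWS2b = 0.10, SWS2a = 0.20,
                        RH2b = 0.25, RH2a = 0.25, LWS = 0),
    "M. auratus|Female" = c(SWS1 = 0.10, SWS2b = 0.10, SWS2a = 0.10,
                            RH2b = 0.35, RH2a = 0.25, LWS = 0.10),
    "M. auratus|Male" = c(SWS1 = 0.10, SWS2b = 0.10, SWS2a = 0.10,
                          RH2b = 0.20, RH2a = 0.40, LWS = 0.10),
    "P. taeniolatus|Female" = c(SWS1 = 0.05, SWS2b = 0.15, SWS2a = 0.10,
                                RH2b = 0.25, RH2a = 0.30, LWS = 0.15),
    "P. taeniolatus|Male" = c(SWS1 = 0.05, SWS2b = 0.15, SWS2a = 0.10,
                              RH2b = 0.25, RH2a = 0.30, LWS = 0.15)
  )
}

#' Draw one synthetic individual
#'
#' @param id Identifier.
#' @param species,sex Group labels.
#' @param subset_label Subset label from the catalogue; `NULL` draws from
#'   the published per-group frequencies.
#' @param config A [synthetic_config()].
#' @param a2 Optional fixed A2 proportion; `NULL` draws from the config
#'   range.
#' @return List of class `synthetic_individual`: ground truth (pigments,
#'   a2_fraction, opponent weights, rmax) for one fish.
#' @export
make_individual <- function(id, species, sex, subset_label = NULL,
                            config = synthetic_config(), a2 = NULL) {
  cat <- subset_catalogue()
  if (is.null(subset_label)) {
    freq <- subset_frequencies()
    f <- freq[freq$species == species & freq$sex == sex, ]
    subset_label <- as.character(
      f$subset[sample.int(nrow(f), 1, prob = f$frequency)])
  }
  row <- cat[cat$subset == subset_label & cat$species == species, ]
  if (nrow(row) == 0L) row <- cat[cat$subset == subset_label, ][1, ]
  classes <- names(pigment_classes())
  pigments <- classes[as.logical(unlist(row[1, classes]))]
  if (is.null(a2))
    a2 <- stats::runif(1, config$a2_range[1], config$a2_range[2])
  pigments <- pigments[order(pigment_classes()[pigments])]
  rmax <- stats::runif(1, config$rmax_range[1], config$rmax_range[2])

  # Opponent weights are rejection-sampled so that every functional cone
  # manifests a sensitivity peak resolvable on the 20 nm grid under the
  # control background and at least one isolation background — the
  # defining property of a functional mechanism in this protocol. If no
  # draw succeeds the weight range shrinks toward weaker opponency.
  conds <- conditions_for_species(species)
  best <- NULL
  best_depth <- -Inf
  # If the configured weight range cannot give this subset a resolvable
  # peak structure, stronger and then weaker opponency are tried — the
  # spectral packing of some subsets demands one or the other.
  tset <- template_set(a2_fraction = a2, classes = pigments,
                       lens = config$lens)
  q_cache <- vapply(config$backgrounds, function(bg)
    vapply(tset, quantum_catch, numeric(1), irradiance = bg),
    numeric(length(tset)))
  ranges <- list(config$opponent_range, c(0.5, 0.8), c(0.15, 0.35))
  for (rng in ranges) {
    for (try in 1:30) {
      m <- matrix(0, length(pigments), length(pigments),
                  dimnames = list(pigments, pigments))
      for (i in seq_along(pigments)) {
        for (j in c(i - 1L, i + 1L)) {
          if (j < 1L || j > length(pigments)) next
          m[pigments[i], pigments[j]] <- stats::runif(1, rng[1], rng[2])
        }
      }
      ind <- structure(list(id = id, species = species, sex = sex,
                            subset = subset_label, pigments = pigments,
                            a2_fraction = a2, opponent = m, rmax = rmax),
                       class = "synthetic_individual")
      depth <- peak_structure_depth(ind, conds, config, tset = tset,
                                    q_cache = q_cache)
      if (!is.na(depth) && depth >= 0.12) return(ind)
      if (!is.na(depth) && depth > best_depth) {
        best <- ind
        best_depth <- depth
      }
    }
    # stronger/weaker opponency is a fallback for subsets whose spectral
    # packing admits no resolvable structure in the configured range
    if (!is.null(best)) break
  }
  if (!is.null(best)) best else ind
}

#' @rdname make_individual
#' @param ind A `synthetic_individual`.
#' @param conds Background conditions of the individual's species.
#' @keywords internal
peaks_resolvable <- function(ind, conds, config, min_notch = 0) {
  d <- peak_structure_depth(ind, conds, config)
  !is.na(d) && d >= min_notch
}

# Depth (log10 units) of the shallowest notch between control-curve peaks,
# or NA if the peak structure is unresolvable: some pigment lacking a grid
# local max within 20 nm of its effective lambda-max under control plus at
# least one isolation condition, or merged/spurious peaks under control.
peak_structure_depth <- function(ind, conds, config, tset = NULL,
                                 q_cache = NULL) {
  mech <- individual_mechanisms(ind, config, tset = tset,
                                q_cache = q_cache)
  eff <- vapply(mech$templates, `[[`, numeric(1), "effective_lambda_max")
  hits <- matrix(FALSE, length(ind$pigments), length(conds),
                 dimnames = list(ind$pigments, conds))
  n_ctrl <- NA_integer_
  depth <- Inf
  for (cn in conds) {
    cv <- simulate_sensitivity(ind, cn, config, noise_sigma = 0,
                               mech = mech)
    idx <- which(local_maxima(cv$log_rel_sensitivity))
    pw <- cv$wavelength[idx]
    if (cn == "control") {
      n_ctrl <- length(pw)
      if (length(idx) > 1L) {
        v <- cv$log_rel_sensitivity
        for (k in seq_len(length(idx) - 1L)) {
          valley <- min(v[idx[k]:idx[k + 1L]])
          depth <- min(depth, min(v[idx[k]], v[idx[k + 1L]]) - valley)
        }
      }
    }
    for (p in ind$pigments)
      hits[p, cn] <- any(abs(pw - eff[[p]]) <= 20 + 1e-9)
  }
  ok <- all(hits[, "control"]) && all(rowSums(hits) >= 2) &&
    identical(n_ctrl, length(ind$pigments))
  if (!ok) NA_real_ else depth
}

# Lens-corrected mixed templates, segment layout and control catches for
# one individual. Segments are delimited at the midpoints between adjacent
# effective lambda-max values; within its segment each cone contributes its
# own absorbance minus the weighted absorbances of its spectral neighbors,
# normalized to peak 1 inside the segment.
individual_mechanisms <- function(ind, config, tset = NULL,
                                  q_cache = NULL) {
  if (is.null(tset))
    tset <- template_set(a2_fraction = ind$a2_fraction,
                         classes = ind$pigments, lens = config$lens)
  grid <- template_grid()
  eff <- vapply(tset, `[[`, numeric(1), "effective_lambda_max")
  bounds <- c(min(grid), (utils::head(eff, -1) + utils::tail(eff, -1)) / 2,
              max(grid))
  segs <- lapply(seq_along(ind$pigments), function(i) {
    p <- ind$pigments[i]
    v <- tset[[p]]$absorbance$value
    w <- stats::setNames(numeric(length(ind$pigments)), ind$pigments)
    w[p] <- 1
    for (q in ind$pigments)
      if (ind$opponent[p, q] > 0) {
        v <- v - ind$opponent[p, q] * tset[[q]]$absorbance$value
        w[q] <- -ind$opponent[p, q]
      }
    inseg <- grid >= bounds[i] & grid <= bounds[i + 1L]
    scale <- max(v[inseg])
    list(pigment = p, range = c(bounds[i], bounds[i + 1L]),
         value = v / scale, weights = w / scale)
  })
  names(segs) <- ind$pigments
  if (is.null(q_cache))
    q_cache <- vapply(config$backgrounds, function(bg)
      vapply(tset, quantum_catch, numeric(1), irradiance = bg),
      numeric(length(tset)))
  list(templates = tset, segments = segs, bounds = bounds,
       q_control = q_cache[, "control"], q_all = q_cache, grid = grid)
}

#' Simulate a spectral-sensitivity curve for one individual and condition
#'
#' Forward model: the spectrum is divided into segments at the midpoints
#' between the effective lambda-max values of the individual's cones;
#' within its segment the dominant cone contributes its signed template sum
#' (its own absorbance minus the weighted absorbances of spectrally
#' adjacent cones, normalized to peak 1 in the segment), scaled by the
#' divisive, saturating Weber adaptation gain
#' `((Q0 + Q_condition) / (Q0 + Q_control))^(-w)`. The piecewise curve is
#' clipped at a small positive floor, sampled onto the 320-700 nm / 20 nm
#' measurement grid, log-transformed, perturbed with Gaussian noise of SD
#' `noise_sigma` and normalized to a maximum of 0.
#'
#' @param ind A `synthetic_individual`.
#' @param condition Background condition name.
#' @param config A [synthetic_config()].
#' @param noise_sigma Log-sensitivity noise SD; default from `config`.
#' @param mech Precomputed [individual_mechanisms] output (internal reuse).
#' @return A `sensitivity_curve`.
#' @export
simulate_sensitivity <- function(ind, condition, config = synthetic_config(),
                                 noise_sigma = config$log_sens_sigma,
                                 mech = NULL) {
  if (is.null(mech)) mech <- individual_mechanisms(ind, config)
  if (!condition %in% colnames(mech$q_all))
    stop("unknown condition: ", condition, call. = FALSE)
  q <- mech$q_all[, condition]
  q0 <- config$dark_light_fraction * mean(mech$q_control)
  gain <- ((q0 + q) / (q0 + mech$q_control))^(-config$adaptation_exponent)
  env <- numeric(length(mech$grid))
  for (sg in mech$segments) {
    inseg <- mech$grid >= sg$range[1] & mech$grid <= sg$range[2]
    env[inseg] <- gain[[sg$pigment]] * sg$value[inseg]
  }
  env <- pmax(env, max(env) * 1e-4)
  sgrid <- sensitivity_grid()
  vals <- env[match(sgrid, mech$grid)]
  log_rel <- log10(vals) - max(log10(vals))
  if (noise_sigma > 0) {
    # multiplicative log-normal noise: sigma is the SD of the natural log
    # of the sensitivity, i.e. ~sigma fractional noise for small sigma
    log_rel <- log_rel +
      stats::rnorm(length(log_rel), 0, noise_sigma / log(10))
    log_rel <- log_rel - max(log_rel)
  }
  structure(list(individual = ind$id, condition = condition,
                 wavelength = sgrid, log_rel_sensitivity = log_rel),
            class = "sensitivity_curve")
}

#' Simulate response-intensity records for one individual and condition
#'
#' Inverts the Naka-Rushton analysis: the half-response irradiance at each
#' wavelength is set from the simulated relative sensitivity
#' (`LogK = peak_log_k - log relative sensitivity`), irradiance levels span
#' `LogK +/- level_span`, and b-wave responses follow
#' `Rmax * I / (I + K)` with Gaussian amplitude noise.
#'
#' @inheritParams simulate_sensitivity
#' @param response_sigma Response noise SD (uV); default from `config`.
#' @param curve Optional precomputed `sensitivity_curve` to invert (bypasses
#'   a fresh [simulate_sensitivity()] call).
#' @return Data frame: `individual`, `condition`, `wavelength_nm`,
#'   `log_irradiance`, `response_uV`.
#' @export
simulate_ri <- function(ind, condition, config = synthetic_config(),
                        response_sigma = config$response_sigma,
                        curve = NULL) {
  if (is.null(curve))
    curve <- simulate_sensitivity(ind, condition, config)
  out <- lapply(seq_along(curve$wavelength), function(i) {
    logk <- config$peak_log_k - curve$log_rel_sensitivity[i]
    logi <- seq(logk - config$level_span, logk + config$level_span,
                length.out = config$n_levels)
    resp <- ind$rmax / (1 + 10^(logk - logi))
    if (response_sigma > 0)
      resp <- pmax(resp + stats::rnorm(length(resp), 0, response_sigma), 0)
    data.frame(individual = ind$id, condition = condition,
               wavelength_nm = curve$wavelength[i],
               log_irradiance = logi, response_uV = resp)
  })
  do.call(rbind, out)
}

#' Simulate qPCR records for one individual
#'
#' Inverts the relative-expression relation: for target fraction `f_g` and
#' drawn efficiency `E_g`, the quantification cycle is
#' `Cq_g = -log(f_g * T) / log(1 + E_g)`; triplicates receive Gaussian Cq
#' noise. Genes with target fraction 0 are omitted (no amplification).
#'
#' @inheritParams simulate_sensitivity
#' @param fractions Optional named target fractions; default the species/sex
#'   preset in `config`.
#' @param cq_sigma Cq noise SD; default from `config`.
#' @return Data frame: `individual`, `species`, `sex`, `gene`, `replicate`,
#'   `Cq`, `efficiency`.
#' @export
simulate_qpcr <- function(ind, config = synthetic_config(),
                          fractions = NULL, cq_sigma = config$cq_sigma) {
  if (is.null(fractions))
    fractions <- config$qpcr_presets[[paste(ind$species, ind$sex,
                                            sep = "|")]]
  if (is.null(fractions))
    stop("no qPCR preset for ", ind$species, "/", ind$sex, call. = FALSE)
  keep <- fractions > 0
  if (any(!keep))
    message(sum(!keep), " gene(s) with zero target fraction omitted for ",
            ind$id)
  fractions <- fractions[keep]
  out <- lapply(names(fractions), function(g) {
    eff <- stats::runif(1, config$efficiency_range[1],
                        config$efficiency_range[2])
    cq <- -log(fractions[[g]] * config$qpcr_total) / log(1 + eff)
    cqs <- cq + if (cq_sigma > 0) stats::rnorm(3, 0, cq_sigma) else rep(0, 3)
    data.frame(individual = ind$id, species = ind$species, sex = ind$sex,
               gene = g, replicate = 1:3, Cq = cqs, efficiency = eff)
  })
  do.call(rbind, out)
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Draws individuals per species and sex, simulates their sensitivity curves
#' under the species' three background conditions, and optionally
#' response-intensity and qPCR records. Fully deterministic under a fixed
#' seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @param with_ri Also simulate response-intensity records.
#' @param with_qpcr Also simulate qPCR records.
#' @return List of class `synthetic_cohort`: `truth` (data frame of ground
#'   truth per individual), `individuals` (list of `synthetic_individual`),
#'   `curves` (nested list individual -> condition -> `sensitivity_curve`),
#'   `ri` and `qpcr` data frames (or `NULL`), `config`, `seed`.
#' @export
simulate_cohort <- function(config = synthetic_config(), seed = 1,
                            with_ri = FALSE, with_qpcr = FALSE) {
  set.seed(seed)
  inds <- list()
  for (grp in names(config$n_per_group)) {
    parts <- strsplit(grp, "|", fixed = TRUE)[[1]]
    n <- config$n_per_group[[grp]]
    for (i in seq_len(n)) {
      id <- sprintf("%s_%s_%02d", abbreviate(parts[1], 4), parts[2], i)
      inds[[id]] <- make_individual(id, parts[1], parts[2], config = config)
    }
  }
  curves <- list()
  ri <- list()
  for (id in names(inds)) {
    ind <- inds[[id]]
    mech <- individual_mechanisms(ind, config)
    curves[[id]] <- list()
    for (cond in conditions_for_species(ind$species)) {
      cv <- simulate_sensitivity(ind, cond, config, mech = mech)
      curves[[id]][[cond]] <- cv
      if (with_ri) ri[[paste(id, cond)]] <-
          simulate_ri(ind, cond, config, curve = cv)
    }
  }
  qpcr <- NULL
  if (with_qpcr)
    qpcr <- do.call(rbind, lapply(inds, simulate_qpcr, config = config))
  truth <- do.call(rbind, lapply(inds, function(x)
    data.frame(individual = x$id, species = x$species, sex = x$sex,
               subset = x$subset,
               pigment_set = paste(x$pigments, collapse = "+"),
               a2_fraction = x$a2_fraction, rmax = x$rmax)))
  rownames(truth) <- NULL
  structure(list(truth = truth, individuals = inds, curves = curves,
                 ri = if (with_ri) do.call(rbind, ri) else NULL,
                 qpcr = qpcr, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d individuals, seed %d>\n",
              nrow(x$truth), x$seed))
  invisible(x)
}

#' Simulate a calibration cohort covering every catalogue subset
#'
#' Builds one individual for every subset catalogue row (in its species
#' context) at each requested A2 proportion — the standard recovery
#' calibration design, spanning the full subset diversity at controlled
#' chromophore states.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @param a2_values A2 proportions at which each subset is instantiated.
#' @return A `synthetic_cohort` (without RI or qPCR records).
#' @export
simulate_subset_grid <- function(config = synthetic_config(), seed = 1,
                                 a2_values = c(0, 0.25, 0.5)) {
  set.seed(seed)
  cat <- subset_catalogue()
  inds <- list()
  for (r in seq_len(nrow(cat))) {
    for (a2 in a2_values) {
      id <- sprintf("s%s_%s_a%02.0f", cat$subset[r],
                    abbreviate(cat$species[r], 4), 100 * a2)
      inds[[id]] <- make_individual(id, cat$species[r], "Female",
                                    as.character(cat$subset[r]),
                                    config = config, a2 = a2)
    }
  }
  curves <- list()
  for (id in names(inds)) {
    ind <- inds[[id]]
    mech <- individual_mechanisms(ind, config)
    curves[[id]] <- list()
    for (cond in conditions_for_species(ind$species))
      curves[[id]][[cond]] <- simulate_sensitivity(ind, cond, config,
                                                   mech = mech)
  }
  truth <- do.call(rbind, lapply(inds, function(x)
    data.frame(individual = x$id, species = x$species, sex = x$sex,
               subset = x$subset,
               pigment_set = paste(x$pigments, collapse = "+"),
               a2_fraction = x$a2_fraction, rmax = x$rmax)))
  rownames(truth) <- NULL
  structure(list(truth = truth, individuals = inds, curves = curves,
                 ri = NULL, qpcr = NULL, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to delimited-text files
#'
#' Emits the truth table, per-individual sensitivity files, and (when
#' present) RI and qPCR tables in the formats the analysis functions read.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sens <- do.call(rbind, lapply(cohort$curves, function(cl)
    do.call(rbind, lapply(cl, function(cv)
      data.frame(individual = cv$individual, condition = cv$condition,
                 wavelength_nm = cv$wavelength,
                 log_rel_sensitivity = cv$log_rel_sensitivity)))))
  utils::write.table(sens, file.path(dir, "sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$ri))
    utils::write.table(cohort$ri, file.path(dir, "ri.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$qpcr))
    utils::write.table(cohort$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
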