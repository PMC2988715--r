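make_curve <- function(log_rel, condition, individual = "f1") {
  structure(list(individual = individual, condition = condition,
                 wavelength = sensitivity_grid(),
                 log_rel_sensitivity = log_rel - max(log_rel)),
            class = "sensitivity_curve")
}

# a steep unimodal log curve peaking at `peak`, with an optional UV bump
shaped_log <- function(peak, uv_bump = NULL) {
  grid <- sensitivity_grid()
  v <- -((grid - peak) / 120)^2 * 4
  if (!is.null(uv_bump))
    v <- pmax(v, uv_bump$height - ((grid - uv_bump$at) / 30)^2)
  v
}

test_that("peaks seen under a single condition are rejected", {
  # condition A shows a prominent UV bump at 380 nm; condition B slopes
  # steadily away there (steeper than the appearance tolerance), so the
  # bump appears under one condition only and is not a cone
  base <- shaped_log(540)
  uv_region <- sensitivity_grid() <= 440
  a_vals <- base
  a_vals[uv_region] <- c(-1.9, -1.4, -0.9, -0.5, -0.9, -1.4, -1.9)
  b_vals <- base
  b_vals[uv_region] <- seq(-3.2, -1.4, by = 0.3)
  res <- detect_peaks(list(make_curve(a_vals, "control"),
                           make_curve(b_vals, "SW")))
  uv <- res[res$wavelength <= 400, ]
  expect_equal(nrow(uv), 1)
  expect_false(uv$accepted)
  expect_equal(uv$label, "single-condition")
  main <- res[res$wavelength > 400, ]
  expect_true(all(main$accepted))
})

test_that("UV peaks are cones or beta-bands by their response to isolation", {
  bgs <- generate_backgrounds()[c("control", "SW")]
  tset <- template_set(0.5, lens = synthetic_lens())

  # amplitude rises under short-wavelength isolation: a UV cone
  up <- list(
    make_curve(shaped_log(540, list(at = 380, height = -0.6)), "control"),
    make_curve(shaped_log(540, list(at = 380, height = -0.1)), "SW"))
  res_up <- detect_peaks(up, backgrounds = bgs, templates = tset)
  uv_up <- res_up[res_up$wavelength <= 400, ]
  expect_true(uv_up$accepted)
  expect_equal(uv_up$label, "cone")

  # amplitude falls under short-wavelength isolation: a beta-band
  down <- list(
    make_curve(shaped_log(540, list(at = 380, height = -0.1)), "control"),
    make_curve(shaped_log(540, list(at = 380, height = -0.6)), "SW"))
  res_dn <- detect_peaks(down, backgrounds = bgs, templates = tset)
  uv_dn <- res_dn[res_dn$wavelength <= 400, ]
  expect_false(uv_dn$accepted)
  expect_equal(uv_dn$label, "beta-band")

  expect_error(detect_peaks(up[1]), "at least two")
})

template_curve <- function(cls, a2, grid = sensitivity_grid()) {
  tmpl <- mixed_template(cls, a2)
  spectrum(grid, resample_spectrum(tmpl$absorbance, grid)$value)
}

test_that("the long-limb fit identifies the pigment and its A2 state", {
  lws <- template_curve("LWS", 0.5)
  peak <- lws$wavelength[which.max(lws$value)]
  fit <- estimate_a2_long_limb(lws, peak)
  expect_equal(fit$pigment, "LWS")
  expect_lt(abs(fit$a2_fraction - 0.5), 0.05)
  expect_gt(fit$r_squared, 0.99)
  expect_false(fit$fallback)

  rh2a <- template_curve("RH2a", 0)
  peak2 <- rh2a$wavelength[which.max(rh2a$value)]
  fit2 <- estimate_a2_long_limb(rh2a, peak2)
  expect_equal(fit2$pigment, "RH2a")
  expect_lt(fit2$a2_fraction, 0.05)

  # limb too short: fall back to the background-design default
  expect_warning(fb <- estimate_a2_long_limb(lws, 660), "falling back")
  expect_equal(fb$a2_fraction, 0.5)
  expect_true(fb$fallback)
})

test_that("full identification recovers a known synthetic individual", {
  cfg <- noiseless_config()
  set.seed(14)
  ind <- make_individual("z1", "M. zebra", "Male", "2", cfg, a2 = 0.25)
  curves <- lapply(conditions_for_species("M. zebra"), function(cn)
    simulate_sensitivity(ind, cn, cfg, noise_sigma = 0))
  bgs <- cfg$backgrounds[conditions_for_species("M. zebra")]
  res <- identify_individual(curves, species = "M. zebra",
                             backgrounds = bgs, lens = cfg$lens)
  expect_setequal(res$assignment$entries$pigment, ind$pigments)
  expect_equal(res$assignment$n_cones, length(ind$pigments))
  expect_equal(res$subset, "2")
  expect_lt(abs(res$a2_fit$a2_fraction - 0.25), 0.1)
  # every reported pigment sits within one grid step of its peak
  expect_true(all(abs(res$assignment$entries$lambda_max -
                        res$assignment$entries$peak_wavelength) <= 40))
})

test_that("catalogue matching is species-aware and extends to new sets", {
  expect_equal(canonical_subset(c("SWS1", "SWS2a", "RH2b", "RH2a"),
                                species = "M. zebra"), "2")
  # the same pigment set carries a different label in M. auratus
  expect_equal(canonical_subset(c("SWS1", "SWS2a", "RH2b", "RH2a"),
                                species = "M. auratus"), "4")
  expect_equal(canonical_subset(c("SWS1", "SWS2b", "RH2b", "RH2a", "LWS"),
                                species = "M. auratus"), "3")
  # an unseen combination gets the next sequential label
  expect_equal(canonical_subset("SWS2b"), "12")
  # unknown species still matches on the set alone (smallest label wins)
  expect_equal(canonical_subset(c("SWS1", "SWS2a", "RH2b", "RH2a")), "2")
})
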