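# a curve equal to a signed template combination over the whole grid; the
# opponency model is then fitted over a prescribed spectral range
combo_curve <- function(weights, templates, gain = 1,
                        grid = sensitivity_grid()) {
  X <- vapply(names(weights), function(cl)
    resample_spectrum(templates[[cl]]$absorbance, grid)$value,
    numeric(length(grid)))
  spectrum(grid, gain * as.vector(as.matrix(X) %*% weights))
}

test_that("notches are local minima plus the curve ends", {
  grid <- sensitivity_grid()
  uni <- gaussian_spectrum(500, 60, grid)
  expect_equal(find_notches(uni), c(320, 700))

  two <- spectrum(grid, gaussian_spectrum(420, 30, grid)$value +
                    gaussian_spectrum(600, 30, grid)$value)
  n <- find_notches(two)
  expect_equal(length(n), 3)
  expect_true(n[2] > 440 & n[2] < 580)
  expect_error(find_notches(spectrum(c(1, 2, 3), c(1, 2, 1))), "5 grid")
})

test_that("simulated curves show one segment per cone mechanism", {
  cfg <- noiseless_config()
  set.seed(19)
  ind <- make_individual("m1", "M. zebra", "Male", "2", cfg, a2 = 0.25)
  ctrl <- to_linear_relative(
    simulate_sensitivity(ind, "control", cfg, noise_sigma = 0))
  notches <- find_notches(ctrl)
  # one interior notch between each pair of adjacent mechanisms
  expect_equal(length(notches), length(ind$pigments) + 1)
  eff <- vapply(template_set(0.25, classes = ind$pigments,
                             lens = cfg$lens),
                `[[`, numeric(1), "effective_lambda_max")
  for (e in eff)
    expect_true(any(e >= notches[-length(notches)] - 20 &
                      e <= notches[-1] + 20))
})

test_that("segment fits solve unconstrained least squares exactly", {
  tset <- template_set(0.2)
  grid <- sensitivity_grid()

  pure <- combo_curve(c(RH2b = 1), tset)
  fit <- fit_segment(pure, c(440, 560), tset, "RH2b")
  expect_equal(unname(fit$weights), 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  curve <- combo_curve(c(RH2b = 1, RH2a = -0.3), tset)
  fit2 <- fit_segment(curve, c(440, 580), tset, c("RH2b", "RH2a"))
  expect_equal(unname(fit2$weights), c(1, -0.3), tolerance = 1e-6)

  # matches the normal-equations solution computed independently
  sel <- grid >= 440 & grid <= 580
  X <- cbind(resample_spectrum(tset$RH2b$absorbance, grid[sel])$value,
             resample_spectrum(tset$RH2a$absorbance, grid[sel])$value)
  y <- curve$value[sel]
  k_ref <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit2$weights), as.vector(k_ref), tolerance = 1e-9)

  expect_error(fit_segment(curve, c(440, 480), tset,
                           c("RH2b", "RH2a", "LWS")), "free parameters")
  expect_error(fit_segment(curve, c(440, 580), tset, character(0)), "1-3")
})

test_that("interaction selection recovers generating combos and signs", {
  tset <- template_set(0.2, classes = c("SWS1", "SWS2a", "RH2b", "RH2a"))
  cases <- list(
    list(range = c(320, 440), weights = c(SWS1 = 1, SWS2a = -0.5)),
    list(range = c(400, 500),
         weights = c(SWS1 = -0.4, SWS2a = 1, RH2b = -0.5)),
    list(range = c(460, 580),
         weights = c(SWS2a = -0.4, RH2b = 1, RH2a = -0.5)),
    list(range = c(520, 700), weights = c(RH2b = -0.5, RH2a = 1)))
  for (cs in cases) {
    # three backgrounds: adaptation scales the weights, signs unchanged
    curves <- lapply(c(ctrl = 1, lw = 1.25, sw = 0.8), combo_curve,
                     weights = cs$weights, templates = tset)
    model <- select_interaction(curves, cs$range, tset)
    sg <- model$segments[[1]]
    expect_setequal(sg$combo, names(cs$weights))
    expect_equal(unname(sg$signs[match(names(cs$weights), sg$combo)]),
                 unname(as.integer(sign(cs$weights))))
    expect_gte(sg$mean_r2, 0.99)
    expect_true(sg$consistent)
    expect_equal(unname(sg$signs[sg$combo == sg$dominant]), 1L)
    k <- sg$per_background$ctrl$weights
    expect_equal(unname(k[names(cs$weights)]), unname(cs$weights),
                 tolerance = 1e-6)
    # deterministic, bit-for-bit reproducible
    model2 <- select_interaction(curves, cs$range, tset)
    expect_identical(model$interaction_table, model2$interaction_table)
  }
})

test_that("parsimony prefers a single cone when it suffices", {
  tset <- template_set(0, classes = c("RH2b", "RH2a", "LWS"))
  pure <- combo_curve(c(RH2a = 1), tset)
  model <- select_interaction(list(ctrl = pure), c(440, 620), tset)
  expect_equal(model$segments[[1]]$combo, "RH2a")
})

test_that("sign-inconsistent candidates are discarded across backgrounds", {
  tset <- template_set(0, classes = c("RH2b", "RH2a"))
  # background b flips the RH2a contribution: criterion 3 must reject the
  # two-cone combo and settle on the sign-consistent single cone
  c1 <- combo_curve(c(RH2b = 1, RH2a = -0.25), tset)
  c2 <- combo_curve(c(RH2b = 1, RH2a = 0.25), tset)
  model <- select_interaction(list(a = c1, b = c2), c(440, 620), tset,
                              margin = 1)
  expect_equal(model$segments[[1]]$combo, "RH2b")
  expect_true(model$segments[[1]]$consistent)
})

test_that("concatenated R2 summarizes segment fits under one background", {
  tset <- template_set(0.2, classes = c("RH2b", "RH2a"))
  cv <- combo_curve(c(RH2b = 1, RH2a = -0.4), tset)
  model <- select_interaction(list(ctrl = cv), c(440, 620), tset)
  g <- mcm_global_r2(model, "ctrl", list(ctrl = cv), tset)
  expect_gte(g$concatenated_r2, 0.99)
  expect_equal(length(g$per_segment_r2), length(model$segments))
})
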