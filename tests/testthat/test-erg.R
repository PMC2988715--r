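test_that("the half-response irradiance equals K by construction", {
  log_i <- seq(-1, 3, length.out = 8)
  fit <- fit_naka_rushton(log_i, nr_responses(log_i, 100, 1))
  expect_equal(fit$r_max, 100, tolerance = 1e-6)
  expect_equal(fit$log_k, 1, tolerance = 1e-6)  # K = 10
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("noiseless generate-and-refit recovers both parameters", {
  set.seed(11)
  for (i in 1:200) {
    r_max <- runif(1, 20, 200)
    log_k <- runif(1, 5, 12)
    log_i <- seq(log_k - 2, log_k + 2, length.out = 8)
    fit <- fit_naka_rushton(log_i, nr_responses(log_i, r_max, log_k))
    expect_equal(fit$r_max, r_max, tolerance = 1e-6)
    expect_equal(fit$log_k, log_k, tolerance = 1e-6)
  }
})

test_that("LogK is recovered within 0.1 log units under response noise", {
  set.seed(12)
  errs <- replicate(500, {
    log_i <- seq(7, 11, length.out = 8)
    y <- pmax(nr_responses(log_i, 100, 9) + rnorm(8, 0, 2), 0)
    abs(fit_naka_rushton(log_i, y)$log_k - 9)
  })
  expect_lt(median(errs), 0.1)
})

test_that("sensitivity is invariant to a common response rescaling", {
  log_i <- seq(0, 4, length.out = 8)
  y <- nr_responses(log_i, 80, 2)
  f1 <- fit_naka_rushton(log_i, y)
  f2 <- fit_naka_rushton(log_i, 3.7 * y)
  expect_equal(f1$log_k, f2$log_k, tolerance = 1e-6)
  expect_equal(f2$r_max, 3.7 * f1$r_max, tolerance = 1e-6)
})

test_that("fixed-Rmax fits and input validation behave", {
  log_i <- seq(0, 4, length.out = 8)
  y <- nr_responses(log_i, 80, 2)
  fit <- fit_naka_rushton(log_i, y, fixed_r_max = 80)
  expect_true(fit$r_max_constrained)
  expect_equal(fit$log_k, 2, tolerance = 1e-6)
  expect_error(fit_naka_rushton(c(1, 2), c(10, 20)), "at least 3")
  expect_error(fit_naka_rushton(c(1, 2, 3), c(-1, 2, 3)), "non-negative")
})

test_that("the edge-wavelength rule fixes Rmax from the interior neighbor", {
  # 340 nm: irradiance range far below saturation -> unreached asymptote
  lo <- ri_frame(340, seq(-2, 0, length.out = 6),
                 nr_responses(seq(-2, 0, length.out = 6), 80, 1.5))
  ok360 <- ri_frame(360, seq(-0.5, 3.5, length.out = 8),
                    nr_responses(seq(-0.5, 3.5, length.out = 8), 80, 1.5))
  in500 <- ri_frame(500, seq(-2, 0, length.out = 6),
                    nr_responses(seq(-2, 0, length.out = 6), 90, 1.5))
  ri <- rbind(lo, ok360, in500)
  fits <- fit_ri_curves(ri)
  expect_gt(fits[["340"]]$r_max, 1.25 * max(lo$response_uV))
  con <- constrain_edge_rmax(fits, ri)
  expect_true(con[["340"]]$r_max_constrained)
  expect_equal(con[["340"]]$r_max, con[["360"]]$r_max)
  # interior wavelengths are never constrained, asymptote or not
  expect_false(con[["500"]]$r_max_constrained)
  # an edge curve that reached its asymptote is left untouched
  ok340 <- ri_frame(340, seq(-0.5, 3.5, length.out = 8),
                    nr_responses(seq(-0.5, 3.5, length.out = 8), 70, 1.5))
  fits2 <- fit_ri_curves(rbind(ok340, ok360))
  con2 <- constrain_edge_rmax(fits2, rbind(ok340, ok360))
  expect_false(con2[["340"]]$r_max_constrained)
})

test_that("log relative sensitivity curves normalize to a zero maximum", {
  wl <- seq(320, 480, by = 20)
  fits <- lapply(wl, function(w) fit_naka_rushton(
    seq(0, 4, length.out = 8), nr_responses(seq(0, 4, length.out = 8),
                                            100, 2)))
  names(fits) <- wl
  flat <- build_sensitivity_curve(fits, "f", "control")
  expect_equal(flat$log_rel_sensitivity, rep(0, length(wl)))

  # halving K at one wavelength raises relative sensitivity by log10(2)
  fits[["400"]] <- fit_naka_rushton(
    seq(0, 4, length.out = 8),
    nr_responses(seq(0, 4, length.out = 8), 100, 2 - log10(2)))
  bump <- build_sensitivity_curve(fits, "f", "control")
  expect_equal(max(bump$log_rel_sensitivity), 0)
  expect_equal(bump$log_rel_sensitivity[bump$wavelength == 400], 0)
  expect_equal(unique(round(
    bump$log_rel_sensitivity[bump$wavelength != 400], 6)),
    round(-log10(2), 6))
  expect_error(build_sensitivity_curve(fits[1:3], "f", "c"), ">= 5")
})

test_that("a forward-simulated curve round-trips through the RI stage", {
  true_logrel <- c(`320` = -1.2, `340` = -0.4, `360` = 0, `380` = -0.1,
                   `400` = -0.6, `420` = -0.9, `440` = -1.4)
  ri <- ri_table(9 - true_logrel)  # LogK = peak anchor minus log rel sens
  curves <- sensitivity_from_ri(ri)
  got <- curves[["f1"]][["control"]]
  expect_equal(got$log_rel_sensitivity, unname(true_logrel),
               tolerance = 1e-6)

  lin <- to_linear_relative(got)
  expect_equal(max(lin$value), 1)
  expect_equal(min(lin$value), 0)
  # min-max is monotone: peak ordering preserved
  expect_equal(order(lin$value), order(got$log_rel_sensitivity))
})
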