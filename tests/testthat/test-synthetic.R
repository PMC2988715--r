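test_that("cohort generation is byte-deterministic under a fixed seed", {
  cfg <- noiseless_config()
  a <- simulate_cohort(cfg, seed = 9)
  b <- simulate_cohort(cfg, seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$curves, b$curves)
  c2 <- simulate_cohort(cfg, seed = 10)
  expect_false(identical(a$truth, c2$truth))
})

test_that("background design gives the intended mechanism catches", {
  bgs <- generate_backgrounds()
  tset <- template_set(0.5)  # the design convention: A2 set to 50%

  q_ctrl <- mechanism_catches(tset, bgs$control)
  expect_lt(max(q_ctrl) / min(q_ctrl), 3)  # control is near-neutral

  # short-wavelength isolation: long mechanisms catch >= 10x the UV cone
  q_sw <- mechanism_catches(tset, bgs$SW)
  expect_gte(q_sw[["LWS"]] / q_sw[["SWS1"]], 10)
  expect_gte(q_sw[["RH2a"]] / q_sw[["SWS1"]], 10)
  # long-wavelength isolation: the short mechanisms dominate the catch
  q_lw <- mechanism_catches(tset, bgs$LW)
  expect_gt(q_lw[["SWS1"]], q_lw[["LWS"]])

  flux <- function(s) integrate_spectrum(s)
  expect_equal(flux(bgs$`Dim-SW`), 0.1 * flux(bgs$SW), tolerance = 1e-9)
  expect_equal(flux(bgs$SW), flux(bgs$control), tolerance = 1e-9)
})

test_that("species condition sets follow the protocol", {
  expect_setequal(conditions_for_species("M. zebra"),
                  c("LW", "control", "SW"))
  expect_setequal(conditions_for_species("P. taeniolatus"),
                  c("Dim-SW", "control", "SW"))
})

test_that("with adaptation off the curve is condition-independent", {
  cfg <- noiseless_config()
  cfg$adaptation_exponent <- 0
  set.seed(2)
  ind <- make_individual("x", "M. zebra", "Male", "2", cfg)
  c1 <- simulate_sensitivity(ind, "control", cfg, noise_sigma = 0)
  c2 <- simulate_sensitivity(ind, "LW", cfg, noise_sigma = 0)
  c3 <- simulate_sensitivity(ind, "SW", cfg, noise_sigma = 0)
  expect_equal(c1$log_rel_sensitivity, c2$log_rel_sensitivity,
               tolerance = 1e-12)
  expect_equal(c1$log_rel_sensitivity, c3$log_rel_sensitivity,
               tolerance = 1e-12)
})

test_that("UV sensitivity rises under short-wavelength isolation", {
  cfg <- noiseless_config()
  set.seed(4)
  ind <- make_individual("x", "M. zebra", "Male", "2", cfg)  # has SWS1
  ctrl <- simulate_sensitivity(ind, "control", cfg, noise_sigma = 0)
  sw <- simulate_sensitivity(ind, "SW", cfg, noise_sigma = 0)
  uv <- ctrl$wavelength <= 400
  rel <- function(cv) mean(10^cv$log_rel_sensitivity[uv]) /
    mean(10^cv$log_rel_sensitivity)
  expect_gt(rel(sw), rel(ctrl))
})

test_that("simulated RI curves invert the Naka-Rushton analysis exactly", {
  cfg <- noiseless_config()
  set.seed(8)
  ind <- make_individual("f1", "M. zebra", "Female", "2", cfg)
  cv <- simulate_sensitivity(ind, "control", cfg, noise_sigma = 0)
  ri <- simulate_ri(ind, "control", cfg, response_sigma = 0, curve = cv)

  # response at I = K is Rmax/2
  for (w in unique(ri$wavelength_nm)) {
    d <- ri[ri$wavelength_nm == w, ]
    logk <- cfg$peak_log_k -
      cv$log_rel_sensitivity[cv$wavelength == w]
    expect_equal(nr_responses(logk, ind$rmax, logk), ind$rmax / 2)
    expect_equal(nrow(d), cfg$n_levels)
  }

  # full round trip through the ERG analysis
  got <- sensitivity_from_ri(ri)[[ind$id]][["control"]]
  expect_equal(got$log_rel_sensitivity, cv$log_rel_sensitivity,
               tolerance = 1e-6)
})

test_that("cohort files are written in the documented formats", {
  cfg <- noiseless_config()
  coh <- simulate_cohort(cfg, seed = 3, with_ri = TRUE, with_qpcr = TRUE)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(all(file.exists(file.path(
    dir, c("truth.tsv", "sensitivity.tsv", "ri.tsv", "qpcr.tsv")))))
  tr <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tr), nrow(coh$truth))
  ri <- read_ri(file.path(dir, "ri.tsv"))
  expect_true(all(c("individual", "condition", "wavelength_nm") %in%
                    names(ri)))
})

test_that("ground truth records everything needed for recovery scoring", {
  cfg <- noiseless_config()
  coh <- simulate_cohort(cfg, seed = 5)
  expect_true(all(c("individual", "species", "sex", "subset",
                    "pigment_set", "a2_fraction", "rmax") %in%
                    names(coh$truth)))
  expect_equal(nrow(coh$truth), sum(cfg$n_per_group))
  ind <- coh$individuals[[1]]
  expect_true(all(ind$opponent >= 0))
  expect_true(ind$a2_fraction >= cfg$a2_range[1] &&
                ind$a2_fraction <= cfg$a2_range[2])
})
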