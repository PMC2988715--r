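test_that("relative expression follows the efficiency-weighted Cq formula", {
  one <- data.frame(gene = "LWS", Cq = 20, efficiency = 0.9)
  expect_equal(unname(relative_expression(one)), 1)

  two <- data.frame(gene = c("a", "b"), Cq = c(10, 11),
                    efficiency = c(1, 1))
  expect_equal(unname(relative_expression(two)), c(2 / 3, 1 / 3))

  six <- data.frame(gene = letters[1:6], Cq = rep(18, 6),
                    efficiency = rep(0.92, 6))
  expect_equal(unname(relative_expression(six)), rep(1 / 6, 6))

  expect_error(relative_expression(
    data.frame(gene = "a", Cq = 20, efficiency = 95)), "percent-style")
  expect_error(relative_expression(
    data.frame(gene = "a", Cq = 20, efficiency = NA)), "missing")
  expect_error(relative_expression(
    data.frame(gene = "a", Cq = -1, efficiency = 0.9)), "positive")
})

test_that("profiles sum to one and shift-invariance needs equal efficiencies", {
  set.seed(21)
  for (i in 1:20) {
    d <- data.frame(gene = letters[1:5], Cq = runif(5, 15, 30),
                    efficiency = runif(5, 0.85, 1))
    f <- relative_expression(d)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    # equal efficiencies: adding a constant to all Cq leaves fractions
    deq <- d
    deq$efficiency <- 0.93
    f1 <- relative_expression(deq)
    deq$Cq <- deq$Cq + 3
    expect_equal(relative_expression(deq), f1, tolerance = 1e-12)
    # unequal efficiencies: the same shift changes fractions
    d2 <- d
    d2$Cq <- d2$Cq + 3
    expect_false(isTRUE(all.equal(relative_expression(d2), f,
                                  tolerance = 1e-6)))
  }
})

test_that("qPCR simulation round-trips through relative expression", {
  cfg <- noiseless_config()
  ind <- list(id = "x", species = "M. auratus", sex = "Female")
  set.seed(5)
  rec <- simulate_qpcr(structure(ind, class = "synthetic_individual"),
                       config = cfg)
  agg <- stats::aggregate(cbind(Cq, efficiency) ~ gene, data = rec,
                          FUN = mean)
  f <- relative_expression(agg)
  target <- cfg$qpcr_presets[["M. auratus|Female"]]
  expect_equal(f[names(target)], target, tolerance = 1e-9)
})

test_that("zero-fraction genes are omitted from simulated qPCR", {
  cfg <- noiseless_config()
  ind <- structure(list(id = "z", species = "M. zebra", sex = "Male"),
                   class = "synthetic_individual")
  set.seed(6)
  expect_message(rec <- simulate_qpcr(ind, config = cfg), "omitted")
  expect_false("LWS" %in% rec$gene)
})

test_that("group summaries report means and standard errors", {
  prof <- data.frame(
    individual = c("a", "b", "c", "d"),
    species = "M. auratus", sex = c("F", "F", "M", "M"),
    gene = "RH2a", fraction = c(0.2, 0.8, 0.5, 0.5))
  gs <- group_summary(prof)
  f <- gs[gs$sex == "F", ]
  expect_equal(f$mean, 0.5)
  expect_equal(f$sem, 0.3)
  m <- gs[gs$sex == "M", ]
  expect_equal(m$sem, 0)
  # permutation invariance
  gs2 <- group_summary(prof[c(3, 1, 4, 2), ])
  expect_equal(gs2, gs)
})

test_that("replicate averaging and control exclusion happen on load", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "individual,species,sex,gene,replicate,Cq,efficiency",
    "f1,M. auratus,Female,LWS,1,20.0,0.9",
    "f1,M. auratus,Female,LWS,2,20.4,0.9",
    "f1,M. auratus,Female,LWS,3,20.2,0.9",
    "NTC,M. auratus,Female,LWS,1,38.0,0.9",
    "No-RT,M. auratus,Female,LWS,1,37.0,0.9"), path)
  expect_message(d <- read_qpcr(path), "2 control rows")
  expect_equal(nrow(d), 1)
  expect_equal(d$Cq, 20.2)
  expect_equal(d$n_replicates, 3)
})

test_that("sex-difference tests use the Bonferroni-corrected threshold", {
  set.seed(31)
  prof <- do.call(rbind, lapply(1:10, function(i) {
    sex <- ifelse(i <= 5, "Female", "Male")
    data.frame(individual = paste0("i", i), species = "sp", sex = sex,
               gene = c("g1", "g2"),
               fraction = c(0.5 + rnorm(1, 0, 0.01), 0.5))
  }))
  res <- sex_difference_tests(prof, "sp")
  expect_equal(nrow(res), 2)
  expect_false(any(res$significant, na.rm = TRUE))
  g2 <- res[res$gene == "g2", ]
  expect_equal(g2$t, 0)
  expect_true(g2$degenerate)

  # a 5-sigma mean shift at n = 5 per sex is detected almost surely
  hits <- replicate(300, {
    f <- rnorm(5, 0.50, 0.01)
    m <- rnorm(5, 0.55, 0.01)
    prof <- data.frame(individual = paste0("i", 1:10), species = "sp",
                       sex = rep(c("Female", "Male"), each = 5),
                       gene = "g", fraction = c(f, m))
    sex_difference_tests(prof, "sp")$significant
  })
  expect_gte(mean(hits), 0.99)
})

test_that("Cochran's C flags a dominant group variance", {
  set.seed(41)
  x_hom <- c(rnorm(10, 0, 1), rnorm(10, 5, 1))
  g <- rep(c("a", "b"), each = 10)
  hom <- cochran_c_test(x_hom, g)
  expect_gt(hom$p_value, 0.05)
  x_het <- c(rnorm(10, 0, 1), rnorm(10, 0, 8))
  het <- cochran_c_test(x_het, g)
  expect_lt(het$p_value, 0.05)
  expect_gt(het$statistic, hom$statistic)
})
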