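test_that("deterministic amplification matches the closed form exactly", {
  t0 <- clone_templates(id = "x", copies = 100, efficiency = 0)
  expect_equal(amplify(t0, 5)$copies, 100)

  t1 <- clone_templates(id = "x", copies = 100, efficiency = 1)
  expect_equal(amplify(t1, 3)$copies, 800)

  t2 <- clone_templates(id = "x", copies = 1000, efficiency = 0.9)
  expect_equal(amplify(t2, 10)$copies, 1000 * 1.9^10)

  expect_equal(amplify(t2, 0)$copies, 1000)
})

test_that("stochastic amplification is unbiased around the closed form", {
  t0 <- clone_templates(id = "x", copies = 50, efficiency = 0.7)
  reps <- vapply(1:200, function(s) {
    amplify(t0, 5, mode = "stochastic", seed = s)$copies
  }, numeric(1))
  expected <- 50 * 1.7^5
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se)
  # reproducible under a fixed seed
  expect_equal(amplify(t0, 5, mode = "stochastic", seed = 1)$copies,
               amplify(t0, 5, mode = "stochastic", seed = 1)$copies)
})

test_that("differential efficiencies skew post-PCR ratios monotonically in cycles", {
  two <- clone_templates(id = c("fast", "slow"), copies = c(1000, 1000),
                         efficiency = c(0.95, 0.70))
  ratios <- vapply(c(5, 10, 20, 30), function(n) {
    out <- amplify(two, n)
    out$copies[1] / out$copies[2]
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_equal(ratios[1], (1.95 / 1.70)^5)
})

test_that("dilution series spans the configured copy range", {
  expect_equal(dilution_series(1e8, 1e3, 10),
               c(1e8, 1e7, 1e6, 1e5, 1e4, 1e3))
  expect_length(dilution_series(1e8, 1e3, 10), 6)
  expect_equal(dilution_series(1e3, 1e3, 10), 1e3)
  expect_error(dilution_series(1e8, 3e3, 10), "reachable")
})

test_that("Ct arithmetic follows the standard-curve line", {
  curve <- standard_curve(-3.3219, 35)
  expect_equal(ct_from_copies(1e3, curve), 35 - 3.3219 * 3)
  expect_equal(ct_from_copies(1, curve), 35)
  # a ten-fold copy increase advances Ct by one slope unit
  expect_equal(ct_from_copies(1e5, curve) - ct_from_copies(1e6, curve),
               3.3219)
  expect_error(ct_from_copies(0, curve), "positive")
})

test_that("standard-curve fitting recovers noise-free parameters exactly", {
  gen <- standard_curve(-1 / log10(2), 35)  # slope -3.3219..., 100% efficiency
  pts <- tibble::tibble(copies = dilution_series(1e8, 1e3, 10))
  pts$ct <- ct_from_copies(pts$copies, gen)
  fit <- fit_standard_curve(pts)
  expect_equal(fit$slope, gen$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, 35, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-9)
  expect_true(fit$valid)

  # two points interpolate exactly
  fit2 <- fit_standard_curve(pts[c(1, 6), ])
  expect_equal(fit2$r_squared, 1)

  # flat response is flagged invalid
  flat <- fit_standard_curve(tibble::tibble(copies = c(1e3, 1e4, 1e5),
                                            ct = c(20, 20, 20)))
  expect_false(flat$valid)
  expect_error(quantify(20, flat), "invalid")

  expect_error(fit_standard_curve(tibble::tibble(copies = c(1e3, 1e3),
                                                 ct = c(20, 21))),
               "distinct")
})

test_that("tidy and glance summarise a fitted curve", {
  pts <- tibble::tibble(copies = dilution_series())
  pts$ct <- ct_from_copies(pts$copies, standard_curve(-3.3219, 35))
  fit <- fit_standard_curve(pts)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- generics::glance(fit)
  expect_equal(gl$n_points, 6L)
  expect_equal(gl$r_squared, 1)
})

test_that("quantification inverts the qPCR read-out at zero noise", {
  curve <- standard_curve(-3.3219, 35)
  copies <- 10^(3:8)
  back <- quantify(ct_from_copies(copies, curve), curve)
  expect_equal(back, copies, tolerance = 1e-9)
  expect_equal(quantify(35, curve), 1)
  # one slope unit of Ct is a ten-fold copy change
  expect_equal(quantify(30 - 3.3219, curve) / quantify(30, curve), 10,
               tolerance = 1e-9)
})

test_that("ratio normalisation maps the smallest clone to 1", {
  expect_equal(normalize_ratio(c(1e6, 3e6, 8e6, 2e6, 1e7)),
               c(1, 3, 8, 2, 10))
  expect_equal(normalize_ratio(c(5, 5)), c(1, 1))
  expect_error(normalize_ratio(c(0, 1)), "positive")
})

test_that("the mock-community simulation is seeded and structurally complete", {
  sim <- simulate_mock_community(seed = 5)
  expect_equal(nrow(sim), 5 * 3 * 3 * 3)  # clones x cycles x bio x exp
  expect_equal(sort(unique(sim$cycles)), c(10, 20, 30))
  # input ratio preserved in the initial-mixture column
  expect_equal(sort(unique(sim$ratio_initial)), c(1, 2, 3, 8, 10))
  # reproducible
  sim2 <- simulate_mock_community(seed = 5)
  expect_equal(sim$ratio, sim2$ratio)
  # every replicate's ratio vector is normalised to min 1
  mins <- tapply(sim$ratio, interaction(sim$cycles, sim$biological,
                                        sim$experimental), min)
  expect_true(all(abs(mins - 1) < 1e-12))
})
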