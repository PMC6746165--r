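# Receptor population decay-kinetics model

test_that("pair partition maximizes mixed pairs and halves the remainder", {
  part <- pair_partition(subunit_mix(0.35, 0.65))
  expect_equal(part$pairs, 0.35)
  expect_equal(part$leftover_immature, 0.15)
  expect_equal(part$leftover_mature, 0)

  part <- pair_partition(subunit_mix(0.5, 0.5))
  expect_equal(part$pairs, 0.5)
  expect_equal(part$leftover_mature, 0)
  expect_equal(part$leftover_immature, 0)

  part <- pair_partition(subunit_mix(1, 0))
  expect_equal(part$pairs, 0)
  expect_equal(part$leftover_mature, 0.5)
  expect_equal(part$leftover_immature, 0)
})

test_that("population kinetics reproduces the worked example and boundaries", {
  # 35% GluN2A / 65% GluN2B: (0.35*50 + 0.15*333) / 0.5 = 134.9 ms
  pred <- population_kinetics(subunit_mix(0.35, 0.65), nmdar_params())
  expect_equal(pred$value_ms, 134.9)
  # boundaries collapse to the single-population constants
  expect_equal(nmdar_decay_ms(1, 0), 36)
  expect_equal(nmdar_decay_ms(0, 1), 333)
  expect_equal(nmdar_decay_ms(0.5, 0.5), 50)
  expect_equal(gabaar_decay_ms(1, 0), 42.2)
  expect_equal(gabaar_decay_ms(0, 1), 129)
  expect_equal(gabaar_decay_ms(0.5, 0.5), 49)
  # interior points match direct arithmetic
  expect_equal(nmdar_decay_ms(0.8, 0.2), 41.6)       # 36 + 28 * 0.2
  expect_equal(gabaar_decay_ms(0.35, 0.65), 73.0)    # 160 * 0.65 - 31
})

test_that("model matches the re-derived piecewise-linear closed form", {
  # weighted average simplifies (denominator is always 1/2):
  #   NMDAR:   36 + 28 b   (b <= 1/2),  566 b - 233  (b >= 1/2)
  #   GABAAR:  42.2 + 13.6 g (g <= 1/2), 160 g - 31  (g >= 1/2)
  nmdar_oracle <- function(b) ifelse(b <= 0.5, 36 + 28 * b, 566 * b - 233)
  gabaar_oracle <- function(g) ifelse(g <= 0.5, 42.2 + 13.6 * g,
                                      160 * g - 31)
  b <- seq(0, 1, length.out = 1001)
  nm <- vapply(b, function(bi) nmdar_decay_ms(1 - bi, bi), numeric(1))
  ga <- vapply(b, function(gi) gabaar_decay_ms(1 - gi, gi), numeric(1))
  expect_lt(max(abs(nm - nmdar_oracle(b))), 1e-9)
  expect_lt(max(abs(ga - gabaar_oracle(b))), 1e-9)
  # continuity at the equal mix, strict monotonicity, bounds
  expect_lt(abs(nmdar_decay_ms(0.5 - 1e-12, 0.5 + 1e-12) - 50), 1e-8)
  expect_true(all(diff(nm) > 0))
  expect_true(all(nm >= 36 & nm <= 333))
  expect_true(all(ga >= 42.2 & ga <= 129))
})

test_that("kinetics depend only on the subunit ratio, not absolute scale", {
  for (scale in c(0.1, 3, 250)) {
    expect_equal(nmdar_decay_ms(0.3 * scale, 0.7 * scale),
                 nmdar_decay_ms(0.3, 0.7))
  }
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(subunit_mix(0, 0), class = "pp_validation_error")
  expect_error(subunit_mix(-1, 2), class = "pp_validation_error")
  expect_error(kinetics_params(50, 60, 333), class = "pp_validation_error")
  expect_error(kinetics_params(-1, -2, -3), class = "pp_validation_error")
})

test_that("trajectory fits recover noiseless generating parameters", {
  x <- seq(1, 10, length.out = 12)
  y <- 40 + 100 * exp(-x / 2)
  fit <- fit_trajectory(x, y, "exponential_decay")
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters[c("y0", "A", "tau")]), c(40, 100, 2),
               tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)

  y4 <- 36 + (300 - 36) / (1 + (x / 4)^2.5)
  fit4 <- fit_trajectory(x, y4, "sigmoid", bounds = c(36, 333))
  expect_true(fit4$converged)
  expect_equal(unname(fit4$parameters[c("lower", "upper", "xmid", "slope")]),
               c(36, 300, 4, 2.5), tolerance = 1e-6)
})

test_that("exponential tau is recovered within 20% median error under noise", {
  set.seed(42)
  x <- seq(0.5, 10, length.out = 20)
  errs <- replicate(100, {
    y <- 40 + 100 * exp(-x / 2) + rnorm(20, sd = 5)
    fit <- fit_trajectory(x, y, "exponential_decay")
    if (!fit$converged) return(NA_real_)
    abs(fit$parameters[["tau"]] - 2) / 2
  })
  expect_lt(median(errs, na.rm = TRUE), 0.20)
})

test_that("trajectory fit reports no-fit instead of erroring", {
  x <- 1:5
  expect_error(fit_trajectory(x[1:3], x[1:3], "exponential_decay"),
               class = "pp_validation_error")
  expect_error(fit_trajectory(-x, x, "exponential_decay"),
               class = "pp_validation_error")
})

test_that("group kinetics table pairs GABAAR x with NMDAR y per group", {
  # equal mixes -> the pure-pair constants (49, 50)
  vals <- matrix(1, 4, 7)
  em <- make_em(vals, condition = c("A", "A", "B", "B"))
  kt <- kinetics_trajectory_table(em)
  expect_equal(kt$nmdar_ms, rep(50, nrow(kt)))
  expect_equal(kt$gabaar_ms, rep(49, nrow(kt)))

  # pure-immature group -> (129, 333)
  vals2 <- matrix(1, 3, 7)
  colnames(vals2) <- protein_panel()
  vals2[, "GluN2A"] <- 0; vals2[, "GABAAa1"] <- 0
  em2 <- make_em(vals2, condition = "IMM")
  kt2 <- kinetics_trajectory_table(em2)
  expect_equal(kt2$nmdar_ms, rep(333, nrow(kt2)))
  expect_equal(kt2$gabaar_ms, rep(129, nrow(kt2)))

  # MD-like group (2A < 2B, a1 > a3): NMDAR slower, GABAAR faster than
  # the equal-mix point (50, 49)
  vals3 <- matrix(1, 3, 7)
  colnames(vals3) <- protein_panel()
  vals3[, "GluN2A"] <- 0.6; vals3[, "GluN2B"] <- 1.3
  vals3[, "GABAAa1"] <- 1.35; vals3[, "GABAAa3"] <- 1.0
  em3 <- make_em(vals3, condition = "MD")
  kt3 <- kinetics_trajectory_table(em3)
  expect_true(all(kt3$nmdar_ms > 50))
  expect_true(all(kt3$gabaar_ms < 49))
})
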