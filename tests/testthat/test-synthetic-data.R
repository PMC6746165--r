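# Synthetic Western-blot dataset generator

test_that("default design reproduces the study layout", {
  des <- default_design()
  pieces <- sum(as.matrix(des$conditions[, des$regions]))
  expect_equal(pieces, 113)
  ds <- generate_dataset(des, default_effects(), seed = 3)
  expect_equal(length(unique(ds$piece_id)), 113)
  expect_equal(nrow(unique(ds[c("piece_id", "run")])), 226)
  expect_setequal(unique(ds$protein), protein_panel())
})

test_that("zero noise and zero missingness give the exact condition means", {
  eff <- tiny_effects(trt_shift = c(GluA2 = 1.6), noise_sd = 0)
  ds <- generate_dataset(tiny_design(), eff, seed = 1)
  for (cond in names(eff)) {
    w <- ds[ds$condition == cond, ]
    expected <- eff[[cond]]$mean_vector[w$protein]
    expect_equal(w$od, unname(expected))
  }
})

test_that("large-sample correlations recover the generating matrix", {
  des <- study_design(data.frame(condition = "X", age_wks = 5,
                                 n_animals = 1, C = 2500, P = 0, M = 0))
  p <- protein_panel()
  r <- diag(7); r[r == 0] <- 0.5; diag(r) <- 1; dimnames(r) <- list(p, p)
  eff <- list(X = effect_spec(stats::setNames(rep(1, 7), p), r,
                              noise_sd = 0.1))
  ds <- generate_dataset(des, eff, seed = 11)
  wide <- matrix(ds$od, ncol = 7, byrow = TRUE)
  expect_lt(max(abs(stats::cor(wide) - r)), 0.05)
})

test_that("generation is bit-identical for a fixed seed", {
  eff <- tiny_effects(missing_rate = 0.1)
  a <- generate_dataset(tiny_design(), eff, seed = 99)
  b <- generate_dataset(tiny_design(), eff, seed = 99)
  expect_identical(a, b)
  c <- generate_dataset(tiny_design(), eff, seed = 100)
  expect_false(identical(a$od, c$od))
})

test_that("missingness is planted at the piece level at the requested rate", {
  des <- study_design(data.frame(condition = "X", age_wks = 5,
                                 n_animals = 1, C = 400, P = 0, M = 0))
  p <- protein_panel()
  eff <- list(X = effect_spec(stats::setNames(rep(1, 7), p), diag(7),
                              noise_sd = 0.1, missing_rate = 0.05))
  ds <- generate_dataset(des, eff, seed = 5)
  # a missing cell is missing in every run of its piece
  byc <- tapply(is.na(ds$od), list(ds$piece_id, ds$protein),
                function(v) all(v) || !any(v))
  expect_true(all(byc))
  # realized piece-level missing fraction within the binomial 99% CI
  cells <- unique(ds[c("piece_id", "protein")])
  frac <- mean(tapply(is.na(ds$od),
                      paste(ds$piece_id, ds$protein), all))
  n_cells <- nrow(cells)
  ci <- 0.05 + c(-1, 1) * stats::qnorm(0.995) *
    sqrt(0.05 * 0.95 / n_cells)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("planted group means are recovered within 3 standard errors", {
  eff <- default_effects(noise_sd = 0.15, missing_rate = 0)
  ds <- generate_dataset(default_design(), eff, seed = 21)
  pl <- average_runs(ds)
  for (cond in names(eff)) {
    w <- pl[pl$condition == cond, ]
    for (prot in protein_panel()) {
      v <- w$od[w$protein == prot]
      se <- 0.15 / sqrt(2) / sqrt(length(v))  # run-averaged pieces
      expect_lt(abs(mean(v) - eff[[cond]]$mean_vector[[prot]]), 3.5 * se)
    }
  }
})

test_that("default effects encode the documented contrasts", {
  eff <- default_effects()
  expect_equal(unname(eff[["5wk_normal"]]$mean_vector), rep(1, 7))
  expect_gt(eff[["BD"]]$mean_vector[["GABAAa1"]],
            eff[["5wk_normal"]]$mean_vector[["GABAAa1"]])
  expect_gt(eff[["RO"]]$mean_vector[["GluA2"]], 1.0)
  expect_gt(eff[["RO"]]$mean_vector[["GluN2A"]], 1.0)
  # LT-BV: near-normal with lowered GABAAR expression
  expect_lt(eff[["LT-BV"]]$mean_vector[["GABAAa1"]], 1.0)
  expect_lt(eff[["LT-BV"]]$mean_vector[["GABAAa3"]], 1.0)
  # every pair of conditions separated by >= 3 noise SD in some protein
  mv <- sapply(eff, function(e) e$mean_vector)
  for (i in seq_len(ncol(mv) - 1)) for (j in (i + 1):ncol(mv))
    expect_gte(max(abs(mv[, i] - mv[, j])), 3 * 0.1 - 1e-9)
})

test_that("configuration and validation errors are specific", {
  eff <- tiny_effects()
  expect_error(generate_dataset(tiny_design(), eff["TRT"], seed = 1),
               class = "pp_config_error")
  p <- protein_panel()
  bad_r <- matrix(0.99, 7, 7); bad_r[1, 2] <- bad_r[2, 1] <- -0.99
  diag(bad_r) <- 1; dimnames(bad_r) <- list(p, p)
  expect_error(effect_spec(stats::setNames(rep(1, 7), p), bad_r),
               class = "pp_validation_error")
  expect_error(effect_spec(stats::setNames(rep(0, 7), p), diag(7)),
               class = "pp_validation_error")
  expect_error(effect_spec(stats::setNames(rep(1, 7), p), diag(7),
                           missing_rate = 1.5),
               class = "pp_validation_error")
  expect_error(study_design(data.frame(condition = "X", age_wks = 5,
                                       n_animals = 1, C = 0, P = 0, M = 0)),
               class = "pp_config_error")
})

test_that("datasets round-trip through CSV", {
  ds <- generate_dataset(tiny_design(), tiny_effects(), seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$od, ds$od, tolerance = 1e-12)
  expect_identical(back$piece_id, ds$piece_id)
})
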