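#' Color scales for phenotype bands
#'
#' Protein-sum bands use a grayscale from white (0) to black (the maximum
#' sum across the displayed groups); index bands use a fixed red-yellow-
#' green gradient with red at -1, yellow at 0 and green at +1. Values are
#' clipped to the scale endpoints. Both maps are pure monotone functions
#' of the value, so equal values always get equal colors.
#'
#' @param v numeric value(s).
#' @param max_sum scale maximum for the grayscale map.
#' @return Hex color string(s).
#' @export
index_color <- function(v) {
  v <- pmin(pmax(v, -1), 1)
  ramp <- grDevices::colorRamp(c("#FF0000", "#FFFF00", "#00FF00"))
  rgb <- ramp((v + 1) / 2)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' @rdname index_color
#' @export
sum_color <- function(v, max_sum) {
  if (max_sum <= 0) pp_stop("pp_validation_error", "max_sum must be > 0")
  frac <- pmin(pmax(v / max_sum, 0), 1)
  grDevices::gray(1 - frac)
}

#' Build the color-coded plasticity phenotype of one group
#'
#' Maps the 9 feature values of a subcluster (3 sums, 6 indices) to the
#' stacked color bands of the phenotype display.
#'
#' @param feature_values named numeric with the 9 [feature_names()].
#' @param sum_max grayscale maximum; use the max sum across all displayed
#'   groups so their gray bands are comparable (default: max of this
#'   group's sums).
#' @param label optional group label.
#' @return A `phenotype_profile` data.frame: `feature`, `kind`, `value`,
#'   `color`, `missing`.
#' @export
build_phenotype <- function(feature_values, sum_max = NULL, label = NULL) {
  fn <- feature_names()
  kind <- feature_kind()
  vals <- feature_values[fn]
  sums <- vals[kind == "sum"]
  if (is.null(sum_max)) sum_max <- max(sums, na.rm = TRUE)
  color <- character(length(fn))
  missing <- is.na(vals)
  color[kind == "sum" & !missing] <- sum_color(sums[!is.na(sums)], sum_max)
  idx <- kind == "index" & !missing
  color[idx] <- index_color(vals[idx])
  color[missing] <- NA_character_
  out <- data.frame(feature = fn, kind = unname(kind[fn]),
                    value = unname(vals), color = color, missing = missing,
                    row.names = NULL)
  if (!is.null(label)) out <- cbind(label = label, out)
  class(out) <- c("phenotype_profile", "data.frame")
  out
}

#' Bootstrap Monte-Carlo configuration
#'
#' @param sim_size points in the simulated Gaussian population (default
#'   1e6).
#' @param resamples bootstrap resamples used to build the CIs of the mean
#'   (default 1e5).
#' @param seed integer seed.
#' @param convention `"simulate_subcluster"` (default): simulate from the
#'   subcluster's mean/SD, resample at the reference group's n, and test
#'   the reference mean against the CIs. `"simulate_reference"` mirrors
#'   the roles. The underlying description of the procedure is ambiguous
#'   about which group anchors the simulation; both are provided.
#' @return A `bootstrap_config` list.
#' @export
bootstrap_config <- function(sim_size = 1e6, resamples = 1e5,
                             seed = 20190903,
                             convention = c("simulate_subcluster",
                                            "simulate_reference")) {
  convention <- match.arg(convention)
  if (sim_size < resamples)
    pp_stop("pp_config_error", "sim_size must be >= resamples")
  list(sim_size = as.integer(sim_size), resamples = as.integer(resamples),
       seed = as.integer(seed), convention = convention)
}

#' Bootstrap comparison of a subcluster feature against the reference
#'
#' Implements the parametric bootstrap / Monte-Carlo test: simulate a
#' Gaussian population (`sim_size` points) from the subcluster's feature
#' mean and SD, repeatedly (`resamples` times) draw samples of size n —
#' the reference group's observation count — with replacement, form the
#' two-sided CIs of the resampled means at the requested levels, and flag
#' the comparison when the reference group's mean falls outside a CI. The
#' reported level is the most extreme one at which the reference mean is
#' excluded. `direction` describes the subcluster relative to the
#' reference: `"greater"` when the reference mean falls below the lower CI
#' bound.
#'
#' Note that the CI width reflects only the resampling variability of a
#' mean of n points around the subcluster's estimated mean; see the
#' package vignette for the calibration consequences.
#'
#' @param subcluster_values numeric vector (>= 2 values).
#' @param reference_values numeric vector (>= 2 values).
#' @param config a [bootstrap_config()].
#' @param levels nominal two-sided levels (default 0.05, 0.01, 0.001),
#'   possibly Bonferroni-scaled by the caller.
#' @return List: `direction` ("greater", "less" or "not_different"),
#'   `level` (most extreme exclusion level or NA), `ci_table`
#'   (data.frame: level, lower, upper, excluded), `reference_mean`.
#' @export
bootstrap_compare <- function(subcluster_values, reference_values,
                              config = bootstrap_config(),
                              levels = c(0.05, 0.01, 0.001)) {
  if (length(subcluster_values) < 2 || length(reference_values) < 2)
    pp_stop("pp_validation_error", "need >= 2 values in each group")
  mirrored <- config$convention == "simulate_reference"
  if (mirrored) {
    # simulate from the reference, resample at the subcluster's n, and
    # test the subcluster mean; direction is flipped back below so it
    # always describes the subcluster relative to the reference
    tmp <- subcluster_values
    subcluster_values <- reference_values
    reference_values <- tmp
  }
  m <- mean(subcluster_values)
  s <- stats::sd(subcluster_values)
  ref_mean <- mean(reference_values)
  n <- length(reference_values)
  levels <- sort(levels, decreasing = TRUE)   # least to most stringent
  if (s == 0) {
    warning("degenerate subcluster (zero SD); exact mean comparison used")
    same <- isTRUE(all.equal(ref_mean, m))
    direction <- if (same) "not_different" else
      if (ref_mean < m) "greater" else "less"
    if (mirrored && direction != "not_different")
      direction <- if (direction == "greater") "less" else "greater"
    ci <- data.frame(level = levels, lower = m, upper = m,
                     excluded = !same)
    return(list(direction = direction,
                level = if (same) NA_real_ else min(levels),
                ci_table = ci, reference_mean = ref_mean))
  }
  set.seed(config$seed)
  sim <- stats::rnorm(config$sim_size, mean = m, sd = s)
  draws <- matrix(sample(sim, n * config$resamples, replace = TRUE),
                  nrow = config$resamples)
  means <- rowMeans(draws)
  lower <- stats::quantile(means, levels / 2, names = FALSE)
  upper <- stats::quantile(means, 1 - levels / 2, names = FALSE)
  excluded <- ref_mean < lower | ref_mean > upper
  level <- if (any(excluded)) min(levels[excluded]) else NA_real_
  direction <- if (!any(excluded)) "not_different" else
    if (ref_mean < lower[which(excluded)[1]]) "greater" else "less"
  if (mirrored && direction != "not_different")
    direction <- if (direction == "greater") "less" else "greater"
  list(direction = direction, level = level,
       ci_table = data.frame(level = levels, lower = lower, upper = upper,
                             excluded = excluded),
       reference_mean = ref_mean)
}

#' Compare every subcluster feature against the normal reference
#'
#' Runs [bootstrap_compare()] for each (subcluster, feature) pair using
#' the per-sample feature table, Bonferroni-correcting over
#' (number of subclusters x 9) tests by scaling the nominal levels
#' (0.05 -> 0.05 / T, etc. — equivalent to widening the CIs and exactly
#' reportable). The resulting grid is the red (greater) / blue (less) /
#' white (not different) banding of the phenotype significance display.
#'
#' @param feature_table per-sample feature table ([compute_feature_table()]).
#' @param subclusters list of `subcluster_profile`s.
#' @param reference_condition label of the reference (default
#'   `"5wk_normal"`); reference values are all samples of that condition.
#' @param config a [bootstrap_config()].
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param levels base nominal levels.
#' @return data.frame grid: `subcluster`, `feature`, `direction`, `level`
#'   (the base-scale level at which flagged, or NA), `color`.
#' @export
compare_all <- function(feature_table, subclusters,
                        reference_condition = "5wk_normal",
                        config = bootstrap_config(),
                        correction = c("bonferroni", "none"),
                        levels = c(0.05, 0.01, 0.001)) {
  correction <- match.arg(correction)
  if (!reference_condition %in% feature_table$condition)
    pp_stop("pp_config_error", "reference condition '%s' not in table",
            reference_condition)
  fn <- feature_names()
  n_tests <- length(subclusters) * length(fn)
  used_levels <- if (correction == "bonferroni") levels / n_tests else levels
  ref_rows <- feature_table$condition == reference_condition
  out <- vector("list", n_tests)
  i <- 0L
  for (sc in subclusters) {
    for (f in fn) {
      i <- i + 1L
      cfg <- config
      cfg$seed <- (config$seed + i) %% .Machine$integer.max
      res <- bootstrap_compare(feature_table[[f]][sc$member_rows],
                               feature_table[[f]][ref_rows],
                               config = cfg, levels = used_levels)
      base_level <- if (is.na(res$level)) NA_real_ else
        levels[match(res$level, used_levels)]
      out[[i]] <- data.frame(
        subcluster = sc$label, feature = f, direction = res$direction,
        level = base_level,
        color = switch(res$direction, greater = "red", less = "blue",
                       not_different = "white"))
    }
  }
  grid <- do.call(rbind, out)
  attr(grid, "n_tests") <- n_tests
  attr(grid, "adjusted_levels") <- used_levels
  grid
}
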