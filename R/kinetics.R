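#' Receptor decay-time constants
#'
#' Decay-kinetics constants (ms) for the three receptor populations of
#' each receptor class: the mixed (mature + immature subunit) pair, the
#' mature-only pair, and the immature-only pair.
#'
#' * NMDAR: GluN2A/GluN2B triheteromer 50 ms, GluN2A-only 36 ms,
#'   GluN2B-only 333 ms.
#' * GABA_A_R: alpha1/alpha3 49 ms, alpha1-only 42.2 ms, alpha3-only
#'   129.0 ms.
#'
#' @param tau_pair,tau_mature,tau_immature decay times in ms; must satisfy
#'   `tau_mature <= tau_pair <= tau_immature`.
#' @return A `kinetics_params` list.
#' @export
kinetics_params <- function(tau_pair, tau_mature, tau_immature) {
  if (any(c(tau_pair, tau_mature, tau_immature) <= 0))
    pp_stop("pp_validation_error", "decay constants must be positive")
  if (!(tau_mature <= tau_pair && tau_pair <= tau_immature))
    pp_stop("pp_validation_error",
            "need tau_mature <= tau_pair <= tau_immature")
  structure(list(tau_pair = tau_pair, tau_mature = tau_mature,
                 tau_immature = tau_immature),
            class = "kinetics_params")
}

#' @rdname kinetics_params
#' @export
nmdar_params <- function() kinetics_params(50, 36, 333)

#' @rdname kinetics_params
#' @export
gabaar_params <- function() kinetics_params(49, 42.2, 129)

#' Subunit mix from relative expression
#'
#' Normalizes the optical densities of the mature subunit (GluN2A or
#' GABA_A alpha1) and the immature subunit (GluN2B or alpha3) to fractions
#' summing to 1; the model depends only on this ratio, not the absolute
#' scale.
#'
#' @param mature,immature nonnegative expression (OD) of each subunit.
#' @return A `subunit_mix` with `frac_mature` + `frac_immature` = 1.
#' @export
subunit_mix <- function(mature, immature) {
  if (mature < 0 || immature < 0)
    pp_stop("pp_validation_error", "subunit expression must be nonnegative")
  total <- mature + immature
  if (total == 0)
    pp_stop("pp_validation_error",
            "both subunit fractions are zero; mix undefined")
  structure(list(frac_mature = mature / total,
                 frac_immature = immature / total),
            class = "subunit_mix")
}

#' Partition a subunit mix into receptor pairs
#'
#' Mixed (mature:immature) pairs are the most common receptors, so the
#' model maximizes them: the number of mixed pairs is limited by the less
#' expressed subunit. The remaining proportion of the more expressed
#' subunit pairs with itself, so it is divided by 2; the scarcer subunit
#' leaves no remainder.
#'
#' @param mix a [subunit_mix()].
#' @return List: `pairs`, `leftover_mature`, `leftover_immature`.
#' @export
#' @examples
#' pair_partition(subunit_mix(0.35, 0.65))  # pairs 0.35, leftover 0.15
pair_partition <- function(mix) {
  stopifnot(inherits(mix, "subunit_mix"))
  pairs <- min(mix$frac_mature, mix$frac_immature)
  leftover <- abs(mix$frac_mature - mix$frac_immature) / 2
  list(pairs = pairs,
       leftover_mature = if (mix$frac_mature > mix$frac_immature) leftover else 0,
       leftover_immature = if (mix$frac_immature > mix$frac_mature) leftover else 0)
}

#' Predicted population decay kinetics for a subunit mix
#'
#' The population decay time is the weighted average of the three receptor
#' decay constants over the pair partition:
#'
#' value = (pairs * tau_pair + leftover_mature * tau_mature +
#'          leftover_immature * tau_immature) /
#'         (pairs + leftover_mature + leftover_immature)
#'
#' For the NMDAR constants this reduces to the piecewise-linear form
#' 36 + 28 b for immature (GluN2B) fraction b <= 0.5 and 566 b - 233 for
#' b >= 0.5; the prediction always lies in
#' `[tau_mature, tau_immature]` and increases monotonically with the
#' immature fraction.
#'
#' @param mix a [subunit_mix()].
#' @param params a [kinetics_params()] (e.g. [nmdar_params()]).
#' @return A `kinetics_prediction`: `value_ms`, `pair_fraction`,
#'   `leftover_mature`, `leftover_immature`.
#' @export
#' @examples
#' # 35% GluN2A / 65% GluN2B pool -> 134.9 ms (prints as 135 ms)
#' population_kinetics(subunit_mix(0.35, 0.65), nmdar_params())$value_ms
population_kinetics <- function(mix, params) {
  stopifnot(inherits(params, "kinetics_params"))
  part <- pair_partition(mix)
  denom <- part$pairs + part$leftover_mature + part$leftover_immature
  value <- (part$pairs * params$tau_pair +
            part$leftover_mature * params$tau_mature +
            part$leftover_immature * params$tau_immature) / denom
  structure(list(value_ms = value, pair_fraction = part$pairs,
                 leftover_mature = part$leftover_mature,
                 leftover_immature = part$leftover_immature),
            class = "kinetics_prediction")
}

#' @export
print.kinetics_prediction <- function(x, ...) {
  cat(sprintf("predicted population decay: %.1f ms (pairs %.3f, mature %.3f, immature %.3f)\n",
              x$value_ms, x$pair_fraction, x$leftover_mature,
              x$leftover_immature))
  invisible(x)
}

#' Convenience wrappers from subunit ODs to decay times
#'
#' @param od_mature,od_immature nonnegative expression of the mature
#'   (GluN2A / alpha1) and immature (GluN2B / alpha3) subunit.
#' @return Predicted population decay time (ms).
#' @export
nmdar_decay_ms <- function(od_mature, od_immature) {
  population_kinetics(subunit_mix(od_mature, od_immature),
                      nmdar_params())$value_ms
}

#' @rdname nmdar_decay_ms
#' @export
gabaar_decay_ms <- function(od_mature, od_immature) {
  population_kinetics(subunit_mix(od_mature, od_immature),
                      gabaar_params())$value_ms
}

#' Fit a developmental / treatment trajectory
#'
#' Nonlinear least squares of decay-kinetics (or feature) values against
#' age or treatment duration. `"exponential_decay"` fits
#' y = y0 + A exp(-x / tau); `"sigmoid"` fits a 4-parameter logistic
#' y = lower + (upper - lower) / (1 + (x / xmid)^slope). A fit is
#' reported only when the optimizer converges.
#'
#' @param x strictly positive predictor (age in weeks, or duration).
#' @param y response values.
#' @param model `"exponential_decay"` or `"sigmoid"`.
#' @param bounds optional `c(lower, upper)` box for the sigmoid
#'   asymptotes (e.g. the receptor constants `c(36, 333)`).
#' @return A `trajectory_fit`: `model`, `converged`, `parameters`,
#'   `r_squared`, `residuals`, `fitted`; or `converged = FALSE` with the
#'   error message when no fit is obtained.
#' @export
fit_trajectory <- function(x, y, model = c("exponential_decay", "sigmoid"),
                           bounds = NULL) {
  model <- match.arg(model)
  if (any(x <= 0)) pp_stop("pp_validation_error", "x must be positive")
  n_par <- if (model == "exponential_decay") 3L else 4L
  if (length(x) < n_par + 1L)
    pp_stop("pp_validation_error", "need >= %d points for the %s model",
            n_par + 1L, model)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (model == "exponential_decay") {
      minpack.lm::nlsLM(
        y ~ y0 + A * exp(-x / tau), data = df,
        start = list(y0 = min(y), A = y[which.min(x)] - min(y) + 1e-6,
                     tau = max(diff(range(x)) / 3, 1e-3)),
        lower = c(y0 = -Inf, A = -Inf, tau = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      lo <- if (is.null(bounds)) min(y) - abs(diff(range(y))) else bounds[1]
      hi <- if (is.null(bounds)) max(y) + abs(diff(range(y))) else bounds[2]
      minpack.lm::nlsLM(
        y ~ lower + (upper - lower) / (1 + (x / xmid)^slope), data = df,
        start = list(lower = min(y), upper = max(y),
                     xmid = stats::median(x), slope = 1),
        lower = c(lower = lo, upper = lo, xmid = 1e-9, slope = -50),
        upper = c(lower = hi, upper = hi, xmid = Inf, slope = 50),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(model = model, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "trajectory_fit"))
  res <- stats::residuals(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  structure(list(model = model, converged = TRUE,
                 parameters = stats::coef(fit), r_squared = r2,
                 residuals = as.numeric(res),
                 fitted = as.numeric(stats::fitted(fit))),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  if (!x$converged) {
    cat("trajectory_fit (", x$model, "): no fit (", x$message, ")\n")
  } else {
    cat("trajectory_fit (", x$model, "): R^2 =", round(x$r_squared, 4), "\n")
    print(round(x$parameters, 6))
  }
  invisible(x)
}

#' Predicted NMDAR and GABA_A_R kinetics per group
#'
#' Computes group-mean subunit expression (GluN2A/GluN2B and
#' alpha1/alpha3) per condition x region and converts both balances into
#' predicted population decay times — the paired XY table behind the
#' kinetics trajectory scatterplot (GABA_A_R ms on x, NMDAR ms on y).
#'
#' @param em an `expression_matrix`.
#' @param by grouping columns of the metadata (default
#'   `c("condition", "region")`).
#' @return data.frame with the group labels, mean subunit ODs, and
#'   `gabaar_ms` / `nmdar_ms`.
#' @export
kinetics_trajectory_table <- function(em, by = c("condition", "region")) {
  meta <- em$metadata
  key <- interaction(meta[by], drop = TRUE, sep = "|")
  groups <- split(seq_len(nrow(meta)), key)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    mu <- colMeans(em$values[idx, , drop = FALSE])
    lab <- strsplit(g, "|", fixed = TRUE)[[1]]
    out <- as.data.frame(as.list(stats::setNames(lab, by)))
    out$n <- length(idx)
    out$glun2a <- mu[["GluN2A"]]; out$glun2b <- mu[["GluN2B"]]
    out$gabaa1 <- mu[["GABAAa1"]]; out$gabaa3 <- mu[["GABAAa3"]]
    out$nmdar_ms <- nmdar_decay_ms(mu[["GluN2A"]], mu[["GluN2B"]])
    out$gabaar_ms <- gabaar_decay_ms(mu[["GABAAa1"]], mu[["GABAAa3"]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
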