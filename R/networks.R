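# Pairwise Pearson correlations with two-sided p-values from the
# t-transform t = r * sqrt((n-2) / (1-r^2)), df = n - 2. Constant columns
# yield NA r and NA p (excluded from significance calls).
pp_corr_with_p <- function(values) {
  n <- nrow(values)
  sds <- apply(values, 2, stats::sd)
  r <- suppressWarnings(stats::cor(values))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds > 0] <- 1
  rr <- pmin(pmax(r, -1), 1)
  tstat <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rr) >= 1] <- 0           # exact collinearity
  p[is.na(rr)] <- NA_real_
  diag(p) <- NA_real_
  list(r = r, p = p, n = n)
}

#' Per-condition protein correlation network
#'
#' Pairwise Pearson correlations among the 7 proteins over the samples of
#' one rearing condition, pooled across the three V1 regions. Two-sided
#' p-values come from the t-transform of R with n - 2 degrees of freedom;
#' the significance threshold is Bonferroni-corrected over the 21 unique
#' protein pairs of the matrix. Proteins are ordered by hierarchical
#' seriation so proteins with similar correlation profiles sit on nearby
#' dendrogram leaves.
#'
#' @param em an `expression_matrix` (see [assemble_matrix()]).
#' @param condition condition label; `NULL` uses all rows.
#' @param alpha base significance level before correction (default 0.05).
#' @return A `correlation_result`: `r`, `p_raw` (7x7), `n`,
#'   `alpha_adjusted` (= alpha / 21), `significant_mask`, `leaf_order`,
#'   `hclust`.
#' @export
condition_correlations <- function(em, condition = NULL, alpha = 0.05) {
  values <- em$values
  if (!is.null(condition)) {
    keep <- em$metadata$condition == condition
    if (!any(keep))
      pp_stop("pp_config_error", "condition '%s' not present", condition)
    values <- values[keep, , drop = FALSE]
  }
  if (nrow(values) < 3)
    pp_stop("pp_validation_error",
            "need >= 3 samples for correlation p-values (got %d)",
            nrow(values))
  cw <- pp_corr_with_p(values)
  m <- ncol(values)
  n_pairs <- m * (m - 1) / 2
  alpha_adjusted <- alpha / n_pairs
  mask <- !is.na(cw$p) & cw$p < alpha_adjusted
  diag(mask) <- FALSE
  ser <- seriate_proteins(cw$r)
  structure(list(condition = condition, r = cw$r, p_raw = cw$p, n = cw$n,
                 n_pairs = n_pairs, alpha_adjusted = alpha_adjusted,
                 significant_mask = mask, leaf_order = ser$order,
                 hclust = ser$hclust),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result", if (!is.null(x$condition)) paste0("(", x$condition, ")"),
      ":", x$n, "samples,", sum(x$significant_mask) / 2, "of", x$n_pairs,
      "pairs significant at adjusted alpha =",
      signif(x$alpha_adjusted, 4), "\n")
  invisible(x)
}

#' Seriate proteins by their correlation profiles
#'
#' Average-linkage hierarchical clustering on the distance d = 1 - r
#' between proteins, so proteins with similar patterns of correlations are
#' adjacent in the dendrogram. Deterministic for a fixed input; when every
#' off-diagonal distance is identical (no structure to exploit) the input
#' order is returned unchanged.
#'
#' @param r square correlation matrix (NAs treated as 0 distance-wise
#'   contribution, i.e. replaced by 0 correlation).
#' @return List with `order` (leaf order, names of `r`) and `hclust`.
#' @export
seriate_proteins <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  r0 <- r
  r0[is.na(r0)] <- 0
  d <- stats::as.dist(1 - r0)
  labels <- colnames(r)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(r)))
  if (max(d) - min(d) < 1e-12) {
    # degenerate: all pairs equally distant -> keep input order
    hc <- stats::hclust(d, method = "average")
    return(list(order = labels, hclust = hc, degenerate = TRUE))
  }
  hc <- stats::hclust(d, method = "average")
  list(order = labels[hc$order], hclust = hc, degenerate = FALSE)
}

#' Correlation networks for every condition in a matrix
#'
#' @param em an `expression_matrix`.
#' @param alpha base significance level (default 0.05).
#' @return Named list of [condition_correlations()] results.
#' @export
all_condition_correlations <- function(em, alpha = 0.05) {
  conds <- unique(em$metadata$condition)
  out <- lapply(conds, function(cc) condition_correlations(em, cc, alpha))
  stats::setNames(out, conds)
}
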