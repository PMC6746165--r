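#' Centered-SVD principal component analysis of the expression matrix
#'
#' Columns are centered (no scaling, matching the protein-space analysis:
#' all columns share the normalized-OD scale) and decomposed by SVD. The
#' sign indeterminacy of the decomposition is fixed by forcing the
#' largest-magnitude entry of each basis vector positive.
#'
#' @param em an `expression_matrix`, or a plain numeric matrix.
#' @return A `plast_pca`: `center` (column means), `basis_vectors` (7x7
#'   orthonormal loadings, columns `Dim1..Dim7`), `scores` (n x 7),
#'   `singular_values`, `variance_fraction` (sums to 1).
#' @export
run_pca <- function(em) {
  x <- if (inherits(em, "expression_matrix")) em$values else as.matrix(em)
  if (nrow(x) < 8)
    pp_stop("pp_validation_error", "PCA needs >= 8 complete rows (got %d)",
            nrow(x))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  # sign convention: largest |entry| of each loading vector is positive
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  v <- sweep(sv$v, 2, flip, `*`)
  u <- sweep(sv$u, 2, flip, `*`)
  d <- sv$d
  scores <- u %*% diag(d, nrow = length(d))
  dims <- paste0("Dim", seq_along(d))
  dimnames(v) <- list(colnames(x), dims)
  dimnames(scores) <- list(rownames(x), dims)
  structure(list(center = center, basis_vectors = v, scores = scores,
                 singular_values = d,
                 variance_fraction = d^2 / sum(d^2)),
            class = "plast_pca")
}

#' @export
print.plast_pca <- function(x, ...) {
  cat("plast_pca:", nrow(x$scores), "samples;",
      "variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction[1:3]),
            collapse = ", "), "(Dim1-3)\n")
  invisible(x)
}

#' Quality of representation (cos2) of each protein on each dimension
#'
#' The squared Pearson correlation between a protein's (centered) column
#' and each score dimension. Because the centered column lies in the span
#' of the orthogonal score vectors, each protein's cos2 values sum to 1
#' over all dimensions. Proteins with zero variance have undefined cos2
#' and are reported as NA.
#'
#' @param pca a `plast_pca`.
#' @param x the matrix the PCA was fit to (an `expression_matrix` or
#'   numeric matrix); needed to correlate columns with scores.
#' @return proteins x dimensions matrix of cos2 values in `[0, 1]`.
#' @export
cos2_by_protein <- function(pca, x) {
  xm <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  xc <- sweep(xm, 2, pca$center)
  out <- matrix(NA_real_, ncol(xm), ncol(pca$scores),
                dimnames = list(colnames(xm), colnames(pca$scores)))
  score_sd <- apply(pca$scores, 2, stats::sd)
  for (j in seq_len(ncol(xm))) {
    if (stats::sd(xc[, j]) == 0) next   # zero-variance protein: undefined
    r <- rep(0, ncol(pca$scores))
    ok <- score_sd > 1e-12
    r[ok] <- suppressWarnings(stats::cor(xc[, j], pca$scores[, ok]))
    out[j, ] <- r^2
  }
  out
}

#' Names of the nine plasticity features
#'
#' Three mean-scaled protein sums and six contrast indices of the form
#' (a - b) / (a + b). `ei_index` is the excitatory:inhibitory balance
#' (GlutR sum vs GABA_A_R sum).
#'
#' @return Character vector of length 9.
#' @export
feature_names <- function() {
  c("all_protein_sum", "glutr_sum", "gabar_sum", "ei_index",
    "gaba1_glun2a", "glun2b_glun2a", "gaba1_gaba3", "glun2b_glua2",
    "glun2a_glua2")
}

# which features are sums vs indices (for phenotype color bands)
feature_kind <- function() {
  stats::setNames(c("sum", "sum", "sum", rep("index", 6)), feature_names())
}

pp_index <- function(a, b) {
  denom <- a + b
  ifelse(denom == 0, NA_real_, (a - b) / denom)
}

#' Compute the nine plasticity features from one protein profile
#'
#' Formulas (per-protein normalized OD, nonnegative):
#' * `all_protein_sum` = (GluA2 + GluN1 + GluN2A + GluN2B + GABAAa1 +
#'   GABAAa3 + Synapsin) / 7
#' * `glutr_sum` = (GluA2 + GluN1 + GluN2A + GluN2B) / 4
#' * `gabar_sum` = (GABAAa1 + GABAAa3) / 2
#' * `ei_index` = (glutr_sum - gabar_sum) / (glutr_sum + gabar_sum)
#' * `gaba1_glun2a` = (GluN2A - GABAAa1) / (GluN2A + GABAAa1)
#' * `glun2b_glun2a` = (GluN2A - GluN2B) / (GluN2A + GluN2B)
#' * `gaba1_gaba3` = (GABAAa1 - GABAAa3) / (GABAAa1 + GABAAa3)
#' * `glun2b_glua2` = (GluN2B - GluA2) / (GluN2B + GluA2)
#' * `glun2a_glua2` = (GluN2A - GluA2) / (GluN2A + GluA2)
#'
#' The feature labels follow the field's "a:b balance" naming; the formula
#' orientation (which subunit is the positive pole) is as listed above and
#' is authoritative. Indices lie in `[-1, 1]` for nonnegative inputs and
#' are invariant to rescaling all proteins by a common factor; sums scale
#' with the factor. An index with a zero denominator is NA.
#'
#' @param od named numeric vector with all 7 proteins of
#'   [protein_panel()], each >= 0.
#' @return Named numeric vector of the 9 features.
#' @export
#' @examples
#' compute_features(setNames(rep(1, 7), protein_panel()))
compute_features <- function(od) {
  p <- protein_panel()
  if (!all(p %in% names(od)))
    pp_stop("pp_validation_error", "od must name all proteins: %s",
            paste(setdiff(p, names(od)), collapse = ", "))
  od <- od[p]
  if (any(od < 0, na.rm = TRUE))
    pp_stop("pp_validation_error", "protein ODs must be nonnegative")
  glutr <- (od["GluA2"] + od["GluN1"] + od["GluN2A"] + od["GluN2B"]) / 4
  gabar <- (od["GABAAa1"] + od["GABAAa3"]) / 2
  out <- c(
    all_protein_sum = unname(sum(od) / 7),
    glutr_sum = unname(glutr),
    gabar_sum = unname(gabar),
    ei_index = unname(pp_index(glutr, gabar)),
    gaba1_glun2a = unname(pp_index(od["GluN2A"], od["GABAAa1"])),
    glun2b_glun2a = unname(pp_index(od["GluN2A"], od["GluN2B"])),
    gaba1_gaba3 = unname(pp_index(od["GABAAa1"], od["GABAAa3"])),
    glun2b_glua2 = unname(pp_index(od["GluN2B"], od["GluA2"])),
    glun2a_glua2 = unname(pp_index(od["GluN2A"], od["GluA2"])))
  out
}

#' Per-sample plasticity feature table
#'
#' @param em an `expression_matrix`.
#' @return data.frame: the matrix metadata plus one column per feature.
#' @export
compute_feature_table <- function(em) {
  feats <- t(apply(em$values, 1, function(row)
    compute_features(stats::setNames(row, colnames(em$values)))))
  cbind(em$metadata, as.data.frame(feats))
}

#' Screen features against the leading PCA dimensions
#'
#' Correlates each of the 9 features with score dimensions 1-3 (27 tests,
#' Bonferroni-corrected). A feature is retained for clustering when it has
#' at least one significant correlation. The E:I index is always carried
#' into the phenotype display — the excitatory:inhibitory balance is
#' central to experience-dependent plasticity — but joins the clustering
#' input only if it passes the screen.
#'
#' @param feature_table data.frame from [compute_feature_table()],
#'   row-aligned with the PCA scores.
#' @param pca a `plast_pca` fit to the same rows.
#' @param alpha base level before Bonferroni (default 0.05).
#' @param n_dims leading dimensions to screen against (default 3).
#' @return List: `r` and `p` (features x dims), `alpha_adjusted`
#'   (= alpha / 27), `retained` (screen passers), `clustering_features`
#'   (retained, E:I removed if it failed), `phenotype_features` (all 9).
#' @export
screen_features <- function(feature_table, pca, alpha = 0.05, n_dims = 3) {
  fn <- feature_names()
  fmat <- as.matrix(feature_table[fn])
  scores <- pca$scores[, seq_len(n_dims), drop = FALSE]
  if (nrow(fmat) != nrow(scores))
    pp_stop("pp_validation_error",
            "feature table (%d rows) and scores (%d) are not aligned",
            nrow(fmat), nrow(scores))
  n <- nrow(fmat)
  r <- stats::cor(fmat, scores)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  n_tests <- length(fn) * n_dims
  alpha_adjusted <- alpha / n_tests
  sig <- !is.na(p) & p < alpha_adjusted
  retained <- fn[rowSums(sig) > 0]
  clustering <- retained
  list(r = r, p = p, n_tests = n_tests, alpha_adjusted = alpha_adjusted,
       significant = sig, retained = retained,
       clustering_features = clustering, phenotype_features = fn)
}
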