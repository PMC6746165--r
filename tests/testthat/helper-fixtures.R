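# shared fixtures, built in code at test time

# minimal two-condition design: reference + one treatment
tiny_design <- function(c_ref = 6, c_trt = 6, runs = 2) {
  study_design(data.frame(
    condition = c("5wk_normal", "TRT"), age_wks = c(5, 5.5),
    n_animals = c(1, 1), C = c(c_ref, c_trt), P = 0, M = 0),
    runs_per_piece = runs)
}

tiny_effects <- function(trt_shift = NULL, noise_sd = 0.1,
                         missing_rate = 0) {
  p <- protein_panel()
  base <- stats::setNames(rep(1, 7), p)
  trt <- base
  if (!is.null(trt_shift)) trt[names(trt_shift)] <- trt_shift
  r <- diag(7); r[r == 0] <- 0.3; diag(r) <- 1
  dimnames(r) <- list(p, p)
  list("5wk_normal" = effect_spec(base, r, noise_sd, missing_rate),
       "TRT" = effect_spec(trt, r, noise_sd, missing_rate))
}

# expression_matrix directly from a numeric matrix (bypasses the long format)
make_em <- function(values, condition = "5wk_normal", region = "C") {
  n <- nrow(values)
  colnames(values) <- protein_panel()
  rownames(values) <- sprintf("pc%03d", seq_len(n))
  meta <- data.frame(piece_id = rownames(values),
                     animal_id = "a1",
                     condition = rep_len(condition, n),
                     age_wks = 5,
                     region = rep_len(region, n))
  structure(list(values = values, metadata = meta,
                 proteins = protein_panel(), n_kept = n, n_dropped = 0L,
                 n_observations = n * 7L),
            class = "expression_matrix")
}

# long-format piece-level dataset from a wide matrix (for assemble_matrix)
make_piece_dataset <- function(values, condition = "5wk_normal") {
  n <- nrow(values)
  data.frame(
    animal_id = "a1", condition = condition, age_wks = 5, region = "C",
    piece_id = rep(sprintf("pc%03d", seq_len(n)), each = 7),
    protein = rep(protein_panel(), times = n),
    od = as.vector(t(values)))
}

# adjusted Rand index (independent of the implementation under test)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab))); sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(sum(tab))
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# full small end-to-end state on the default design (cached per session)
default_run_state <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    ds <- generate_dataset(default_design(), default_effects(), seed = seed)
    em <- assemble_matrix(average_runs(normalize_to_reference(ds)))
    pca <- run_pca(em)
    ft <- compute_feature_table(em)
    screen <- screen_features(ft, pca)
    cache <<- list(seed = seed, ds = ds, em = em, pca = pca, ft = ft,
                   screen = screen)
    cache
  }
})
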