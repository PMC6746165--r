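#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. The
#' master seed fans out to labeled substreams (data generation, tSNE,
#' k-means, bootstrap) so stages can be re-run independently yet
#' reproducibly.
#'
#' @param outdir output directory (created if needed).
#' @param seed master integer seed.
#' @param input_csv optional path to a user dataset in the long-format
#'   schema; `NULL` (default) simulates from `design` / `effects`.
#' @param design a [study_design()] (default [default_design()]).
#' @param effects named list of [effect_spec()]s (default
#'   [default_effects()]).
#' @param reference_condition normalization / comparison reference.
#' @param perplexity,tsne_iter tSNE parameters.
#' @param k_range,kmeans_restarts k selection / k-means parameters.
#' @param sim_size,resamples bootstrap sizes; `reduced = TRUE` switches to
#'   test-scale sizes (1e5 / 1e4).
#' @param reduced use reduced bootstrap sizes (default FALSE).
#' @param make_plots also write PNG figures (default TRUE; requires the
#'   suggested ggplot2 / pheatmap packages).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 20190903, input_csv = NULL,
                            design = default_design(),
                            effects = default_effects(),
                            reference_condition = "5wk_normal",
                            perplexity = 15, tsne_iter = 1000,
                            k_range = 2:9, kmeans_restarts = 50,
                            sim_size = 1e6, resamples = 1e5,
                            reduced = FALSE, make_plots = TRUE) {
  if (!is.null(input_csv) && !file.exists(input_csv))
    pp_stop("pp_config_error", "input_csv '%s' does not exist", input_csv)
  if (is.null(input_csv)) {
    if (!reference_condition %in% design$conditions$condition)
      pp_stop("pp_config_error",
              "reference condition '%s' is not in the design",
              reference_condition)
  }
  if (reduced) { sim_size <- 1e5; resamples <- 1e4 }
  set.seed(as.integer(seed))
  streams <- stats::setNames(
    as.list(sample.int(.Machine$integer.max - 1L, 4)),
    c("data", "tsne", "kmeans", "bootstrap"))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 streams = streams, input_csv = input_csv, design = design,
                 effects = effects,
                 reference_condition = reference_condition,
                 perplexity = perplexity, tsne_iter = tsne_iter,
                 k_range = k_range, kmeans_restarts = kmeans_restarts,
                 sim_size = sim_size, resamples = resamples,
                 reduced = reduced, make_plots = make_plots),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized keys mirror the arguments of [pipeline_config()] (scalar
#' fields only; design and effects stay at their defaults unless
#' `input_csv` points at user data).
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @param outdir,seed overrides taking precedence over the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL, seed = NULL) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        setdiff(names(formals(pipeline_config)),
                                c("design", "effects")))]
  if ("k_range" %in% names(args)) args$k_range <- do.call(seq, as.list(
    as.integer(args$k_range[c(1, length(args$k_range))])))
  if (!is.null(outdir)) args$outdir <- outdir
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(pipeline_config, args)
}

pp_path <- function(config, ...) file.path(config$outdir, ...)

pp_stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    pp_stop("pp_stage_error", "pipeline stage '%s' failed: %s", stage,
            conditionMessage(e))
  })
}

#' Run one pipeline stage
#'
#' Each stage reads only files written by prior stages into
#' `config$outdir` and writes its own outputs there, so a run can be
#' resumed stage by stage. Stages (in order): `simulate`, `preprocess`,
#' `networks`, `pca`, `features`, `cluster`, `phenotype`, `kinetics`.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return Invisibly, a character vector of files written.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "preprocess", "networks", "pca",
                              "features", "cluster", "phenotype",
                              "kinetics"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  pp_stage_guard(stage, switch(stage,
    simulate = pp_stage_simulate(config),
    preprocess = pp_stage_preprocess(config),
    networks = pp_stage_networks(config),
    pca = pp_stage_pca(config),
    features = pp_stage_features(config),
    cluster = pp_stage_cluster(config),
    phenotype = pp_stage_phenotype(config),
    kinetics = pp_stage_kinetics(config)))
}

pp_stage_simulate <- function(config) {
  path <- pp_path(config, "dataset.csv")
  if (is.null(config$input_csv)) {
    ds <- generate_dataset(config$design, config$effects,
                           seed = config$streams$data)
  } else {
    ds <- read_dataset(config$input_csv)
  }
  write_dataset(ds, path)
  invisible(path)
}

pp_stage_preprocess <- function(config) {
  ds <- read_dataset(pp_path(config, "dataset.csv"))
  ds <- normalize_to_reference(ds, config$reference_condition)
  ds <- average_runs(ds)
  em <- assemble_matrix(ds, drop_incomplete = TRUE)
  write_matrix(em, pp_path(config, "matrix.csv"))
  invisible(pp_path(config, "matrix.csv"))
}

pp_stage_networks <- function(config) {
  em <- read_matrix(pp_path(config, "matrix.csv"))
  dir.create(pp_path(config, "networks"), showWarnings = FALSE)
  nets <- all_condition_correlations(em)
  files <- character(0)
  for (cond in names(nets)) {
    cr <- nets[[cond]]
    safe <- gsub("[^A-Za-z0-9_-]", "_", cond)
    ord <- cr$leaf_order
    rf <- pp_path(config, "networks", paste0(safe, "_r.csv"))
    pf <- pp_path(config, "networks", paste0(safe, "_p.csv"))
    utils::write.csv(cr$r[ord, ord], rf)
    utils::write.csv(cr$p_raw[ord, ord], pf)
    files <- c(files, rf, pf)
    if (config$make_plots)
      files <- c(files, plot_correlation_heatmap(
        cr, pp_path(config, "networks", paste0(safe, "_heatmap.png"))))
  }
  invisible(files)
}

pp_stage_pca <- function(config) {
  em <- read_matrix(pp_path(config, "matrix.csv"))
  pca <- run_pca(em)
  utils::write.csv(data.frame(dim = colnames(pca$scores),
                              variance_fraction = pca$variance_fraction),
                   pp_path(config, "pca_variance.csv"), row.names = FALSE)
  utils::write.csv(pca$basis_vectors, pp_path(config, "pca_loadings.csv"))
  utils::write.csv(pca$scores, pp_path(config, "pca_scores.csv"))
  utils::write.csv(cos2_by_protein(pca, em), pp_path(config, "pca_cos2.csv"))
  invisible(pp_path(config, c("pca_variance.csv", "pca_loadings.csv",
                              "pca_scores.csv", "pca_cos2.csv")))
}

pp_stage_features <- function(config) {
  em <- read_matrix(pp_path(config, "matrix.csv"))
  pca <- run_pca(em)
  ft <- compute_feature_table(em)
  screen <- screen_features(ft, pca)
  utils::write.csv(ft, pp_path(config, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(alpha_adjusted = screen$alpha_adjusted, n_tests = screen$n_tests,
         retained = screen$retained,
         clustering_features = screen$clustering_features,
         r = as.data.frame(screen$r), p = as.data.frame(screen$p)),
    pp_path(config, "screening.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(pp_path(config, c("features.csv", "screening.json")))
}

pp_stage_cluster <- function(config) {
  ft <- utils::read.csv(pp_path(config, "features.csv"),
                        stringsAsFactors = FALSE)
  screen <- jsonlite::read_json(pp_path(config, "screening.json"),
                                simplifyVector = TRUE)
  feats <- unlist(screen$clustering_features)
  if (length(feats) < 2) feats <- feature_names()   # degenerate screen
  fmat <- as.matrix(ft[feats])
  emb <- embed_tsne(fmat, perplexity = config$perplexity,
                    seed = config$streams$tsne,
                    max_iter = config$tsne_iter)
  ck <- choose_k(emb, k_range = config$k_range,
                 seed = config$streams$kmeans,
                 restarts = config$kmeans_restarts)
  assign <- kmeans_assign(emb, ck$k, seed = config$streams$kmeans,
                          restarts = config$kmeans_restarts)
  subs <- annotate_subclusters(assign, ft, fmat)
  utils::write.csv(cbind(ft[c("piece_id", "condition", "region")],
                         as.data.frame(emb), cluster = assign),
                   pp_path(config, "assignments.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(k = ck$k, tau = ck$tau, method = ck$method,
         wss = as.list(ck$wss), perplexity = config$perplexity,
         tsne_seed = config$streams$tsne,
         kmeans_seed = config$streams$kmeans),
    pp_path(config, "wss_tau.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  sub_df <- do.call(rbind, lapply(subs, function(s) data.frame(
    label = s$label, condition = s$condition, cluster = s$cluster,
    regions = paste(s$regions, collapse = ""), n = s$n,
    frac = s$frac, t(s$mean_features))))
  utils::write.csv(sub_df, pp_path(config, "subclusters.csv"),
                   row.names = FALSE)
  files <- pp_path(config, c("assignments.csv", "wss_tau.json",
                             "subclusters.csv"))
  if (length(subs) >= 3) {
    sim <- subcluster_similarity(subs)
    ord <- sim$leaf_order
    utils::write.csv(sim$r[ord, ord],
                     pp_path(config, "subcluster_r.csv"))
    utils::write.csv(sim$p[ord, ord],
                     pp_path(config, "subcluster_p.csv"))
    files <- c(files, pp_path(config, c("subcluster_r.csv",
                                        "subcluster_p.csv")))
    if (config$make_plots)
      files <- c(files, plot_subcluster_heatmap(
        sim, pp_path(config, "subcluster_heatmap.png")))
  }
  if (config$make_plots)
    files <- c(files, plot_tsne_clusters(
      emb, assign, ft$condition, pp_path(config, "tsne_clusters.png")))
  invisible(files)
}

# rebuild subcluster profiles from the written assignment/feature files so
# the phenotype stage depends only on prior-stage outputs
pp_load_subclusters <- function(config) {
  ft <- utils::read.csv(pp_path(config, "features.csv"),
                        stringsAsFactors = FALSE)
  assign <- utils::read.csv(pp_path(config, "assignments.csv"),
                            stringsAsFactors = FALSE)
  screen <- jsonlite::read_json(pp_path(config, "screening.json"),
                                simplifyVector = TRUE)
  feats <- unlist(screen$clustering_features)
  if (length(feats) < 2) feats <- feature_names()
  list(ft = ft,
       subs = annotate_subclusters(assign$cluster, ft,
                                   as.matrix(ft[feats])))
}

pp_stage_phenotype <- function(config) {
  state <- pp_load_subclusters(config)
  ft <- state$ft; subs <- state$subs
  if (length(subs) == 0)
    pp_stop("pp_validation_error", "no subclusters qualified")
  fn <- feature_names()
  means <- lapply(subs, function(s)
    colMeans(as.matrix(ft[s$member_rows, fn])))
  sum_max <- max(vapply(means, function(m)
    max(m[feature_kind() == "sum"]), numeric(1)))
  bands <- do.call(rbind, Map(function(s, m)
    build_phenotype(m, sum_max = sum_max, label = s$label), subs, means))
  utils::write.csv(bands, pp_path(config, "phenotypes.csv"),
                   row.names = FALSE)
  cfg <- bootstrap_config(sim_size = config$sim_size,
                          resamples = config$resamples,
                          seed = config$streams$bootstrap)
  grid <- compare_all(ft, subs,
                      reference_condition = config$reference_condition,
                      config = cfg)
  utils::write.csv(grid, pp_path(config, "significance.csv"),
                   row.names = FALSE)
  files <- pp_path(config, c("phenotypes.csv", "significance.csv"))
  if (config$make_plots)
    files <- c(files, plot_phenotype_bands(
      bands, pp_path(config, "phenotypes.png")))
  invisible(files)
}

pp_stage_kinetics <- function(config) {
  em <- read_matrix(pp_path(config, "matrix.csv"))
  kt <- kinetics_trajectory_table(em)
  utils::write.csv(kt, pp_path(config, "kinetics.csv"), row.names = FALSE)
  invisible(pp_path(config, "kinetics.csv"))
}

#' Run the full plasticity-phenotyping pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> networks -> pca ->
#' features -> cluster -> phenotype -> kinetics, writing every stage's
#' tables (and figures when `make_plots`) under `config$outdir`, plus a
#' run manifest recording the package version, seeds and parameters.
#' Re-running with the same config and seed into a clean directory
#' reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- c("simulate", "preprocess", "networks", "pca", "features",
              "cluster", "phenotype", "kinetics")
  written <- list()
  for (st in stages) written[[st]] <- as.character(run_stage(st, config))
  manifest <- list(
    package = "plastphen",
    version = as.character(utils::packageVersion("plastphen")),
    seed = config$seed, streams = config$streams,
    reference_condition = config$reference_condition,
    perplexity = config$perplexity, k_range = range(config$k_range),
    kmeans_restarts = config$kmeans_restarts,
    bootstrap = list(sim_size = config$sim_size,
                     resamples = config$resamples,
                     reduced = config$reduced),
    files = lapply(written, basename))
  jsonlite::write_json(manifest, pp_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
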