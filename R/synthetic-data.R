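#' Study design for synthetic Western-blot datasets
#'
#' Describes how many cortical tissue pieces are sampled per rearing
#' condition and V1 region, how often each piece is run on a gel, and which
#' proteins are probed. The bundled default ([default_design()]) reproduces
#' the study layout: six rearing conditions (5 wk normal, monocular
#' deprivation, reverse occlusion, binocular deprivation, short- and
#' long-term binocular vision), three V1 regions (central `C`, peripheral
#' `P`, monocular `M`), and duplicate runs per piece.
#'
#' @param conditions data.frame with columns `condition` (label), `age_wks`
#'   (positive), `n_animals` (positive integer) and one column per region
#'   giving the number of pieces.
#' @param regions character subset of `c("C", "P", "M")`.
#' @param runs_per_piece positive integer; gels run per tissue piece.
#' @param proteins ordered character vector of exactly 7 unique names.
#' @return An object of class `study_design`.
#' @export
study_design <- function(conditions, regions = c("C", "P", "M"),
                         runs_per_piece = 2L, proteins = protein_panel()) {
  stopifnot(is.data.frame(conditions), "condition" %in% names(conditions),
            "age_wks" %in% names(conditions))
  if (length(proteins) != 7L || anyDuplicated(proteins))
    pp_stop("pp_config_error", "`proteins` must be 7 unique names")
  if (!all(regions %in% c("C", "P", "M")))
    pp_stop("pp_config_error", "regions must be a subset of C, P, M")
  if (runs_per_piece < 1L)
    pp_stop("pp_config_error", "runs_per_piece must be >= 1")
  if (any(conditions$age_wks <= 0))
    pp_stop("pp_config_error", "ages must be positive")
  counts <- as.matrix(conditions[, regions, drop = FALSE])
  if (any(counts < 0) || any(counts != floor(counts)))
    pp_stop("pp_config_error", "piece counts must be nonnegative integers")
  if (any(rowSums(counts) < 1))
    pp_stop("pp_config_error",
            "every condition needs >= 1 piece in >= 1 region")
  structure(list(conditions = conditions, regions = regions,
                 runs_per_piece = as.integer(runs_per_piece),
                 proteins = proteins),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$conditions), "conditions,",
      sum(as.matrix(x$conditions[, x$regions])), "pieces,",
      x$runs_per_piece, "runs/piece\n")
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Bundled Western-blot run counts for the emulated study design
#'
#' Measurement counts (gel runs after duplicate replication) per rearing
#' condition, V1 region and protein, together with animal and tissue-piece
#' counts. Shipped as a plain-text fixture; this is the layout the default
#' synthetic design is patterned on.
#'
#' @return data.frame with columns `condition`, `n_animals`, `region`,
#'   `pieces`, and one count column per protein.
#' @export
wb_run_counts <- function() {
  path <- system.file("extdata", "wb_run_counts.tsv", package = "plastphen",
                      mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Default study design patterned on the emulated experiment
#'
#' 5 wk normal (12 pieces), MD (15), RO (12), BD (14), ST-BV (24) and
#' LT-BV (36) across the C/P/M regions of V1 — 113 pieces, duplicate runs.
#' Ages are the nominal ages at tissue collection (MD and treatments start
#' from 5 wk; RO lasts 18 d, BD 4 d, ST-BV 1-6 h, LT-BV 1-4 d).
#'
#' @return A [study_design()] object.
#' @export
default_design <- function() {
  counts <- wb_run_counts()
  pieces <- stats::reshape(
    counts[, c("condition", "n_animals", "region", "pieces")],
    idvar = c("condition", "n_animals"), timevar = "region",
    direction = "wide")
  names(pieces) <- sub("^pieces\\.", "", names(pieces))
  ages <- c("5wk_normal" = 5, "MD" = 5, "RO" = 7.5, "BD" = 5.5,
            "ST-BV" = 5, "LT-BV" = 5.5)
  pieces$age_wks <- ages[pieces$condition]
  study_design(pieces[, c("condition", "age_wks", "n_animals",
                          "C", "P", "M")])
}

#' Per-condition effect specification for the generator
#'
#' @param mean_vector named positive numeric of length 7 (per-protein
#'   expected normalized OD; the reference condition is 1 for all).
#' @param correlation 7x7 symmetric positive-semidefinite matrix with unit
#'   diagonal.
#' @param noise_sd per-protein standard deviation (length 1 or 7, >= 0).
#' @param missing_rate probability in `[0, 1]` that a piece's protein cell
#'   is absent (both runs).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(mean_vector, correlation, noise_sd = 0.1,
                        missing_rate = 0) {
  p <- length(mean_vector)
  if (p != 7L) pp_stop("pp_validation_error", "mean_vector must be length 7")
  if (any(mean_vector <= 0))
    pp_stop("pp_validation_error", "mean_vector must be positive")
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10)))
    pp_stop("pp_validation_error", "correlation matrix is not symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    pp_stop("pp_validation_error", "correlation diagonal must be 1")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    pp_stop("pp_validation_error",
            "correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
            min(ev))
  noise_sd <- rep_len(noise_sd, p)
  if (any(noise_sd < 0))
    pp_stop("pp_validation_error", "noise_sd must be >= 0")
  if (missing_rate < 0 || missing_rate > 1)
    pp_stop("pp_validation_error", "missing_rate must be in [0, 1]")
  structure(list(mean_vector = mean_vector, correlation = correlation,
                 noise_sd = noise_sd, missing_rate = missing_rate),
            class = "effect_spec")
}

# block-structured correlation builder; glut = GluA2/GluN1/GluN2A/GluN2B,
# gaba = a1/a3, syn alone
pp_block_correlation <- function(within_glut, within_gaba, cross,
                                 syn_glut, syn_gaba, glun2a_weak = NA) {
  proteins <- protein_panel()
  glut <- 1:4; gaba <- 5:6; syn <- 7
  r <- diag(7)
  r[glut, glut] <- within_glut
  r[gaba, gaba] <- within_gaba
  r[glut, gaba] <- cross; r[gaba, glut] <- cross
  r[glut, syn] <- syn_glut; r[syn, glut] <- syn_glut
  r[gaba, syn] <- syn_gaba; r[syn, gaba] <- syn_gaba
  if (!is.na(glun2a_weak)) { # decouple GluN2A from the rest
    i <- match("GluN2A", proteins)
    r[i, -i] <- glun2a_weak; r[-i, i] <- glun2a_weak
  }
  diag(r) <- 1
  dimnames(r) <- list(proteins, proteins)
  # guard: shrink toward identity until PSD (keeps construction honest)
  while (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < 1e-8)
    r <- 0.95 * r + 0.05 * diag(7)
  r
}

#' Default planted condition effects
#'
#' Mean vectors and correlation structures that mirror the study's
#' qualitative findings: the 5 wk normal reference sits at 1 for every
#' protein; MD delays the GluN2B-to-GluN2A shift and prematurely raises
#' GABA_A alpha1 while decoupling glutamatergic from GABAergic proteins;
#' RO is dominated by an overabundance of GluA2 with more GluN2A than 2B
#' and a general loss of expression; BD raises GABA_A alpha1 throughout
#' with less GluN2A; ST-BV is an intermediate transient; LT-BV is
#' near-normal but with GABA_A_R expression lowered. Each condition pair is
#' separated by at least three noise SD (0.3 at the default
#' `noise_sd = 0.1`) in at least one protein so planted effects are
#' recoverable by the clustering stages.
#'
#' @param noise_sd per-protein SD shared by all conditions (default 0.1).
#' @param missing_rate probability of an absent piece-level protein cell
#'   (default 0.005, a handful of dropped samples per full design).
#' @return Named list of [effect_spec()], one per default condition.
#' @export
default_effects <- function(noise_sd = 0.1, missing_rate = 0.005) {
  p <- protein_panel()
  mv <- function(...) stats::setNames(c(...), p)
  #             GluA2 GluN1 GluN2A GluN2B  a1    a3   Syn
  means <- list(
    "5wk_normal" = mv(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    "MD"         = mv(1.00, 0.85, 0.60, 1.30, 1.35, 1.00, 0.90),
    "RO"         = mv(1.60, 0.70, 1.50, 0.75, 1.00, 0.80, 0.70),
    "BD"         = mv(0.90, 1.00, 0.70, 1.00, 1.50, 1.00, 0.80),
    "ST-BV"      = mv(1.15, 1.00, 0.70, 1.15, 1.30, 1.00, 1.20),
    "LT-BV"      = mv(1.00, 1.00, 1.00, 1.15, 0.60, 0.60, 1.00))
  cors <- list(
    "5wk_normal" = pp_block_correlation(0.6, 0.6, 0.6, 0.6, 0.6,
                                        glun2a_weak = 0.15),
    "MD"         = pp_block_correlation(0.5, 0.5, -0.2, -0.15, 0.4),
    "RO"         = pp_block_correlation(0.35, 0.35, 0.1, 0.1, 0.3),
    "BD"         = pp_block_correlation(0.5, 0.5, 0.5, -0.25, -0.25),
    "ST-BV"      = pp_block_correlation(0.4, 0.4, 0.25, 0.3, 0.3),
    "LT-BV"      = pp_block_correlation(0.45, 0.45, 0.35, 0.4, 0.4))
  out <- lapply(names(means), function(cond) {
    effect_spec(means[[cond]], cors[[cond]], noise_sd = noise_sd,
                missing_rate = missing_rate)
  })
  stats::setNames(out, names(means))
}

#' Generate a synthetic Western-blot expression dataset
#'
#' Draws one record per (piece, run): the 7 normalized optical densities of
#' a run are a draw from the condition's multivariate Gaussian
#' (`mean_vector`, `diag(noise_sd) %*% correlation %*% diag(noise_sd)`)
#' truncated at 0 (an OD cannot be negative). Missing cells are planted at
#' the piece level — when a piece's protein cell is absent it is absent in
#' every run, mirroring how a sample drops out of the assembled matrix. A
#' single master seed fans out to deterministic per-condition substreams so
#' the same (design, effects, seed) always yields a bit-identical dataset.
#'
#' @param design a [study_design()].
#' @param effects named list of [effect_spec()], one per design condition.
#' @param seed integer master seed.
#' @return Long-format data.frame with columns `animal_id`, `condition`,
#'   `age_wks`, `region`, `piece_id`, `run`, `protein`, `od`.
#' @export
#' @examples
#' ds <- generate_dataset(default_design(), default_effects(), seed = 1)
#' length(unique(ds$piece_id))  # 113 pieces
generate_dataset <- function(design, effects, seed) {
  stopifnot(inherits(design, "study_design"))
  conds <- design$conditions$condition
  if (!setequal(conds, names(effects)))
    pp_stop("pp_config_error",
            "conditions in design and effects differ: design has {%s}, effects has {%s}",
            paste(conds, collapse = ", "),
            paste(names(effects), collapse = ", "))
  for (cond in conds)
    if (!inherits(effects[[cond]], "effect_spec"))
      pp_stop("pp_validation_error", "effects[[%s]] is not an effect_spec", cond)

  set.seed(as.integer(seed))
  cond_seeds <- sample.int(.Machine$integer.max - 1L, length(conds))
  proteins <- design$proteins
  rows <- vector("list", length(conds))

  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    spec <- effects[[cond]]
    info <- design$conditions[ci, ]
    set.seed(cond_seeds[ci])
    sigma <- diag(spec$noise_sd) %*% spec$correlation %*% diag(spec$noise_sd)
    n_animals <- if ("n_animals" %in% names(info)) info$n_animals else 1L
    crows <- list()
    piece_counter <- 0L
    runs <- design$runs_per_piece
    for (region in design$regions) {
      n_pieces <- info[[region]]
      if (is.null(n_pieces) || n_pieces == 0) next
      n_rec <- n_pieces * runs
      od <- if (all(spec$noise_sd == 0)) {
        matrix(spec$mean_vector, n_rec, 7, byrow = TRUE)
      } else {
        pmax(MASS::mvrnorm(n_rec, mu = spec$mean_vector, Sigma = sigma), 0)
      }
      if (!is.matrix(od)) od <- matrix(od, nrow = 1)  # n_rec == 1
      # piece-level missing cells: absent in every run of the piece
      missing <- matrix(stats::runif(n_pieces * 7) < spec$missing_rate,
                        n_pieces, 7)
      od[missing[rep(seq_len(n_pieces), each = runs), , drop = FALSE]] <-
        NA_real_
      piece_idx <- piece_counter + seq_len(n_pieces)
      piece_counter <- piece_counter + n_pieces
      piece_ids <- sprintf("%s_%s%02d", cond, region, seq_len(n_pieces))
      animal_ids <- sprintf("%s_a%d", cond,
                            ((piece_idx - 1L) %% n_animals) + 1L)
      rec_piece <- rep(seq_len(n_pieces), each = runs)
      crows[[length(crows) + 1L]] <- data.frame(
        animal_id = rep(animal_ids[rec_piece], each = 7),
        condition = cond, age_wks = info$age_wks, region = region,
        piece_id = rep(piece_ids[rec_piece], each = 7),
        run = rep(rep(seq_len(runs), times = n_pieces), each = 7),
        protein = rep(proteins, times = n_rec),
        od = as.vector(t(od)), stringsAsFactors = FALSE)
    }
    rows[[ci]] <- do.call(rbind, crows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a long-format expression dataset as CSV
#'
#' @param dataset long-format data.frame as from [generate_dataset()].
#' @param path file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   data.frame.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path))
    pp_stop("pp_config_error", "dataset file '%s' does not exist", path)
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "condition", "age_wks", "region", "piece_id",
            "run", "protein", "od")
  if (!all(need %in% names(ds)))
    pp_stop("pp_config_error", "dataset CSV must have columns: %s",
            paste(need, collapse = ", "))
  ds
}
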