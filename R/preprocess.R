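#' Normalize a band density to the per-gel control sample
#'
#' Every gel carries a control sample (a pool of all samples); expression
#' is the ratio of the sample's band density to the control band density
#' on the same gel.
#'
#' @param band_density nonnegative number(s).
#' @param control_density positive number(s).
#' @return `band_density / control_density`.
#' @export
normalize_to_gel_control <- function(band_density, control_density) {
  if (any(control_density <= 0))
    pp_stop("pp_degenerate_gel_error",
            "control band density must be positive (got %s)",
            paste(utils::head(control_density[control_density <= 0], 3),
                  collapse = ", "))
  if (any(band_density < 0, na.rm = TRUE))
    pp_stop("pp_validation_error", "band density must be nonnegative")
  band_density / control_density
}

#' Normalize expression to the mean of a reference condition
#'
#' Divides each protein's values by that protein's mean over the reference
#' condition, so the reference mean is exactly 1 per protein. Reference
#' means are computed at the piece level (after run averaging) and pooled
#' across regions. Applying the function twice is a no-op, and rescaling
#' all raw densities by a common factor leaves the result unchanged.
#'
#' @param dataset long-format dataset (see [generate_dataset()]).
#' @param reference_condition condition label (default `"5wk_normal"`).
#' @return The dataset with `od` rescaled.
#' @export
normalize_to_reference <- function(dataset, reference_condition = "5wk_normal") {
  if (!reference_condition %in% dataset$condition)
    pp_stop("pp_config_error", "reference condition '%s' not in dataset",
            reference_condition)
  ref <- average_runs(dataset[dataset$condition == reference_condition, ])
  ref_means <- tapply(ref$od, ref$protein, mean, na.rm = TRUE)
  if (any(!is.finite(ref_means)))
    pp_stop("pp_config_error",
            "reference condition has no non-missing value for some protein")
  dataset$od <- dataset$od / unname(ref_means[dataset$protein])
  dataset
}

#' Average replicate runs to piece-level expression
#'
#' One row per (piece, protein): the arithmetic mean of the non-missing
#' runs. A cell is absent only when every run is absent.
#'
#' @param dataset long-format dataset.
#' @return Long-format data.frame with `run` dropped.
#' @export
average_runs <- function(dataset) {
  key <- c("animal_id", "condition", "age_wks", "region", "piece_id",
           "protein")
  agg <- stats::aggregate(dataset["od"], by = dataset[key],
                          FUN = function(v) {
                            v <- v[!is.na(v)]
                            if (length(v) == 0) NA_real_ else mean(v)
                          })
  # stable order: piece appearance order, protein panel order
  agg$piece_id <- factor(agg$piece_id, levels = unique(dataset$piece_id))
  agg$protein <- factor(agg$protein, levels = unique(dataset$protein))
  agg <- agg[order(agg$piece_id, agg$protein), ]
  agg$piece_id <- as.character(agg$piece_id)
  agg$protein <- as.character(agg$protein)
  rownames(agg) <- NULL
  agg
}

#' Assemble the samples-by-proteins analysis matrix
#'
#' Pivots a piece-level dataset to a complete n x 7 matrix. With
#' `drop_incomplete = TRUE` (the study's rule) every row with at least one
#' absent cell is removed and the kept/dropped counts are recorded.
#'
#' @param dataset piece-level long-format dataset (see [average_runs()]).
#' @param drop_incomplete drop rows with any missing cell (default TRUE).
#' @param proteins column order (default [protein_panel()]).
#' @return An `expression_matrix`: list with `values` (numeric matrix),
#'   `metadata` (data.frame: `piece_id`, `animal_id`, `condition`,
#'   `age_wks`, `region`), `proteins`, and counts `n_kept` / `n_dropped`.
#'   `n_observations` = rows x proteins.
#' @export
assemble_matrix <- function(dataset, drop_incomplete = TRUE,
                            proteins = protein_panel()) {
  if ("run" %in% names(dataset))
    pp_stop("pp_config_error",
            "dataset still has runs; call average_runs() first")
  pieces <- unique(dataset$piece_id)
  meta_cols <- c("piece_id", "animal_id", "condition", "age_wks", "region")
  meta <- unique(dataset[meta_cols])
  meta <- meta[match(pieces, meta$piece_id), ]
  values <- matrix(NA_real_, nrow = length(pieces), ncol = length(proteins),
                   dimnames = list(pieces, proteins))
  idx <- cbind(match(dataset$piece_id, pieces),
               match(dataset$protein, proteins))
  keep <- !is.na(idx[, 2])
  values[idx[keep, , drop = FALSE]] <- dataset$od[keep]
  complete <- stats::complete.cases(values)
  n_dropped <- 0L
  if (drop_incomplete) {
    n_dropped <- sum(!complete)
    values <- values[complete, , drop = FALSE]
    meta <- meta[complete, , drop = FALSE]
  }
  if (nrow(values) == 0)
    pp_stop("pp_empty_matrix_error", "no complete rows after filtering")
  rownames(meta) <- NULL
  structure(list(values = values, metadata = meta, proteins = proteins,
                 n_kept = nrow(values), n_dropped = n_dropped,
                 n_observations = nrow(values) * length(proteins)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", x$n_kept, "samples x", length(x$proteins),
      "proteins (", x$n_observations, "observations;", x$n_dropped,
      "incomplete rows dropped )\n")
  cat("conditions:", paste(unique(x$metadata$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write an assembled matrix as CSV plus a JSON metadata sidecar
#'
#' @param em an `expression_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(em, path) {
  df <- cbind(em$metadata, as.data.frame(em$values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(proteins = em$proteins, n_kept = em$n_kept,
         n_dropped = em$n_dropped, n_observations = em$n_observations),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    pp_stop("pp_config_error", "matrix file '%s' does not exist", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  proteins <- intersect(protein_panel(), names(df))
  meta <- df[setdiff(names(df), proteins)]
  values <- as.matrix(df[proteins])
  rownames(values) <- meta$piece_id
  structure(list(values = values, metadata = meta, proteins = proteins,
                 n_kept = nrow(values), n_dropped = NA_integer_,
                 n_observations = nrow(values) * length(proteins)),
            class = "expression_matrix")
}
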