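#' tSNE embedding of the plasticity-feature matrix
#'
#' Features are z-scored per column before embedding (sums sit near 1
#' while indices live in `[-1, 1]`; without standardization the sums would
#' dominate Euclidean distances). The embedding is exact (theta = 0) and
#' deterministic for a fixed seed.
#'
#' @param x numeric matrix (samples x features).
#' @param perplexity tSNE perplexity (default 15, suited to n near 100).
#' @param seed integer seed (default 20190903).
#' @param max_iter gradient iterations (default 1000).
#' @param standardize z-score columns first (default TRUE).
#' @return n x 2 coordinate matrix with attributes `perplexity`, `seed`.
#' @export
embed_tsne <- function(x, perplexity = 15, seed = 20190903,
                       max_iter = 1000, standardize = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= 3 * perplexity)
    pp_stop("pp_validation_error",
            "perplexity %.1f too large for n = %d (need n > 3 * perplexity = %.1f)",
            perplexity, n, 3 * perplexity)
  if (standardize) x <- pp_zscore(x)
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                      max_iter = max_iter, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  y <- fit$Y
  dimnames(y) <- list(rownames(x), c("tsne1", "tsne2"))
  attr(y, "perplexity") <- perplexity
  attr(y, "seed") <- seed
  y
}

# z-score columns; zero-variance columns are centered only
pp_zscore <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0] <- 1
  scale(x, center = mu, scale = sd)[, , drop = FALSE]
}

#' Choose k with the exponential-tau elbow rule
#'
#' Runs best-of-restarts k-means for each k in `k_range`, fits a
#' single-exponential decay WSS(k) = A exp(-k / tau) + C to the
#' within-cluster sums of squares, and takes the elbow at k* =
#' round-half-up(4 tau), clamped into `k_range`. If the fit fails (e.g.
#' the WSS profile is not decreasing) the largest second-difference elbow
#' is used instead, with a warning.
#'
#' @param x numeric matrix to cluster (typically the 2-D tSNE embedding).
#' @param k_range candidate k values (default 2:9).
#' @param seed integer seed.
#' @param restarts k-means restarts per k (default 50).
#' @return List: `k` (chosen), `tau`, `wss` (named by k), `fit`
#'   (coefficients or NULL), `method` ("exponential_tau" or
#'   "largest_drop").
#' @export
choose_k <- function(x, k_range = 2:9, seed = 20190903, restarts = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (max(k_range) > n - 1)
    pp_stop("pp_validation_error", "k_range must lie within 2..(n-1)")
  set.seed(as.integer(seed))
  wss <- vapply(k_range, function(k)
    stats::kmeans(x, centers = k, nstart = restarts,
                  iter.max = 100)$tot.withinss, numeric(1))
  names(wss) <- k_range
  out <- fit_wss_elbow(wss, k_range)
  out$wss <- wss
  out
}

#' Fit the exponential-tau elbow to a WSS profile
#'
#' Least-squares fit of WSS(k) = A exp(-k / tau) + C; the elbow is
#' k* = round-half-up(4 tau), clamped into `k_range`.
#'
#' @param wss within-cluster sums of squares, one per k.
#' @param k_range the k values matching `wss`.
#' @return List: `k`, `tau`, `fit` (coefficients or NULL), `method`.
#' @export
fit_wss_elbow <- function(wss, k_range = as.integer(names(wss))) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      wss ~ A * exp(-k / tau) + C,
      data = data.frame(k = k_range, wss = wss),
      start = list(A = max(wss) - min(wss) + 1e-9, tau = 1.5,
                   C = min(wss)),
      lower = c(A = 0, tau = 1e-6, C = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && stats::coef(fit)[["A"]] > 0) {
    tau <- stats::coef(fit)[["tau"]]
    k_star <- round_half_up(4 * tau)
    k_star <- min(max(k_star, min(k_range)), max(k_range))
    return(list(k = as.integer(k_star), tau = tau,
                fit = stats::coef(fit), method = "exponential_tau"))
  }
  warning("exponential elbow fit failed; falling back to largest-drop heuristic")
  if (length(k_range) >= 3) {
    d2 <- diff(diff(wss))                 # second differences
    k_star <- k_range[which.max(d2) + 1L]
  } else k_star <- k_range[which.max(-diff(wss)) + 1L]
  list(k = as.integer(k_star), tau = NA_real_, fit = NULL,
       method = "largest_drop")
}

#' k-means assignment with canonical labels
#'
#' Best (lowest within-cluster sum of squares) of `restarts` k-means++-style
#' random restarts; cluster labels are canonicalized so cluster 1 is the
#' largest (ties broken by first appearance).
#'
#' @param x numeric matrix (typically the tSNE coordinates).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts random restarts (default 50).
#' @return Integer vector of assignments in 1..k with attribute `wss`.
#' @export
kmeans_assign <- function(x, k, seed = 20190903, restarts = 50) {
  x <- as.matrix(x)
  if (k > nrow(x))
    pp_stop("pp_validation_error", "k = %d exceeds n = %d", k, nrow(x))
  if (k == nrow(x)) {            # every point its own cluster, WSS = 0
    out <- seq_len(k)
    attr(out, "wss") <- 0
    return(out)
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  sizes <- table(km$cluster)
  relabel <- order(-as.integer(sizes), as.integer(names(sizes)))
  map <- integer(k)
  map[as.integer(names(sizes))[relabel]] <- seq_len(k)
  out <- map[km$cluster]
  attr(out, "wss") <- km$tot.withinss
  out
}

#' Annotate condition subclusters within k-means clusters
#'
#' Groups samples by (rearing condition x cluster). A group qualifies as a
#' subcluster when it has at least `min_n` members and makes up strictly
#' more than `min_frac` of its cluster. Labels are
#' `"<condition> <cluster>"`, with a region subscript (e.g. `"MD 3_PM"`)
#' when the members come from a strict subset of the three V1 regions.
#'
#' @param assignments integer cluster labels (from [kmeans_assign()]).
#' @param metadata data.frame aligned with `assignments`; needs
#'   `condition` and `region` columns.
#' @param feature_matrix numeric matrix aligned with `assignments`
#'   (clustering features; used for the subcluster mean vectors).
#' @param min_n minimum members (default 2).
#' @param min_frac minimum fraction of the cluster, strict (default 0.20).
#' @return List of `subcluster_profile`s: `label`, `condition`, `cluster`,
#'   `regions`, `member_rows`, `n`, `frac`, `mean_features`.
#' @export
annotate_subclusters <- function(assignments, metadata, feature_matrix,
                                 min_n = 2, min_frac = 0.20) {
  stopifnot(length(assignments) == nrow(metadata))
  feature_matrix <- as.matrix(feature_matrix)
  cluster_sizes <- table(assignments)
  out <- list()
  for (cl in sort(unique(assignments))) {
    csize <- cluster_sizes[[as.character(cl)]]
    in_cl <- which(assignments == cl)
    for (cond in unique(metadata$condition[in_cl])) {
      rows <- in_cl[metadata$condition[in_cl] == cond]
      n <- length(rows)
      frac <- n / csize
      if (n < min_n || frac <= min_frac) next
      regions <- intersect(c("C", "P", "M"), unique(metadata$region[rows]))
      label <- sprintf("%s %d", cond, cl)
      if (length(regions) < 3)
        label <- paste0(label, "_", paste(regions, collapse = ""))
      out[[length(out) + 1L]] <- structure(
        list(label = label, condition = cond, cluster = cl,
             regions = regions, member_rows = rows, n = n, frac = frac,
             mean_features = colMeans(feature_matrix[rows, , drop = FALSE])),
        class = "subcluster_profile")
    }
  }
  out
}

#' Subcluster similarity matrix and dendrogram order
#'
#' Pearson correlations between the subcluster mean-feature vectors
#' (correlating across the clustering features, so with f features the
#' p-values use f - 2 degrees of freedom). The Bonferroni threshold is
#' alpha / C(m, 2) for m subclusters. Subclusters are ordered by
#' average-linkage hierarchical clustering on 1 - R for display.
#'
#' @param subclusters list of `subcluster_profile`s.
#' @param alpha base level (default 0.05).
#' @return List: `r`, `p` (m x m), `alpha_adjusted`, `n_pairs`,
#'   `significant_mask`, `leaf_order`, `hclust`.
#' @export
subcluster_similarity <- function(subclusters, alpha = 0.05) {
  m <- length(subclusters)
  if (m < 3)
    pp_stop("pp_validation_error", "need >= 3 subclusters (got %d)", m)
  mat <- t(vapply(subclusters, function(s) s$mean_features,
                  subclusters[[1]]$mean_features))
  rownames(mat) <- vapply(subclusters, `[[`, "", "label")
  cw <- pp_corr_with_p(t(mat))          # correlate subclusters across features
  n_pairs <- m * (m - 1) / 2
  alpha_adjusted <- alpha / n_pairs
  mask <- !is.na(cw$p) & cw$p < alpha_adjusted
  diag(mask) <- FALSE
  ser <- seriate_proteins(cw$r)
  list(r = cw$r, p = cw$p, n_features = ncol(mat), n_pairs = n_pairs,
       alpha_adjusted = alpha_adjusted, significant_mask = mask,
       leaf_order = ser$order, hclust = ser$hclust)
}
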