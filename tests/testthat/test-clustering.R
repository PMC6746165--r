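# tSNE embedding, k selection, k-means, subcluster annotation

# two well-separated Gaussian blobs in 8-D feature space
make_blobs <- function(n_per = 30, n_blobs = 2, sep = 10, sd = 1,
                       seed = 31) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    center <- rep(0, 8); center[b] <- sep * sd * b
    sweep(matrix(rnorm(n_per * 8, sd = sd), n_per, 8), 2, center, `+`)
  }))
  list(x = x, labels = rep(seq_len(n_blobs), each = n_per))
}

test_that("tSNE embedding is seed-deterministic and near the origin", {
  blobs <- make_blobs()
  e1 <- embed_tsne(blobs$x, perplexity = 10, seed = 7)
  e2 <- embed_tsne(blobs$x, perplexity = 10, seed = 7)
  expect_identical(e1[, ], e2[, ])
  expect_lt(max(abs(colMeans(e1))), 5)
  expect_error(embed_tsne(blobs$x[1:20, ], perplexity = 10),
               class = "pp_validation_error")
})

test_that("planted blobs separate cleanly in the embedding", {
  blobs <- make_blobs(sep = 10)
  emb <- embed_tsne(blobs$x, perplexity = 10, seed = 7)
  sil <- cluster::silhouette(blobs$labels, stats::dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("the exponential-tau elbow recovers an exact synthetic profile", {
  k <- 2:9
  wss <- 100 * exp(-k / 1.5) + 10
  fit <- fit_wss_elbow(wss, k)
  expect_equal(fit$tau, 1.5, tolerance = 1e-6)
  expect_equal(fit$k, 6L)                     # round-half-up(4 * 1.5)
  expect_identical(fit$method, "exponential_tau")
})

test_that("choose_k agrees with the max-curvature oracle on planted blobs", {
  blobs <- make_blobs(n_per = 25, n_blobs = 3, sep = 12, seed = 33)
  ck <- choose_k(blobs$x, k_range = 2:9, seed = 5, restarts = 20)
  expect_true(ck$k >= min(2:9) && ck$k <= max(2:9))
  # independent oracle: elbow at the largest second difference of WSS
  oracle_k <- as.integer(names(ck$wss)[which.max(diff(diff(ck$wss))) + 1L])
  expect_lte(abs(ck$k - oracle_k), 1L)
  expect_error(choose_k(blobs$x[1:5, ], k_range = 2:9),
               class = "pp_validation_error")
})

test_that("k-means honors the degenerate k limits and recovers blobs", {
  blobs <- make_blobs(n_per = 20, sep = 10, seed = 34)
  x <- blobs$x
  a1 <- kmeans_assign(x, 1, seed = 1)
  expect_true(all(a1 == 1))
  scatter <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(attr(a1, "wss"), scatter, tolerance = 1e-8)
  an <- kmeans_assign(x, nrow(x), seed = 1)
  expect_equal(attr(an, "wss"), 0, tolerance = 1e-8)
  a2 <- kmeans_assign(x, 2, seed = 1)
  expect_equal(ari(a2, blobs$labels), 1.0)
  # labels canonical: cluster 1 is the largest
  a3 <- kmeans_assign(rbind(x, x[1:10, ] + 0.01), 2, seed = 1)
  expect_gte(sum(a3 == 1), sum(a3 == 2))
  expect_error(kmeans_assign(x, nrow(x) + 1, seed = 1),
               class = "pp_validation_error")
})

test_that("subcluster rule applies n >= 2 and strict > 20% membership", {
  meta <- data.frame(
    condition = c(rep("A", 2), rep("B", 8), rep("C", 1), rep("D", 8),
                  rep("E", 31)),
    region = "C")
  assignments <- c(rep(1, 10), rep(2, 40))
  fmat <- matrix(seq_len(nrow(meta) * 3) + 0.5, ncol = 3)
  subs <- annotate_subclusters(assignments, meta, fmat)
  labels <- vapply(subs, `[[`, "", "label")
  # cluster 1 (10 samples): A has n = 2 at exactly 20% -> excluded (strict)
  expect_false(any(grepl("^A ", labels)))
  # B: 8 of 10 -> included
  expect_true(any(grepl("^B ", labels)))
  # cluster 2 (40 samples): C singleton in cluster 1? C is 1 sample -> excluded
  expect_false(any(grepl("^C ", labels)))
  # D: 8 of 39? cluster 2 has 40 samples; 8/40 = 20% -> excluded
  expect_false(any(grepl("^D ", labels)))
  # E: 31 of 40 -> included
  expect_true(any(grepl("^E ", labels)))
  # deterministic pure function
  subs2 <- annotate_subclusters(assignments, meta, fmat)
  expect_identical(vapply(subs2, `[[`, "", "label"), labels)
})

test_that("a 20.5% group passes while the same n at 20% fails", {
  meta <- data.frame(condition = c(rep("A", 8), rep("Z", 31)), region = "C")
  fmat <- matrix(1, 39, 2) + seq_len(39) / 10
  subs <- annotate_subclusters(rep(1, 39), meta, fmat)
  expect_true("A 1_C" %in% vapply(subs, `[[`, "", "label"))  # 8/39 = 20.5%
})

test_that("subcluster labels carry region subscripts for partial coverage", {
  meta <- data.frame(condition = rep("MD", 6),
                     region = c("P", "P", "M", "M", "P", "M"))
  fmat <- matrix(rnorm(12), 6, 2)
  subs <- annotate_subclusters(rep(3, 6), meta, fmat)
  expect_identical(subs[[1]]$label, "MD 3_PM")
  meta$region <- c("C", "C", "P", "P", "M", "M")
  subs2 <- annotate_subclusters(rep(1, 6), meta, fmat)
  expect_identical(subs2[[1]]$label, "MD 1")
})

test_that("subcluster similarity applies Bonferroni over all pairs", {
  mk <- function(label, mean_features) {
    structure(list(label = label, condition = label, cluster = 1,
                   regions = "C", member_rows = 1:2, n = 2, frac = 0.5,
                   mean_features = mean_features),
              class = "subcluster_profile")
  }
  set.seed(35)
  base <- rnorm(8)
  subs13 <- lapply(1:13, function(i) mk(paste0("S", i),
                                        base + rnorm(8, sd = 0.3)))
  sim <- subcluster_similarity(subs13)
  expect_equal(sim$n_pairs, 78)
  expect_equal(sim$alpha_adjusted, 0.05 / 78)
  expect_lt(abs(sim$alpha_adjusted - 0.0006), 5e-5)
  expect_equal(sim$n_features, 8)

  subs4 <- subs13[1:4]
  sim4 <- subcluster_similarity(subs4)
  expect_equal(sim4$n_pairs, 6)
  expect_equal(sim4$alpha_adjusted, 0.05 / 6, tolerance = 1e-12)

  # identical mean vectors: R = 1 and adjacent dendrogram leaves
  twin <- c(subs13[1:3], list(mk("S1twin", subs13[[1]]$mean_features)))
  simt <- subcluster_similarity(twin)
  expect_equal(simt$r["S1", "S1twin"], 1.0, tolerance = 1e-12)
  pos <- match(c("S1", "S1twin"), simt$leaf_order)
  expect_equal(abs(diff(pos)), 1)
  expect_error(subcluster_similarity(subs13[1:2]),
               class = "pp_validation_error")
})
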