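## Toy data: n_per cluster members around each of k well-separated
## prototype profiles over n_sites CpG sites.
make_clusters <- function(k = 3, n_per = 8, n_sites = 60, noise = 0.02,
                          seed = 31) {
  set.seed(seed)
  protos <- matrix(sample(c(0.05, 0.95), k * n_sites, replace = TRUE),
                   nrow = n_sites)
  while (any(duplicated(t(protos))))
    protos <- matrix(sample(c(0.05, 0.95), k * n_sites, replace = TRUE),
                     nrow = n_sites)
  truth <- rep(seq_len(k), each = n_per)
  b <- protos[, truth] + matrix(rnorm(n_sites * length(truth), 0, noise),
                                nrow = n_sites)
  b <- pmin(pmax(b, 0), 1)
  dimnames(b) <- list(sprintf("cg%04d", seq_len(n_sites)),
                      sprintf("s%03d", seq_along(truth)))
  list(beta = b, truth = setNames(truth, colnames(b)), protos = protos)
}

test_that("consensus clustering recovers well-separated planted clusters", {
  tc <- make_clusters(k = 3, n_per = 8)
  res <- bootstrap_consensus(tc$beta, k_range = 3, n_boot = 50, seed = 5)
  lab <- res$labels_by_k[["3"]]
  expect_equal(ari(lab, tc$truth), 1)
  ## frequencies live in [0,1] with unit diagonal, symmetric
  f <- res$cocluster_freq[["3"]]
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  expect_identical(f, t(f))
  expect_true(all(diag(f) == 1))
})

test_that("a single bootstrap iteration yields binary co-clustering frequencies", {
  tc <- make_clusters(k = 2, n_per = 2, n_sites = 40)
  ## seed chosen so the single resample covers every sample
  res <- bootstrap_consensus(tc$beta, k_range = 2, n_boot = 1, seed = 3)
  f <- res$cocluster_freq[["2"]]
  expect_true(all(f[!is.na(f)] %in% c(0, 1)))
  ## samples never drawn in any iteration are an error advising more
  ## iterations
  tc2 <- make_clusters(k = 2, n_per = 6, n_sites = 40)
  expect_error(bootstrap_consensus(tc2$beta, k_range = 2, n_boot = 1,
                                   seed = 2), "never resampled")
})

test_that("duplicated samples always co-cluster", {
  tc <- make_clusters(k = 3, n_per = 6)
  b <- cbind(tc$beta, dup = tc$beta[, 1])
  res <- bootstrap_consensus(b, k_range = 3, n_boot = 60, seed = 9)
  f <- res$cocluster_freq[["3"]]
  expect_equal(f[colnames(tc$beta)[1], "dup"], 1)
})

test_that("the clustering outcome is invariant under sample reordering", {
  tc <- make_clusters(k = 3, n_per = 8)
  perm <- sample(ncol(tc$beta))
  res1 <- bootstrap_consensus(tc$beta, k_range = 3, n_boot = 60, seed = 7)
  res2 <- bootstrap_consensus(tc$beta[, perm], k_range = 3, n_boot = 60,
                              seed = 8)
  l1 <- res1$labels_by_k[["3"]]
  l2 <- res2$labels_by_k[["3"]][names(l1)]
  expect_equal(ari(l1, l2), 1)
})

test_that("more bootstrap iterations shrink the Monte-Carlo noise of the frequencies", {
  ## same data, replicate seeds: the seed-to-seed sd of the co-clustering
  ## frequency of an ambiguous pair should scale roughly as 1/sqrt(n_boot)
  set.seed(44)
  b <- matrix(runif(40 * 12), nrow = 40,
              dimnames = list(sprintf("cg%03d", 1:40), sprintf("s%02d", 1:12)))
  freq_sd <- function(n_boot) {
    reps <- vapply(1:12, function(s) {
      f <- bootstrap_consensus(b, k_range = 3, n_boot = n_boot,
                               seed = 1000 + s)$cocluster_freq[["3"]]
      f[1, 2]
    }, numeric(1))
    sd(reps)
  }
  s_small <- freq_sd(20)
  s_large <- freq_sd(180)    # 9x iterations: expect ~3x smaller sd
  expect_lt(s_large, s_small)
  expect_lt(s_large, s_small / 1.5)
})

test_that("choose_k flags undersized and unstable solutions and keeps the largest robust k", {
  tc <- make_clusters(k = 3, n_per = 8)
  res <- bootstrap_consensus(tc$beta, k_range = 2:5, n_boot = 60, seed = 13)
  kc <- choose_k(res, min_cluster_size = 5)
  expect_identical(kc$k, 3L)
  ## splitting a clean cluster at k = 4 produces either an undersized or an
  ## unstable cluster
  d4 <- kc$diagnostics[kc$diagnostics$k == 4, ]
  expect_false(d4$admissible)
  ## a planted cluster below the minimum size makes its k inadmissible
  tc2 <- make_clusters(k = 3, n_per = 8)
  b2 <- tc2$beta[, c(1:8, 9:16, 17:19)]   # third cluster has only 3 members
  res2 <- bootstrap_consensus(b2, k_range = 3, n_boot = 60, seed = 14)
  kc2 <- choose_k(res2, min_cluster_size = 5)
  expect_true(is.na(kc2$k))
  ## single admissible candidate is returned as such
  res3 <- bootstrap_consensus(tc$beta[, 1:16], k_range = 2, n_boot = 60,
                              seed = 15)
  expect_identical(choose_k(res3, min_cluster_size = 5)$k, 2L)
})

test_that("centroids are per-site means over observed members", {
  b <- matrix(c(0.2, 0.4, 0.8,
                0.1, NA, 0.7), nrow = 2, byrow = TRUE,
              dimnames = list(c("cg1", "cg2"), c("a", "b", "c")))
  model <- build_centroids(beta_matrix(b), c(a = "g1", b = "g1", c = "g2"))
  expect_equal(model$centroids["cg1", "g1"], 0.3)
  expect_equal(model$centroids["cg2", "g1"], 0.1)  # mean over the observed
  ## single-member epitype equals that sample
  expect_equal(model$centroids[, "g2"], c(cg1 = 0.8, cg2 = 0.7))
})

test_that("epitypes are ordered by similarity to the normal profile", {
  tc <- make_clusters(k = 3, n_per = 6)
  normal_profile <- tc$protos[, 2]          # cluster 2 mimics normals
  names(normal_profile) <- rownames(tc$beta)
  model <- build_centroids(beta_matrix(tc$beta), tc$truth,
                           normal_profile = normal_profile)
  expect_identical(unname(model$cluster_map["2"]), "ET1")
  expect_identical(model$epitype_order, c("ET1", "ET2", "ET3"))
})

test_that("classification assigns the most correlated centroid with deterministic ties", {
  tc <- make_clusters(k = 3, n_per = 6)
  model <- build_centroids(beta_matrix(tc$beta), tc$truth)
  ## a sample equal to a centroid gets its label with correlation 1
  x <- model$centroids[, "2"]
  res <- classify_by_centroid(matrix(x, dimnames = list(names(x), "q")),
                              model, min_overlap = 10)
  expect_identical(res$label, "2")
  expect_equal(res$best_cor, 1)
  expect_gte(res$margin, 0)
  ## exact tie: duplicate centroid columns; the first label in order wins
  m2 <- model
  m2$centroids <- model$centroids[, c(1, 1, 2)]
  colnames(m2$centroids) <- c("A", "B", "C")
  m2$epitype_order <- c("A", "B", "C")
  res2 <- classify_by_centroid(matrix(model$centroids[, 1],
                                      dimnames = list(rownames(model$centroids),
                                                      "q")),
                               m2, min_overlap = 10)
  expect_identical(res2$label, "A")
  expect_equal(res2$margin, 0)
  ## a sample is always assigned to the argmax centroid, even when every
  ## correlation is weak or negative
  q <- 1 - rowMeans(model$centroids)
  res3 <- classify_by_centroid(matrix(q, dimnames = list(names(q), "q")),
                               model, min_overlap = 10)
  r_manual <- cor(q, model$centroids)
  expect_identical(res3$label, colnames(model$centroids)[which.max(r_manual)])
  expect_equal(res3$best_cor, max(r_manual))
  ## zero-variance profile is an error
  expect_error(classify_by_centroid(
    matrix(0.5, nrow(model$centroids), 1,
           dimnames = list(rownames(model$centroids), "flat")),
    model, min_overlap = 10), "variance")
})

test_that("training samples are reassigned to their discovery epitype", {
  co <- small_cohort()
  sp <- split_normalized(co, "small_split")
  truth <- co$truth$epitype_labels
  sel <- c(co$truth$planted_sets$cancer_methylated,
           co$truth$planted_sets$cancer_unmethylated)
  bsel <- subset_probes(sp$tumors, sel)
  model <- build_centroids(bsel, truth)
  res <- classify_by_centroid(bsel, model, min_overlap = 50)
  agree <- mean(res$label == truth[res$sample_id])
  expect_gte(agree, 0.9)
})
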