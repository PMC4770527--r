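test_that("categorical association switches to the exact test on sparse tables", {
  labels <- rep(c("A", "B"), each = 5)
  x <- c(rep("yes", 5), rep("no", 5))
  res <- assoc_test(labels, x)
  expect_identical(res$test, "fisher")
  expect_equal(res$p_value,
               fisher_p_enumeration(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-12)
  ## large balanced table uses chi-squared without continuity correction
  set.seed(2)
  labels2 <- rep(c("A", "B"), each = 60)
  x2 <- sample(c("yes", "no"), 120, replace = TRUE)
  res2 <- assoc_test(labels2, x2)
  expect_identical(res2$test, "chi-squared")
  ref <- suppressWarnings(chisq.test(table(labels2, x2), correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$df, 1)
})

test_that("continuous association uses Kruskal-Wallis and detects gross separation", {
  set.seed(3)
  labels <- rep(c("A", "B", "C"), each = 30)
  x <- rnorm(90)
  x[labels == "C"] <- x[labels == "C"] + 100
  res <- assoc_test(labels, x, kind = "continuous")
  expect_identical(res$test, "kruskal-wallis")
  expect_lt(res$p_value, 1e-6)
  expect_error(assoc_test(rep("A", 10), rnorm(10)), "2 groups")
})

test_that("the association test is calibrated under the null", {
  ## permuted labels on a fixed variable: the rejection rate at 0.05 stays
  ## within 3 binomial SD of nominal over 1000 permutations
  set.seed(4)
  x <- rnorm(60)
  labels <- rep(c("A", "B", "C"), each = 20)
  p <- vapply(1:1000, function(i)
    assoc_test(sample(labels), x, kind = "continuous")$p_value, numeric(1))
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("BH adjustment matches the hand step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_stepup_oracle(p), c(0.04, 0.04, 0.04, 0.5))
  ## all vectors of length <= 6 over a p-grid
  grid <- c(0.001, 0.02, 0.2, 0.9)
  for (len in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    worst <- max(apply(combos, 1, function(pv)
      max(abs(p.adjust(pv, "BH") - bh_stepup_oracle(pv)))))
    expect_lt(worst, 1e-12)
  }
})

test_that("feature screens filter by count, adjust with BH and flag the significant set", {
  set.seed(6)
  labels <- rep(c("A", "B"), each = 20)
  ## binary mutation-like features: one strongly associated, one mutated in
  ## only 4 samples (filtered before testing)
  strong <- c(rep(1, 18), rep(0, 22))
  rare <- c(rep(1, 4), rep(0, 36))
  null1 <- rbinom(40, 1, 0.3); null2 <- rbinom(40, 1, 0.3)
  feats <- rbind(strong = strong, rare = rare, null1 = null1, null2 = null2)
  colnames(feats) <- paste0("s", 1:40)
  res <- screen_features(feats, labels, test = "chisq", fdr_level = 0.01,
                         min_count = 5)
  expect_false("rare" %in% res$feature)
  expect_true(res$significant[res$feature == "strong"])
  expect_equal(res$q, bh_stepup_oracle(res$p), ignore_attr = TRUE)
  expect_true(all(res$q >= res$p))
  ## q is monotone along the p ranking
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_error(screen_features(feats, labels, test = "chisq", min_count = 50),
               "no features")
})

test_that("a null feature screen makes few discoveries on average", {
  set.seed(7)
  labels <- rep(c("A", "B", "C"), each = 12)
  n_disc <- vapply(1:8, function(s) {
    feats <- matrix(rnorm(200 * 36), nrow = 200,
                    dimnames = list(sprintf("f%03d", 1:200), NULL))
    sum(screen_features(feats, labels, test = "kruskal",
                        fdr_level = 0.05)$significant)
  }, numeric(1))
  expect_lt(mean(n_disc), 1)
})

test_that("Wilcoxon screens work for two groups", {
  set.seed(8)
  labels <- rep(c("A", "B"), each = 15)
  feats <- rbind(shifted = c(rnorm(15), rnorm(15, 5)), flat = rnorm(30))
  colnames(feats) <- paste0("s", 1:30)
  res <- screen_features(feats, labels, test = "wilcoxon", fdr_level = 0.05)
  expect_true(res$significant[res$feature == "shifted"])
  expect_false(res$significant[res$feature == "flat"])
})

test_that("Kaplan-Meier without censoring equals the empirical survivor function", {
  times <- c(1, 2, 2, 3, 5, 8)
  clin <- data.frame(sample_id = paste0("s", 1:6), time_years = times,
                     event = 1)
  sc <- survival_logrank(clin, setNames(rep("G", 6), clin$sample_id))
  curve <- sc$curves[[1]]
  emp <- vapply(curve$time, function(t) mean(times > t), numeric(1))
  expect_equal(curve$survival, emp)
  expect_true(all(diff(curve$survival) <= 0))
})

test_that("identical groups give a log-rank p of 1 and separated hazards are detected", {
  clin <- data.frame(sample_id = paste0("s", 1:20),
                     time_years = rep(c(1, 2, 3, 4, 6, 7, 9, 11, 13, 15), 2),
                     event = rep(c(1, 0), 10))
  labels <- setNames(rep(c("A", "B"), each = 10), clin$sample_id)
  ## group B is an exact copy of group A
  clin$time_years[11:20] <- clin$time_years[1:10]
  clin$event[11:20] <- clin$event[1:10]
  res <- survival_logrank(clin, labels)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  ## exponential hazards 0.05 vs 0.2, n = 200 per group: detected in nearly
  ## every replicate
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    t1 <- rexp(200, 0.05); t2 <- rexp(200, 0.2)
    cens <- runif(400, 0, 30)
    tt <- pmin(c(t1, t2), cens)
    ev <- as.integer(c(t1, t2) <= cens)
    cl <- data.frame(sample_id = paste0("s", 1:400), time_years = tt,
                     event = ev)
    survival_logrank(cl, setNames(rep(c("A", "B"), each = 200),
                                  cl$sample_id))$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("follow-up truncation converts late events to censorings", {
  clin <- data.frame(sample_id = c("a", "b", "c"),
                     time_years = c(5, 12, 9), event = c(1, 1, 0))
  labels <- setNames(c("G1", "G1", "G2"), clin$sample_id)
  res <- survival_logrank(clin, labels, truncate_years = 10)
  ## the 12-year event no longer appears as an event; at-risk drops at 10
  g1 <- res$curves[["G1"]]
  expect_false(any(g1$time > 10))
  expect_equal(sum(g1$n_event), 1)
})

test_that("duplicate patients are reduced to their first record", {
  clin <- data.frame(sample_id = c("a", "b", "c"),
                     patient_id = c("P1", "P1", "P2"),
                     time_years = c(5, 7, 9), event = c(1, 1, 1))
  labels <- setNames(c("G1", "G1", "G2"), clin$sample_id)
  res <- survival_logrank(clin, labels)
  expect_equal(sum(res$n), 2)
})
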