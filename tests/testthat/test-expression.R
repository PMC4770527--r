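test_that("expression transforms follow the pseudocount/log2 conventions", {
  m <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("g", c("a", "b", "c")))
  rel <- transform_expression(m, "relative")
  expect_equal(unname(rel[1, ]) + 1, c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(mean(rel[1, ]), 0)
  ## constant gene centers to zeros
  cm <- matrix(5, nrow = 1, ncol = 4, dimnames = list("g", letters[1:4]))
  expect_true(all(transform_expression(cm, "relative") == 0))
  ## absolute mode: TPM columns sum to 1e6 before the log transform
  am <- matrix(c(10, 30, 90, 70), nrow = 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  ab <- transform_expression(am, "absolute")
  expect_equal(colSums(2^ab - 1), c(a = 1e6, b = 1e6))
  expect_error(transform_expression(-m), "non-negative")
})

test_that("probe collapsing keeps the most variable probe per gene", {
  x <- rbind(p1 = c(1, 1.1, 0.9, 1),      # gene G, low variance
             p2 = c(0, 2, 1, 3),          # gene G, high variance
             p3 = c(5, 5, 5, 5))          # gene H
  colnames(x) <- paste0("s", 1:4)
  out <- collapse_probes(x, c("G", "G", "H"))
  expect_identical(rownames(out), c("G", "H"))
  expect_identical(unname(attr(out, "selected_probe")["G"]), "p2")
  expect_equal(out["G", ], x["p2", ])
})

test_that("the closed-form correlation p value matches the t-test oracle", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30) + 0.3 * x
    ct <- cor.test(x, y)
    expect_equal(correlation_pvalue(ct$estimate, 30), ct$p.value,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(expected_chance_correlations(0.2, 101, 1000),
               1000 * correlation_pvalue(0.2, 101))
})

test_that("methylation-expression correlation classifies and partitions CpG sites", {
  set.seed(3)
  n <- 40
  b <- rbind(cg1 = seq(0, 1, length.out = n),          # perfectly coupled
             cg2 = rep(0.5, n),                        # no variation
             cg3 = runif(n), cg4 = runif(n), cg5 = runif(n))
  colnames(b) <- paste0("s", 1:n)
  e <- rbind(gA = -seq(0, 1, length.out = n),          # exact anticorrelation
             gB = rnorm(n), gC = rnorm(n), gD = rnorm(n))
  colnames(e) <- colnames(b)
  map <- data.frame(probe_id = paste0("cg", 1:5),
                    gene = c("gA", "gB", "gC", "gA;gB", "missing"))
  res <- correlate_meth_expr(b, e, map)
  expect_equal(res$r[res$probe_id == "cg1"], -1)
  expect_identical(res$class[res$probe_id == "cg1"], "negative")
  expect_identical(res$class[res$probe_id == "cg2"], "unmapped")
  expect_identical(res$reason[res$probe_id == "cg2"], "no methylation variation")
  expect_identical(res$class[res$probe_id == "cg4"], "unmapped")
  expect_identical(res$reason[res$probe_id == "cg4"], "multiple genes")
  expect_identical(res$reason[res$probe_id == "cg5"],
                   "gene not in expression data")
  ## classes partition the mapped, variable CpG sites
  mapped <- res[res$class != "unmapped", ]
  expect_identical(nrow(mapped),
                   sum(res$class %in% c("positive", "negative", "low")))
})

test_that("planted coupled genes are recovered as negative correlations", {
  co <- lownoise_cohort()
  map <- co$annotation[, c("probe_id", "gene")]
  neg_genes <- names(co$truth$expr_truth)[co$truth$expr_truth < 0]
  probes <- co$annotation$probe_id[co$annotation$gene %in% neg_genes]
  res <- correlate_meth_expr(co$beta$beta[probes, , drop = FALSE],
                             co$expression, map)
  expect_true(all(res$class == "negative"))
})

test_that("module scores are means over the matched genes and are linear", {
  e <- rbind(g1 = c(1, 5), g2 = c(3, 7), g3 = c(10, 20))
  colnames(e) <- c("a", "b")
  expect_equal(module_score(e, "g1"), c(a = 1, b = 5), ignore_attr = TRUE)
  s12 <- module_score(e, c("g1", "g2"))
  expect_equal(unname(s12["a"]), 2)
  ## genes absent from the matrix are ignored
  s_half <- module_score(e, c("g1", "g2", "nope", "nada"))
  expect_equal(s_half, s12, ignore_attr = TRUE)
  expect_identical(attr(s_half, "n_genes"), 2L)
  expect_error(module_score(e, c("x", "y")), "no module genes")
  ## linearity: score of a disjoint union is the size-weighted mean
  sA <- module_score(e, c("g1", "g2")); sB <- module_score(e, "g3")
  sAB <- module_score(e, c("g1", "g2", "g3"))
  expect_equal(unname(sAB), unname((2 * sA + 1 * sB) / 3),
               ignore_attr = TRUE)
})

test_that("promoter windows are strand-aware and the caller applies strict thresholds", {
  ann <- data.frame(probe_id = paste0("cg", 1:4),
                    chrom = "chr1",
                    pos = c(950, 1500, 2600, 3100))
  tr <- data.frame(gene = "G", chrom = "chr1", start = 1000, end = 2500,
                   strand = "+")
  ## + strand: window is [start - 1kb, end]; cg1 (upstream) and cg2 are in,
  ## cg3 and cg4 are downstream of the transcript end
  set.seed(8)
  n <- 30
  meth <- c(rep(0.6, 10), rep(0.01, n - 10))
  b <- rbind(cg1 = meth + rnorm(n, 0, 0.005),
             cg2 = meth + rnorm(n, 0, 0.005),
             cg3 = runif(n), cg4 = runif(n))
  colnames(b) <- paste0("s", 1:n)
  e <- matrix(2 - 2 * meth + rnorm(n, 0, 0.05), nrow = 1,
              dimnames = list("G", colnames(b)))
  call <- call_promoter_status(b, e, ann, tr, "G",
                               preset = promoter_preset("brca1"))
  expect_setequal(call$informative, c("cg1", "cg2"))
  expect_identical(unname(call$status[1:10]), rep("methylated", 10))
  expect_identical(unname(call$status[11:n]), rep("not_methylated", n - 10))
  expect_lt(call$median_r, -0.2)
  ## minus strand: upstream is beyond the transcript end
  tr_minus <- data.frame(gene = "G", chrom = "chr1", start = 1000, end = 2500,
                         strand = "-")
  probes_minus <- promoter_window_probes(ann, tr_minus, "G")
  expect_setequal(probes_minus, c("cg2", "cg3", "cg4"))
  ## a sample mean exactly at the threshold is not called (strict >)
  b_exact <- matrix(c(0.2, 0.2), nrow = 2,
                    dimnames = list(c("cg1", "cg2"), "s1"))
  call2 <- call_promoter_status(b_exact, e, ann, tr, "G",
                                preset = promoter_preset("brca1"),
                                screen_beta = b)
  expect_identical(unname(call2$status), "not_methylated")
  ## all-zero informative betas are never called methylated
  b0 <- matrix(0, nrow = 2, dimnames = list(c("cg1", "cg2"), "s1"))
  call3 <- call_promoter_status(b0, e, ann, tr, "G",
                                preset = promoter_preset("brca1"),
                                screen_beta = b)
  expect_identical(unname(call3$status), "not_methylated")
})

test_that("a gene with no negatively correlated promoter CpG is uncallable", {
  ann <- data.frame(probe_id = "cg1", chrom = "chr1", pos = 1200)
  tr <- data.frame(gene = "G", chrom = "chr1", start = 1000, end = 2500,
                   strand = "+")
  set.seed(9)
  b <- matrix(runif(20), nrow = 1, dimnames = list("cg1", paste0("s", 1:20)))
  e <- matrix(b[1, ] * 2 + rnorm(20, 0, 0.01), nrow = 1,
              dimnames = list("G", colnames(b)))   # positive coupling
  call <- call_promoter_status(b, e, ann, tr, "G",
                               preset = promoter_preset("brca1"))
  expect_true(all(call$status == "uncallable"))
  expect_length(call$informative, 0)
})

test_that("the planted promoter drivers are recovered on the synthetic cohort", {
  co <- lownoise_cohort()
  tumors <- colnames(co$expression)
  si <- co$sample_info
  normals <- si$sample_id[si$cohort == "normal"]
  ## BRCA1-like: silenced subset called methylated, everything else not
  call1 <- call_promoter_status(
    beta_matrix(co$beta$beta[, c(tumors, normals)]), co$expression,
    co$annotation, co$transcripts, "PRM1L",
    preset = promoter_preset("brca1"),
    screen_beta = beta_matrix(co$beta$beta[, tumors]))
  expect_setequal(call1$informative, co$truth$promoter$PRM1L$informative)
  silenced <- co$truth$promoter$PRM1L$silenced
  expect_true(all(call1$status[silenced] == "methylated"))
  expect_true(all(call1$status[setdiff(tumors, silenced)] == "not_methylated"))
  ## specificity: no normal sample is called methylated
  expect_true(all(call1$status[normals] == "not_methylated"))
  ## HORMAD1-like: demethylated subset called unmethylated; normals stay
  ## methylated
  call2 <- call_promoter_status(
    beta_matrix(co$beta$beta[, c(tumors, normals)]), co$expression,
    co$annotation, co$transcripts, "PRM2L",
    preset = promoter_preset("hormad1"),
    screen_beta = beta_matrix(co$beta$beta[, tumors]))
  expect_setequal(call2$informative, co$truth$promoter$PRM2L$informative)
  unmeth <- co$truth$promoter$PRM2L$unmethylated
  expect_true(all(call2$status[unmeth] == "unmethylated"))
  expect_true(all(call2$status[normals] == "not_unmethylated"))
})
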