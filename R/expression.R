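#' Transform raw expression values
#'
#' Two modes. `"relative"`: values are offset by a pseudocount of 1,
#' log2-transformed and mean-centered per gene across samples, giving
#' relative expression levels. `"absolute"`: scaled estimates are converted
#' to transcripts per million (TPM) by normalizing each sample to sum to
#' 1e6, then log2(TPM + 1) is returned, giving expression levels comparable
#' between genes.
#'
#' @param x non-negative genes x samples matrix of counts (relative mode)
#'   or scaled estimates (absolute mode).
#' @param mode `"relative"` or `"absolute"`.
#' @return numeric matrix with attribute `mode`.
#' @examples
#' m <- matrix(c(0, 1, 3), nrow = 1, dimnames = list("g", c("a", "b", "c")))
#' transform_expression(m, "relative")
#' @export
transform_expression <- function(x, mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("expression input must be non-negative")
  out <- if (mode == "relative") {
    l <- log2(x + 1)
    l - rowMeans(l, na.rm = TRUE)
  } else {
    tpm <- sweep(x, 2, colSums(x, na.rm = TRUE), "/") * 1e6
    log2(tpm + 1)
  }
  attr(out, "mode") <- mode
  out
}

#' Collapse expression probes to genes by largest variance
#'
#' When several array probes map to one gene, the probe with the largest
#' expression variance across samples is kept for that gene.
#'
#' @param x probes x samples expression matrix.
#' @param probe_gene character vector (parallel to rows) of gene ids.
#' @return genes x samples matrix, one row per gene, with attribute
#'   `"selected_probe"` recording the retained probe per gene.
#' @export
collapse_probes <- function(x, probe_gene) {
  x <- as.matrix(x)
  if (length(probe_gene) != nrow(x)) stop("probe_gene must match rows of x")
  v <- apply(x, 1, stats::var, na.rm = TRUE)
  keep <- vapply(split(seq_len(nrow(x)), probe_gene),
                 function(idx) idx[which.max(v[idx])], integer(1))
  out <- x[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  attr(out, "selected_probe") <- stats::setNames(rownames(x)[keep], names(keep))
  out
}

#' Two-sided p value of a Pearson correlation under the null
#'
#' Closed-form t transform: t = r * sqrt((n - 2) / (1 - r^2)) referred to a
#' t distribution with n - 2 degrees of freedom.
#'
#' @param r correlation magnitude(s).
#' @param n sample size.
#' @return two-sided p value(s).
#' @export
correlation_pvalue <- function(r, n) {
  if (n <= 2) stop("n must exceed 2")
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-t, df = n - 2)
}

#' Expected number of CpG sites exceeding a correlation threshold by chance
#'
#' Multiplies the two-sided null p value of `|r| > threshold` at sample
#' size `n` by the number of tested CpG sites.
#'
#' @param threshold correlation magnitude threshold.
#' @param n sample size.
#' @param n_sites number of CpG sites tested.
#' @return expected chance count.
#' @export
expected_chance_correlations <- function(threshold, n, n_sites) {
  n_sites * correlation_pvalue(threshold, n)
}

#' Correlate CpG methylation with expression of the mapped gene
#'
#' For each CpG site mapping to exactly one gene present in the expression
#' matrix, computes the pairwise-complete Pearson correlation between its
#' beta values and the gene's expression across the shared samples, and
#' classifies it as `positive` (r > `r_threshold`), `negative`
#' (r < `-r_threshold`) or `low`. CpG sites without a unique mapped gene,
#' with fewer than `min_pairs` complete pairs, or with zero variance in
#' methylation or expression are classified `unmapped` with a reason.
#'
#' @param beta [beta_matrix()] (or matrix) of methylation values.
#' @param expr genes x samples expression matrix.
#' @param cpg_to_gene data frame with columns `probe_id` and `gene`;
#'   multi-gene annotations separated by `";"` are treated as ambiguous.
#' @param r_threshold classification threshold (strict inequalities).
#' @param min_pairs minimum complete pairs before a correlation is
#'   reported.
#' @return data frame per CpG: `gene`, `r`, `n_pairs`, `class`, `reason`.
#' @export
correlate_meth_expr <- function(beta, expr, cpg_to_gene, r_threshold = 0.2,
                                min_pairs = 10L) {
  b <- as_beta(beta)
  shared <- intersect(colnames(b), colnames(expr))
  if (!length(shared)) stop("no shared samples between beta and expression")
  if (length(shared) < 3) stop("need at least 3 shared samples")
  b <- b[, shared, drop = FALSE]
  e <- expr[, shared, drop = FALSE]
  gene <- cpg_to_gene$gene[match(rownames(b), cpg_to_gene$probe_id)]
  res <- data.frame(probe_id = rownames(b), gene = gene, r = NA_real_,
                    n_pairs = 0L, class = "unmapped", reason = NA_character_,
                    stringsAsFactors = FALSE)
  ambiguous <- !is.na(gene) & grepl(";", gene)
  res$reason[is.na(gene)] <- "no gene"
  res$reason[ambiguous] <- "multiple genes"
  usable <- !is.na(gene) & !ambiguous & gene %in% rownames(e)
  res$reason[!is.na(gene) & !ambiguous & !usable] <- "gene not in expression data"
  for (i in which(usable)) {
    x <- b[i, ]; y <- e[res$gene[i], ]
    ok <- !is.na(x) & !is.na(y)
    res$n_pairs[i] <- sum(ok)
    if (sum(ok) < min_pairs) { res$reason[i] <- "too few pairs"; next }
    if (stats::sd(x[ok]) == 0) { res$reason[i] <- "no methylation variation"; next }
    if (stats::sd(y[ok]) == 0) { res$reason[i] <- "no expression variation"; next }
    r <- stats::cor(x[ok], y[ok])
    res$r[i] <- r
    res$class[i] <- if (r > r_threshold) "positive"
      else if (r < -r_threshold) "negative" else "low"
  }
  res
}

#' Average relative expression of a gene module
#'
#' The module score of a sample is the mean relative expression of the
#' module genes found in the matrix.
#'
#' @param expr relative (mean-centered) genes x samples matrix.
#' @param module character vector of gene ids.
#' @return named numeric vector of per-sample scores with attribute
#'   `"n_genes"`, the number of module genes matched.
#' @export
module_score <- function(expr, module) {
  found <- intersect(module, rownames(expr))
  if (!length(found)) stop("no module genes present in expression matrix")
  s <- colMeans(expr[found, , drop = FALSE], na.rm = TRUE)
  attr(s, "n_genes") <- length(found)
  s
}

#' Promoter methylation call presets
#'
#' Shipped configurations for the two candidate-driver callers: the
#' BRCA1-style preset calls a sample promoter *methylated* when the mean
#' beta over the informative CpG sites exceeds 0.2; the HORMAD1-style
#' preset calls a sample promoter *unmethylated* when that mean is below
#' 0.8. Both screen candidate CpG sites for negative
#' methylation--expression correlation below -0.2.
#'
#' @param name `"brca1"` or `"hormad1"`.
#' @return list with `direction`, `threshold`, `r_max`, `upstream`.
#' @export
promoter_preset <- function(name = c("brca1", "hormad1")) {
  name <- match.arg(name)
  switch(name,
         brca1 = list(direction = "methylated", threshold = 0.2,
                      r_max = -0.2, upstream = 1000L),
         hormad1 = list(direction = "unmethylated", threshold = 0.8,
                        r_max = -0.2, upstream = 1000L))
}

## CpG sites within a gene's transcripts or within `upstream` bp upstream
## of the transcription start (strand-aware, union over transcripts).
promoter_window_probes <- function(annotation, transcripts, gene,
                                   upstream = 1000L) {
  tr <- transcripts[transcripts$gene == gene, , drop = FALSE]
  if (!nrow(tr)) stop("gene absent from transcript table: ", gene)
  windows <- GenomicRanges::GRanges(
    tr$chrom,
    IRanges::IRanges(
      start = ifelse(tr$strand == "+", tr$start - upstream, tr$start),
      end = ifelse(tr$strand == "+", tr$end, tr$end + upstream)))
  probes <- GenomicRanges::GRanges(annotation$chrom,
                                   IRanges::IRanges(annotation$pos,
                                                    width = 1L))
  hits <- GenomicRanges::findOverlaps(probes, windows)
  annotation$probe_id[unique(S4Vectors::queryHits(hits))]
}

#' Call promoter methylation status of a candidate driver gene
#'
#' Screens all CpG sites located within the gene's transcripts or 1 kb
#' upstream for negative correlation with the gene's expression (Pearson
#' r < `r_max`, computed on the screening cohort), then classifies each
#' sample by the mean beta value over the informative CpG sites using the
#' preset's direction and threshold (strict inequality). With zero
#' informative CpG sites every sample is `"uncallable"`.
#'
#' @param beta [beta_matrix()] of the cohort to classify.
#' @param expr genes x samples expression matrix of the screening cohort.
#' @param annotation probe annotation with `probe_id`, `chrom`, `pos`.
#' @param transcripts transcript table with `gene`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param gene gene id.
#' @param preset a [promoter_preset()] (or compatible list).
#' @param screen_beta optional [beta_matrix()] of the screening cohort;
#'   defaults to `beta`. The screening cohort must share samples with
#'   `expr`.
#' @return list of class `promoter_call`: `status` (named per-sample
#'   character vector), `mean_beta`, `informative` (probe ids),
#'   `candidates`, `median_r`, `screen_r`.
#' @export
call_promoter_status <- function(beta, expr, annotation, transcripts, gene,
                                 preset = promoter_preset("brca1"),
                                 screen_beta = beta) {
  candidates <- promoter_window_probes(annotation, transcripts, gene,
                                       preset$upstream)
  if (!length(candidates)) stop("no CpG sites in the promoter window of ", gene)
  if (!gene %in% rownames(expr)) stop("gene absent from expression data: ", gene)
  sb <- as_beta(screen_beta)
  shared <- intersect(colnames(sb), colnames(expr))
  if (length(shared) < 3) stop("too few shared screening samples")
  cand_present <- intersect(candidates, rownames(sb))
  r <- vapply(cand_present, function(p) {
    x <- sb[p, shared]; y <- expr[gene, shared]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  informative <- cand_present[!is.na(r) & r < preset$r_max]
  b <- as_beta(beta)
  if (!length(informative)) {
    status <- stats::setNames(rep("uncallable", ncol(b)), colnames(b))
    return(structure(list(status = status,
                          mean_beta = stats::setNames(rep(NA_real_, ncol(b)),
                                                      colnames(b)),
                          informative = character(0), candidates = candidates,
                          median_r = NA_real_, screen_r = r),
                     class = "promoter_call"))
  }
  mb <- colMeans(b[informative, , drop = FALSE], na.rm = TRUE)
  called <- if (preset$direction == "methylated") mb > preset$threshold
            else mb < preset$threshold
  status <- ifelse(is.na(called), "uncallable",
                   ifelse(called, preset$direction,
                          paste0("not_", preset$direction)))
  names(status) <- colnames(b)
  structure(list(status = status, mean_beta = mb, informative = informative,
                 candidates = candidates,
                 median_r = stats::median(r[match(informative, cand_present)]),
                 screen_r = r),
            class = "promoter_call")
}

#' @export
print.promoter_call <- function(x, ...) {
  cat(sprintf("promoter call: %d informative of %d candidate CpG sites (median r %.2f)\n",
              length(x$informative), length(x$candidates), x$median_r))
  print(table(x$status))
  invisible(x)
}
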