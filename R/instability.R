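#' Call copy-number gains and losses from estimates
#'
#' Thresholds log-ratio-like copy-number estimates into
#' gain/loss/neutral calls. Used only when calls are not supplied with the
#' input; supplied calls always take precedence downstream.
#'
#' @param estimate probes x samples numeric matrix.
#' @param gain,loss thresholds (strict inequalities).
#' @return character matrix of `"gain"`, `"loss"`, `"neutral"`.
#' @export
call_gain_loss <- function(estimate, gain = 0.2, loss = -0.2) {
  estimate <- as.matrix(estimate)
  out <- matrix("neutral", nrow = nrow(estimate), ncol = ncol(estimate),
                dimnames = dimnames(estimate))
  out[estimate > gain] <- "gain"
  out[estimate < loss] <- "loss"
  out
}

#' Fraction of the genome altered
#'
#' FGA = (number of probes called gain or loss) / (total probes on the
#' platform), per sample.
#'
#' @param call character matrix (or vector) of `"gain"` / `"loss"` /
#'   `"neutral"` calls, probes in rows.
#' @return named numeric vector of per-sample fractions in \[0, 1\].
#' @examples
#' compute_fga(c("gain", "loss", rep("neutral", 8)))
#' @export
compute_fga <- function(call) {
  if (is.null(dim(call))) call <- matrix(call, ncol = 1)
  if (nrow(call) == 0) stop("empty copy-number profile")
  altered <- call == "gain" | call == "loss"
  colSums(altered) / nrow(call)
}

#' Call amplifications over a catalogue of recurrent regions
#'
#' A region is called amplified in a sample when the mean copy-number
#' estimate of the probes it contains is strictly greater than
#' `threshold`. Regions containing no probes are reported uncallable.
#'
#' @param probes data frame with `probe_id`, `chrom`, `pos`.
#' @param estimate probes x samples estimate matrix (rows matching
#'   `probes`).
#' @param regions data frame of the region catalogue: `region`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param threshold mean-estimate threshold for an amplification call.
#' @return list: `amplified` (regions x samples logical matrix, `NA` rows
#'   for uncallable regions), `n_amplifications` (per sample),
#'   `uncallable` (region names), `region_means`.
#' @export
call_amplifications <- function(probes, estimate, regions, threshold = 0.8) {
  estimate <- as.matrix(estimate)
  stopifnot(nrow(probes) == nrow(estimate))
  means <- matrix(NA_real_, nrow = nrow(regions), ncol = ncol(estimate),
                  dimnames = list(regions$region, colnames(estimate)))
  uncallable <- character(0)
  for (i in seq_len(nrow(regions))) {
    in_r <- probes$chrom == regions$chrom[i] &
      probes$pos >= regions$start[i] & probes$pos <= regions$end[i]
    if (!any(in_r)) { uncallable <- c(uncallable, regions$region[i]); next }
    means[i, ] <- colMeans(estimate[in_r, , drop = FALSE], na.rm = TRUE)
  }
  amplified <- means > threshold
  list(amplified = amplified,
       n_amplifications = colSums(amplified, na.rm = TRUE),
       uncallable = uncallable, region_means = means)
}

#' Nonsilent variant classifications
#'
#' The default set of MAF `Variant_Classification` values *excluded* from
#' gene-level mutation calls (silent and non-coding categories).
#'
#' @return character vector of excluded classifications.
#' @export
silent_classifications <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "5'Flank", "3'Flank", "RNA")
}

#' Merge mutation calls from multiple experiments per tumor
#'
#' A gene is called mutated in a tumor when it carries a nonsilent mutation
#' in at least one experiment for that tumor; the per-tumor substitution
#' count is the average of the per-experiment counts (all rows counted,
#' including silent).
#'
#' @param maf MAF-minimal data frame (`Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification`, and an `Experiment`
#'   column), or a list of per-experiment data frames.
#' @param silent classifications excluded from gene-level calls.
#' @return list of class `mutation_catalog`: `mutated_genes` (named list
#'   per tumor), `substitution_count` (named per-tumor mean), `gene_matrix`
#'   (genes x tumors logical), `n_experiments` per tumor.
#' @export
merge_mutation_experiments <- function(maf,
                                       silent = silent_classifications()) {
  if (is.data.frame(maf)) {
    if (!"Experiment" %in% names(maf)) maf$Experiment <- "E1"
    maf <- split(maf, maf$Experiment)
  }
  exp_names <- names(maf) %||% paste0("E", seq_along(maf))
  exp_names[exp_names == ""] <- paste0("E", which(exp_names == ""))
  maf <- lapply(seq_along(maf), function(i) {
    df <- maf[[i]]
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
    if (!all(need %in% names(df)))
      stop("MAF tables need columns: ", paste(need, collapse = ", "))
    df$Experiment <- exp_names[i]
    df
  })
  all_rows <- do.call(rbind, lapply(maf, function(df)
    df[c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
         "Experiment")]))
  tumors <- sort(unique(all_rows$Tumor_Sample_Barcode))
  nonsilent <- all_rows[!all_rows$Variant_Classification %in% silent, ,
                        drop = FALSE]
  nonsilent <- unique(nonsilent[c("Hugo_Symbol", "Tumor_Sample_Barcode")])
  mutated_genes <- lapply(stats::setNames(tumors, tumors), function(s)
    sort(unique(nonsilent$Hugo_Symbol[nonsilent$Tumor_Sample_Barcode == s])))
  genes <- sort(unique(nonsilent$Hugo_Symbol))
  gene_matrix <- matrix(FALSE, nrow = length(genes), ncol = length(tumors),
                        dimnames = list(genes, tumors))
  if (nrow(nonsilent))
    gene_matrix[cbind(match(nonsilent$Hugo_Symbol, genes),
                      match(nonsilent$Tumor_Sample_Barcode, tumors))] <- TRUE
  per_exp <- table(all_rows$Tumor_Sample_Barcode, all_rows$Experiment)
  n_experiments <- rowSums(per_exp > 0)
  subs <- vapply(tumors, function(s) {
    cnt <- per_exp[s, per_exp[s, ] > 0]
    mean(cnt)
  }, numeric(1))
  structure(list(mutated_genes = mutated_genes, substitution_count = subs,
                 gene_matrix = gene_matrix,
                 n_experiments = n_experiments[tumors]),
            class = "mutation_catalog")
}
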