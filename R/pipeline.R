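#' Pipeline parameter set
#'
#' All tunable parameters of [run_pipeline()] with their default values:
#' detection masking (p > 0.05, beads < 3), normal-status thresholds
#' (beta > 0.7 / beta < 0.3, 2 missing allowed), tumor-specific selection
#' (>= 5 % of tumors switched), bootstrap consensus (2000 iterations, k in
#' 3..10, minimum cluster size 5), pattern thresholds (0.5 / 0.1 / 0.7),
#' copy-number calling (+/- 0.2, amplification mean > 0.8), promoter
#' presets (methylated > 0.2, unmethylated < 0.8, informative r < -0.2),
#' and FDR levels.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(p_max = 0.05, min_beads = 3L,
            bandwidth = 0.04, grid_n = 1001L, min_peak_separation = 0.2,
            meth_min = 0.7, unmeth_max = 0.3, max_missing = 2L,
            min_fraction = 0.05,
            n_boot = 2000L, k_range = 3:10, min_cluster_size = 5L,
            min_within = 0.8, min_gap = 0.6,
            pattern_thresholds = list(high = 0.5, low = 0.1, retained = 0.7),
            roles = NULL,
            cn_gain = 0.2, cn_loss = -0.2, amp_threshold = 0.8,
            min_overlap = 100L,
            mutation_min_count = 5L, mutation_fdr = 0.01,
            truncate_years = 10)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  class(p) <- "pipeline_params"
  p
}

#' Run the full epityping analysis
#'
#' Orchestrates the pipeline on a cohort: peak normalization, normal-status
#' calling, tumor-specific CpG selection, bootstrap consensus clustering
#' with automatic choice of the number of epitypes, centroid construction
#' (epitypes ordered by similarity to the normal profile, most normal-like
#' first), centroid classification of a validation cohort (or
#' self-classification in single-cohort mode), epitype-specific pattern
#' extraction, hypermethylation scores, and the downstream association and
#' survival statistics available from the cohort's tables.
#'
#' @param cohort a `methylation_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a fixture directory path.
#' @param params a [pipeline_params()].
#' @param seed RNG seed for the bootstrap; reruns with the same cohort,
#'   params and seed reproduce the report exactly.
#' @param validation_beta optional [beta_matrix()] of a second cohort to
#'   classify with the trained centroids.
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, the resolved parameters, selected sites, centroids and
#'   assignments as plain text.
#' @return list of class `pipeline_result`: all stage objects plus
#'   `report`, a JSON-ready summary (epitype sizes, set sizes, scores,
#'   test results, seed and parameters).
#' @export
run_pipeline <- function(cohort, params = pipeline_params(), seed = 1L,
                         validation_beta = NULL, out_dir = NULL) {
  if (is.character(cohort)) {
    if (!dir.exists(cohort)) stop("no such fixture directory: ", cohort)
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "methylation_cohort"),
            inherits(params, "pipeline_params"))

  norm <- peak_normalize(cohort$beta, bandwidth = params$bandwidth,
                         grid_n = params$grid_n,
                         min_separation = params$min_peak_separation)
  is_tumor <- cohort$sample_info$cohort == "tumor"
  tumor_ids <- cohort$sample_info$sample_id[is_tumor]
  normal_ids <- cohort$sample_info$sample_id[!is_tumor]
  bt <- beta_matrix(norm$beta[, tumor_ids, drop = FALSE], norm$assay_type, TRUE)
  bn <- beta_matrix(norm$beta[, normal_ids, drop = FALSE], norm$assay_type, TRUE)

  status <- call_normal_status(bn, meth_min = params$meth_min,
                               unmeth_max = params$unmeth_max,
                               max_missing = params$max_missing)
  sets <- select_tumor_specific(bt, status, min_fraction = params$min_fraction,
                                meth_min = params$meth_min,
                                unmeth_max = params$unmeth_max)
  selected <- c(sets$cancer_methylated, sets$cancer_unmethylated)
  if (length(selected) < 10)
    stop("too few tumor-specific CpG sites selected (", length(selected), ")")

  bsel <- subset_probes(bt, selected)
  consensus <- bootstrap_consensus(bsel, k_range = params$k_range,
                                   n_boot = params$n_boot, seed = seed)
  kc <- choose_k(consensus, min_cluster_size = params$min_cluster_size,
                 min_within = params$min_within, min_gap = params$min_gap)
  if (is.na(kc$k))
    stop("no admissible number of epitypes; inspect choose_k diagnostics")
  raw_labels <- consensus$labels_by_k[[as.character(kc$k)]]

  normal_profile <- rowMeans(bn$beta[selected, , drop = FALSE], na.rm = TRUE)
  model <- build_centroids(bsel, raw_labels, normal_profile = normal_profile)
  labels <- stats::setNames(model$cluster_map[as.character(raw_labels)],
                            names(raw_labels))

  assignment <- classify_by_centroid(
    if (!is.null(validation_beta)) subset_probes(validation_beta, selected)
    else bsel,
    model, min_overlap = min(params$min_overlap, length(selected)))

  patterns <- NULL
  roles <- params$roles
  if (is.null(roles) && kc$k >= 5) {
    ## positional convention on the normal-similarity ordering
    roles <- c(basal = paste0("ET", kc$k),
               hyper_luminal = paste0("ET", kc$k - 2),
               global_hypo = paste0("ET", kc$k - 3))
  }
  if (!is.null(roles) && all(roles %in% labels))
    patterns <- extract_paper_patterns(bt, labels, sets, roles = roles,
                                       thresholds = params$pattern_thresholds)

  scores <- hypermethylation_score(norm, cohort$annotation)

  stats_out <- list()
  if (!is.null(cohort$clinical) && nrow(cohort$clinical) > 0) {
    surv_tr <- survival_logrank(cohort$clinical, labels,
                                truncate_years = params$truncate_years)
    surv_full <- survival_logrank(cohort$clinical, labels)
    stats_out$survival <- list(
      truncated = list(horizon_years = params$truncate_years,
                       chisq = surv_tr$chisq, df = surv_tr$df,
                       p_value = surv_tr$p_value),
      full = list(chisq = surv_full$chisq, df = surv_full$df,
                  p_value = surv_full$p_value))
  }
  if (!is.null(cohort$copynumber)) {
    fga <- compute_fga(cohort$copynumber$call)
    stats_out$fga_by_epitype <- tapply(fga[names(labels)], labels, mean)
    kw <- assoc_test(labels[names(fga)], fga, kind = "continuous")
    stats_out$fga_kruskal <- list(statistic = kw$statistic, df = kw$df,
                                  p_value = kw$p_value)
    amp <- call_amplifications(cohort$copynumber$probes,
                               cohort$copynumber$estimate,
                               cohort$copynumber$regions,
                               threshold = params$amp_threshold)
    stats_out$mean_amplifications_by_epitype <-
      tapply(amp$n_amplifications[names(labels)], labels, mean)
  }
  if (!is.null(cohort$mutations) && nrow(cohort$mutations) > 0) {
    catalog <- merge_mutation_experiments(cohort$mutations)
    gm <- catalog$gene_matrix
    common <- intersect(colnames(gm), names(labels))
    full <- matrix(FALSE, nrow = nrow(gm), ncol = length(labels),
                   dimnames = list(rownames(gm), names(labels)))
    full[, common] <- gm[, common]
    screen <- tryCatch(
      screen_features(full, labels, test = "chisq",
                      fdr_level = params$mutation_fdr,
                      min_count = params$mutation_min_count),
      error = function(e) NULL)
    if (!is.null(screen))
      stats_out$mutation_screen <- list(
        n_tested = nrow(screen),
        significant = screen$feature[screen$significant])
  }

  report <- list(
    n_tumors = length(tumor_ids), n_normals = length(normal_ids),
    n_probes = nrow(cohort$beta$beta),
    n_cancer_methylated = length(sets$cancer_methylated),
    n_cancer_unmethylated = length(sets$cancer_unmethylated),
    chosen_k = kc$k,
    epitype_sizes = as.list(table(labels)),
    pattern_set_sizes = if (!is.null(patterns)) lapply(
      patterns[c("et_basal_methylated", "et_luminal_methylated",
                 "et_global_hypo_specific", "et_luminal_hypo",
                 "et_basal_hypo_specific")], length),
    mean_global_score = mean(scores$global_score),
    mean_promoter_island_score = mean(scores$promoter_island_score),
    statistics = stats_out,
    seed = seed,
    parameters = unclass(params))

  result <- structure(list(normalized = norm, normal_status = status,
                           sets = sets, consensus = consensus, k_choice = kc,
                           labels = labels, model = model,
                           assignment = assignment, patterns = patterns,
                           scores = scores, report = report),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    utils::write.table(
      data.frame(probe_id = selected,
                 direction = rep(c("cancer_methylated", "cancer_unmethylated"),
                                 c(length(sets$cancer_methylated),
                                   length(sets$cancer_unmethylated))),
                 switched_fraction = sets$switched_fraction[selected]),
      file.path(out_dir, "selected_sites.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_tsv_matrix(model$centroids, file.path(out_dir, "centroids.tsv"))
    utils::write.table(assignment, file.path(out_dir, "assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("epityping pipeline: %d epitypes over %d selected CpG sites\n",
              x$report$chosen_k,
              x$report$n_cancer_methylated + x$report$n_cancer_unmethylated))
  print(table(x$labels))
  invisible(x)
}
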