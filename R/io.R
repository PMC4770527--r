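## Plain-text readers and writers for the cohort tables. All matrices are
## written as TSV with row names in the first column and "NA" for missing.

write_tsv_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path, numeric = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (numeric) storage.mode(m) <- "double"
  m
}

#' Read a beta-value matrix from TSV
#'
#' Expects probes in rows (first column = probe id), samples in columns,
#' `NA` for missing measurements.
#'
#' @param path TSV file.
#' @param annotation optional probe annotation data frame with `probe_id`
#'   and `assay_type` columns; used to attach assay chemistry.
#' @param normalized provenance flag for the returned object.
#' @return a [beta_matrix()].
#' @export
read_beta_tsv <- function(path, annotation = NULL, normalized = FALSE) {
  m <- read_tsv_matrix(path)
  assay <- "II"
  if (!is.null(annotation)) {
    idx <- match(rownames(m), annotation$probe_id)
    assay <- annotation$assay_type[idx]
    assay[is.na(assay)] <- "II"
  }
  beta_matrix(m, assay, normalized)
}

#' Read a probe-level signal table from TSV
#'
#' Accepts the GenomeStudio-like dialect (columns `probe_id`, `sample_id`,
#' `M`, `U`, `detection_p`, `n_beads`) and the TCGA-like dialect without the
#' `n_beads` column.
#'
#' @param path TSV file.
#' @return data frame of per probe/sample signals.
#' @export
read_signal_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "sample_id", "M", "U", "detection_p")
  if (!all(need %in% names(df)))
    stop("signal table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Write a synthetic cohort to a fixture directory
#'
#' Serializes every table of a [generate_cohort()] result as plain text
#' (TSV + JSON truth) and writes a manifest with per-file MD5 checksums.
#'
#' @param cohort a `methylation_cohort`.
#' @param dir output directory (created if absent).
#' @param include_signals write the (large) probe-level signal table?
#' @return invisibly, the manifest data frame.
#' @export
write_fixture <- function(cohort, dir, include_signals = TRUE) {
  stopifnot(inherits(cohort, "methylation_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  p <- function(f) file.path(dir, f)

  write_tsv_matrix(cohort$beta$beta, p("beta.tsv"))
  utils::write.table(cohort$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (include_signals)
    utils::write.table(cohort$signals, p("signals.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv_matrix(cohort$expression, p("expression.tsv"))
  utils::write.table(cohort$copynumber$probes, p("cn_probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_tsv_matrix(cohort$copynumber$estimate, p("cn_estimate.tsv"))
  write_tsv_matrix(cohort$copynumber$call, p("cn_call.tsv"))
  utils::write.table(cohort$copynumber$regions, p("cn_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mutations, p("mutations.maf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, p("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sample_info, p("sample_info.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$transcripts, p("transcripts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(chrom = names(cohort$chrom_lengths),
                                length = unname(cohort$chrom_lengths)),
                     p("chrom_lengths.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- cohort$truth
  truth$amplified <- NULL   # matrix: rebuilt from cn tables when needed
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = FALSE, digits = NA,
                       null = "list")
  jsonlite::write_json(unclass(cohort$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- list.files(dir)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir, files))),
                         bytes = file.size(file.path(dir, files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Read a fixture directory back into a cohort
#'
#' Inverse of [write_fixture()]. The planted truth is restored from
#' `truth.json`; the amplification truth matrix is not round-tripped.
#'
#' @param dir fixture directory.
#' @return a list of class `methylation_cohort`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  if (!file.exists(p("beta.tsv"))) stop("not a fixture directory: ", dir)
  annotation <- utils::read.delim(p("annotation.tsv"), stringsAsFactors = FALSE)
  beta <- read_beta_tsv(p("beta.tsv"), annotation)
  expression <- read_tsv_matrix(p("expression.tsv"))
  attr(expression, "mode") <- "relative"
  cl <- utils::read.delim(p("chrom_lengths.tsv"), stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$class_means <- NULL
  truth$epitype_labels <- unlist(truth$epitype_labels)
  truth$site_class <- unlist(truth$site_class)
  truth$expr_truth <- unlist(truth$expr_truth)
  cohort <- list(
    signals = if (file.exists(p("signals.tsv"))) read_signal_tsv(p("signals.tsv")),
    beta = beta,
    annotation = annotation,
    expression = expression,
    transcripts = utils::read.delim(p("transcripts.tsv"), stringsAsFactors = FALSE),
    copynumber = list(
      probes = utils::read.delim(p("cn_probes.tsv"), stringsAsFactors = FALSE),
      estimate = read_tsv_matrix(p("cn_estimate.tsv")),
      call = read_tsv_matrix(p("cn_call.tsv"), numeric = FALSE),
      regions = utils::read.delim(p("cn_regions.tsv"), stringsAsFactors = FALSE)),
    mutations = utils::read.delim(p("mutations.maf.tsv"), stringsAsFactors = FALSE),
    clinical = utils::read.delim(p("clinical.tsv"), stringsAsFactors = FALSE),
    sample_info = utils::read.delim(p("sample_info.tsv"), stringsAsFactors = FALSE),
    chrom_lengths = stats::setNames(cl$length, cl$chrom),
    truth = truth,
    config = jsonlite::read_json(p("config.json"), simplifyVector = TRUE))
  class(cohort) <- "methylation_cohort"
  cohort
}
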