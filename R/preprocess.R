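#' Convert signal intensities to beta values with quality masking
#'
#' Computes beta = M / (M + U) per probe and sample and masks low-quality
#' measurements: entries with detection p value strictly greater than
#' `p_max`, or with fewer than `min_beads` beads, are set missing. When the
#' table carries no `n_beads` column (TCGA-style level-2 data) only the
#' detection-p rule applies. Entries with M + U = 0 are flagged missing, not
#' errored.
#'
#' @param signals long-format signal table (see [read_signal_tsv()]):
#'   columns `probe_id`, `sample_id`, `M`, `U`, `detection_p` and optionally
#'   `n_beads`.
#' @param p_max detection p value above which a measurement is missing
#'   (strict inequality; a value exactly at `p_max` is retained).
#' @param min_beads minimum bead count; entries with fewer are missing.
#' @param annotation optional probe annotation supplying `assay_type`.
#' @param warn_missing per-sample missing-count above which a QC warning is
#'   emitted.
#' @return a [beta_matrix()] (raw, not normalized) with attribute
#'   `"qc"`: a data frame of per-sample missing totals.
#' @examples
#' sig <- data.frame(probe_id = "cg1", sample_id = "s1", M = 75, U = 25,
#'                   detection_p = 0.01, n_beads = 10)
#' compute_beta_and_mask(sig)$beta
#' @export
compute_beta_and_mask <- function(signals, p_max = 0.05, min_beads = 3L,
                                  annotation = NULL, warn_missing = 10000L) {
  stopifnot(is.data.frame(signals))
  if (any(signals$M < 0, na.rm = TRUE) || any(signals$U < 0, na.rm = TRUE))
    stop("negative signal intensities")
  if (any(signals$detection_p < 0 | signals$detection_p > 1, na.rm = TRUE))
    stop("detection_p values must lie in [0, 1]")
  probes <- unique(signals$probe_id)
  samples <- unique(signals$sample_id)
  tot <- signals$M + signals$U
  beta <- ifelse(tot > 0, signals$M / tot, NA_real_)
  miss <- tot <= 0 | is.na(tot)
  miss <- miss | (signals$detection_p > p_max)      # strictly greater than
  if ("n_beads" %in% names(signals))
    miss <- miss | (!is.na(signals$n_beads) & signals$n_beads < min_beads)
  beta[miss] <- NA_real_
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(signals$probe_id, probes),
          match(signals$sample_id, samples))] <- beta
  assay <- "II"
  if (!is.null(annotation)) {
    assay <- annotation$assay_type[match(probes, annotation$probe_id)]
    assay[is.na(assay)] <- "II"
  }
  out <- beta_matrix(m, assay, normalized = FALSE)
  qc <- data.frame(sample_id = samples,
                   n_missing = as.integer(colSums(is.na(m))),
                   stringsAsFactors = FALSE)
  over <- qc$sample_id[qc$n_missing > warn_missing]
  if (length(over))
    warning("samples with more than ", warn_missing, " missing values: ",
            paste(over, collapse = ", "))
  attr(out, "qc") <- qc
  out
}

## Locate the unmethylated/methylated density peaks of one sample stratum.
## Point masses at exactly 0 or 1 (atoms produced by the clamping step of a
## previous normalization) are treated as peaks directly when they carry at
## least `boundary_atom` of the stratum; the kernel estimate is meaningful
## only for the continuous part and would diffuse such atoms inward.
find_beta_peaks <- function(x, bandwidth, grid_n, midpoint,
                            boundary_atom = 0.05) {
  d <- stats::density(x, bw = bandwidth, kernel = "epanechnikov",
                      from = 0, to = 1, n = grid_n)
  lo <- d$x < midpoint
  c(unmeth = if (mean(x == 0) >= boundary_atom) 0
             else d$x[lo][which.max(d$y[lo])],
    meth = if (mean(x == 1) >= boundary_atom) 1
           else d$x[!lo][which.max(d$y[!lo])])
}

#' Peak normalization of Infinium I/II beta values
#'
#' Per sample and per assay chemistry independently, estimates the
#' unmethylated and methylated density peaks of the beta distribution with
#' an Epanechnikov smoothing kernel, then linearly rescales so the
#' unmethylated peak moves to 0 and the methylated peak to 1 (values in
#' between stretched accordingly). Rescaled values below 0 are set to 0 and
#' values above 1 to 1. Missing values stay missing. This removes the
#' dynamic-range compression of type-II probes relative to type-I probes.
#'
#' @param beta a [beta_matrix()] (or plain matrix with `assay_type`
#'   supplied).
#' @param bandwidth kernel bandwidth on the beta scale.
#' @param grid_n number of evaluation points on the density grid over
#'   \[0, 1\].
#' @param midpoint peaks are searched below (unmethylated) and at/above
#'   (methylated) this value.
#' @param min_separation minimum allowed distance between the two peaks;
#'   a smaller distance (effectively unimodal stratum) is an error naming
#'   the sample and assay type.
#' @param min_values minimum non-missing values required per sample/assay
#'   stratum.
#' @param assay_type per-probe chemistry, used when `beta` is a plain
#'   matrix.
#' @return a [beta_matrix()] with `normalized = TRUE` and attribute
#'   `"peaks"`: a data frame of the estimated peaks per sample and assay
#'   type.
#' @export
peak_normalize <- function(beta, bandwidth = 0.04, grid_n = 1001L,
                           midpoint = 0.5, min_separation = 0.2,
                           min_values = 30L, assay_type = NULL) {
  if (!inherits(beta, "beta_matrix"))
    beta <- beta_matrix(beta, assay_type %||% "II")
  b <- beta$beta
  out <- b
  peaks <- list()
  for (at in unique(beta$assay_type)) {
    rows <- beta$assay_type == at
    for (j in seq_len(ncol(b))) {
      x <- b[rows, j]
      x <- x[!is.na(x)]
      if (length(x) < min_values)
        stop(sprintf("sample %s, assay type %s: only %d non-missing values",
                     colnames(b)[j], at, length(x)))
      pk <- find_beta_peaks(x, bandwidth, grid_n, midpoint)
      if (pk["meth"] - pk["unmeth"] < min_separation)
        stop(sprintf(
          "sample %s, assay type %s: peak separation %.3f below %.3f (unimodal?)",
          colnames(b)[j], at, pk["meth"] - pk["unmeth"], min_separation))
      y <- (b[rows, j] - pk["unmeth"]) / (pk["meth"] - pk["unmeth"])
      out[rows, j] <- pmin(pmax(y, 0), 1)
      peaks[[length(peaks) + 1L]] <-
        data.frame(sample_id = colnames(b)[j], assay_type = at,
                   unmeth_peak = unname(pk["unmeth"]),
                   meth_peak = unname(pk["meth"]), stringsAsFactors = FALSE)
    }
  }
  res <- beta_matrix(out, beta$assay_type, normalized = TRUE)
  attr(res, "peaks") <- do.call(rbind, peaks)
  res
}

#' Per-sample hypermethylation scores
#'
#' Two scores per sample, each the mean beta value over a contributing CpG
#' set (missing values excluded): a global score over all probes, and a
#' promoter CpG island score over probes annotated to a promoter region
#' (TSS1500 or TSS200) *and* to a CpG island.
#'
#' @param beta a normalized [beta_matrix()].
#' @param annotation probe annotation with columns `probe_id`, `region`
#'   and `island`.
#' @return data frame with one row per sample: `global_score`,
#'   `promoter_island_score` and the contributing-site counts.
#' @export
hypermethylation_score <- function(beta, annotation) {
  b <- as_beta(beta)
  idx <- match(rownames(b), annotation$probe_id)
  if (anyNA(idx)) stop("probes missing from annotation")
  promoter <- annotation$region[idx] %in% c("TSS1500", "TSS200") &
    annotation$island[idx] == "Island"
  if (!any(promoter)) stop("no promoter CpG island probes in annotation")
  if (nrow(b) == 0) stop("empty beta matrix")
  data.frame(
    sample_id = colnames(b),
    global_score = colMeans(b, na.rm = TRUE),
    promoter_island_score = colMeans(b[promoter, , drop = FALSE], na.rm = TRUE),
    n_global = as.integer(colSums(!is.na(b))),
    n_promoter_island = as.integer(colSums(!is.na(b[promoter, , drop = FALSE]))),
    row.names = NULL, stringsAsFactors = FALSE)
}
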