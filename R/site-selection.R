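#' Call constitutive methylation status in a normal cohort
#'
#' A probe is called `methylated` when every non-missing normal beta value
#' is strictly greater than `meth_min`, and `unmethylated` when every
#' non-missing value is strictly less than `unmeth_max`; at most
#' `max_missing` missing values are allowed. Any non-missing value in the
#' intermediate band, or too many missing values, excludes the probe.
#'
#' @param normal_beta normalized [beta_matrix()] of the normal cohort.
#' @param meth_min lower bound for the methylated call (strict `>`).
#' @param unmeth_max upper bound for the unmethylated call (strict `<`).
#' @param max_missing maximum missing values allowed per probe (inclusive).
#' @return data frame with one row per probe: `status` in
#'   `{"methylated", "unmethylated", "excluded"}`, `n_missing`, and
#'   `n_violations` (values on neither clear side).
#' @examples
#' b <- matrix(c(0.9, 0.95, 0.85, 0.1, 0.05, 0.2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("cg1", "cg2"), c("n1", "n2", "n3")))
#' call_normal_status(beta_matrix(b))
#' @export
call_normal_status <- function(normal_beta, meth_min = 0.7, unmeth_max = 0.3,
                               max_missing = 2L) {
  b <- as_beta(normal_beta)
  if (ncol(b) == 0) stop("empty normal cohort")
  n_missing <- rowSums(is.na(b))
  all_meth <- rowSums(b > meth_min, na.rm = TRUE) == rowSums(!is.na(b))
  all_unmeth <- rowSums(b < unmeth_max, na.rm = TRUE) == rowSums(!is.na(b))
  none_observed <- rowSums(!is.na(b)) == 0
  status <- rep("excluded", nrow(b))
  status[all_meth & !none_observed] <- "methylated"
  status[all_unmeth & !none_observed] <- "unmethylated"
  status[n_missing > max_missing] <- "excluded"
  n_violations <- rowSums(!is.na(b) & b >= unmeth_max & b <= meth_min)
  data.frame(probe_id = rownames(b), status = status,
             n_missing = unname(n_missing),
             n_violations = unname(n_violations),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select CpG sites with tumor-specific methylation status
#'
#' Given constitutive status calls from the normal cohort, selects probes
#' that switch status in at least a minimum fraction of tumors:
#' `cancer_methylated` are probes unmethylated in normals with beta >
#' `meth_min` in at least `ceiling(min_fraction * n_tumors)` tumors, and
#' `cancer_unmethylated` are probes methylated in normals with beta <
#' `unmeth_max` in at least that many tumors. Missing tumor values never
#' count as switched; the denominator stays the full tumor count.
#'
#' @param tumor_beta normalized [beta_matrix()] of the tumor cohort.
#' @param normal_status result of [call_normal_status()].
#' @param min_fraction minimum fraction of tumors that must switch
#'   (in (0, 1]).
#' @param meth_min,unmeth_max the switching thresholds (strict
#'   inequalities), matching the normal-status thresholds.
#' @return list of class `tumor_specific_sets`: `cancer_methylated` and
#'   `cancer_unmethylated` probe-id vectors, `threshold_count`, and
#'   `switched_fraction` (per probe, NA for probes excluded in normals).
#' @export
select_tumor_specific <- function(tumor_beta, normal_status,
                                  min_fraction = 0.05, meth_min = 0.7,
                                  unmeth_max = 0.3) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  b <- as_beta(tumor_beta)
  st <- normal_status$status[match(rownames(b), normal_status$probe_id)]
  if (anyNA(st)) stop("probes missing from normal_status")
  n_tumors <- ncol(b)
  threshold_count <- ceiling(min_fraction * n_tumors)
  n_meth <- rowSums(b > meth_min, na.rm = TRUE)
  n_unmeth <- rowSums(b < unmeth_max, na.rm = TRUE)
  switched <- ifelse(st == "unmethylated", n_meth,
                     ifelse(st == "methylated", n_unmeth, NA_real_))
  cancer_meth <- rownames(b)[st == "unmethylated" & n_meth >= threshold_count]
  cancer_unmeth <- rownames(b)[st == "methylated" & n_unmeth >= threshold_count]
  structure(list(cancer_methylated = cancer_meth,
                 cancer_unmethylated = cancer_unmeth,
                 threshold_count = threshold_count,
                 switched_fraction = stats::setNames(switched / n_tumors,
                                                     rownames(b))),
            class = "tumor_specific_sets")
}

#' @export
print.tumor_specific_sets <- function(x, ...) {
  cat(sprintf("tumor-specific CpG sites: %d cancer-methylated, %d cancer-unmethylated (>= %d switched tumors)\n",
              length(x$cancer_methylated), length(x$cancer_unmethylated),
              x$threshold_count))
  invisible(x)
}
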