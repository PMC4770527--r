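#' Beta-value matrix with assay annotation
#'
#' Lightweight container for a probes-by-samples matrix of methylation beta
#' values (fractions in [0, 1], `NA` for masked measurements) together with
#' the Infinium assay chemistry of each probe ("I" or "II") and a provenance
#' flag recording whether peak normalization has been applied.
#'
#' @param beta numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns (colnames = sample ids). Non-missing values must lie in
#'   [0, 1].
#' @param assay_type character vector of "I"/"II" per probe, recycled if of
#'   length 1. Defaults to "II" for every probe.
#' @param normalized logical; has peak normalization been applied?
#' @return An object of class `beta_matrix`: a list with elements `beta`,
#'   `assay_type` and `normalized`.
#' @examples
#' b <- matrix(c(0.1, 0.9, 0.2, 0.8), nrow = 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' bm <- beta_matrix(b, assay_type = c("I", "II"))
#' n_missing(bm)
#' @export
beta_matrix <- function(beta, assay_type = "II", normalized = FALSE) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta)) stop("'beta' must be numeric")
  if (length(beta) && !all(is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta values must lie in [0, 1]")
  }
  if (is.null(rownames(beta)))
    rownames(beta) <- sprintf("cg%08d", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- sprintf("S%04d", seq_len(ncol(beta)))
  assay_type <- rep_len(as.character(assay_type), nrow(beta))
  if (!all(assay_type %in% c("I", "II")))
    stop("assay_type must be 'I' or 'II'")
  structure(list(beta = beta, assay_type = assay_type,
                 normalized = isTRUE(normalized)),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%s, %d missing values)\n",
              nrow(x$beta), ncol(x$beta),
              if (x$normalized) "peak-normalized" else "raw",
              sum(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

## Accept either a beta_matrix or a plain matrix everywhere downstream.
as_beta <- function(x) {
  if (inherits(x, "beta_matrix")) x$beta else as.matrix(x)
}

#' Per-sample missing-value counts
#'
#' @param x a [beta_matrix()] or plain matrix.
#' @return named integer vector, one count per sample (column).
#' @export
n_missing <- function(x) {
  b <- as_beta(x)
  colSums(is.na(b))
}

#' Restrict a beta matrix to a probe set
#'
#' @param x a [beta_matrix()].
#' @param probes character vector of probe ids (rownames).
#' @return a [beta_matrix()] over the requested probes, in the given order.
#' @export
subset_probes <- function(x, probes) {
  stopifnot(inherits(x, "beta_matrix"))
  idx <- match(probes, rownames(x$beta))
  if (anyNA(idx))
    stop("unknown probes: ", paste(utils::head(probes[is.na(idx)], 5), collapse = ", "))
  beta_matrix(x$beta[idx, , drop = FALSE], x$assay_type[idx], x$normalized)
}
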