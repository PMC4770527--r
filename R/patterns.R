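#' Per-epitype mean beta values
#'
#' @param beta [beta_matrix()] (or matrix), tumors in columns.
#' @param labels per-tumor epitype labels (named by sample id, or in
#'   column order).
#' @param probes optional probe subset.
#' @return matrix probes x epitypes of mean beta over the non-missing
#'   member values; `NaN` where an epitype has no observed value at a
#'   probe.
#' @export
epitype_means <- function(beta, labels, probes = NULL) {
  b <- as_beta(beta)
  if (!is.null(names(labels))) labels <- labels[colnames(b)]
  if (length(labels) != ncol(b)) stop("labels must cover all samples")
  if (!is.null(probes)) b <- b[probes, , drop = FALSE]
  groups <- sort(unique(as.character(labels)))
  m <- vapply(groups, function(g)
    rowMeans(b[, labels == g, drop = FALSE], na.rm = TRUE), numeric(nrow(b)))
  if (nrow(b) == 1) m <- matrix(m, nrow = 1, dimnames = list(rownames(b), groups))
  rownames(m) <- rownames(b)
  m
}

#' Select probes satisfying per-epitype mean-beta constraints
#'
#' A probe from the universe is retained iff every constraint holds with a
#' strict inequality on its mean beta value (over non-missing members)
#' within the named epitype. A probe with no observed value in a
#' constrained epitype fails that constraint.
#'
#' @param beta [beta_matrix()] of the tumor cohort.
#' @param labels per-tumor epitype labels.
#' @param universe probe ids forming the selection universe.
#' @param constraints data frame with columns `epitype`, `bound` (`">"` or
#'   `"<"`) and `threshold`; an empty frame returns the whole universe.
#' @return character vector of retained probe ids, with attribute
#'   `"means"`: the per-epitype mean table over the universe.
#' @export
select_constrained_set <- function(beta, labels, universe, constraints) {
  if (!length(universe)) stop("empty universe")
  means <- epitype_means(beta, labels, probes = universe)
  keep <- rep(TRUE, length(universe))
  if (nrow(constraints %||% data.frame()) > 0) {
    for (i in seq_len(nrow(constraints))) {
      et <- constraints$epitype[i]
      if (!et %in% colnames(means))
        stop("constraint references absent epitype: ", et)
      thr <- constraints$threshold[i]
      v <- means[, et]
      ok <- switch(constraints$bound[i],
                   ">" = !is.nan(v) & v > thr,
                   "<" = !is.nan(v) & v < thr,
                   stop("bound must be '>' or '<'"))
      keep <- keep & ok
    }
  }
  structure(universe[keep], means = means)
}

#' Extract the five epitype-specific methylation pattern sets
#'
#' Applies the mean-beta constraint rules defining the epitype-specific
#' hyper- and hypomethylation patterns. Hypermethylation rules act on the
#' cancer-methylated universe and hypomethylation rules on the
#' cancer-unmethylated universe:
#' \describe{
#'   \item{et_basal_methylated}{mean beta > 0.5 in the basal-like epitype.}
#'   \item{et_luminal_methylated}{mean beta > 0.5 in the hypermethylated
#'     luminal epitype and < 0.1 in the basal-like epitype.}
#'   \item{et_global_hypo_specific}{mean beta < 0.5 in the globally
#'     hypomethylated epitype and > 0.7 in both the hypermethylated luminal
#'     and the basal-like epitypes.}
#'   \item{et_luminal_hypo}{mean beta < 0.5 in the hypermethylated luminal
#'     epitype and > 0.7 in the basal-like epitype.}
#'   \item{et_basal_hypo_specific}{mean beta < 0.5 in the basal-like
#'     epitype and > 0.7 in the globally hypomethylated epitype.}
#' }
#'
#' @param beta [beta_matrix()] of the tumor cohort.
#' @param labels per-tumor epitype labels.
#' @param sets a [select_tumor_specific()] result (or list with
#'   `cancer_methylated` / `cancer_unmethylated`).
#' @param roles named character vector mapping the pattern roles to epitype
#'   labels: `basal`, `hyper_luminal`, `global_hypo`. On new data the
#'   ordinal epitype names carry no biology, so the mapping is declared
#'   rather than inferred.
#' @param thresholds named list overriding the rule thresholds `high`
#'   (0.5), `low` (0.1) and `retained` (0.7).
#' @return list of class `epitype_pattern_sets` with the five probe-id
#'   vectors and `means`, the per-epitype mean tables of both universes.
#' @export
extract_paper_patterns <- function(beta, labels, sets,
                                   roles = c(basal = "ET7",
                                             hyper_luminal = "ET5",
                                             global_hypo = "ET4"),
                                   thresholds = list(high = 0.5, low = 0.1,
                                                     retained = 0.7)) {
  need <- c("basal", "hyper_luminal", "global_hypo")
  if (!all(need %in% names(roles)))
    stop("roles must map: ", paste(need, collapse = ", "))
  present <- unique(as.character(labels))
  missing_roles <- setdiff(unname(roles[need]), present)
  if (length(missing_roles))
    stop("role epitypes absent from labels: ",
         paste(missing_roles, collapse = ", "))
  hi <- thresholds$high; lo <- thresholds$low; ret <- thresholds$retained
  con <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(epitype = m[, 1], bound = m[, 2],
               threshold = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  }
  basal <- roles[["basal"]]; hl <- roles[["hyper_luminal"]]
  gh <- roles[["global_hypo"]]
  meth_u <- sets$cancer_methylated
  unmeth_u <- sets$cancer_unmethylated
  pat <- list(
    et_basal_methylated = select_constrained_set(
      beta, labels, meth_u, con(basal, ">", hi)),
    et_luminal_methylated = select_constrained_set(
      beta, labels, meth_u, con(hl, ">", hi, basal, "<", lo)),
    et_global_hypo_specific = select_constrained_set(
      beta, labels, unmeth_u, con(gh, "<", hi, hl, ">", ret, basal, ">", ret)),
    et_luminal_hypo = select_constrained_set(
      beta, labels, unmeth_u, con(hl, "<", hi, basal, ">", ret)),
    et_basal_hypo_specific = select_constrained_set(
      beta, labels, unmeth_u, con(basal, "<", hi, gh, ">", ret)))
  means <- list(cancer_methylated = attr(pat$et_basal_methylated, "means"),
                cancer_unmethylated = attr(pat$et_global_hypo_specific, "means"))
  pat <- lapply(pat, function(x) { attributes(x) <- NULL; x })
  structure(c(pat, list(means = means, roles = roles)),
            class = "epitype_pattern_sets")
}

#' @export
print.epitype_pattern_sets <- function(x, ...) {
  sizes <- vapply(x[c("et_basal_methylated", "et_luminal_methylated",
                      "et_global_hypo_specific", "et_luminal_hypo",
                      "et_basal_hypo_specific")], length, integer(1))
  cat("epitype pattern sets:\n")
  for (nm in names(sizes)) cat(sprintf("  %s: %d CpG sites\n", nm, sizes[nm]))
  invisible(x)
}
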