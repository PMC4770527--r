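#' Bootstrap consensus clustering of methylation profiles
#'
#' Discovers sample clusters by accumulating co-clustering frequencies over
#' bootstrap resamples. Each iteration resamples the samples with
#' replacement to the cohort size; the unique resampled samples are
#' clustered by agglomerative Ward linkage (`ward.D`) on the Pearson
#' correlation-based distance `1 - cor` between methylation profiles (the
#' inner clustering), and the tree is cut at every `k` in `k_range`. The
#' co-clustering frequency of a sample pair is its number of co-assignments
#' divided by its number of co-presences across iterations. The outer
#' clustering then applies the same Ward linkage with Pearson-based distance
#' to the rows of the co-clustering frequency matrix and is cut at the same
#' `k`.
#'
#' @param beta [beta_matrix()] (or matrix) restricted to the selected CpG
#'   sites; samples in columns.
#' @param k_range integer vector of cluster numbers to evaluate.
#' @param n_boot number of bootstrap iterations.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param outer_distance `"pearson"` (distance between rows of the
#'   frequency matrix, the default) or `"consensus"` (`1 - frequency`
#'   directly).
#' @return list of class `consensus_result`: `cocluster_freq` (per k),
#'   `copresence_count`, `labels_by_k`, `stability_by_k` (per-cluster
#'   within/between consensus and sizes), `k_range`, `n_boot`, `seed`.
#' @export
bootstrap_consensus <- function(beta, k_range = 3:10, n_boot = 2000L,
                                seed = 1L, outer_distance = c("pearson",
                                                              "consensus")) {
  outer_distance <- match.arg(outer_distance)
  b <- as_beta(beta)
  n <- ncol(b)
  if (n < 2) stop("need at least 2 samples")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > n))
    stop("k_range values must lie in [2, n_samples]")
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")

  D <- 1 - stats::cor(b, use = "pairwise.complete.obs")
  if (anyNA(D)) stop("undefined pairwise correlations between samples")
  ids <- colnames(b)

  copresence <- matrix(0L, n, n, dimnames = list(ids, ids))
  coassign <- lapply(k_range, function(k) copresence)
  names(coassign) <- as.character(k_range)
  for (it in seq_len(n_boot)) {
    uniq <- sort(unique(sample.int(n, n, replace = TRUE)))
    copresence[uniq, uniq] <- copresence[uniq, uniq] + 1L
    hc <- stats::hclust(stats::as.dist(D[uniq, uniq]), method = "ward.D")
    for (k in k_range) {
      if (k > length(uniq)) next
      lab <- stats::cutree(hc, k = k)
      same <- outer(lab, lab, "==")
      key <- as.character(k)
      coassign[[key]][uniq, uniq] <- coassign[[key]][uniq, uniq] + same
    }
  }
  if (any(diag(copresence) == 0))
    stop("some samples were never resampled; increase n_boot")

  cocluster <- lapply(coassign, function(ca) {
    f <- ca / pmax(copresence, 1L)
    f[copresence == 0] <- NA_real_
    f
  })

  labels_by_k <- list()
  stability_by_k <- list()
  for (k in k_range) {
    key <- as.character(k)
    f <- cocluster[[key]]
    f0 <- f
    f0[is.na(f0)] <- 0
    Do <- if (outer_distance == "pearson") 1 - stats::cor(f0) else 1 - f0
    hc <- stats::hclust(stats::as.dist(Do), method = "ward.D")
    lab <- stats::cutree(hc, k = k)
    names(lab) <- ids
    labels_by_k[[key]] <- lab
    stability_by_k[[key]] <- cluster_stability(f0, lab)
  }

  structure(list(cocluster_freq = cocluster, copresence_count = copresence,
                 labels_by_k = labels_by_k, stability_by_k = stability_by_k,
                 k_range = k_range, n_boot = n_boot, seed = seed),
            class = "consensus_result")
}

## Per-cluster consensus summaries: mean within-cluster co-clustering
## frequency, mean frequency to samples outside the cluster, their gap,
## and the cluster size.
cluster_stability <- function(freq, labels) {
  do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    inside <- labels == cl
    fin <- freq[inside, inside, drop = FALSE]
    within <- if (sum(inside) > 1) mean(fin[upper.tri(fin)]) else 1
    between <- if (any(!inside)) mean(freq[inside, !inside, drop = FALSE]) else 0
    data.frame(cluster = cl, size = sum(inside), within = within,
               between = between, gap = within - between)
  }))
}

#' Choose the number of epitypes from consensus diagnostics
#'
#' Flags each evaluated `k` as inadmissible when any cluster is smaller
#' than `min_cluster_size` or less stable than the thresholds, and returns
#' the largest admissible `k` (the solution with the largest number of
#' robust clusters). Stability is assessed per cluster from the
#' co-clustering frequencies: the mean within-cluster consensus must reach
#' `min_within`, and the gap between within- and between-cluster consensus
#' must reach `min_gap`.
#'
#' @param consensus a [bootstrap_consensus()] result.
#' @param min_cluster_size minimum admissible cluster size.
#' @param min_within minimum per-cluster mean within-cluster consensus.
#' @param min_gap minimum per-cluster within-minus-between consensus gap.
#' @return list of class `k_choice`: `k` (the chosen value; `NA` with all
#'   diagnostics when no k is admissible), `admissible`, and a per-k
#'   `diagnostics` data frame.
#' @export
choose_k <- function(consensus, min_cluster_size = 5L, min_within = 0.8,
                     min_gap = 0.6) {
  stopifnot(inherits(consensus, "consensus_result"))
  diag_rows <- lapply(consensus$k_range, function(k) {
    st <- consensus$stability_by_k[[as.character(k)]]
    data.frame(k = k, min_size = min(st$size), min_within = min(st$within),
               min_gap = min(st$gap),
               admissible = min(st$size) >= min_cluster_size &
                 min(st$within) >= min_within & min(st$gap) >= min_gap)
  })
  diagnostics <- do.call(rbind, diag_rows)
  admissible <- diagnostics$k[diagnostics$admissible]
  k <- if (length(admissible)) max(admissible) else NA_integer_
  structure(list(k = k, admissible = admissible, diagnostics = diagnostics),
            class = "k_choice")
}

#' @export
print.k_choice <- function(x, ...) {
  if (is.na(x$k)) cat("no admissible number of clusters\n")
  else cat(sprintf("chosen k = %d (admissible: %s)\n", x$k,
                   paste(x$admissible, collapse = ", ")))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Build epitype centroids from cluster labels
#'
#' The centroid of an epitype is the per-CpG mean beta value over its
#' member tumors (missing values excluded per site). When a normal-cohort
#' reference profile is supplied, epitypes are relabeled ET1..ETk in order
#' of decreasing Pearson correlation between centroid and reference, so
#' the most normal-like cluster becomes ET1.
#'
#' @param beta [beta_matrix()] over the model CpG sites.
#' @param labels per-sample cluster labels (named by sample id, or in
#'   column order).
#' @param normal_profile optional per-probe mean beta of the normal cohort,
#'   used to order the epitypes.
#' @return list of class `epitype_model`: `centroids` (probes x epitypes),
#'   `epitype_order`, `cluster_map` (input label -> epitype name),
#'   `n_training`.
#' @export
build_centroids <- function(beta, labels, normal_profile = NULL) {
  b <- as_beta(beta)
  if (!is.null(names(labels))) {
    if (!all(colnames(b) %in% names(labels)))
      stop("labels missing for some samples")
    labels <- labels[colnames(b)]
  } else if (length(labels) != ncol(b)) {
    stop("labels must match the number of samples")
  }
  groups <- sort(unique(as.character(labels)))
  if (any(table(labels) == 0)) stop("empty epitype")
  centroids <- vapply(groups, function(g)
    rowMeans(b[, labels == g, drop = FALSE], na.rm = TRUE),
    numeric(nrow(b)))
  rownames(centroids) <- rownames(b)
  if (!is.null(normal_profile)) {
    r <- cor_to_columns(normal_profile[rownames(b)], centroids)
    ord <- order(r, decreasing = TRUE)
    centroids <- centroids[, ord, drop = FALSE]
    cluster_map <- stats::setNames(paste0("ET", seq_along(groups)), groups[ord])
    colnames(centroids) <- paste0("ET", seq_along(groups))
  } else {
    cluster_map <- stats::setNames(groups, groups)
  }
  structure(list(centroids = centroids, epitype_order = colnames(centroids),
                 cluster_map = cluster_map,
                 n_training = as.integer(table(labels)[names(cluster_map)])),
            class = "epitype_model")
}

#' @export
print.epitype_model <- function(x, ...) {
  cat(sprintf("epitype model: %d CpG sites, %d epitypes (%s)\n",
              nrow(x$centroids), ncol(x$centroids),
              paste(x$epitype_order, collapse = ", ")))
  invisible(x)
}

#' Classify samples by nearest correlation to epitype centroids
#'
#' Computes the Pearson correlation between each sample's beta profile and
#' every epitype centroid over the sites non-missing in both, and assigns
#' the sample to the centroid with the largest correlation. Exact ties are
#' broken deterministically by the first label in the model's epitype
#' order.
#'
#' @param beta [beta_matrix()] (or matrix/vector) over the model sites.
#' @param model an [build_centroids()] result.
#' @param min_overlap minimum number of sites non-missing in both sample
#'   and centroid before a correlation is accepted.
#' @return data frame with one row per sample: `label`, `best_cor`,
#'   `margin` (best minus second-best correlation), plus one correlation
#'   column per epitype.
#' @export
classify_by_centroid <- function(beta, model, min_overlap = 100L) {
  stopifnot(inherits(model, "epitype_model"))
  b <- as_beta(beta)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1, dimnames = list(names(b), "sample"))
  idx <- match(rownames(model$centroids), rownames(b))
  if (anyNA(idx)) stop("sample profiles lack some model sites")
  b <- b[idx, , drop = FALSE]
  res <- lapply(seq_len(ncol(b)), function(j) {
    x <- b[, j]
    ok_n <- min(colSums(!is.na(model$centroids) & !is.na(x)))
    if (ok_n < min_overlap)
      stop(sprintf("sample %s: only %d sites overlap the model (minimum %d)",
                   colnames(b)[j], ok_n, min_overlap))
    if (stats::sd(x, na.rm = TRUE) == 0)
      stop(sprintf("sample %s: zero variance over model sites", colnames(b)[j]))
    r <- cor_to_columns(x, model$centroids, min_pairs = min_overlap)
    names(r) <- colnames(model$centroids)
    best <- which(r == max(r))[1]          # ties: first label in order
    sec <- if (length(r) > 1) max(r[-best]) else r[best]
    c(list(label = names(r)[best], best_cor = unname(r[best]),
           margin = unname(r[best] - sec)), as.list(r))
  })
  out <- do.call(rbind, lapply(res, function(x) as.data.frame(x, stringsAsFactors = FALSE)))
  out <- cbind(data.frame(sample_id = colnames(b), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
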