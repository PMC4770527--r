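## Genomic-context annotation of CpG sites. Coordinates: probe positions
## are 1-based (Illumina-style annotation); BED-style interval inputs are
## 0-based half-open and converted on read.

#' Read a BED-style interval track
#'
#' Minimal BED reader (chrom, start, end, and optionally a name column used
#' as the interval label). BED coordinates are 0-based half-open and are
#' converted to the 1-based closed convention of GRanges.
#'
#' @param path BED file (plain text, no header).
#' @param label_col which extra column holds the label (default the BED
#'   name field, column 4); `NA` for none.
#' @return a `GRanges` with metadata column `label` when present.
#' @export
read_bed_track <- function(path, label_col = 4L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(start = df[[2]] + 1L,
                                                end = df[[3]]))
  if (!is.na(label_col) && ncol(df) >= label_col)
    S4Vectors::mcols(gr)$label <- df[[label_col]]
  gr
}

probes_as_granges <- function(probes) {
  if (methods::is(probes, "GRanges")) return(probes)
  GenomicRanges::GRanges(probes$chrom,
                         IRanges::IRanges(probes$pos, width = 1L))
}

#' Map CpG sites to genomic context
#'
#' Assigns each probe the label of the covering interval in every supplied
#' state track (per cell type), flags overlap with peak and repeat tracks,
#' and tabulates per-track label fractions over the assigned probes.
#' Uncovered probes (including probes on chromosomes absent from a track)
#' are `unassigned` and counted separately; fractions are computed over the
#' assigned probes only, so they sum to 1.
#'
#' @param probes data frame with `probe_id`, `chrom`, `pos` (1-based), or a
#'   named `GRanges`.
#' @param state_tracks named list of `GRanges` with a `label` metadata
#'   column (e.g. 15-state chromatin segmentations per cell type).
#' @param overlap_tracks named list of `GRanges` for binary overlap flags
#'   (peaks, repeats).
#' @return list of class `context_profile`: `assignments` (data frame, one
#'   state column per track and one logical column per overlap track),
#'   `fractions` (named list of per-track label fraction tables),
#'   `n_unassigned` per track.
#' @export
annotate_context <- function(probes, state_tracks = list(),
                             overlap_tracks = list()) {
  gr <- probes_as_granges(probes)
  ids <- if (!is.null(probes$probe_id)) probes$probe_id else names(gr)
  out <- data.frame(probe_id = ids, stringsAsFactors = FALSE)
  fractions <- list()
  n_unassigned <- integer(0)
  for (nm in names(state_tracks)) {
    trk <- state_tracks[[nm]]
    hits <- GenomicRanges::findOverlaps(gr, trk, select = "first")
    lab <- ifelse(is.na(hits), NA_character_,
                  S4Vectors::mcols(trk)$label[hits])
    out[[nm]] <- lab
    assigned <- lab[!is.na(lab)]
    fractions[[nm]] <- if (length(assigned))
      table(assigned) / length(assigned) else table(character(0))
    n_unassigned[nm] <- sum(is.na(lab))
  }
  for (nm in names(overlap_tracks)) {
    out[[nm]] <- IRanges::overlapsAny(gr, overlap_tracks[[nm]])
  }
  structure(list(assignments = out, fractions = fractions,
                 n_unassigned = n_unassigned),
            class = "context_profile")
}

#' Repeat-class enrichment of a CpG set
#'
#' Tests whether a target CpG set overlaps a repeat class (e.g. LINE/LTR
#' elements) more often than a background set, by a two-sided Fisher's
#' exact test on the 2x2 table (in repeat vs not) x (target vs background).
#' A probe covered by several repeat intervals counts once. The default
#' background is all non-target probes.
#'
#' @param target data frame (or `GRanges`) of target probes.
#' @param background data frame of background probes; rows also present in
#'   `target` (by `probe_id`) are removed unless
#'   `background_includes_target`.
#' @param repeats `GRanges` of repeat intervals, with a `label` metadata
#'   column when `classes` should be filtered.
#' @param classes repeat classes counted as "in repeat"; `NULL` for all.
#' @param background_includes_target keep target probes in the background
#'   (platform-wide background)?
#' @return list: `table` (2x2 counts), `odds_ratio` (sample odds ratio),
#'   `p_value` (two-sided Fisher).
#' @export
repeat_enrichment <- function(target, background, repeats,
                              classes = c("LINE", "LTR"),
                              background_includes_target = FALSE) {
  if (!is.null(classes) && !is.null(S4Vectors::mcols(repeats)$label))
    repeats <- repeats[S4Vectors::mcols(repeats)$label %in% classes]
  if (!background_includes_target && !is.null(background$probe_id) &&
      !is.null(target$probe_id))
    background <- background[!background$probe_id %in% target$probe_id, ,
                             drop = FALSE]
  in_t <- IRanges::overlapsAny(probes_as_granges(target), repeats)
  in_b <- IRanges::overlapsAny(probes_as_granges(background), repeats)
  tab <- matrix(c(sum(in_t), sum(!in_t), sum(in_b), sum(!in_b)), nrow = 2,
                dimnames = list(c("in_repeat", "not_in_repeat"),
                                c("target", "background")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in enrichment table")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, p_value = ft$p.value)
}

#' Subtelomeric enrichment and chromosome-end distances
#'
#' Computes each probe's distance to the nearest chromosome end (on the
#' 0-based scale: `min(pos - 1, length - pos + 1)`), the fraction of
#' probes within `window` of an end for the target versus the remaining
#' platform probes, and a two-sided two-sample t test comparing the
#' distances.
#'
#' @param target data frame of target probes (`probe_id`, `chrom`, `pos`).
#' @param platform data frame of all platform probes.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window subtelomere window in bp (default 5 Mb).
#' @return list: `fraction_target`, `fraction_background`, `t_statistic`,
#'   `p_value`, `distances` (per-probe, named list for target and
#'   background).
#' @export
subtelomere_stats <- function(target, platform, chrom_lengths,
                              window = 5e6) {
  end_distance <- function(df) {
    len <- chrom_lengths[df$chrom]
    if (anyNA(len)) stop("chromosome absent from chrom_lengths")
    pos0 <- df$pos - 1
    if (any(pos0 < 0) || any(pos0 > len))
      stop("probe position outside chromosome bounds")
    pmin(pos0, len - pos0)
  }
  bg <- platform[!platform$probe_id %in% target$probe_id, , drop = FALSE]
  dt <- end_distance(target)
  db <- end_distance(bg)
  if (length(dt) >= 2 && length(db) >= 2) {
    tt <- stats::t.test(dt, db, alternative = "two.sided")
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    t_stat <- NA_real_; p <- NA_real_
  }
  list(fraction_target = mean(dt <= window),
       fraction_background = mean(db <= window),
       t_statistic = t_stat, p_value = p,
       distances = list(target = dt, background = db))
}
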