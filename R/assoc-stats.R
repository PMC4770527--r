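#' Association test between epitype labels and a variable
#'
#' Categorical variables are tested with a chi-squared test on the
#' contingency table without continuity correction (df = groups - 1 for a
#' k x 2 table), falling back to Fisher's exact test when any expected
#' cell count is below 5. Continuous variables are tested with the
#' Kruskal--Wallis rank-sum test across groups. All p values are
#' two-sided.
#'
#' @param labels group labels (epitypes).
#' @param variable the tested variable, categorical or numeric.
#' @param kind `"auto"` (numeric -> continuous), `"categorical"` or
#'   `"continuous"`.
#' @param exact_when_expected_below expected-count threshold triggering
#'   Fisher's exact test.
#' @return list: `test` (name used), `statistic`, `df` (NA for exact
#'   tests), `p_value`, `table` (for categorical tests).
#' @export
assoc_test <- function(labels, variable, kind = c("auto", "categorical",
                                                  "continuous"),
                       exact_when_expected_below = 5) {
  kind <- match.arg(kind)
  ok <- !is.na(labels) & !is.na(variable)
  labels <- labels[ok]; variable <- variable[ok]
  if (length(unique(labels)) < 2) stop("need at least 2 groups with data")
  if (kind == "auto")
    kind <- if (is.numeric(variable)) "continuous" else "categorical"
  if (kind == "continuous") {
    kw <- stats::kruskal.test(variable, factor(labels))
    return(list(test = "kruskal-wallis", statistic = unname(kw$statistic),
                df = unname(kw$parameter), p_value = kw$p.value,
                table = NULL))
  }
  tab <- table(labels, variable)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < exact_when_expected_below)) {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(test = "fisher", statistic = NA_real_, df = NA_real_,
         p_value = ft$p.value, table = tab)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test = "chi-squared", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value, table = tab)
  }
}

#' FDR-controlled feature screen across groups
#'
#' Tests each feature (row) for association with the group labels,
#' adjusts p values over the tested features with the Benjamini--Hochberg
#' step-up procedure, and reports the significant set at the requested FDR
#' level. Features can be pre-filtered by a minimum positive count (e.g.
#' genes mutated in at least 5 tumors for a binary mutation matrix).
#'
#' @param features features x samples matrix (numeric, or logical for the
#'   chi-squared test).
#' @param labels per-sample group labels.
#' @param test `"kruskal"` (k groups, numeric), `"wilcoxon"` (2 groups,
#'   numeric) or `"chisq"` (binary features, k x 2 tables without
#'   continuity correction).
#' @param fdr_level FDR threshold for the significant set.
#' @param min_count minimum number of positive (`TRUE`/nonzero) samples a
#'   feature needs to be tested; applies to binary features.
#' @return data frame of class `screen_result` with per-feature
#'   `statistic`, `p`, `q` (BH-adjusted) and `significant`.
#' @export
screen_features <- function(features, labels, test = c("kruskal", "wilcoxon",
                                                       "chisq"),
                            fdr_level = 0.05, min_count = 0L) {
  test <- match.arg(test)
  features <- as.matrix(features)
  if (length(labels) != ncol(features))
    stop("labels must match the feature matrix columns")
  if (min_count > 0) {
    pos <- rowSums(features != 0 & !is.na(features), na.rm = TRUE)
    features <- features[pos >= min_count, , drop = FALSE]
  }
  if (nrow(features) == 0) stop("no features left after filtering")
  f <- factor(labels)
  res <- t(apply(features, 1, function(x) {
    ok <- !is.na(x)
    tryCatch({
      switch(test,
             kruskal = {
               kt <- stats::kruskal.test(x[ok], f[ok])
               c(unname(kt$statistic), kt$p.value)
             },
             wilcoxon = {
               lv <- levels(droplevels(f[ok]))
               if (length(lv) != 2) stop("wilcoxon needs exactly 2 groups")
               wt <- suppressWarnings(
                 stats::wilcox.test(x[ok][f[ok] == lv[1]],
                                    x[ok][f[ok] == lv[2]]))
               c(unname(wt$statistic), wt$p.value)
             },
             chisq = {
               ct <- suppressWarnings(
                 stats::chisq.test(table(f[ok], x[ok] != 0), correct = FALSE))
               c(unname(ct$statistic), ct$p.value)
             })
    }, error = function(e) c(NA_real_, NA_real_))
  }))
  out <- data.frame(feature = rownames(features), statistic = res[, 1],
                    p = res[, 2], stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q <= fdr_level
  class(out) <- c("screen_result", class(out))
  out
}

#' Kaplan--Meier curves and log-rank comparison across epitypes
#'
#' Estimates the survival function per group with the Kaplan--Meier
#' estimator and compares groups with the k-sample log-rank test (standard
#' hypergeometric variance with ties). Follow-up can be administratively
#' truncated: events after the horizon become censored at the horizon.
#' When several samples share a patient, the first record per patient (in
#' table order) is kept.
#'
#' @param clinical data frame with `sample_id`, `time_years`, `event`
#'   (0/1) and optionally `patient_id`.
#' @param labels per-sample group labels (named by sample id, or parallel
#'   to `clinical`).
#' @param truncate_years optional follow-up horizon.
#' @return list of class `survival_comparison`: `fit` (a
#'   [survival::survfit] object), `curves` (per-group data frames of time,
#'   at-risk and survival), `chisq`, `df`, `p_value`, `n` per group.
#' @export
survival_logrank <- function(clinical, labels, truncate_years = NULL) {
  if (!is.null(names(labels)))
    labels <- labels[clinical$sample_id]
  if (length(labels) != nrow(clinical))
    stop("labels must cover the clinical table")
  df <- data.frame(time = clinical$time_years, event = clinical$event,
                   group = as.character(labels),
                   stringsAsFactors = FALSE)
  if (!is.null(clinical$patient_id))
    df <- df[!duplicated(clinical$patient_id), , drop = FALSE]
  df <- df[!is.na(df$time) & !is.na(df$event) & !is.na(df$group), ,
           drop = FALSE]
  if (any(df$time < 0)) stop("negative survival times")
  if (!is.null(truncate_years)) {
    over <- df$time > truncate_years
    df$event[over] <- 0L
    df$time[over] <- truncate_years
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (length(unique(df$group)) > 1) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    chisq <- unname(sd$chisq)
    df_test <- length(sd$n) - 1
    p <- stats::pchisq(chisq, df = df_test, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; df_test <- 0L; p <- NA_real_
  }
  strata <- rep(names(fit$strata) %||% "group=all", fit$strata %||% length(fit$time))
  curves <- split(data.frame(time = fit$time, n_risk = fit$n.risk,
                             n_event = fit$n.event, survival = fit$surv),
                  strata)
  names(curves) <- sub("^group=", "", names(curves))
  structure(list(fit = fit, curves = curves, chisq = chisq,
                 df = df_test, p_value = p,
                 n = table(df$group)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f on %d df, p = %.3g\n",
              x$chisq, x$df, x$p_value))
  print(x$n)
  invisible(x)
}
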