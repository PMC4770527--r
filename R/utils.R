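#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncated-normal draws on [0, 1]
#'
#' Inverse-CDF sampler for a normal distribution truncated to the unit
#' interval. Used for all beta-value noise in the synthetic cohort generator:
#' the sd is interpreted on the beta scale, and truncation (rather than
#' clipping) keeps draws in [0, 1] with light tails on both sides.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the untruncated normal. Vectors are
#'   recycled against `n`.
#' @return numeric vector of length `n` with values in [0, 1].
#' @keywords internal
rtrunc01 <- function(n, mean, sd) {
  if (any(sd < 0)) stop("sd must be non-negative")
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  u <- stats::runif(n, lo, hi)
  x <- stats::qnorm(u, mean, sd)
  pmin(pmax(x, 0), 1)
}

## Pairwise-complete Pearson correlation between a vector and each column of
## a matrix; returns NA where fewer than min_pairs observations overlap.
cor_to_columns <- function(x, m, min_pairs = 3L) {
  vapply(seq_len(ncol(m)), function(j) {
    y <- m[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
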