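## Independent oracles used across test files.

## Two-sided Fisher exact p by exhaustive hypergeometric enumeration over
## all 2x2 tables with the observed margins: sum of probabilities of tables
## no more likely than the observed one (relative tolerance as in the
## standard exact-test convention).
fisher_p_enumeration <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

## Benjamini-Hochberg step-up by hand: q_i = min over j >= rank(i) of
## p_(j) * m / j, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Adjusted Rand index between two labelings (via mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## KDE mode of a beta-value vector on the normalizer's grid.
kde_mode <- function(x, lower = 0, upper = 1, bw = 0.04, n = 1001) {
  d <- stats::density(x[!is.na(x)], bw = bw, kernel = "epanechnikov",
                      from = lower, to = upper, n = n)
  d$x[which.max(d$y)]
}

## Clamped-normal draws for constructing test beta vectors (independent of
## the package's truncated-normal sampler).
rclamp01 <- function(n, mean, sd) pmin(pmax(stats::rnorm(n, mean, sd), 0), 1)
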