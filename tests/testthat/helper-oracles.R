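## Independent oracles used to cross-check the package's algorithms.
## These deliberately re-derive results by brute force or closed form and
## share no code with the implementation under test.

## Exhaustive penalized change-point search: enumerate every placement of
## 0..max_cp boundaries (minimum segment length respected), score each by
## SSE + penalty * n_cp, return the best (ties -> fewer change points).
## Boundaries are 0-based "change after sample s", as in the package.
oracle_segment_exhaustive <- function(x, beta, minseg = 2L, max_cp = 4L) {
  n <- length(x)
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  segcost <- function(s, t) (S2[t + 1] - S2[s + 1]) -
    (S1[t + 1] - S1[s + 1])^2 / (t - s)
  best <- list(cost = segcost(0, n), bounds = integer(0))
  positions <- seq(minseg, n - minseg)
  for (k in seq_len(max_cp)) {
    if (length(positions) < k) break
    combs <- utils::combn(positions, k)
    if (k > 1)
      combs <- combs[, apply(combs, 2, function(b) all(diff(b) >= minseg)),
                     drop = FALSE]
    if (!ncol(combs)) next
    edges <- rbind(0L, combs, n)              # (k+2) x M boundary matrix
    cost <- rep(beta * k, ncol(combs))
    for (i in seq_len(k + 1)) {               # vectorized over placements
      s <- edges[i, ]; t <- edges[i + 1, ]
      cost <- cost + (S2[t + 1] - S2[s + 1]) -
        (S1[t + 1] - S1[s + 1])^2 / (t - s)
    }
    j <- which.min(cost)
    if (cost[j] < best$cost - 1e-9 - 1e-12 * abs(best$cost))
      best <- list(cost = cost[j], bounds = combs[, j])
  }
  best
}

## Brute-force Costes threshold scan: total-least-squares fit via
## eigen-decomposition (a different route from the implementation), then
## evaluate the below-threshold correlation at EVERY unique intensity of
## channel a in descending order and return the first non-positive
## crossing.
oracle_costes_bruteforce <- function(a, b, mask) {
  av <- a[mask]; bv <- b[mask]
  cv <- stats::cov(cbind(av, bv))
  ev <- eigen(cv)$vectors[, 1]
  slope <- ev[2] / ev[1]
  intercept <- mean(bv) - slope * mean(av)
  cand <- sort(unique(av), decreasing = TRUE)
  rs <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    ta <- cand[i]; tb <- slope * ta + intercept
    sel <- av < ta & bv < tb
    if (sum(sel) < 2) next
    x <- av[sel]; y <- bv[sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    rs[i] <- stats::cor(x, y)
  }
  hit <- which(!is.na(rs) & rs <= 0)[1]
  if (is.na(hit) && stats::cor(av, bv) <= 0) hit <- 1L
  if (is.na(hit)) {
    list(threshold_a = min(av), threshold_b = slope * min(av) + intercept,
         crossed = FALSE)
  } else {
    list(threshold_a = cand[hit],
         threshold_b = slope * cand[hit] + intercept, crossed = TRUE)
  }
}

## Direct-summation Pearson correlation (explicit formula, no stats::cor).
oracle_pearson_direct <- function(av, bv) {
  n <- length(av)
  sxy <- sum(av * bv) - sum(av) * sum(bv) / n
  sxx <- sum(av^2) - sum(av)^2 / n
  syy <- sum(bv^2) - sum(bv)^2 / n
  sxy / sqrt(sxx * syy)
}

## Direct-summation Manders coefficients.
oracle_manders_direct <- function(av, bv, ta, tb) {
  list(m1 = sum(av[bv > tb]) / sum(av),
       m2 = sum(bv[av > ta]) / sum(bv))
}

## Closed-form per-stimulus amplitudes of the geometric depression
## recursion (independent re-derivation of the train model).
oracle_depression_closed_form <- function(a1, plateau_frac, tau, times) {
  p <- plateau_frac * a1
  p + (a1 - p) * exp(-(times - times[1]) / tau)
}
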