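## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || (if (strict) x <= 0 else x < 0))
    stop_field(field, if (strict) "must be > 0" else "must be >= 0")
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

#' Derive a child seed from a top-level seed
#'
#' Sub-generators (one per active zone, bouton or sweep) are seeded
#' independently so that adding one unit does not perturb the random
#' stream of the others. Child seeds stay within the 32-bit integer range.
#'
#' @param seed top-level integer seed.
#' @param index 1-based index of the sub-generator.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

## Separable Gaussian smoothing of a 2-D or 3-D array. `sigma` is given in
## voxels per axis (recycled); sigma = 0 on an axis skips that axis.
gauss_smooth <- function(x, sigma) {
  d <- dim(x)
  nd <- length(d)
  sigma <- rep(sigma, length.out = nd)
  for (ax in seq_len(nd)) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    x <- apply_along(x, ax, function(v) conv_same(v, k))
  }
  x
}

## 1-D convolution with replicate padding, output length == input length.
conv_same <- function(v, k) {
  r <- (length(k) - 1L) %/% 2L
  vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
  stats::filter(vp, k, sides = 2)[(r + 1L):(r + length(v))]
}

## Apply a vectorised function along axis `ax` of an array, keeping shape.
apply_along <- function(x, ax, f) {
  d <- dim(x)
  perm <- c(ax, seq_along(d)[-ax])
  y <- aperm(x, perm)
  dy <- dim(y)
  y <- matrix(y, nrow = dy[1])
  y <- apply(y, 2, f)
  dim(y) <- dy
  aperm(y, order(perm))
}

## Connected-component labelling of a logical 2-D/3-D array
## (6/4-connectivity), iterative flood fill. EBImage::bwlabel is 2-D only.
label_components <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  lab <- array(0L, d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  ## neighbour offsets in linear index space (+/- 1 along each axis)
  strides <- as.integer(cumprod(c(1L, d[-nd])))
  current <- 0L
  n <- prod(d)
  coords <- arrayInd(seq_len(n), d)
  queue <- integer(length(idx_all))
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue[1] <- start
    qh <- 1L; qt <- 1L
    lab[start] <- current
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      for (ax in seq_len(nd)) {
        for (dr in c(-1L, 1L)) {
          ci <- coords[p, ax] + dr
          if (ci < 1L || ci > d[ax]) next
          q <- p + dr * strides[ax]
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- current
            qt <- qt + 1L
            queue[qt] <- q
          }
        }
      }
    }
  }
  lab
}

## Exact 1-D k-means on sorted values by dynamic programming over
## contiguous partitions (deterministic; no RNG). Returns cluster
## assignment in the original order plus centers.
kmeans1d <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  segcost <- function(i, j) {           # SSE of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- segcost(1, j)
  if (k > 1) for (m in 2:k) for (j in m:n) {
    best <- Inf; bi <- 0L
    for (i in m:j) {
      c0 <- D[m - 1, i - 1] + segcost(i, j)
      if (c0 < best - 1e-12) { best <- c0; bi <- i }
    }
    D[m, j] <- best; B[m, j] <- bi
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  if (k > 1) for (m in k:2) { i <- B[m, j]; bounds[m] <- i - 1L; j <- i - 1L }
  bounds[1] <- 0L
  assign_sorted <- integer(n)
  centers <- numeric(k)
  for (m in 1:k) {
    seg <- (bounds[m] + 1L):bounds[m + 1]
    assign_sorted[seg] <- m
    centers[m] <- mean(xs[seg])
  }
  cl <- integer(n)
  cl[ord] <- assign_sorted
  list(cluster = cl, centers = centers, tot_withinss = D[k, n])
}

## Mean silhouette width for a 1-D clustering (singletons score 0).
silhouette1d <- function(x, cl) {
  k <- max(cl)
  n <- length(x)
  if (k < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- x[cl == cl[i]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(abs(x[i] - own)) / (length(own) - 1)
    b <- min(vapply(setdiff(seq_len(k), cl[i]),
                    function(m) mean(abs(x[i] - x[cl == m])), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
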