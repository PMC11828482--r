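## Shared fixture builders (all generated in code; no stored data).

## Piecewise-constant staircase trace with optional Gaussian noise.
## seg_len may be a vector (one length per level).
make_staircase <- function(levels, seg_len, noise_sd = 0, uv_onset = 1L,
                           frame_rate = 20) {
  x <- rep(levels, times = rep(seg_len, length.out = length(levels)))
  if (noise_sd > 0) x <- x + rnorm(length(x), 0, noise_sd)
  bleach_trace(x, times = (seq_along(x) - 1) / frame_rate,
               uv_onset_frame = uv_onset)
}

## Random short step traces for the segmentation oracle suite:
## n in [40, 60], 0..4 steps, mixed noise levels. Deterministic per id.
make_oracle_case <- function(id) {
  set.seed(9000 + id)
  n <- sample(40:60, 1)
  k <- sample(0:4, 1)
  bounds <- if (k > 0) sort(sample(seq(5, n - 5), k)) else integer(0)
  while (k > 1 && any(diff(bounds) < 5))
    bounds <- sort(sample(seq(5, n - 5), k))
  ## steps well above the noise floor so the penalized optimum keeps the
  ## true model order (the premise of the <= 4-step oracle comparison)
  steps <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 90, 250)
  levels <- cumsum(c(runif(1, 0, 500), steps))
  x <- rep(levels, diff(c(0, bounds, n)))
  noise_sd <- sample(c(0, 5, 12), 1)
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  list(x = x, true_bounds = bounds, noise_sd = noise_sd)
}

## Two-population image pair: correlated foreground block on independent
## uniform background; used for Costes and Manders checks. Intensities
## are quantized so the unique-value grid stays small.
make_coloc_pair <- function(seed, n = 64, quant = 0.5) {
  set.seed(seed)
  fg <- matrix(0, n, n)
  r0 <- sample(5:25, 1); c0 <- sample(5:25, 1)
  fg[r0:(r0 + 25), c0:(c0 + 25)] <- 1
  a <- matrix(runif(n * n, 0, 10), n, n) +
    fg * (40 + matrix(runif(n * n, 0, 30), n, n))
  b <- matrix(runif(n * n, 0, 10), n, n) + fg * (15 + 0.5 * a)
  a <- round(a / quant) * quant
  b <- round(b / quant) * quant
  list(a = a, b = b, mask = matrix(TRUE, n, n), fg = fg == 1)
}

## Single 3-D Gaussian spot at a known (possibly subvoxel) center.
make_spot_stack <- function(center_vox, amp = 100, sigma_vox = c(0.6, 1.2, 1.2),
                            dim3 = c(5, 32, 32), noise_sd = 0) {
  arr <- array(0, dim3)
  for (z in seq_len(dim3[1])) for (y in seq_len(dim3[2])) {
    x <- seq_len(dim3[3])
    arr[z, y, ] <- arr[z, y, ] + amp *
      exp(-0.5 * (((z - 1 - center_vox[1]) / sigma_vox[1])^2 +
                    ((y - 1 - center_vox[2]) / sigma_vox[2])^2 +
                    ((x - 1 - center_vox[3]) / sigma_vox[3])^2))
  }
  if (noise_sd > 0) arr <- arr + array(rnorm(prod(dim3), 0, noise_sd), dim3)
  arr
}

## Match detected puncta against truth; returns recall and precision at
## a voxel-space match radius.
match_puncta <- function(detected, truth_nm, voxel_size, radius = 2) {
  if (!nrow(detected)) return(c(recall = 0, precision = NA))
  dvox <- cbind(detected$z_nm / voxel_size[1], detected$y_nm / voxel_size[2],
                detected$x_nm / voxel_size[3])
  tvox <- cbind(truth_nm$z_nm / voxel_size[1], truth_nm$y_nm / voxel_size[2],
                truth_nm$x_nm / voxel_size[3])
  dmin_truth <- vapply(seq_len(nrow(tvox)), function(i)
    min(sqrt(rowSums((dvox - matrix(tvox[i, ], nrow(dvox), 3,
                                    byrow = TRUE))^2))), numeric(1))
  dmin_det <- vapply(seq_len(nrow(dvox)), function(i)
    min(sqrt(rowSums((tvox - matrix(dvox[i, ], nrow(tvox), 3,
                                    byrow = TRUE))^2))), numeric(1))
  c(recall = mean(dmin_truth <= radius), precision = mean(dmin_det <= radius))
}
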