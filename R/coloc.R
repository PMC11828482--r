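#' Build an analysis mask from a channel image
#'
#' Default method: Gaussian smoothing followed by Otsu thresholding on
#' the intensity histogram of all voxels, then removal of connected
#' components smaller than `min_size` voxels. Used to turn the HRP
#' membrane staining into the region within which colocalization and
#' intensity statistics are evaluated, and the brp staining into per-AZ
#' masks.
#'
#' @param image 2-D or 3-D numeric array (axis order `(z, y, x)` for
#'   stacks).
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param smooth_sigma smoothing SD in voxels (scalar or per axis).
#' @param min_size minimum connected-component size in voxels.
#' @param quantile_prob threshold quantile for `method = "quantile"`.
#' @return a logical array of the same shape, with attributes
#'   `threshold` and `provenance`.
#' @export
build_mask <- function(image, method = c("otsu", "quantile"),
                       smooth_sigma = 1, min_size = 9L,
                       quantile_prob = 0.95) {
  method <- match.arg(method)
  if (diff(range(image)) == 0) stop("cannot build a mask from a constant image")
  sm <- gauss_smooth(image, rep(smooth_sigma, length.out = length(dim(image))))
  if (method == "otsu") {
    ## EBImage::otsu works on the value histogram; feed it the scaled
    ## voxel values as one 2-D frame (arrangement is irrelevant).
    v <- as.numeric(sm)
    lo <- min(v); hi <- max(v)
    thr01 <- EBImage::otsu(matrix((v - lo) / (hi - lo), nrow = length(v)),
                           range = c(0, 1))
    thr <- lo + thr01 * (hi - lo)
  } else {
    thr <- stats::quantile(sm, quantile_prob, names = FALSE)
  }
  mask <- sm > thr
  if (min_size > 1 && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_size)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  if (!any(mask)) stop("mask empty after thresholding and cleanup")
  attr(mask, "threshold") <- thr
  attr(mask, "provenance") <- sprintf("method=%s smooth_sigma=%s min_size=%d",
                                      method, paste(smooth_sigma, collapse = ","),
                                      min_size)
  mask
}

#' Pearson correlation of two channels within a mask
#'
#' @param a,b numeric arrays of identical shape.
#' @param mask logical array of the same shape (non-empty).
#' @return the sample Pearson correlation over masked voxels, or `NA`
#'   with a `reason` attribute when undefined (fewer than 2 voxels or
#'   zero variance).
#' @export
pearson_within_mask <- function(a, b, mask) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(mask)))
  av <- a[mask]; bv <- b[mask]
  if (length(av) < 2)
    return(structure(NA_real_, reason = "fewer than 2 masked voxels"))
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    return(structure(NA_real_, reason = "zero variance in a channel"))
  stats::cor(av, bv)
}

## Orthogonal (total least squares) regression b ~ slope * a + intercept.
orthogonal_regression <- function(av, bv) {
  saa <- stats::var(av); sbb <- stats::var(bv); sab <- stats::cov(av, bv)
  slope <- if (abs(sab) < .Machine$double.eps) {
    0
  } else {
    (sbb - saa + sqrt((sbb - saa)^2 + 4 * sab^2)) / (2 * sab)
  }
  list(slope = slope, intercept = mean(bv) - slope * mean(av))
}

#' Automatic Costes thresholds for two channels
#'
#' Fits the orthogonal regression `b ~ slope * a + intercept` over masked
#' voxels, then scans candidate thresholds `T_a` downward through the
#' unique observed intensities of `a` with `T_b = slope * T_a +
#' intercept`, and returns the first pair at which the Pearson
#' correlation of the voxels *below both* thresholds falls to zero or
#' below. Voxels outside the mask never contribute. If the
#' below-threshold correlation never crosses zero, the minimum observed
#' intensities are returned with flag `"no Costes crossing"`.
#'
#' @inheritParams pearson_within_mask
#' @param max_candidates cap on the number of scanned thresholds. When
#'   the image holds more unique intensities (typical for float-valued
#'   stacks) the scan descends through an evenly decimated subset of the
#'   sorted unique values; below the cap every observed intensity is
#'   visited, so small test images are scanned exhaustively.
#' @return list with `threshold_a`, `threshold_b`, `slope`, `intercept`,
#'   `flag` (`NULL` or `"no Costes crossing"`).
#' @export
costes_thresholds <- function(a, b, mask, max_candidates = 1024L) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(mask)))
  av <- a[mask]; bv <- b[mask]
  if (length(av) < 3 || stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("Costes thresholds require >= 3 masked voxels with variance in both channels")
  reg <- orthogonal_regression(av, bv)
  ## channels that are globally anti-correlated have no positive
  ## association to threshold away: the crossing is immediate
  r_all <- stats::cor(av, bv)
  cand <- sort(unique(av), decreasing = TRUE)
  if (length(cand) > max_candidates)
    cand <- cand[unique(round(seq(1, length(cand),
                                  length.out = max_candidates)))]
  for (ta in cand) {
    tb <- reg$slope * ta + reg$intercept
    below <- av < ta & bv < tb
    if (sum(below) < 2) next
    x <- av[below]; y <- bv[below]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    if (r <= 0) {
      return(list(threshold_a = ta, threshold_b = tb,
                  slope = reg$slope, intercept = reg$intercept, flag = NULL))
    }
  }
  if (r_all <= 0) {
    ta <- cand[1]
    return(list(threshold_a = ta, threshold_b = reg$slope * ta + reg$intercept,
                slope = reg$slope, intercept = reg$intercept, flag = NULL))
  }
  list(threshold_a = min(av), threshold_b = reg$slope * min(av) + reg$intercept,
       slope = reg$slope, intercept = reg$intercept,
       flag = "no Costes crossing")
}

#' Manders co-occurrence coefficients within a mask
#'
#' `M1` is the fraction of channel `a`'s integrated masked intensity in
#' voxels where `b` exceeds its threshold; `M2` is symmetric. With
#' `thresholds = NULL` the coefficients are computed against zero (any
#' positive signal counts), the un-thresholded variant.
#'
#' @inheritParams pearson_within_mask
#' @param thresholds list with `threshold_a`, `threshold_b` (e.g. from
#'   [costes_thresholds()]), or `NULL`.
#' @return list with `m1`, `m2` (each `NA` with a reason attribute when
#'   the denominator is zero).
#' @export
manders_within_mask <- function(a, b, mask, thresholds = NULL) {
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(mask)))
  ta <- if (is.null(thresholds)) 0 else thresholds$threshold_a
  tb <- if (is.null(thresholds)) 0 else thresholds$threshold_b
  av <- a[mask]; bv <- b[mask]
  m1 <- if (sum(av) <= 0) {
    structure(NA_real_, reason = "zero integrated intensity in a")
  } else sum(av[bv > tb]) / sum(av)
  m2 <- if (sum(bv) <= 0) {
    structure(NA_real_, reason = "zero integrated intensity in b")
  } else sum(bv[av > ta]) / sum(bv)
  list(m1 = m1, m2 = m2)
}

#' Full masked colocalization analysis of two channels
#'
#' Pearson correlation, Costes thresholds and Manders coefficients of
#' two channels inside a membrane mask, as applied to cac and brp
#' stainings within the HRP mask.
#'
#' @inheritParams pearson_within_mask
#' @inheritParams costes_thresholds
#' @param thresholded compute Manders with Costes thresholds (default)
#'   or against zero.
#' @return a one-row data frame with `pearson_r`, `m1`, `m2`,
#'   `threshold_a`, `threshold_b`, `regression_slope`,
#'   `regression_intercept`, `n_voxels`, `flag`.
#' @export
coloc_within_mask <- function(a, b, mask, thresholded = TRUE,
                              max_candidates = 1024L) {
  r <- pearson_within_mask(a, b, mask)
  th <- costes_thresholds(a, b, mask, max_candidates = max_candidates)
  m <- manders_within_mask(a, b, mask, if (thresholded) th else NULL)
  data.frame(pearson_r = as.numeric(r), m1 = as.numeric(m$m1),
             m2 = as.numeric(m$m2),
             threshold_a = th$threshold_a, threshold_b = th$threshold_b,
             regression_slope = th$slope, regression_intercept = th$intercept,
             n_voxels = sum(mask), flag = th$flag %||% "")
}
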