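#' Per-AZ bleaching trace
#'
#' Background-subtracted summed ROI intensity of one active zone over a
#' photoconversion/bleaching movie.
#'
#' @param intensity numeric per-frame intensity (a.u.).
#' @param times frame times (s).
#' @param uv_onset_frame 1-based photoconversion onset frame.
#' @param roi_center optional `(row, col)` of the ROI.
#' @param roi_size ROI side length in pixels.
#' @return a `bleach_trace` object.
#' @export
bleach_trace <- function(intensity, times = NULL, uv_onset_frame = 1L,
                         roi_center = NULL, roi_size = 5L) {
  stopifnot(is.numeric(intensity), length(intensity) >= 2)
  if (is.null(times)) times <- seq_along(intensity) - 1
  stopifnot(length(times) == length(intensity))
  if (uv_onset_frame < 1 || uv_onset_frame > length(intensity))
    stop_field("uv_onset_frame", "outside trace")
  structure(list(intensity = as.numeric(intensity), times = as.numeric(times),
                 uv_onset_frame = as.integer(uv_onset_frame),
                 roi_center = roi_center, roi_size = roi_size),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("bleach_trace: %d frames, UV onset %d, range [%.1f, %.1f] a.u.\n",
              length(x$intensity), x$uv_onset_frame,
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Correct rigid lateral drift of a movie
#'
#' Estimates a per-frame `(dy, dx)` translation by cross-correlating each
#' frame against the temporal-median image (computed once), refines the
#' correlation peak to subpixel precision by parabolic interpolation, and
#' re-registers each frame by bilinear interpolation. The returned shifts
#' are the translations *applied* to each frame, i.e. the negated
#' estimated drift.
#'
#' @param movie an `az_movie`.
#' @return list with the corrected `movie` and `shifts`, an
#'   `n_frames x 2` matrix of applied `(dy, dx)` in pixels.
#' @export
correct_drift <- function(movie) {
  stopifnot(inherits(movie, "az_movie"))
  fr <- movie$frames
  nf <- dim(fr)[1]
  if (nf < 2) stop("drift correction needs at least 2 frames")
  if (all(fr == 0)) {
    warning("all-zero movie; drift correction skipped")
    return(list(movie = movie, shifts = matrix(0, nf, 2,
                                               dimnames = list(NULL, c("dy", "dx")))))
  }
  ref <- apply(fr, c(2, 3), stats::median)
  ref_c <- ref - mean(ref)
  ref_norm <- sqrt(sum(ref_c^2))
  Fref <- stats::fft(ref_c)
  d <- dim(ref)
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- fr
  for (t in seq_len(nf)) {
    frame <- fr[t, , ]
    if (stats::sd(frame) == 0) next
    frame_c <- frame - mean(frame)
    cc <- Re(stats::fft(Fref * Conj(stats::fft(frame_c)),
                        inverse = TRUE)) / length(frame)
    pk <- arrayInd(which.max(cc), d)
    ## frames that barely correlate with the reference (e.g. pure noise
    ## before photoconversion) carry no registration information: leave
    ## them untouched rather than chase a spurious peak
    ncc <- max(cc) / (ref_norm * sqrt(sum(frame_c^2)) + .Machine$double.xmin)
    if (!is.finite(ncc) || ncc < 0.2) next
    sh <- numeric(2)
    for (ax in 1:2) {
      i <- pk[ax]
      ## wrap to signed shift and refine with a 3-point parabola
      im <- if (i == 1) d[ax] else i - 1
      ip <- if (i == d[ax]) 1 else i + 1
      y0 <- if (ax == 1) cc[im, pk[2]] else cc[pk[1], im]
      y1 <- cc[pk[1], pk[2]]
      y2 <- if (ax == 1) cc[ip, pk[2]] else cc[pk[1], ip]
      denom <- y0 - 2 * y1 + y2
      frac <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
      frac <- max(min(frac, 0.5), -0.5)
      s <- (i - 1) + frac
      if (s > d[ax] / 2) s <- s - d[ax]
      sh[ax] <- s
    }
    ## the peak at s means frame ~ ref translated by +s; undo it
    shifts[t, ] <- sh
    out[t, , ] <- translate_bilinear(frame, sh[1], sh[2])
  }
  list(movie = az_movie(out, movie$frame_interval, movie$pixel_size,
                        movie$uv_onset_frame),
       shifts = shifts)
}

## Translate an image by (dy, dx) with bilinear interpolation and
## replicate edges: out(r, c) = img(r - dy, c - dx).
translate_bilinear <- function(img, dy, dx) {
  d <- dim(img)
  r <- pmin(pmax(seq_len(d[1]) - dy, 1), d[1])
  c <- pmin(pmax(seq_len(d[2]) - dx, 1), d[2])
  r0 <- floor(r); r1 <- pmin(r0 + 1, d[1]); fr <- r - r0
  c0 <- floor(c); c1 <- pmin(c0 + 1, d[2]); fc <- c - c0
  img[r0, c0] * outer(1 - fr, 1 - fc) +
    img[r1, c0] * outer(fr, 1 - fc) +
    img[r0, c1] * outer(1 - fr, fc) +
    img[r1, c1] * outer(fr, fc)
}

#' Extract a background-subtracted ROI intensity trace
#'
#' Sums intensity over a square window (default 5 x 5 px) centred on an
#' AZ and subtracts, per frame, the local background estimated as the
#' mean over a square annulus around the window (default: pixels inside
#' the 9 x 9 but outside the 5 x 5 box), scaled to the ROI area.
#'
#' @param movie an `az_movie`.
#' @param center `(row, col)` pixel coordinates (1-based) of the AZ.
#' @param roi_size ROI side length (odd, default 5).
#' @param bg_inner,bg_outer inner/outer side lengths of the background
#'   annulus (odd; inner defaults to the ROI size).
#' @return a [bleach_trace()].
#' @export
extract_roi_trace <- function(movie, center, roi_size = 5L,
                              bg_inner = 5L, bg_outer = 9L) {
  stopifnot(inherits(movie, "az_movie"))
  d <- dim(movie$frames)
  hw <- (roi_size - 1) %/% 2
  ctr <- round(center)
  if (ctr[1] - hw < 1 || ctr[1] + hw > d[2] || ctr[2] - hw < 1 || ctr[2] + hw > d[3])
    stop(sprintf("ROI of %d x %d px around (%d, %d) falls outside the image",
                 roi_size, roi_size, ctr[1], ctr[2]))
  rows <- (ctr[1] - hw):(ctr[1] + hw)
  cols <- (ctr[2] - hw):(ctr[2] + hw)
  ho <- (bg_outer - 1) %/% 2
  hi <- (bg_inner - 1) %/% 2
  brows <- max(1, ctr[1] - ho):min(d[2], ctr[1] + ho)
  bcols <- max(1, ctr[2] - ho):min(d[3], ctr[2] + ho)
  ann <- outer(abs(brows - ctr[1]), abs(bcols - ctr[2]), pmax) > hi
  roi_sum <- apply(movie$frames[, rows, cols, drop = FALSE], 1, sum)
  bg <- vapply(seq_len(d[1]), function(t)
    mean(movie$frames[t, brows, bcols][ann]), numeric(1))
  intensity <- roi_sum - bg * roi_size^2
  bleach_trace(intensity,
               times = (seq_len(d[1]) - 1) * movie$frame_interval,
               uv_onset_frame = movie$uv_onset_frame,
               roi_center = ctr, roi_size = roi_size)
}

## Penalized least-squares change-point segmentation (PELT; exact for
## this objective). x: numeric; beta: penalty per change point;
## minseg: minimum segment length. Ties resolved toward fewer change
## points. Returns 0-based boundary positions (change after sample s).
pelt_segment <- function(x, beta, minseg = 2L) {
  n <- length(x)
  S1 <- c(0, cumsum(x)); S2 <- c(0, cumsum(x^2))
  F <- rep(Inf, n + 1); F[1] <- -beta
  cnt <- integer(n + 1)
  prev <- integer(n + 1)
  cand <- 0L
  for (t in seq_len(n)) {
    valid <- cand[t - cand >= minseg]
    if (length(valid)) {
      len <- t - valid
      cost <- (S2[t + 1] - S2[valid + 1]) - (S1[t + 1] - S1[valid + 1])^2 / len
      tot <- F[valid + 1] + cost + beta
      m <- min(tot)
      near <- which(tot <= m + 1e-9 * max(1, abs(m)))
      bi <- near[which.min(cnt[valid[near] + 1])]
      F[t + 1] <- tot[bi]
      prev[t + 1] <- valid[bi]
      cnt[t + 1] <- cnt[valid[bi] + 1] + 1L
      keep <- F[valid + 1] + cost <= F[t + 1]
      cand <- c(valid[keep], cand[t - cand < minseg])
    }
    cand <- c(cand, t)
  }
  bounds <- integer(0)
  s <- prev[n + 1]
  t <- n
  while (t > 0 && s > 0) {
    bounds <- c(s, bounds)
    t <- s
    s <- prev[t + 1]
  }
  bounds
}

#' Detect intensity steps in a bleaching trace
#'
#' Fits a piecewise-constant model to the trace by penalized
#' least-squares change-point segmentation (exact pruned dynamic
#' programming). The default penalty is `2 * sigma^2 * log(n)` with the
#' noise SD estimated robustly from the median absolute first
#' differences; ties are broken toward fewer change points.
#'
#' @param trace a [bleach_trace()].
#' @param penalty positive penalty per change point; `NULL` uses the
#'   default above.
#' @param min_seg minimum segment length in frames.
#' @return a `step_model`: `change_points` (1-based first frame of each
#'   new segment), `segment_levels` (per-segment means), `step_amplitudes`
#'   (signed level differences), `sigma_hat`, `penalty`.
#' @export
detect_steps <- function(trace, penalty = NULL, min_seg = 2L) {
  stopifnot(inherits(trace, "bleach_trace"))
  x <- trace$intensity
  n <- length(x)
  if (n - trace$uv_onset_frame < 20)
    stop("trace must extend at least 20 frames past UV onset")
  if (!is.null(penalty) && (!is.numeric(penalty) || penalty <= 0))
    stop_field("penalty", "must be a positive number")
  sigma_hat <- stats::mad(diff(x)) / sqrt(2)
  if (is.null(penalty)) {
    penalty <- 2 * sigma_hat^2 * log(n)
    ## floor keeps the penalty above the rounding error of cumulative-sum
    ## SSE evaluation (otherwise spurious ties on noiseless segments) while
    ## scaling with the trace like the main term
    floor_num <- 1e4 * n * .Machine$double.eps * mean(x^2)
    penalty <- max(penalty, floor_num, .Machine$double.xmin)
  }
  bounds <- pelt_segment(x, penalty, min_seg)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  levels <- vapply(seq_along(starts),
                   function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  structure(list(change_points = bounds + 1L,
                 segment_starts = starts, segment_ends = ends,
                 segment_levels = levels,
                 step_amplitudes = diff(levels),
                 sigma_hat = sigma_hat, penalty = penalty),
            class = "step_model")
}

#' @export
print.step_model <- function(x, ...) {
  cat(sprintf("step_model: %d change points, sigma_hat = %.3g, penalty = %.3g\n",
              length(x$change_points), x$sigma_hat, x$penalty))
  invisible(x)
}

#' Estimate the unitary single-molecule intensity
#'
#' Single tagged molecules reveal themselves as discrete blinking and
#' bleaching steps late in the trace, once most fluorophores have
#' bleached. This collects the absolute amplitudes of steps whose new
#' segment starts in the second half of the illumination sequence
#' (frames at or beyond `uv_onset + 0.5 * (n - uv_onset)`), isolates the
#' smallest-amplitude mode of their distribution by exact 1-D clustering
#' (k in 1..3 chosen by mean silhouette), and returns the median of that
#' mode. Step distributions are multimodal when two molecules change
#' state within one segment (amplitudes at integer multiples of the
#' unitary intensity), hence the mode isolation.
#'
#' @param step_model a `step_model` from [detect_steps()].
#' @param trace the corresponding [bleach_trace()].
#' @param use_upward include upward (blink-on) steps as well as downward
#'   steps (default `TRUE`).
#' @param min_amplitude ignore steps smaller than this fraction of the
#'   largest late-trace step (guards against residual drift segments).
#' @param min_event_len only use steps whose flanking segments both span
#'   at least this many frames. Events shorter than the minimum segment
#'   length are fitted as averages over mixed frames and yield
#'   attenuated (fractional) amplitudes; this guard excludes them.
#' @param max_channels physical plausibility bound: a single molecule
#'   cannot be dimmer than the converted peak divided by the largest
#'   credible channel count per AZ, so late-trace steps below
#'   `peak / max_channels` (residual drift, noise segments) are excluded
#'   from the amplitude distribution.
#' @return list with `unitary` (a.u., `NA` when no events), `n_events`,
#'   and `qc` (character reason when unavailable).
#' @export
estimate_unitary_intensity <- function(step_model, trace, use_upward = TRUE,
                                       min_amplitude = 0.05,
                                       min_event_len = 3L,
                                       max_channels = 30) {
  stopifnot(inherits(step_model, "step_model"), inherits(trace, "bleach_trace"))
  n <- length(trace$intensity)
  uv <- trace$uv_onset_frame
  half_start <- uv + ceiling(0.5 * (n - uv))
  seg_len <- step_model$segment_ends - step_model$segment_starts + 1L
  long_enough <- seg_len[-length(seg_len)] >= min_event_len &
    seg_len[-1] >= min_event_len
  sel <- step_model$change_points >= half_start & long_enough
  amps <- step_model$step_amplitudes[sel]
  if (!use_upward) amps <- amps[amps < 0]
  amps <- abs(amps)
  amps <- amps[amps > min_amplitude * max(amps, 0)]
  post <- step_model$segment_ends >= uv
  peak <- max(step_model$segment_levels[post], 0)
  amps <- amps[amps >= peak / max_channels]
  if (!length(amps))
    return(list(unitary = NA_real_, n_events = 0L,
                qc = "no single-molecule events"))
  k_max <- min(3L, length(unique(amps)))
  best_k <- 1L
  if (k_max > 1) {
    sil <- vapply(2:k_max, function(k)
      silhouette1d(amps, kmeans1d(amps, k)$cluster), numeric(1))
    if (max(sil) > 0.5) best_k <- (2:k_max)[which.max(sil)]
  }
  cl <- kmeans1d(amps, best_k)
  mode_id <- which.min(cl$centers)
  members <- amps[cl$cluster == mode_id]
  list(unitary = stats::median(members), n_events = length(members), qc = NULL)
}

#' Count channels in one active zone
#'
#' The channel count is the ratio of the maximal converted fluorescence
#' shortly after photoconversion onset to the unitary single-molecule
#' intensity. "Shortly after onset" is operationalized as the maximum
#' fitted segment level among segments overlapping a window from UV
#' onset to `peak_window_frac` of the post-onset trace. Counts are
#' reported un-rounded.
#'
#' @param trace a [bleach_trace()].
#' @param step_model the fitted `step_model`.
#' @param unitary unitary intensity (a.u., > 0), from
#'   [estimate_unitary_intensity()].
#' @param n_unitary_events number of events behind `unitary` (for QC).
#' @param peak_window_frac fraction of post-onset frames forming the
#'   peak-search window (default 0.25).
#' @param min_events minimum events for a reliable unitary estimate.
#' @return a `channel_count_estimate`: `peak_intensity`,
#'   `unitary_intensity`, `n_channels`, `n_unitary_events`, `qc_pass`,
#'   `qc_flags`.
#' @export
count_channels <- function(trace, step_model, unitary,
                           n_unitary_events = NA_integer_,
                           peak_window_frac = 0.25, min_events = 2L) {
  stopifnot(inherits(trace, "bleach_trace"), inherits(step_model, "step_model"))
  if (!is.numeric(unitary) || is.na(unitary) || unitary <= 0)
    stop("unitary intensity must be > 0")
  n <- length(trace$intensity)
  uv <- trace$uv_onset_frame
  wend <- uv + ceiling(peak_window_frac * (n - uv))
  overlap <- step_model$segment_starts <= wend & step_model$segment_ends >= uv
  qc_flags <- character(0)
  if (!any(overlap)) {
    peak <- 0
    qc_flags <- c(qc_flags, "peak window empty")
  } else {
    peak <- max(step_model$segment_levels[overlap])
    best <- which(overlap)[which.max(step_model$segment_levels[overlap])]
    if (step_model$segment_ends[best] < uv)
      qc_flags <- c(qc_flags, "peak before uv onset")
  }
  if (peak <= 0) {
    qc_flags <- c(qc_flags, "no signal")
    peak <- max(peak, 0)
  }
  if (!is.na(n_unitary_events) && n_unitary_events < min_events)
    qc_flags <- c(qc_flags, "unitary unreliable")
  structure(list(peak_intensity = peak, unitary_intensity = unitary,
                 n_channels = peak / unitary,
                 n_unitary_events = n_unitary_events,
                 qc_pass = !length(qc_flags), qc_flags = qc_flags),
            class = "channel_count_estimate")
}

#' @export
print.channel_count_estimate <- function(x, ...) {
  cat(sprintf("channel_count_estimate: %.2f channels (peak %.1f / unitary %.1f), qc %s\n",
              x$n_channels, x$peak_intensity, x$unitary_intensity,
              if (x$qc_pass) "pass" else paste("fail:", paste(x$qc_flags, collapse = "; "))))
  invisible(x)
}

#' Run the full per-trace counting procedure
#'
#' Convenience wrapper: [detect_steps()], [estimate_unitary_intensity()]
#' and [count_channels()] in sequence.
#'
#' @inheritParams detect_steps
#' @inheritParams estimate_unitary_intensity
#' @inheritParams count_channels
#' @return a `channel_count_estimate` (with a `"no single-molecule
#'   events"` QC failure when no unitary estimate is available).
#' @export
count_channels_trace <- function(trace, penalty = NULL, min_seg = 2L,
                                 use_upward = TRUE, peak_window_frac = 0.25) {
  sm <- detect_steps(trace, penalty = penalty, min_seg = min_seg)
  un <- estimate_unitary_intensity(sm, trace, use_upward = use_upward)
  if (is.na(un$unitary)) {
    return(structure(list(peak_intensity = NA_real_, unitary_intensity = NA_real_,
                          n_channels = NA_real_, n_unitary_events = 0L,
                          qc_pass = FALSE, qc_flags = un$qc),
                     class = "channel_count_estimate"))
  }
  count_channels(trace, sm, un$unitary, n_unitary_events = un$n_events,
                 peak_window_frac = peak_window_frac)
}

#' Aggregate per-AZ channel counts by animal and genotype
#'
#' QC-failing AZs are excluded (and counted); animals with fewer than
#' `min_az` passing AZs are flagged; the genotype summary is the mean of
#' animal means, mirroring a design with at least 30 AZs per animal and
#' several animals per genotype.
#'
#' @param estimates list of `channel_count_estimate` objects.
#' @param labels data frame with one row per estimate, columns `animal`
#'   and `genotype`.
#' @param min_az minimum passing AZs per animal (default 30).
#' @return list of data frames `per_az`, `per_animal`, `per_genotype`.
#' @export
aggregate_counts <- function(estimates, labels, min_az = 30L) {
  stopifnot(is.list(estimates), nrow(labels) == length(estimates),
            all(c("animal", "genotype") %in% names(labels)))
  per_az <- data.frame(
    animal = labels$animal, genotype = labels$genotype,
    n_channels = vapply(estimates, function(e) e$n_channels, numeric(1)),
    qc_pass = vapply(estimates, function(e) e$qc_pass, logical(1)))
  ok <- per_az[per_az$qc_pass, ]
  groups <- unique(per_az[c("animal", "genotype")])
  per_animal <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- ok[ok$animal == groups$animal[i] & ok$genotype == groups$genotype[i], ]
    n_all <- sum(per_az$animal == groups$animal[i] &
                   per_az$genotype == groups$genotype[i])
    if (!nrow(g)) {
      warning(sprintf("animal '%s': no qc-passing AZs; omitted", groups$animal[i]))
      return(NULL)
    }
    data.frame(animal = groups$animal[i], genotype = groups$genotype[i],
               n_az = nrow(g), n_excluded = n_all - nrow(g),
               mean = mean(g$n_channels), sd = stats::sd(g$n_channels),
               flag = if (nrow(g) < min_az) "below minimum AZ count" else "")
  }))
  per_genotype <- do.call(rbind, lapply(unique(per_animal$genotype), function(gt) {
    a <- per_animal[per_animal$genotype == gt, ]
    data.frame(genotype = gt, n_animals = nrow(a),
               mean = mean(a$mean), sd = stats::sd(a$mean))
  }))
  list(per_az = per_az, per_animal = per_animal, per_genotype = per_genotype)
}
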