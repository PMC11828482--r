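#' Zero-phase Gaussian low-pass filter
#'
#' Smooths a sweep with a symmetric Gaussian kernel whose frequency
#' response is -3 dB at `cutoff_minus3db`. For the Gaussian transfer
#' function `H(f) = exp(-2 pi^2 sigma_t^2 f^2)` this requires
#' `sigma_t = sqrt(-ln(10^(-3/20)) / (2 pi^2)) / f_c` (approximately
#' `0.1325 / f_c` seconds). The kernel is normalized to unit sum (DC
#' gain exactly 1) and applied with replicate padding, so the filter is
#' zero-phase.
#'
#' @param sweep an [az_sweep()].
#' @param cutoff_minus3db -3 dB cutoff frequency (Hz), below Nyquist.
#' @return the filtered `az_sweep`.
#' @export
gaussian_lowpass <- function(sweep, cutoff_minus3db = 360) {
  stopifnot(inherits(sweep, "az_sweep"))
  fs <- sweep$sampling_rate
  if (cutoff_minus3db >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  check_pos(cutoff_minus3db, "cutoff_minus3db")
  sigma_t <- sqrt(-log(10^(-3 / 20)) / (2 * pi^2)) / cutoff_minus3db
  sigma_n <- sigma_t * fs
  r <- ceiling(6 * sigma_n)
  k <- exp(-0.5 * ((-r:r) / sigma_n)^2)
  k <- k / sum(k)
  out <- conv_same(sweep$current, k)
  az_sweep(as.numeric(out), fs, sweep$stimulus_times, sweep$metadata)
}

#' Measure a single evoked EPSC
#'
#' Baseline is the mean current over a pre-stimulus window; the
#' amplitude is the positive magnitude of the peak inward (negative)
#' deflection within the response window; the half-width is the full
#' width at half-amplitude with linear interpolation between samples;
#' the charge is the integral of `(baseline - current)` over the
#' response window, by default counting only samples below baseline.
#'
#' @param sweep a (filtered) [az_sweep()].
#' @param stim_time stimulus onset (s).
#' @param response_window response window length after the stimulus (s).
#' @param baseline_window pre-stimulus baseline window length (s).
#' @param baseline_gap gap between baseline window end and stimulus (s).
#' @param clip_positive count only samples below baseline in the charge
#'   integral (default `TRUE`).
#' @param noise_k amplitudes below `noise_k` pre-stimulus SDs are
#'   flagged `"no event"`.
#' @return an `epsc_measure`: `baseline` (nA), `amplitude` (nA,
#'   magnitude), `half_width` (ms), `charge` (nC), `window`, `flag`.
#' @export
measure_epsc <- function(sweep, stim_time, response_window = 0.02,
                         baseline_window = 0.005, baseline_gap = 0.0005,
                         clip_positive = TRUE, noise_k = 3) {
  stopifnot(inherits(sweep, "az_sweep"))
  fs <- sweep$sampling_rate
  n <- length(sweep$current)
  t <- (seq_len(n) - 1) / fs
  if (stim_time < 0 || stim_time >= n / fs) stop("stimulus outside sweep")
  if (stim_time + response_window > n / fs)
    stop("response window exceeds sweep")
  bl_idx <- which(t >= stim_time - baseline_gap - baseline_window &
                    t < stim_time - baseline_gap)
  if (!length(bl_idx)) bl_idx <- which(t < stim_time)
  if (!length(bl_idx)) bl_idx <- 1L
  baseline <- mean(sweep$current[bl_idx])
  noise_sd <- stats::sd(sweep$current[bl_idx])
  win <- which(t >= stim_time & t <= stim_time + response_window)
  seg <- sweep$current[win]
  i_min <- which.min(seg)
  amplitude <- baseline - seg[i_min]
  flag <- NULL
  if (!is.na(noise_sd) && amplitude <= noise_k * noise_sd) flag <- "no event"
  if (amplitude < 0) amplitude <- 0

  half_width <- NA_real_
  if (amplitude > 0 && is.null(flag)) {
    level <- baseline - amplitude / 2
    below <- seg <= level
    ## first downward and last upward crossing around the peak
    i1 <- which(below[seq_len(i_min)])[1]
    i2 <- i_min - 1 + rev(which(below[i_min:length(seg)]))[1]
    t1 <- if (!is.na(i1) && i1 > 1)
      interp_crossing(t[win][i1 - 1], t[win][i1], seg[i1 - 1], seg[i1], level)
    else t[win][1]
    t2 <- if (!is.na(i2) && i2 < length(seg))
      interp_crossing(t[win][i2], t[win][i2 + 1], seg[i2], seg[i2 + 1], level)
    else t[win][length(seg)]
    half_width <- (t2 - t1) * 1000
  }
  dev <- baseline - seg
  if (clip_positive) dev <- pmax(dev, 0)
  charge <- sum(dev) / fs   # nA * s = nC
  structure(list(baseline = baseline, amplitude = amplitude,
                 half_width = half_width, charge = charge,
                 window = c(stim_time, stim_time + response_window),
                 flag = flag),
            class = "epsc_measure")
}

interp_crossing <- function(ta, tb, ya, yb, level) {
  if (yb == ya) return(tb)
  ta + (level - ya) / (yb - ya) * (tb - ta)
}

#' @export
print.epsc_measure <- function(x, ...) {
  cat(sprintf("epsc_measure: amplitude %.2f nA, half-width %s ms, charge %.4f nC%s\n",
              x$amplitude,
              if (is.na(x$half_width)) "NA" else sprintf("%.2f", x$half_width),
              x$charge,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Charge transfer during a stimulation burst
#'
#' Integral of `(baseline - current)` over the burst window, counting
#' only samples below the pre-burst baseline. Used to compare total
#' charge transfer during 200 ms high-frequency bursts.
#'
#' @param sweep an [az_sweep()].
#' @param burst_window `(start, end)` in seconds.
#' @param baseline_window seconds of pre-burst data for the baseline.
#' @return charge in nC.
#' @export
burst_charge <- function(sweep, burst_window, baseline_window = 0.005) {
  stopifnot(inherits(sweep, "az_sweep"), length(burst_window) == 2)
  fs <- sweep$sampling_rate
  n <- length(sweep$current)
  t <- (seq_len(n) - 1) / fs
  if (burst_window[1] < 0 || burst_window[2] > n / fs)
    stop("burst window outside sweep")
  bl_idx <- which(t >= burst_window[1] - baseline_window & t < burst_window[1])
  if (!length(bl_idx)) stop("no pre-burst samples for baseline")
  baseline <- mean(sweep$current[bl_idx])
  win <- which(t >= burst_window[1] & t <= burst_window[2])
  sum(pmax(baseline - sweep$current[win], 0)) / fs
}

#' Paired-pulse ratio under both averaging schemes
#'
#' Scheme A averages the per-sweep ratios `A2/A1`; scheme B divides the
#' mean of all second-pulse amplitudes by the mean of all first-pulse
#' amplitudes. Sweeps with a zero first amplitude are excluded with a
#' warning.
#'
#' @param first_amps,second_amps paired amplitude vectors (nA,
#'   magnitudes).
#' @param ipi_ms optional inter-pulse interval for bookkeeping.
#' @return a `ppr_result`: `ipi`, `ppr_per_sweep`, `ppr_scheme_a`,
#'   `ppr_scheme_b`, `n_sweeps`.
#' @export
compute_ppr <- function(first_amps, second_amps, ipi_ms = NA_real_) {
  stopifnot(length(first_amps) == length(second_amps),
            length(first_amps) >= 1)
  bad <- first_amps == 0
  if (any(bad)) {
    warning(sprintf("%d sweep(s) with zero first amplitude excluded", sum(bad)))
    first_amps <- first_amps[!bad]; second_amps <- second_amps[!bad]
  }
  if (!length(first_amps)) stop("no usable sweeps")
  per_sweep <- second_amps / first_amps
  structure(list(ipi = ipi_ms, ppr_per_sweep = per_sweep,
                 ppr_scheme_a = mean(per_sweep),
                 ppr_scheme_b = mean(second_amps) / mean(first_amps),
                 n_sweeps = length(per_sweep)),
            class = "ppr_result")
}

#' Coefficient of variation of PPR across animals, per IPI
#'
#' @param per_animal_ppr data frame with columns `ipi` and `ppr` (one
#'   row per animal per IPI).
#' @return data frame `ipi`, `n`, `mean`, `sd`, `cov_percent` (`NA` with
#'   a reason when the mean is non-positive).
#' @export
ppr_cov <- function(per_animal_ppr) {
  stopifnot(all(c("ipi", "ppr") %in% names(per_animal_ppr)))
  do.call(rbind, lapply(split(per_animal_ppr, per_animal_ppr$ipi), function(g) {
    if (nrow(g) < 2)
      stop(sprintf("need >= 2 animals per IPI (IPI %s)", g$ipi[1]))
    m <- mean(g$ppr)
    data.frame(ipi = g$ipi[1], n = nrow(g), mean = m, sd = stats::sd(g$ppr),
               cov_percent = if (m <= 0) NA_real_ else 100 * stats::sd(g$ppr) / m)
  }))
}

#' Fit single-exponential synaptic depression
#'
#' Least-squares fit of `A(t) = plateau + (A0 - plateau) * exp(-t / tau)`
#' to per-stimulus amplitudes of a train, initialized with `A0` = first
#' amplitude, plateau = mean of the last 20% of points, and tau = the
#' time at which the amplitude first reaches halfway between.
#'
#' @param amplitudes per-stimulus amplitudes (nA, positive).
#' @param times stimulus times (s), same length.
#' @return a `depression_fit`: `tau` (s), `plateau_fraction`
#'   (`plateau / A0`), `initial_amplitude`, `fit_residual` (RMS), and
#'   `flag` (`NULL`, `"degenerate"` for constant input, or
#'   `"no convergence"`).
#' @export
fit_depression <- function(amplitudes, times) {
  stopifnot(length(amplitudes) == length(times), length(amplitudes) >= 5,
            all(amplitudes > 0))
  a0 <- amplitudes[1]
  if (stats::sd(amplitudes) < 1e-12 * abs(a0)) {
    return(structure(list(tau = NA_real_, plateau_fraction = 1,
                          initial_amplitude = a0, fit_residual = 0,
                          flag = "degenerate"),
                     class = "depression_fit"))
  }
  n <- length(amplitudes)
  plateau0 <- mean(amplitudes[max(1, ceiling(0.8 * n)):n])
  half <- (a0 + plateau0) / 2
  i_half <- which(amplitudes <= half)[1]
  tau0 <- if (!is.na(i_half)) max(times[i_half] - times[1], diff(range(times)) / 20)
  else diff(range(times)) / 4
  df <- data.frame(t = times - times[1], a = amplitudes)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ plateau + (A0 - plateau) * exp(-t / tau), data = df,
                      start = list(A0 = a0, plateau = plateau0, tau = tau0),
                      lower = c(A0 = 0, plateau = 0, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, plateau_fraction = NA_real_,
                          initial_amplitude = a0,
                          fit_residual = stats::sd(amplitudes),
                          flag = "no convergence"),
                     class = "depression_fit"))
  }
  p <- coef(fit)
  structure(list(tau = unname(p["tau"]),
                 plateau_fraction = unname(p["plateau"] / p["A0"]),
                 initial_amplitude = unname(p["A0"]),
                 fit_residual = sqrt(mean(residuals(fit)^2)),
                 flag = NULL),
            class = "depression_fit")
}

#' @export
print.depression_fit <- function(x, ...) {
  cat(sprintf("depression_fit: tau %.3g s, plateau %.3g of A0 = %.3g%s\n",
              x$tau, x$plateau_fraction, x$initial_amplitude,
              if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Mean quantal content of a recording
#'
#' Mean evoked EPSC amplitude divided by the mean miniature EPSC
#' amplitude of the same recording.
#'
#' @param epsc_amps evoked amplitudes (nA, magnitudes).
#' @param mepsc_amps miniature amplitudes (nA, magnitudes).
#' @return a `quantal_stats`: `mean_epsc`, `mean_mepsc`, `mqc`.
#' @export
mean_quantal_content <- function(epsc_amps, mepsc_amps) {
  if (!length(epsc_amps) || !length(mepsc_amps))
    stop("both amplitude lists must be non-empty")
  me <- mean(epsc_amps); mm <- mean(mepsc_amps)
  if (me <= 0 || mm <= 0) stop("mean amplitudes must be > 0")
  structure(list(mean_epsc = me, mean_mepsc = mm, mqc = me / mm),
            class = "quantal_stats")
}

#' @export
print.quantal_stats <- function(x, ...) {
  cat(sprintf("quantal_stats: mean EPSC %.2f nA / mean mEPSC %.3f nA = mQC %.1f\n",
              x$mean_epsc, x$mean_mepsc, x$mqc))
  invisible(x)
}

#' Read a sweep from two-column delimited text
#'
#' Expects columns `time_s` and `current_nA` (header optional when the
#' first row is non-numeric).
#'
#' @param path file path.
#' @param stimulus_times stimulus onsets (s).
#' @param metadata metadata list.
#' @return an [az_sweep()].
#' @export
read_sweep <- function(path, stimulus_times = numeric(0), metadata = list()) {
  df <- utils::read.table(path, header = TRUE)
  stopifnot(ncol(df) >= 2)
  dt <- diff(df[[1]])
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("non-uniform sampling")
  az_sweep(df[[2]], 1 / dt[1], stimulus_times, metadata)
}

#' Write a sweep as two-column delimited text
#'
#' @param sweep an [az_sweep()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "az_sweep"))
  t <- (seq_along(sweep$current) - 1) / sweep$sampling_rate
  utils::write.table(data.frame(time_s = t, current_nA = sweep$current),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
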