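#' Configuration for synthetic two-electrode voltage-clamp sweeps
#'
#' Emulates postsynaptic current recordings from larval muscle during
#' motor-nerve stimulation: stimulus-locked evoked EPSCs (inward,
#' negative deflections) with configurable amplitude and kinetics,
#' paired-pulse behavior per inter-pulse interval, single-exponential
#' depression during trains, spontaneous miniature EPSCs as a Poisson
#' process, and Gaussian recording noise. Sampling defaults to 50 kHz.
#' Depression defaults (steady state at 80% of the initial amplitude,
#' time constant 5 s) match the 1 Hz train behavior of the preparation
#' being emulated.
#'
#' @param sampling_rate Hz.
#' @param epsc_amplitude first-pulse EPSC amplitude (nA, positive
#'   magnitude).
#' @param rise_tau,decay_tau EPSC kernel time constants (ms).
#' @param ppr_true paired-pulse ratio: a single number, or a named
#'   vector keyed by IPI in ms (e.g. `c("10" = 0.8, "100" = 1)`).
#' @param depression_tau depression time constant (s).
#' @param depression_plateau steady-state fraction of the initial
#'   amplitude, in `(0, 1]`.
#' @param mepsc_amplitude mean miniature amplitude (nA).
#' @param mepsc_rate miniature rate (Hz).
#' @param mepsc_cv lognormal CV of miniature amplitudes.
#' @param noise_sd Gaussian noise SD (nA).
#' @param seed integer seed.
#' @return a `tevc_sim_config`.
#' @export
tevc_sim_config <- function(sampling_rate = 50000,
                            epsc_amplitude = 80,
                            rise_tau = 1, decay_tau = 6,
                            ppr_true = 1.0,
                            depression_tau = 5,
                            depression_plateau = 0.8,
                            mepsc_amplitude = 0.9,
                            mepsc_rate = 2,
                            mepsc_cv = 0.25,
                            noise_sd = 0.4,
                            seed = 1L) {
  check_pos(sampling_rate, "sampling_rate")
  check_pos(epsc_amplitude, "epsc_amplitude", strict = FALSE)
  check_pos(rise_tau, "rise_tau"); check_pos(decay_tau, "decay_tau")
  if (rise_tau >= decay_tau) stop_field("rise_tau", "must be < decay_tau")
  if (any(ppr_true <= 0)) stop_field("ppr_true", "must be > 0")
  check_pos(depression_tau, "depression_tau")
  if (depression_plateau <= 0 || depression_plateau > 1)
    stop_field("depression_plateau", "must be in (0, 1]")
  check_pos(mepsc_amplitude, "mepsc_amplitude", strict = FALSE)
  check_pos(mepsc_rate, "mepsc_rate", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 epsc_amplitude = epsc_amplitude,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 ppr_true = ppr_true,
                 depression_tau = depression_tau,
                 depression_plateau = depression_plateau,
                 mepsc_amplitude = mepsc_amplitude, mepsc_rate = mepsc_rate,
                 mepsc_cv = mepsc_cv, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "tevc_sim_config")
}

#' Stimulation protocol
#'
#' @param stimulus_times stimulus onset times (s), strictly increasing.
#' @param duration sweep duration (s); all stimuli must fall inside.
#' @return a `stim_protocol`.
#' @export
stim_protocol <- function(stimulus_times, duration) {
  stopifnot(is.numeric(stimulus_times), length(stimulus_times) >= 0)
  if (length(stimulus_times) && any(diff(stimulus_times) <= 0))
    stop("stimulus times must be strictly increasing")
  if (length(stimulus_times) &&
      (min(stimulus_times) < 0 || max(stimulus_times) >= duration))
    stop("stimulus times must lie within the sweep duration")
  structure(list(stimulus_times = as.numeric(stimulus_times),
                 duration = duration), class = "stim_protocol")
}

#' Voltage-clamp sweep container
#'
#' @param current current samples (nA; inward currents negative).
#' @param sampling_rate Hz.
#' @param stimulus_times stimulus onsets (s).
#' @param metadata named list (animal, genotype, external calcium ...).
#' @return an `az_sweep`.
#' @export
az_sweep <- function(current, sampling_rate, stimulus_times = numeric(0),
                     metadata = list()) {
  stopifnot(is.numeric(current), sampling_rate > 0)
  dur <- length(current) / sampling_rate
  if (length(stimulus_times) && max(stimulus_times) >= dur)
    stop("stimulus after sweep end")
  structure(list(current = as.numeric(current), sampling_rate = sampling_rate,
                 stimulus_times = as.numeric(stimulus_times),
                 metadata = metadata), class = "az_sweep")
}

#' @export
print.az_sweep <- function(x, ...) {
  cat(sprintf("az_sweep: %.3f s at %g kHz, %d stimuli\n",
              length(x$current) / x$sampling_rate, x$sampling_rate / 1000,
              length(x$stimulus_times)))
  invisible(x)
}

## Normalized EPSC kernel (peaks at 1): difference of exponentials.
epsc_kernel <- function(t, rise_tau_s, decay_tau_s) {
  h <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  tpk <- log(decay_tau_s / rise_tau_s) * rise_tau_s * decay_tau_s /
    (decay_tau_s - rise_tau_s)
  hpk <- exp(-tpk / decay_tau_s) - exp(-tpk / rise_tau_s)
  ifelse(t < 0, 0, h / hpk)
}

#' True per-stimulus amplitudes under the depression/PPR model
#'
#' For twin-pulse protocols the second amplitude is `ppr_true(ipi)` times
#' the first. For trains (3+ stimuli) amplitudes follow the
#' geometric-decay recursion towards the plateau,
#' `A[k+1] = P + (A[k] - P) * exp(-dt / tau)` with
#' `P = plateau * A[1]`, whose closed form is
#' `A(t) = P + (A[1] - P) * exp(-(t - t[1]) / tau)`.
#'
#' @param config a [tevc_sim_config()].
#' @param stimulus_times stimulus onsets (s).
#' @return numeric vector of noiseless amplitudes (nA, magnitudes).
#' @export
true_epsc_amplitudes <- function(config, stimulus_times) {
  k <- length(stimulus_times)
  if (k == 0) return(numeric(0))
  a1 <- config$epsc_amplitude
  if (k == 1) return(a1)
  if (k == 2) {
    ipi_ms <- (stimulus_times[2] - stimulus_times[1]) * 1000
    ppr <- config$ppr_true
    if (!is.null(names(ppr))) {
      hit <- which.min(abs(as.numeric(names(ppr)) - ipi_ms))
      ppr <- ppr[[hit]]
    }
    return(c(a1, a1 * ppr))
  }
  plateau <- config$depression_plateau * a1
  amps <- numeric(k)
  amps[1] <- a1
  for (i in 2:k) {
    dt <- stimulus_times[i] - stimulus_times[i - 1]
    amps[i] <- plateau + (amps[i - 1] - plateau) * exp(-dt / config$depression_tau)
  }
  amps
}

#' Simulate voltage-clamp sweeps with ground truth
#'
#' Each stimulus adds a (negative-going) EPSC kernel scaled by the
#' depression/paired-pulse model; overlapping kernels summate.
#' Miniature EPSCs are added as a Poisson process with lognormal
#' amplitudes; Gaussian noise is superimposed.
#'
#' @param config a [tevc_sim_config()].
#' @param protocol a [stim_protocol()].
#' @param n_sweeps number of sweeps.
#' @param metadata metadata list attached to each sweep.
#' @return list with `sweeps` (list of `az_sweep`) and `truth` (data
#'   frame: `sweep`, `stimulus`, `time_s`, `true_amplitude_nA`), plus
#'   `mepscs` (per-sweep event times and amplitudes).
#' @export
simulate_tevc_sweeps <- function(config, protocol, n_sweeps = 1L,
                                 metadata = list()) {
  stopifnot(inherits(config, "tevc_sim_config"),
            inherits(protocol, "stim_protocol"))
  fs <- config$sampling_rate
  n <- round(protocol$duration * fs)
  t <- (seq_len(n) - 1) / fs
  amps <- true_epsc_amplitudes(config, protocol$stimulus_times)
  sweeps <- vector("list", n_sweeps)
  truth <- list(); minis <- list()
  for (s in seq_len(n_sweeps)) {
    set.seed(child_seed(config$seed, s))
    cur <- numeric(n)
    for (i in seq_along(protocol$stimulus_times)) {
      t0 <- protocol$stimulus_times[i]
      idx <- which(t >= t0)
      cur[idx] <- cur[idx] - amps[i] *
        epsc_kernel(t[idx] - t0, config$rise_tau / 1000, config$decay_tau / 1000)
    }
    ev_t <- numeric(0); ev_a <- numeric(0)
    if (config$mepsc_rate > 0 && config$mepsc_amplitude > 0) {
      n_ev <- rpois(1, config$mepsc_rate * protocol$duration)
      if (n_ev > 0) {
        ev_t <- sort(runif(n_ev, 0, protocol$duration))
        sdlog <- sqrt(log(1 + config$mepsc_cv^2))
        ev_a <- config$mepsc_amplitude *
          exp(rnorm(n_ev, -sdlog^2 / 2, sdlog))
        for (j in seq_len(n_ev)) {
          idx <- which(t >= ev_t[j])
          cur[idx] <- cur[idx] - ev_a[j] *
            epsc_kernel(t[idx] - ev_t[j], config$rise_tau / 1000,
                        config$decay_tau / 1000)
        }
      }
    }
    if (config$noise_sd > 0) cur <- cur + rnorm(n, 0, config$noise_sd)
    sweeps[[s]] <- az_sweep(cur, fs, protocol$stimulus_times, metadata)
    if (length(amps))
      truth[[s]] <- data.frame(sweep = s, stimulus = seq_along(amps),
                               time_s = protocol$stimulus_times,
                               true_amplitude_nA = amps)
    minis[[s]] <- data.frame(sweep = rep(s, length(ev_t)), time_s = ev_t,
                             amplitude_nA = ev_a)
  }
  list(sweeps = sweeps,
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       mepscs = do.call(rbind, minis))
}
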