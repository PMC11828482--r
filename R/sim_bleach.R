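#' Configuration for photoconversion/bleaching simulations
#'
#' Describes a single-channel acquisition of mEOS4b-tagged channels at
#' neuromuscular-junction active zones (AZs): an initial pre-conversion
#' illumination phase, UV-triggered green-to-red photoconversion, then
#' stochastic blinking and irreversible bleaching under continuous
#' readout. Defaults follow the acquisition conditions of the experiment
#' being emulated: 20 Hz frame rate, up to 5000 frames, photoconversion
#' onset at frame 250, 71 nm effective pixel size.
#'
#' Each fluorophore is a 4-state Markov chain stepped once per frame:
#' unconverted -> converted-bright <-> converted-dark -> bleached.
#' `conversion_rate` is the per-frame probability of photoconversion after
#' UV onset, `bleach_rate` the per-frame probability that a bright
#' fluorophore bleaches, and `blink_off_rate`/`blink_on_rate` the
#' reversible dark-state transition probabilities. The blinking kinetics
#' of mEOS4b are not constrained by the counting method itself; the
#' defaults here are free parameters chosen to produce isolated
#' single-molecule events late in the trace.
#'
#' @param n_az number of active zones.
#' @param channels_per_az either a single integer (fixed count per AZ) or
#'   an integer vector of length `n_az` giving each AZ's true count.
#' @param unitary_intensity fluorescence of one converted molecule (a.u.).
#' @param conversion_rate,bleach_rate,blink_off_rate,blink_on_rate
#'   per-frame Markov transition probabilities, all in `[0, 1]`.
#' @param background_level constant background offset (a.u.).
#' @param noise_sd additive Gaussian noise SD (a.u.); applied per pixel
#'   per frame in movie rendering, per trace sample in trace simulation.
#' @param frame_rate acquisition rate (Hz).
#' @param n_frames number of frames (must be at least `uv_onset_frame + 10`).
#' @param uv_onset_frame 1-based frame at which UV photoconversion starts.
#' @param pixel_size pixel pitch (nm).
#' @param psf_sigma_px Gaussian point-spread SD used when rendering spots
#'   (pixels).
#' @param drift_per_frame numeric length-2 `(dy, dx)` rigid drift per
#'   frame (pixels).
#' @param poisson_noise if `TRUE`, Poisson shot noise is applied to the
#'   noiseless image before additive Gaussian noise (off by default;
#'   additive noise suffices for estimator testing).
#' @param seed integer seed; identical config + seed reproduces outputs
#'   bit-exactly.
#' @return an object of class `bleach_sim_config`.
#' @seealso [simulate_bleach_movie()], [simulate_bleach_traces()]
#' @export
bleach_sim_config <- function(n_az = 1L,
                              channels_per_az = 10L,
                              unitary_intensity = 100,
                              conversion_rate = 0.1,
                              bleach_rate = 0.001,
                              blink_off_rate = 0.003,
                              blink_on_rate = 0.15,
                              background_level = 50,
                              noise_sd = 10,
                              frame_rate = 20,
                              n_frames = 2500L,
                              uv_onset_frame = 250L,
                              pixel_size = 71,
                              psf_sigma_px = 1.3,
                              drift_per_frame = c(0, 0),
                              poisson_noise = FALSE,
                              seed = 1L) {
  n_az <- check_count(n_az, "n_az")
  if (!is.numeric(channels_per_az) ||
      !(length(channels_per_az) %in% c(1L, n_az)) ||
      any(channels_per_az < 0) || any(channels_per_az != round(channels_per_az)))
    stop_field("channels_per_az", "must be a non-negative integer scalar or vector of length n_az")
  channels_per_az <- as.integer(rep(channels_per_az, length.out = n_az))
  check_pos(unitary_intensity, "unitary_intensity")
  for (f in c("conversion_rate", "bleach_rate", "blink_off_rate", "blink_on_rate"))
    check_prob(get(f), f)
  check_pos(background_level, "background_level", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  check_pos(frame_rate, "frame_rate")
  n_frames <- check_count(n_frames, "n_frames")
  uv_onset_frame <- check_count(uv_onset_frame, "uv_onset_frame")
  if (n_frames < uv_onset_frame + 10)
    stop_field("n_frames", "must be >= uv_onset_frame + 10")
  check_pos(pixel_size, "pixel_size")
  check_pos(psf_sigma_px, "psf_sigma_px", strict = FALSE)
  if (length(drift_per_frame) != 2 || any(!is.finite(drift_per_frame)))
    stop_field("drift_per_frame", "must be finite (dy, dx)")
  structure(list(
    n_az = n_az, channels_per_az = channels_per_az,
    unitary_intensity = unitary_intensity,
    conversion_rate = conversion_rate, bleach_rate = bleach_rate,
    blink_off_rate = blink_off_rate, blink_on_rate = blink_on_rate,
    background_level = background_level, noise_sd = noise_sd,
    frame_rate = frame_rate, n_frames = n_frames,
    uv_onset_frame = uv_onset_frame, pixel_size = pixel_size,
    psf_sigma_px = psf_sigma_px, drift_per_frame = as.numeric(drift_per_frame),
    poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed)),
    class = "bleach_sim_config")
}

## Simulate the Markov state trajectory of `n` fluorophores in one AZ.
## Returns the per-frame bright-fluorophore count and per-fluorophore
## conversion/bleach frames (NA when the event never happens).
sim_fluorophore_states <- function(n, cfg) {
  nf <- cfg$n_frames
  bright <- integer(nf)
  conv_frame <- rep(NA_integer_, n)
  bleach_frame <- rep(NA_integer_, n)
  if (n == 0) return(list(bright = bright, conversion_frame = conv_frame,
                          bleach_frame = bleach_frame))
  ## states: 0 unconverted, 1 bright, 2 dark, 3 bleached
  state <- integer(n)
  for (t in seq_len(nf)) {
    if (t >= cfg$uv_onset_frame && cfg$conversion_rate > 0) {
      u <- state == 0L
      if (any(u)) {
        conv <- u & (runif(n) < cfg$conversion_rate)
        state[conv] <- 1L
        conv_frame[conv & is.na(conv_frame)] <- t
      }
    }
    b <- state == 1L
    d <- state == 2L
    if (any(b)) {
      r <- runif(n)
      to_bleach <- b & (r < cfg$bleach_rate)
      to_dark <- b & !to_bleach & (r < cfg$bleach_rate + cfg$blink_off_rate)
      state[to_bleach] <- 3L
      bleach_frame[to_bleach] <- t
      state[to_dark] <- 2L
    }
    if (any(d)) {
      back <- d & (runif(n) < cfg$blink_on_rate)
      state[back] <- 1L
    }
    bright[t] <- sum(state == 1L)
  }
  list(bright = bright, conversion_frame = conv_frame, bleach_frame = bleach_frame)
}

#' Simulate noiseless-geometry bleaching traces (no image rendering)
#'
#' Runs the fluorophore state model for each AZ and returns per-AZ summed
#' ROI intensity traces directly, with additive Gaussian noise of SD
#' `noise_sd` per sample. This is the fast path for estimator studies;
#' [simulate_bleach_movie()] renders the same model into image frames.
#'
#' @param config a [bleach_sim_config()].
#' @return a list with `traces` (list of [bleach_trace()] objects) and
#'   `truth` (data frame: `az_id`, `true_channels`, `n_converted`) plus
#'   `events` (per-fluorophore conversion/bleach frames).
#' @export
simulate_bleach_traces <- function(config) {
  stopifnot(inherits(config, "bleach_sim_config"))
  traces <- vector("list", config$n_az)
  truth <- data.frame(az_id = seq_len(config$n_az),
                      true_channels = config$channels_per_az,
                      n_converted = NA_integer_)
  events <- vector("list", config$n_az)
  times <- (seq_len(config$n_frames) - 1) / config$frame_rate
  for (i in seq_len(config$n_az)) {
    set.seed(child_seed(config$seed, i))
    st <- sim_fluorophore_states(config$channels_per_az[i], config)
    intensity <- st$bright * config$unitary_intensity
    if (config$noise_sd > 0)
      intensity <- intensity + rnorm(config$n_frames, 0, config$noise_sd)
    traces[[i]] <- bleach_trace(intensity, times,
                                uv_onset_frame = config$uv_onset_frame)
    truth$n_converted[i] <- sum(!is.na(st$conversion_frame))
    events[[i]] <- data.frame(az_id = i,
                              fluorophore = seq_along(st$conversion_frame),
                              conversion_frame = st$conversion_frame,
                              bleach_frame = st$bleach_frame)
  }
  list(traces = traces, truth = truth,
       events = do.call(rbind, events))
}

#' Simulate a photoconversion/bleaching movie
#'
#' Renders the fluorophore state model of [bleach_sim_config()] into a
#' single-channel frame stack. Each AZ is a diffraction-limited Gaussian
#' spot whose amplitude tracks `unitary_intensity` times the number of
#' converted, non-bleached, non-dark fluorophores; a rigid per-frame
#' drift translates all spots; constant background and Gaussian camera
#' noise are added. AZ positions are laid out on a jittered grid with a
#' 6-pixel margin.
#'
#' @param config a [bleach_sim_config()].
#' @param image_size `(rows, cols)` of each frame; chosen automatically
#'   when `NULL`.
#' @return a list with `movie` (an `az_movie`: array `(frame, row, col)`
#'   with frame interval, pixel size and UV onset attributes), `truth`
#'   (per-AZ table with true channel counts and spot positions) and
#'   `events` (per-fluorophore conversion/bleach frames).
#' @export
simulate_bleach_movie <- function(config, image_size = NULL) {
  stopifnot(inherits(config, "bleach_sim_config"))
  n_az <- config$n_az
  if (is.null(image_size)) {
    side <- ceiling(sqrt(n_az))
    image_size <- rep(2L * 6L + side * 9L, 2)
  }
  nr <- image_size[1]; nc <- image_size[2]
  set.seed(config$seed)
  side <- ceiling(sqrt(n_az))
  gy <- seq(7, nr - 6, length.out = side)
  gx <- seq(7, nc - 6, length.out = side)
  grid <- expand.grid(row = gy, col = gx)[seq_len(n_az), , drop = FALSE]
  pos <- cbind(grid$row + runif(n_az, -1, 1), grid$col + runif(n_az, -1, 1))

  states <- vector("list", n_az)
  for (i in seq_len(n_az)) {
    set.seed(child_seed(config$seed, i))
    states[[i]] <- sim_fluorophore_states(config$channels_per_az[i], config)
  }
  bright <- vapply(states, `[[`, integer(config$n_frames), "bright")
  if (is.null(dim(bright))) bright <- matrix(bright, ncol = n_az)

  frames <- array(config$background_level,
                  dim = c(config$n_frames, nr, nc))
  s <- max(config$psf_sigma_px, 1e-3)
  r <- ceiling(4 * s)
  for (t in seq_len(config$n_frames)) {
    dy <- config$drift_per_frame[1] * (t - 1)
    dx <- config$drift_per_frame[2] * (t - 1)
    for (i in seq_len(n_az)) {
      amp <- bright[t, i] * config$unitary_intensity
      if (amp == 0) next
      cy <- pos[i, 1] + dy; cx <- pos[i, 2] + dx
      ry <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
      rx <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
      if (!length(ry) || !length(rx)) next
      gy1 <- exp(-0.5 * ((ry - cy) / s)^2)
      gx1 <- exp(-0.5 * ((rx - cx) / s)^2)
      patch <- outer(gy1, gx1)
      patch <- amp * patch / (2 * pi * s^2)   # unit-integral PSF
      frames[t, ry, rx] <- frames[t, ry, rx] + patch
    }
  }
  set.seed(child_seed(config$seed, n_az + 1L))
  if (config$poisson_noise)
    frames[] <- rpois(length(frames), pmax(frames, 0))
  if (config$noise_sd > 0)
    frames <- frames + rnorm(length(frames), 0, config$noise_sd)

  movie <- az_movie(frames, frame_interval = 1 / config$frame_rate,
                    pixel_size = config$pixel_size,
                    uv_onset_frame = config$uv_onset_frame)
  truth <- data.frame(az_id = seq_len(n_az),
                      true_channels = config$channels_per_az,
                      row = pos[, 1], col = pos[, 2],
                      n_converted = vapply(states, function(s)
                        sum(!is.na(s$conversion_frame)), integer(1)))
  events <- do.call(rbind, lapply(seq_len(n_az), function(i)
    data.frame(az_id = i,
               fluorophore = seq_along(states[[i]]$conversion_frame),
               conversion_frame = states[[i]]$conversion_frame,
               bleach_frame = states[[i]]$bleach_frame)))
  list(movie = movie, truth = truth, events = events)
}

#' Movie container
#'
#' @param frames numeric array `(frame, row, col)`.
#' @param frame_interval seconds between frames.
#' @param pixel_size nm per pixel.
#' @param uv_onset_frame 1-based photoconversion onset frame.
#' @return an `az_movie` object.
#' @export
az_movie <- function(frames, frame_interval, pixel_size, uv_onset_frame) {
  stopifnot(length(dim(frames)) == 3, frame_interval > 0,
            uv_onset_frame >= 1, uv_onset_frame <= dim(frames)[1])
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size,
                 uv_onset_frame = as.integer(uv_onset_frame)),
            class = "az_movie")
}

#' @export
print.az_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("az_movie: %d frames of %d x %d px, %.1f Hz, %g nm/px, UV onset frame %d\n",
              d[1], d[2], d[3], 1 / x$frame_interval, x$pixel_size,
              x$uv_onset_frame))
  invisible(x)
}

#' Write a movie (or image stack) as multi-page TIFF
#'
#' TIFF samples are stored on a 32-bit scale normalized to the movie's
#' intensity range; the range (plus pixel size, frame interval and UV
#' onset) goes into a JSON sidecar so [read_movie_tiff()] restores the
#' original intensities.
#'
#' @param movie an `az_movie`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "az_movie"))
  rng <- range(movie$frames)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(movie$frames)[1]),
                  function(t) (movie$frames[t, , ] - rng[1]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(frame_interval = movie$frame_interval,
               pixel_size = movie$pixel_size,
               uv_onset_frame = movie$uv_onset_frame,
               intensity_min = rng[1], intensity_span = span)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie written by [write_movie_tiff()]
#'
#' @param path TIFF path (expects the JSON sidecar alongside).
#' @return an `az_movie`.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * meta$intensity_span + meta$intensity_min
  az_movie(frames, meta$frame_interval, meta$pixel_size, meta$uv_onset_frame)
}
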