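#' Configuration for synthetic synapse image stacks
#'
#' Emulates triple-stained boutons of the larval neuromuscular junction
#' imaged in 3-D: an HRP membrane channel used as the analysis mask, a
#' brp scaffold channel in which each active zone (AZ) appears as four
#' puncta symmetrically ringing the channel cluster, and two cac channel
#' channels (one per tagged splice isoform). Default sampling matches the
#' STED acquisition being emulated (x/y 24.44 nm, z 191.69 nm); the
#' default ring radius matches the measured control geometry (106 nm
#' median cac-to-brp distance).
#'
#' Coordinate convention (used throughout the package): voxel indices are
#' 0-based, axis order is `(z, y, x)`, punctum centers sit at voxel
#' centers, and physical position (nm) = index x voxel size.
#'
#' @param stack_shape integer `(planes, rows, cols)`.
#' @param voxel_size numeric `(z, y, x)` in nm.
#' @param n_boutons number of boutons in the field.
#' @param az_per_bouton active zones per bouton.
#' @param brp_puncta_per_az puncta per scaffold ring (default 4).
#' @param ring_radius scaffold ring radius in nm (> 0).
#' @param psf_sigma Gaussian PSF SD per axis `(z, y, x)` in nm; 0 renders
#'   point masses into single voxels.
#' @param cac_intensity_A,cac_intensity_B mean per-AZ peak intensity of
#'   the two isoform channels (a.u.). The 2:1 default expresses the
#'   roughly two-fold excess of I-IIB over I-IIA channels per AZ.
#' @param brp_intensity,hrp_intensity peak intensities of the scaffold
#'   puncta and membrane channel (a.u.).
#' @param content_fractions named probabilities of per-AZ isoform content
#'   `c(both=, A_only=, B_only=)`; must sum to 1.
#' @param intensity_cv multiplicative (lognormal) per-AZ intensity
#'   coefficient of variation.
#' @param noise_sd additive Gaussian noise SD per voxel (a.u.).
#' @param seed integer seed.
#' @return a `synapse_sim_config` object.
#' @seealso [simulate_synapse_stack()]
#' @export
synapse_sim_config <- function(stack_shape = c(9L, 160L, 160L),
                               voxel_size = c(191.69, 24.44, 24.44),
                               n_boutons = 2L,
                               az_per_bouton = 4L,
                               brp_puncta_per_az = 4L,
                               ring_radius = 106,
                               psf_sigma = c(120, 30, 30),
                               cac_intensity_A = 50,
                               cac_intensity_B = 100,
                               brp_intensity = 100,
                               hrp_intensity = 60,
                               content_fractions = c(both = 0.95, A_only = 0.0,
                                                     B_only = 0.05),
                               intensity_cv = 0.2,
                               noise_sd = 4,
                               seed = 1L) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1))
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  n_boutons <- check_count(n_boutons, "n_boutons")
  az_per_bouton <- check_count(az_per_bouton, "az_per_bouton")
  brp_puncta_per_az <- check_count(brp_puncta_per_az, "brp_puncta_per_az")
  check_pos(ring_radius, "ring_radius")
  stopifnot(length(psf_sigma) == 3, all(psf_sigma >= 0))
  check_pos(cac_intensity_A, "cac_intensity_A", strict = FALSE)
  check_pos(cac_intensity_B, "cac_intensity_B", strict = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  cf <- content_fractions[c("both", "A_only", "B_only")]
  if (any(is.na(cf)) || any(cf < 0) || abs(sum(cf) - 1) > 1e-9)
    stop_field("content_fractions", "must be named both/A_only/B_only and sum to 1")
  if (ring_radius < min(voxel_size[2:3]))
    warning("ring_radius is smaller than one in-plane voxel; geometry generated anyway")
  structure(list(stack_shape = as.integer(stack_shape),
                 voxel_size = as.numeric(voxel_size),
                 n_boutons = n_boutons, az_per_bouton = az_per_bouton,
                 brp_puncta_per_az = brp_puncta_per_az,
                 ring_radius = ring_radius, psf_sigma = as.numeric(psf_sigma),
                 cac_intensity_A = cac_intensity_A,
                 cac_intensity_B = cac_intensity_B,
                 brp_intensity = brp_intensity, hrp_intensity = hrp_intensity,
                 content_fractions = cf, intensity_cv = intensity_cv,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synapse_sim_config")
}

## Render a Gaussian point mass of peak amplitude `amp` at continuous
## 0-based voxel position `pos` (z,y,x) into array `arr`; sigma in voxels.
render_spot <- function(arr, pos, amp, sigma_vox) {
  d <- dim(arr)
  if (all(sigma_vox <= 0)) {
    ## trilinear mass splitting: preserves the subvoxel center (the
    ## intensity-weighted centroid of the split equals `pos` exactly)
    base <- floor(pos)
    frac <- pos - base
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      idx <- base + c(dz, dy, dx) + 1
      w <- prod(ifelse(c(dz, dy, dx) == 1, frac, 1 - frac))
      if (w > 0 && all(idx >= 1) && all(idx <= d))
        arr[idx[1], idx[2], idx[3]] <- arr[idx[1], idx[2], idx[3]] + amp * w
    }
    return(arr)
  }
  s <- pmax(sigma_vox, 1e-6)
  r <- pmax(1, ceiling(4 * s))
  rng <- lapply(1:3, function(ax)
    max(1, floor(pos[ax] + 1 - r[ax])):min(d[ax], ceiling(pos[ax] + 1 + r[ax])))
  if (any(!lengths(rng))) return(arr)
  gz <- exp(-0.5 * ((rng[[1]] - 1 - pos[1]) / s[1])^2)
  gy <- exp(-0.5 * ((rng[[2]] - 1 - pos[2]) / s[2])^2)
  gx <- exp(-0.5 * ((rng[[3]] - 1 - pos[3]) / s[3])^2)
  patch <- amp * outer(gz, outer(gy, gx))
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + patch
  arr
}

#' Simulate a multi-channel synapse image stack with ground truth
#'
#' Generates boutons (smoothed ellipsoidal HRP signal), places AZs inside
#' them, and renders for each AZ a central cac cluster (split between the
#' two isoform channels according to its drawn content class) ringed by
#' `brp_puncta_per_az` scaffold puncta at `ring_radius`, all within one
#' focal plane per AZ. The PSF is applied as the Gaussian width of each
#' rendered spot; Gaussian noise is added per voxel.
#'
#' @param config a [synapse_sim_config()].
#' @return list with `stack` (an `az_stack`: named channel arrays `hrp`,
#'   `brp`, `cac_a`, `cac_b`, plus `voxel_size`) and `truth`, a data
#'   frame with one row per punctum/cluster: `az_id`, `bouton`, `type`
#'   (`"cac"` or `"brp"`), `plane_index`, positions in nm (`z_nm`,
#'   `y_nm`, `x_nm`), per-channel intensities and `content_class`.
#' @export
simulate_synapse_stack <- function(config) {
  stopifnot(inherits(config, "synapse_sim_config"))
  d <- config$stack_shape
  vs <- config$voxel_size
  chans <- list(hrp = array(0, d), brp = array(0, d),
                cac_a = array(0, d), cac_b = array(0, d))

  set.seed(config$seed)
  ## bouton centers on a coarse in-plane grid, middle plane
  side <- ceiling(sqrt(config$n_boutons))
  margin <- 0.22 * d[2:3]
  gy <- seq(margin[1], d[2] - 1 - margin[1], length.out = max(side, 2))
  gx <- seq(margin[2], d[3] - 1 - margin[2], length.out = max(side, 2))
  centers <- expand.grid(y = gy, x = gx)[seq_len(config$n_boutons), , drop = FALSE]
  ## bouton radius: large enough to hold the AZs, small enough that
  ## neighboring boutons never touch
  grid_sp <- if (config$n_boutons > 1)
    min(c(diff(unique(sort(gy))), diff(unique(sort(gx)))), Inf) else Inf
  bouton_r <- min(0.2 * min(d[2:3]), 0.42 * grid_sp)
  zc <- (d[1] - 1) / 2

  ## HRP: solid ellipsoids, later smoothed
  zi <- (seq_len(d[1]) - 1 - zc) / max((d[1] - 1) / 2, 1)
  for (b in seq_len(config$n_boutons)) {
    for (p in seq_len(d[1])) {
      rp <- bouton_r * sqrt(pmax(1 - zi[p]^2, 0))
      if (rp <= 0) next
      yy <- outer((seq_len(d[2]) - 1 - centers$y[b])^2,
                  (seq_len(d[3]) - 1 - centers$x[b])^2, "+")
      chans$hrp[p, , ][yy <= rp^2] <- config$hrp_intensity
    }
  }
  chans$hrp <- gauss_smooth(chans$hrp, c(0.5, 1.5, 1.5))

  classes <- c("both", "A_only", "B_only")
  truth <- list()
  az_id <- 0L
  ## AZs of one bouton keep a realistic nearest-neighbor distance
  ## (~0.6 um for the default ring) in projection, whatever their focal
  ## plane, so scaffold rings and their dilated masks stay separable
  min_spacing_vox <- 2 * (config$ring_radius / min(vs[2:3]) + 8)
  for (b in seq_len(config$n_boutons)) {
    set.seed(child_seed(config$seed, b))
    planes_avail <- seq(2, max(d[1] - 1, 2))
    plane_order <- rep(sample(planes_avail),
                       length.out = config$az_per_bouton)
    placed <- matrix(numeric(0), ncol = 3)  # (plane, y, x) of accepted AZs
    for (k in seq_len(config$az_per_bouton)) {
      az_id <- az_id + 1L
      plane <- plane_order[k]
      ## rejection-sample the in-plane position so same-plane AZs of one
      ## bouton keep their scaffold rings apart
      for (try in 1:100) {
        ang0 <- runif(1, 0, 2 * pi)
        rr <- runif(1, 0, 0.8 * bouton_r)
        pos_yx <- c(centers$y[b] + rr * sin(ang0), centers$x[b] + rr * cos(ang0))
        if (!nrow(placed) ||
            all(sqrt((placed[, 2] - pos_yx[1])^2 + (placed[, 3] - pos_yx[2])^2) >=
                  min_spacing_vox)) break
      }
      placed <- rbind(placed, c(plane, pos_yx))
      pos <- c(plane - 1, pos_yx)                   # 0-based (z,y,x) voxels
      cls <- classes[sample.int(3, 1, prob = config$content_fractions)]
      jitter <- exp(rnorm(2, 0, config$intensity_cv))
      ia <- if (cls %in% c("both", "A_only")) config$cac_intensity_A * jitter[1] else 0
      ib <- if (cls %in% c("both", "B_only")) config$cac_intensity_B * jitter[2] else 0

      sig_vox <- config$psf_sigma / vs
      chans$cac_a <- render_spot(chans$cac_a, pos, ia, sig_vox)
      chans$cac_b <- render_spot(chans$cac_b, pos, ib, sig_vox)
      truth[[length(truth) + 1L]] <- data.frame(
        az_id = az_id, bouton = b, type = "cac", punctum = 0L,
        plane_index = plane - 1L,
        z_nm = pos[1] * vs[1], y_nm = pos[2] * vs[2], x_nm = pos[3] * vs[3],
        intensity_a = ia, intensity_b = ib,
        brp_intensity = 0, content_class = cls)

      theta <- runif(1, 0, 2 * pi)
      for (j in seq_len(config$brp_puncta_per_az)) {
        a <- theta + (j - 1) * 2 * pi / config$brp_puncta_per_az
        off_nm <- config$ring_radius * c(sin(a), cos(a))
        ppos <- pos + c(0, off_nm / vs[2:3])
        ibrp <- config$brp_intensity * exp(rnorm(1, 0, config$intensity_cv))
        chans$brp <- render_spot(chans$brp, ppos, ibrp, sig_vox)
        truth[[length(truth) + 1L]] <- data.frame(
          az_id = az_id, bouton = b, type = "brp", punctum = j,
          plane_index = plane - 1L,
          z_nm = ppos[1] * vs[1], y_nm = ppos[2] * vs[2], x_nm = ppos[3] * vs[3],
          intensity_a = 0, intensity_b = 0,
          brp_intensity = ibrp, content_class = cls)
      }
    }
  }
  set.seed(child_seed(config$seed, 1000L))
  if (config$noise_sd > 0)
    for (nm in names(chans))
      chans[[nm]] <- chans[[nm]] +
        array(rnorm(prod(d), 0, config$noise_sd), d)

  stack <- structure(list(channels = chans, voxel_size = vs),
                     class = "az_stack")
  list(stack = stack, truth = do.call(rbind, truth))
}

#' @export
print.az_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("az_stack: %d x %d x %d voxels (z,y,x), %s nm, channels: %s\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Write an image stack to per-channel multi-page TIFFs
#'
#' One TIFF per channel (`<stem>_<channel>.tif`, planes as pages) with
#' samples normalized to each channel's intensity range, plus a JSON
#' sidecar carrying the voxel size and per-channel ranges so
#' [read_stack_tiff()] restores the original intensities.
#'
#' @param stack an `az_stack`.
#' @param stem output path stem.
#' @return the stem, invisibly.
#' @export
write_stack_tiff <- function(stack, stem) {
  stopifnot(inherits(stack, "az_stack"))
  ranges <- list()
  for (nm in names(stack$channels)) {
    ch <- stack$channels[[nm]]
    rng <- range(ch)
    span <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(ch)[1]),
                    function(p) (ch[p, , ] - rng[1]) / span)
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", stem, nm),
                    bits.per.sample = 32, reduce = FALSE)
    ranges[[nm]] <- c(rng[1], span)
  }
  jsonlite::write_json(list(voxel_size = stack$voxel_size,
                            channels = names(stack$channels),
                            ranges = ranges),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param stem path stem used when writing.
#' @return an `az_stack`.
#' @export
read_stack_tiff <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  chans <- list()
  for (nm in meta$channels) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", stem, nm), all = TRUE)
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (p in seq_along(pages))
      arr[p, , ] <- pages[[p]] * meta$ranges[[nm]][2] + meta$ranges[[nm]][1]
    chans[[nm]] <- arr
  }
  structure(list(channels = chans, voxel_size = meta$voxel_size),
            class = "az_stack")
}
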