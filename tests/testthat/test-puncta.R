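vs_sted <- c(191.69, 24.44, 24.44)

test_that("a single Gaussian spot is found near its true center", {
  arr <- make_spot_stack(c(2, 14.4, 17.7))
  p <- detect_puncta(arr, vs_sted)
  expect_equal(nrow(p), 1)
  expect_lt(abs(p$y_nm / vs_sted[2] - 14.4), 0.25)
  expect_lt(abs(p$x_nm / vs_sted[3] - 17.7), 0.25)
  expect_equal(p$plane_index, 2)
})

test_that("well-separated spots are each detected once", {
  arr <- make_spot_stack(c(2, 8, 8)) + make_spot_stack(c(2, 22, 22))
  p <- detect_puncta(arr, vs_sted, min_separation = 3)
  expect_equal(nrow(p), 2)
  flat <- array(0, c(3, 20, 20)) + 1e-12
  expect_equal(nrow(detect_puncta(flat + array(rnorm(1200, 0, 1e-6), c(3, 20, 20)),
                                  vs_sted)), 0)
})

test_that("detection on simulated stacks reaches high recall and precision", {
  cfg <- synapse_sim_config(seed = 31)
  out <- simulate_synapse_stack(cfg)
  pb <- detect_puncta(out$stack$channels$brp, cfg$voxel_size)
  truth_b <- out$truth[out$truth$type == "brp", ]
  mp <- match_puncta(pb, truth_b, cfg$voxel_size, radius = 2)
  expect_gte(mp["recall"], 0.95)
  expect_gte(mp["precision"], 0.95)
})

test_that("nearest distances are in-plane and same-section only", {
  cac <- data.frame(z_nm = 0, y_nm = 0, x_nm = 0, plane_index = 0L)
  brp <- data.frame(z_nm = c(0, 0), y_nm = c(0, 500), x_nm = c(100, 0),
                    plane_index = c(0L, 0L))
  d <- nearest_brp_distance(cac, brp)
  expect_equal(d$distance_nm, 100)

  brp_other <- data.frame(z_nm = 200, y_nm = 0, x_nm = 10, plane_index = 1L)
  d2 <- nearest_brp_distance(cac, brp_other)
  expect_equal(nrow(d2), 0)
  expect_equal(attr(d2, "n_excluded"), 1L)
  expect_error(nearest_brp_distance(cac, brp[0, ]), "non-empty")
})

test_that("in-plane rotation leaves the distance distribution unchanged", {
  cfg <- synapse_sim_config(seed = 12)
  out <- simulate_synapse_stack(cfg)
  ch <- out$stack$channels
  cac <- ch$cac_a + ch$cac_b
  rot <- function(a) { # 90 degree in-plane rotation (y, x) -> (x, ny - y)
    d <- dim(a)
    aperm(a, c(1, 3, 2))[, , d[2]:1]
  }
  d0 <- nearest_brp_distance(detect_puncta(cac, cfg$voxel_size),
                             detect_puncta(ch$brp, cfg$voxel_size))
  d1 <- nearest_brp_distance(detect_puncta(rot(cac), cfg$voxel_size),
                             detect_puncta(rot(ch$brp), cfg$voxel_size))
  expect_equal(nrow(d1), nrow(d0))
  expect_equal(stats::median(d1$distance_nm), stats::median(d0$distance_nm),
               tolerance = 0.5 * 24.44 / 106)
})

test_that("masked means are exact on constant signals and dilation behaves", {
  sig <- array(7, c(3, 30, 30))
  msk <- array(FALSE, c(3, 30, 30)); msk[2, 10:20, 10:20] <- TRUE
  mi <- masked_intensity(sig, msk)
  expect_equal(mi$per_az$mean_intensity, 7)
  expect_equal(mi$global_mean, 7)

  ## dilation 0 is the identity
  src <- array(0, c(3, 30, 30))
  src[2, 14:16, 14:16] <- 100
  src <- src + array(abs(rnorm(2700, 0, 0.1)), c(3, 30, 30))
  m0 <- masked_intensity(src, src, dilation_radius = 0, min_size = 4)
  m1 <- masked_intensity(src, src, dilation_radius = 0, min_size = 4)
  expect_identical(m0$per_az, m1$per_az)

  ## centrally peaked signal: masked mean non-increasing with dilation
  peak <- make_spot_stack(c(1, 15, 15), amp = 100, dim3 = c(3, 30, 30))
  mask0 <- array(FALSE, c(3, 30, 30)); mask0[2, 13:17, 13:17] <- TRUE
  means <- vapply(0:3, function(r)
    masked_intensity(peak, mask0, dilation_radius = r)$global_mean, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
  expect_error(masked_intensity(sig, array(FALSE, c(3, 30, 30))), "mask")
})

test_that("normalization to control is exact and idempotent", {
  df <- data.frame(group = c("ctrl", "ctrl", "ctrl", "mut", "mut"),
                   value = c(2, 2, 2, 1, 1))
  nd <- normalize_to_control(df, "ctrl")
  expect_equal(nd$normalized, c(1, 1, 1, 0.5, 0.5))
  nd2 <- normalize_to_control(data.frame(group = nd$group, value = nd$normalized),
                              "ctrl")
  expect_equal(nd2$normalized, nd$normalized, tolerance = 1e-12)
  expect_error(normalize_to_control(df, "missing"), "control")
})

test_that("content classification combines the two presence calls", {
  set.seed(3)
  bg <- rnorm(2000, 0, 4)
  res <- classify_az_content(intensity_a = c(50, 50, 0.1, 0.1),
                             intensity_b = c(60, 0.1, 60, 0.1),
                             background_a = bg, background_b = bg)
  expect_equal(res$per_az$content_class, c("both", "A_only", "B_only", "none"))
  expect_equal(unname(res$fractions["both"]), 0.25)
  expect_error(classify_az_content(numeric(0), numeric(0), bg, bg), "AZ")
})

test_that("cohort content fractions recover the generator mixture", {
  cls <- c(both = 0, A_only = 0, B_only = 0, none = 0); n <- 0
  for (s in 1:4) {
    cfg <- synapse_sim_config(seed = 40 + s)
    st <- simulate_synapse_stack(cfg)
    res <- az_content_from_stack(st$stack)
    cls <- cls + res$fractions * res$n_az
    n <- n + res$n_az
  }
  frac <- cls / n
  ## binomial 95% band around the configured 5% B_only share
  expect_lt(abs(frac[["B_only"]] - 0.05), 2 * sqrt(0.05 * 0.95 / n) + 0.02)
  expect_gt(frac[["both"]], 0.85)
  expect_equal(frac[["none"]], 0)
})
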