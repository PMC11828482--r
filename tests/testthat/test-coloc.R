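test_that("mask building separates a bimodal image and rejects constants", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64, 10, 1), 64, 64)
  img[17:32, 17:48] <- rnorm(16 * 32, 60, 1)   # high mode: 512/4096 = 12.5%
  m <- build_mask(img, min_size = 4)
  expect_equal(sum(m) / length(m), 512 / 4096, tolerance = 0.05 * 8)
  expect_true(all(which(m) %in% which(img > 30)))
  expect_error(build_mask(matrix(5, 10, 10)), "constant")
})

test_that("Pearson within mask hits the exact limits", {
  set.seed(2)
  a <- matrix(runif(400, 1, 9), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  expect_equal(pearson_within_mask(a, a, mask), 1.0)
  expect_equal(pearson_within_mask(a, max(a) - a, mask), -1.0)
  flat <- matrix(1, 20, 20)
  r <- pearson_within_mask(a, flat, mask)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "variance")
})

test_that("independent channels give near-zero correlation", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- matrix(runif(1e4), 100, 100)
    b <- matrix(runif(1e4), 100, 100)
    if (abs(pearson_within_mask(a, b, matrix(TRUE, 100, 100))) < 0.03)
      hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("Costes scan matches the brute-force oracle on constructed pairs", {
  for (s in 1:6) {
    p <- make_coloc_pair(s)
    got <- costes_thresholds(p$a, p$b, p$mask)
    want <- oracle_costes_bruteforce(p$a, p$b, p$mask)
    expect_equal(got$threshold_a, want$threshold_a, tolerance = 1e-12)
    expect_equal(got$threshold_b, want$threshold_b, tolerance = 1e-8)
    expect_null(got$flag)
  }
})

test_that("degenerate and anti-correlated pairs hit the documented edges", {
  a <- matrix(seq(1, 16), 4, 4)
  mask <- matrix(TRUE, 4, 4)
  perfect <- costes_thresholds(a, 2 * a, mask)
  expect_equal(perfect$flag, "no Costes crossing")
  expect_equal(perfect$threshold_a, min(a))

  anti <- costes_thresholds(a, max(a) - a, mask)
  expect_null(anti$flag)
  expect_equal(anti$threshold_a, max(a))
})

test_that("Manders coefficients follow direct summation", {
  a <- matrix(seq(0, 15), 4, 4)
  mask <- matrix(TRUE, 4, 4)
  m <- manders_within_mask(a, a, mask, list(threshold_a = 0, threshold_b = 0))
  expect_equal(m$m1, 1.0)
  expect_equal(m$m2, 1.0)

  b <- matrix(0, 4, 4); b[a == 0] <- 5     # disjoint supports
  md <- manders_within_mask(a, b, mask, list(threshold_a = 0.5, threshold_b = 0.5))
  expect_equal(md$m1, 0.0)
  expect_equal(md$m2, 0.0)

  ## half of a's integrated intensity sits in b-positive voxels
  a2 <- matrix(c(rep(1, 8), rep(3, 8)), 4, 4)
  b2 <- matrix(0, 4, 4)
  b2[c(1:4, 9:12)] <- 10    # covers 4 ones and 4 threes: 16 of 32
  mh <- manders_within_mask(a2, b2, mask, list(threshold_a = 0, threshold_b = 1))
  expect_equal(mh$m1, 0.5)
})

test_that("Pearson is affine-invariant and Manders scale-invariant", {
  p <- make_coloc_pair(7)
  r0 <- pearson_within_mask(p$a, p$b, p$mask)
  expect_equal(pearson_within_mask(3.2 * p$a + 11, p$b, p$mask), r0,
               tolerance = 1e-12)
  th <- costes_thresholds(p$a, p$b, p$mask)
  m0 <- manders_within_mask(p$a, p$b, p$mask, th)
  th_s <- list(threshold_a = th$threshold_a * 5, threshold_b = th$threshold_b)
  m1 <- manders_within_mask(5 * p$a, p$b, p$mask, th_s)
  expect_equal(m1$m1, m0$m1, tolerance = 1e-12)
  expect_equal(m1$m2, m0$m2, tolerance = 1e-12)
})

test_that("restricting the mask to a tightly correlated foreground raises r", {
  set.seed(10)
  n <- 48
  fg <- matrix(FALSE, n, n); fg[10:30, 10:30] <- TRUE
  a <- matrix(runif(n * n, 0, 10), n, n)
  b <- matrix(runif(n * n, 0, 10), n, n)
  a[fg] <- 40 + runif(sum(fg), 0, 30)
  b[fg] <- 2 * a[fg]                       # exact relation inside fg
  r_all <- pearson_within_mask(a, b, matrix(TRUE, n, n))
  r_fg <- pearson_within_mask(a, b, fg)
  expect_equal(r_fg, 1.0)
  expect_gte(r_fg, r_all - 1e-9)
})
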