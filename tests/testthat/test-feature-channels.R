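const_grid <- function(v = 2, n = 8) array(v, c(n, n, n))

test_that("operators map constant grids to the expected constant", {
  x <- const_grid()
  expect_equal(gaussian_filter(x, 2), x)
  expect_equal(tv_denoise(x, 10, n_iter = 20), x)
  expect_equal(local_centering(x, 2), x * 0)
  expect_equal(local_normalization(x, 2), x * 0)
  expect_equal(log_filter(x, 2), x * 0)
  expect_equal(dog_filter(x, 2, 1.6), x * 0)
  expect_equal(structure_tensor_det_filter(x, 2, 2), x * 0)
  expect_equal(threshold_mask(x, vmin = 0), x / 2) # all ones
})

test_that("gaussian filtering equals dense brute-force convolution", {
  set.seed(7)
  x <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(gaussian_filter(x, 1), brute_gauss3(x, 1), tolerance = 1e-10)
  # impulse response
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  expect_equal(gaussian_filter(imp, 1), brute_gauss3(imp, 1),
               tolerance = 1e-12)
})

test_that("gaussian is linear", {
  set.seed(8)
  a <- array(rnorm(5^3), c(5, 5, 5))
  b <- array(rnorm(5^3), c(5, 5, 5))
  expect_equal(gaussian_filter(2 * a + 3 * b, 1.5),
               2 * gaussian_filter(a, 1.5) + 3 * gaussian_filter(b, 1.5),
               tolerance = 1e-10)
})

test_that("TV denoising reduces discrete TV and respects clamping", {
  set.seed(9)
  ph <- make_multiregion(size = 12, n_regions = 2, noise_sd = 0.3,
                         seed = 3, layout = "slabs")
  out <- tv_denoise(ph$volume, lambda = 5, n_iter = 60)
  expect_lt(discrete_tv(out), discrete_tv(ph$volume))
  # clamp truncates the input before denoising
  x <- ph$volume
  cl <- tv_denoise(x, lambda = 0.001, n_iter = 1, clamp = c(0, 0.5))
  expect_gte(min(cl), 0 - 1e-6)
  expect_lte(max(cl), 0.5 + 1e-6)
  expect_error(tv_denoise(x, 5, clamp = c(2, 1)), "ordered")
  expect_error(tv_denoise(x, lambda = -1), "lambda")
})

test_that("threshold mask counts match a brute-force count", {
  set.seed(10)
  x <- array(rnorm(8^3), c(8, 8, 8))
  m <- threshold_mask(x, vmin = -0.5, vmax = 0.7)
  expect_equal(sum(m), sum(x >= -0.5 & x <= 0.7))
  expect_true(all(m %in% c(0, 1)))
  m2 <- threshold_mask(array(c(-1, 2), c(2, 2, 2)), vmin = 0)
  expect_equal(which(m2 == 1), which(array(c(-1, 2), c(2, 2, 2)) == 2))
  expect_equal(sum(threshold_mask(-abs(x), vmin = 0)),
               sum(x == 0)) # all-negative grid -> empty mask
  expect_error(threshold_mask(x), "bound")
})

test_that("gaussian centering has near-zero mean under periodic boundary", {
  set.seed(11)
  x <- array(runif(10^3, 0, 5), c(10, 10, 10))
  ctr <- x - gaussian_filter(x, 2, boundary = "periodic")
  expect_lt(abs(mean(ctr)), 1e-6 * diff(range(x)))
})

test_that("gaussian normalization is invariant to affine rescale", {
  set.seed(12)
  x <- array(rnorm(8^3), c(8, 8, 8))
  n1 <- local_normalization(x, 2)
  n2 <- local_normalization(3.7 * x + 11, 2)
  expect_equal(n1, n2, tolerance = 1e-3)
})

test_that("LoG peaks at a bright blob center and obeys sign options", {
  d <- c(13, 13, 13)
  blob <- exp(-(slice.index(array(0, d), 1) - 7)^2 / 8 -
               (slice.index(array(0, d), 2) - 7)^2 / 8 -
               (slice.index(array(0, d), 3) - 7)^2 / 8)
  bright <- log_filter(blob, sigma = 2, response = "bright")
  expect_equal(which.max(bright), which(blob == max(blob)))
  dark <- log_filter(blob, sigma = 2, response = "dark")
  expect_equal(dark, -bright)
  thr <- log_filter(blob, sigma = 2, response = "bright", thresh = TRUE)
  expect_gte(min(thr), 0)
  # matches the dense second-derivative oracle
  oracle <- -(brute_gauss3(blob, 2, c(2, 0, 0)) +
                brute_gauss3(blob, 2, c(0, 2, 0)) +
                brute_gauss3(blob, 2, c(0, 0, 2)))
  expect_equal(bright, oracle, tolerance = 1e-10)
})

test_that("DoG equals the explicit difference of two gaussian channels", {
  set.seed(13)
  x <- array(rnorm(8^3), c(8, 8, 8))
  expect_equal(dog_filter(x, 1, 1.6),
               gaussian_filter(x, 1) - gaussian_filter(x, 1.6),
               tolerance = 1e-12)
})

test_that("structure tensor det matches per-voxel 3x3 determinants", {
  set.seed(14)
  x <- array(rnorm(7^3), c(7, 7, 7))
  got <- structure_tensor_det_filter(x, 1, 1)
  gz <- brute_gauss3(x, 1, c(1, 0, 0))
  gy <- brute_gauss3(x, 1, c(0, 1, 0))
  gx <- brute_gauss3(x, 1, c(0, 0, 1))
  S <- function(v) brute_gauss3(v, 1)
  jzz <- S(gz * gz); jyy <- S(gy * gy); jxx <- S(gx * gx)
  jzy <- S(gz * gy); jzx <- S(gz * gx); jyx <- S(gy * gx)
  oracle <- array(0, dim(x))
  for (i in seq_along(x)) {
    M <- matrix(c(jzz[i], jzy[i], jzx[i],
                  jzy[i], jyy[i], jyx[i],
                  jzx[i], jyx[i], jxx[i]), 3, 3)
    oracle[i] <- det(M)
  }
  expect_equal(got, oracle, tolerance = 1e-8)
  expect_gte(min(got), -1e-10) # PSD determinant
})

test_that("channel queue resolves dependencies and rejects bad specs", {
  ph <- make_multiregion(size = 12, seed = 4)
  ws <- new_workspace(ph$volume)
  # chained queue (listed out of order) equals manual composition
  compute_queue(ws, list(
    list(name = "tv", operator = "total_variation", source = "g",
         params = list(lambda = 2, n_iter = 50)),
    list(name = "g", operator = "gaussian", params = list(sigma = 1))
  ))
  manual <- tv_denoise(gaussian_filter(roi_data(ws), 1), 2, n_iter = 50)
  expect_equal(ws$channels$tv$data, manual)

  expect_silent(compute_queue(ws, list())) # empty queue: no change
  expect_error(compute_queue(ws, list(
    list(name = "z", operator = "gaussian", source = "nope",
         params = list(sigma = 1)))), "undefined source")
  expect_error(compute_queue(ws, list(
    list(name = "a", operator = "gaussian", source = "b",
         params = list(sigma = 1)),
    list(name = "b", operator = "gaussian", source = "a",
         params = list(sigma = 1)))), "cyclic")
})

test_that("recomputing a channel invalidates its dependents", {
  ph <- make_multiregion(size = 12, seed = 4)
  ws <- new_workspace(ph$volume)
  compute_channel(ws, "g", "gaussian", params = list(sigma = 1))
  compute_channel(ws, "tv", "total_variation", source = "g",
                  params = list(lambda = 2, n_iter = 50))
  compute_channel(ws, "g", "gaussian", params = list(sigma = 2))
  expect_null(ws$channels$tv)
})

test_that("parameters outside the documented ranges warn", {
  ph <- make_multiregion(size = 10, seed = 4)
  ws <- new_workspace(ph$volume)
  expect_warning(compute_channel(ws, "g", "gaussian",
                                 params = list(sigma = 20)), "range")
  expect_silent(compute_channel(ws, "g2", "gaussian",
                                params = list(sigma = 2)))
})
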