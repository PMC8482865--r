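test_that("histogram matching maps onto the reference distribution", {
  set.seed(11)
  img <- matrix(runif(400, 0, 255), 20)

  # identity and pure-shift inputs recover the reference exactly
  expect_equal(match_histogram(img, img), img, tolerance = 1e-10)
  shifted <- img + 50
  expect_equal(match_histogram(shifted, img), img, tolerance = 1e-10)

  # matching never increases the KS distance to the reference
  ref <- matrix(rgamma(400, shape = 2, scale = 30), 20)
  out <- match_histogram(img, ref)
  ks <- function(x, y) suppressWarnings(ks.test(as.vector(x),
                                                as.vector(y))$statistic)
  expect_lte(ks(out, ref), ks(img, ref))

  # idempotence under the same reference
  expect_equal(match_histogram(out, ref), out, tolerance = 1e-10)

  expect_error(match_histogram(img, matrix(5, 4, 4)), "constant")
})

test_that("blob enhancement is a mean-conserving Gaussian convolution", {
  # impulse response is the sampled Gaussian kernel
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  out <- blob_enhance(img, sigma = 2)
  k <- exp(-0.5 * (-6:6)^2 / 4); k <- k / sum(k)
  expect_equal(out[11, 5:17], k[7] * k, tolerance = 1e-12)

  # constant image unchanged; mean conserved within 1 %
  cst <- matrix(3.5, 16, 16)
  expect_equal(blob_enhance(cst, 1.5), cst, tolerance = 1e-12)
  set.seed(2)
  noisy <- matrix(runif(64 * 64), 64)
  sm <- blob_enhance(noisy, 2)
  expect_lt(abs(mean(sm) / mean(noisy) - 1), 0.01)
  expect_lt(var(as.vector(sm)), var(as.vector(noisy)))

  # physical sigma honours anisotropic voxels: a 3D blur with
  # voxel-matched sigma equals the voxel-space blur
  arr <- array(0, dim = c(9, 9, 9)); arr[5, 5, 5] <- 1
  a <- blob_enhance(arr, sigma = 1, voxel_size = c(0.5, 0.25, 0.25))
  b <- blob_enhance(arr, sigma = c(2, 4, 4))
  expect_equal(a, b, tolerance = 1e-12)

  expect_error(blob_enhance(cst, 0), "sigma")
})

test_that("difference of Gaussians is a linear band-pass", {
  cst <- matrix(7, 32, 32)
  expect_equal(dog_enhance(cst, 1, 4), matrix(0, 32, 32), tolerance = 1e-10)

  set.seed(3)
  img <- matrix(runif(1024), 32)
  expect_equal(dog_enhance(3 * img, 1, 4), 3 * dog_enhance(img, 1, 4),
               tolerance = 1e-10)

  # response to a disk of radius ~ sqrt(s_small * s_large) peaks at center
  img2 <- matrix(0, 41, 41)
  rr <- sqrt((row(img2) - 21)^2 + (col(img2) - 21)^2)
  img2[rr <= 2] <- 1
  resp <- dog_enhance(img2, 1, 4)
  expect_equal(which(resp == max(resp), arr.ind = TRUE)[1, ],
               c(row = 21, col = 21))

  expect_error(dog_enhance(img, 4, 1), "sigma_small")
})

test_that("disk background subtraction keeps small features, removes background", {
  cst <- matrix(13, 30, 30)
  expect_equal(subtract_background(cst, 5), matrix(0, 30, 30))

  # bright spot on flat background: amplitude kept, background zeroed
  img <- matrix(10, 40, 40)
  img[20:21, 20:21] <- 10 + 55
  out <- subtract_background(img, 6)
  expect_equal(out[20, 20], 55)
  expect_equal(out[5, 5], 0)

  # anti-extensivity: output never exceeds input
  set.seed(4)
  img2 <- matrix(rgamma(900, 2, 1), 30)
  expect_true(all(subtract_background(img2, 4) <= img2 + 1e-12))

  expect_error(subtract_background(matrix(1:16, 4), 10), "larger")
})

test_that("Otsu threshold equals the exhaustive between-class-variance argmax", {
  # perfectly separable bi-valued image
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10)
  ot <- otsu_threshold(img)
  expect_identical(unname(ot$mask), unname(img == 200))

  # oracle equivalence on assorted histograms, including a 16-bin toy
  set.seed(5)
  cases <- c(
    list(matrix(sample(seq(0, 150, 10), 256, replace = TRUE), 16)),
    lapply(1:8, function(i) matrix(c(rnorm(300, 40, 12),
                                     rnorm(i * 30, 160, 20)), ncol = 10))
  )
  for (img_i in cases) {
    expect_equal(otsu_threshold(img_i)$threshold,
                 oracle_otsu_threshold(img_i), tolerance = 1e-12)
  }

  # mask invariant under monotone affine rescaling
  img3 <- cases[[3]]
  expect_identical(otsu_threshold(img3)$mask,
                   otsu_threshold(2.5 * img3 + 7)$mask)

  expect_error(otsu_threshold(matrix(1, 5, 5)), "constant")
})

test_that("active contours refine toward intensity boundaries and stay put on them", {
  img <- matrix(0, 64, 64)
  disk <- (row(img) - 32)^2 + (col(img) - 32)^2 <= 15^2
  img[disk] <- 1

  # matching init is an exact fixed point of the un-smoothed flow
  expect_identical(refine_active_contour(img, disk, 35, smoothing = 0), disk)

  # with curvature smoothing the digital disk stays within a whisker
  out <- refine_active_contour(img, disk, 35, smoothing = 1)
  expect_gt(sum(out & disk) / sum(out | disk), 0.98)

  # an eroded init recovers nearly all of the true disk
  eroded <- (row(img) - 32)^2 + (col(img) - 32)^2 <= 13^2
  rec <- refine_active_contour(img, eroded, 35, smoothing = 1)
  expect_gt(sum(rec & disk) / sum(rec | disk), 0.95)

  # zero iterations = identity; empty init errors
  expect_identical(refine_active_contour(img, eroded, 0), eroded)
  expect_error(refine_active_contour(img, disk & FALSE, 10), "empty")
})
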