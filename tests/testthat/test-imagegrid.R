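test_that("voxel grid containers validate their geometry", {
  expect_error(voxel_grid(matrix(0, 2, 2)), "3D")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  expect_error(binary_mask(array(2, c(2, 2, 2))), "0 and 1")
  g <- voxel_grid(array(1, c(2, 3, 4)), spacing = c(1, 1, 2),
                  origin = c(-1, 0, 5))
  expect_identical(dim(g$data), c(2L, 3L, 4L))
  expect_error(dynamic_sequence(list(g)), "2 frames")
})

test_that("mask I/O round-trips NIfTI and MetaImage voxelwise", {
  set.seed(42)
  m <- binary_mask(array(as.integer(stats::runif(1000) > 0.5), c(10, 10, 10)),
                   spacing = c(1.5, 2, 2.5))
  for (ext in c("nii.gz", "mhd")) {
    path <- file.path(tempdir(), paste0("m.", ext))
    write_mask(m, path)
    back <- read_mask(path)
    expect_identical(back$data, m$data)
    expect_equal(back$spacing, m$spacing, tolerance = 1e-5)
  }
  # all-ones 2x2x2 identity case
  one <- binary_mask(array(1L, c(2, 2, 2)))
  p <- file.path(tempdir(), "one.nii.gz")
  write_mask(one, p)
  expect_equal(sum(read_mask(p)$data), 8)
  expect_error(read_mask(file.path(tempdir(), "missing.nii.gz")), "not found")
})

test_that("Otsu threshold maximises between-class variance", {
  # perfectly separable two-level volume
  v <- voxel_grid(array(rep(c(10, 200), each = 500), c(10, 10, 10)))
  m <- otsu_threshold(v)
  expect_identical(sum(m$data), 500L)
  expect_true(all(m$data[v$data == 200] == 1L))
  # bimodal Gaussian mixture: threshold separates the modes and matches
  # an exhaustive scan over all 256 bin cuts (the variance plateaus over
  # the empty gap; ties resolve toward the lower cut by design)
  set.seed(1)
  x <- c(stats::rnorm(5e4, 50, 10), stats::rnorm(5e4, 180, 10))
  vol <- voxel_grid(array(x, c(100, 100, 10)))
  m2 <- otsu_threshold(vol)
  thr <- attr(m2, "threshold")
  expect_gt(thr, 50); expect_lt(thr, 180)
  expect_equal(sum(m2$data), 5e4, tolerance = 0.01)
  breaks <- seq(min(x), max(x), length.out = 257)
  h <- as.numeric(tabulate(findInterval(x, breaks, all.inside = TRUE), 256))
  mids <- (breaks[-1] + breaks[-257]) / 2
  best <- -Inf; best_k <- NA
  for (k in 1:255) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):256] * mids[(k + 1):256]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-6) { best <- sb; best_k <- k }
  }
  expect_equal(thr, breaks[best_k + 1], tolerance = 1e-10)
  expect_error(otsu_threshold(voxel_grid(array(5, c(3, 3, 3)))), "constant")
})

test_that("body mask excludes the lung mask and matches Otsu otherwise", {
  set.seed(2)
  v <- voxel_grid(array(stats::rnorm(8^3, 100, 5), c(8, 8, 8)))
  v$data[3:6, 3:6, 3:6] <- stats::rnorm(64, 10, 2)     # dark hole
  m0 <- build_body_mask(v)
  expect_identical(m0$data, otsu_threshold(v)$data)
  expect_true(all(m0$data[3:6, 3:6, 3:6] == 0L))
  excl <- binary_mask(array(1L, c(8, 8, 8)))
  expect_warning(m1 <- build_body_mask(v, excl), "empty")
  expect_identical(sum(m1$data), 0L)
})

test_that("iterative bias correction drives the corrector with fresh masks", {
  set.seed(3)
  v <- voxel_grid(array(stats::rnorm(10^3, 100, 3), c(10, 10, 10)))
  ident <- function(volume, mask) volume
  out <- iterative_bias_correction(v, ident, n_iter = 3)
  expect_equal(out$data, v$data)
  expect_error(iterative_bias_correction(v, ident, n_iter = 0), "n_iter")
  # multiplicative linear bias on a two-tissue phantom: coefficient of
  # variation inside the body decreases monotonically over iterations
  n <- 16L
  base <- array(10, c(n, n, n))
  base[4:13, 4:13, 4:13] <- 120
  bias <- array(rep(seq(0.6, 1.6, length.out = n), each = n * n / n) , c(n, n, n))
  bias <- aperm(bias, c(3, 1, 2))
  vol <- voxel_grid(base * bias)
  cvs <- numeric(3)
  for (it in 1:3) {
    corr <- iterative_bias_correction(vol, poly_bias_corrector(order = 2),
                                      n_iter = it)
    body <- attr(corr, "mask")$data == 1L
    cvs[it] <- stats::sd(corr$data[body]) / mean(corr$data[body])
  }
  body0 <- otsu_threshold(vol)$data == 1L
  cv0 <- stats::sd(vol$data[body0]) / mean(vol$data[body0])
  expect_true(all(diff(c(cv0, cvs)) <= 1e-8))
})

test_that("dilation is a physical-space ball and is monotone", {
  m <- binary_mask(array(0L, c(9, 9, 9)))
  m$data[5, 5, 5] <- 1L
  expect_identical(dilate_mask(m, 0)$data, m$data)
  d2 <- dilate_mask(m, 2)
  idx <- which(array(TRUE, dim(m$data)), arr.ind = TRUE)
  dist <- sqrt(rowSums(sweep(idx, 2, c(5, 5, 5))^2))
  expect_identical(as.vector(d2$data[idx]), as.integer(dist <= 2))
  # anisotropic spacing: same physical radius
  ma <- binary_mask(array(0L, c(9, 9, 5)), spacing = c(1, 1, 2))
  ma$data[5, 5, 3] <- 1L
  da <- dilate_mask(ma, 2)
  expect_identical(sum(da$data[5, 5, ]), 3L)   # +-1 voxel along z (2 mm)
  expect_identical(sum(da$data[, 5, 3] ), 5L)  # +-2 voxels along x
  # monotone in radius and extensive
  d1 <- dilate_mask(m, 1)
  expect_true(all(d1$data >= m$data))
  expect_true(all(d2$data >= d1$data))
  expect_error(dilate_mask(m, -1), ">= 0")
})

test_that("Dice overlap counts voxels", {
  a <- binary_mask(array(0L, c(6, 6, 6))); a$data[2:3, 2:3, 2:3] <- 1L
  expect_equal(dice_overlap(a, a), 1)
  b <- binary_mask(array(0L, c(6, 6, 6))); b$data[5, 5, 5] <- 1L
  expect_equal(dice_overlap(a, b), 0)
  # 8-voxel cube shifted one voxel along x: overlap 4 -> Dice 0.5
  s <- binary_mask(array(0L, c(6, 6, 6))); s$data[3:4, 2:3, 2:3] <- 1L
  expect_equal(dice_overlap(a, s), 0.5)
  expect_equal(dice_overlap(s, a), 0.5)
  e <- binary_mask(array(0L, c(6, 6, 6)))
  expect_equal(dice_overlap(e, e), 1)
  expect_error(dice_overlap(a, binary_mask(array(0L, c(5, 5, 5)))), "grid")
})

test_that("connected components and largest-component filter", {
  m <- binary_mask(array(0L, c(10, 10, 10)))
  m$data[2:5, 2:5, 2:5] <- 1L
  m$data[8:9, 8:9, 8:9] <- 1L
  lab <- mask_components(m)
  expect_identical(attr(lab, "sizes"), c(64L, 8L))
  big <- largest_component(m)
  expect_identical(sum(big$data), 64L)
  expect_true(all(big$data[8:9, 8:9, 8:9] == 0L))
})
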