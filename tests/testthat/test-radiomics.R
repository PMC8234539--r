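test_that("znormalize matches its definition and is affine invariant", {
  set.seed(1)
  x <- array(rnorm(8^3, 5, 3), dim = c(8, 8, 8))
  z <- znormalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  expect_equal(znormalize(2.5 * x - 7), z, tolerance = 1e-12)
  # population-SD convention on a toy vector
  toy <- array(c(1, 2, 3, 4), dim = c(4, 1, 1))
  expect_equal(as.numeric(znormalize(toy)),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
  expect_error(znormalize(array(3, dim = c(4, 4, 4))), "zero variance")
})

test_that("discretize maps to 1..n_bins with equal-width bins", {
  vals <- array(c(0, 1, 2, 3), dim = c(4, 1, 1))
  roi <- image_roi(vals, array(TRUE, dim = c(4, 1, 1)))
  expect_equal(as.numeric(discretize(roi, 4)$intensities), 1:4)
  cst <- image_roi(array(5, dim = c(3, 3, 1)), array(TRUE, dim = c(3, 3, 1)))
  expect_true(all(discretize(cst, 8)$intensities == 1L))
  expect_error(discretize(roi, 1), "n_bins")
  # uniform sample spreads evenly over bins
  set.seed(3)
  u <- array(runif(1e4), dim = c(100, 100, 1))
  roi_u <- image_roi(u, array(TRUE, dim = c(100, 100, 1)))
  counts <- tabulate(discretize(roi_u, 8)$intensities, 8)
  expect_true(all(abs(counts - 1250) < 5 * sqrt(1e4 * (1 / 8) * (7 / 8))))
})

test_that("first-order features match hand computations and sentinels", {
  roi <- image_roi(array(c(1, 2, 3, 4, 5), dim = c(5, 1, 1)),
                   array(TRUE, dim = c(5, 1, 1)))
  fo <- first_order(roi)
  expect_equal(unname(fo["Mean"]), 3)
  expect_equal(unname(fo["Variance"]), 2)   # population variance
  expect_equal(unname(fo["Range"]), 4)
  expect_equal(unname(fo["Median"]), 3)
  expect_equal(unname(fo["Energy"]), sum((1:5)^2))
  # two-value histogram: 1 bit of entropy
  roi2 <- image_roi(array(rep(c(0, 1), each = 8), dim = c(16, 1, 1)),
                    array(TRUE, dim = c(16, 1, 1)))
  expect_equal(unname(first_order(roi2)["Entropy"]), 1)
  # constant ROI sentinels
  cst <- image_roi(array(7, dim = c(3, 3, 3)), array(TRUE, dim = c(3, 3, 3)))
  fc <- first_order(cst)
  expect_equal(unname(fc[c("Variance", "Skewness", "Kurtosis")]), c(0, 0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("shape features: volume, sphericity limit, PCA axis ratios", {
  single <- array(FALSE, dim = c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(unname(shape_features(single)["VoxelVolume"]), 1)
  expect_equal(unname(shape_features(single, c(2, 2, 2))["VoxelVolume"]), 8)

  sph <- vapply(c(5, 8, 11), function(r) {
    unname(shape_features(ball_mask(2 * r + 8, r))["Sphericity"])
  }, 0)
  expect_true(all(sph >= 0.9))
  expect_true(all(sph <= 1))
  expect_true(all(diff(sph) >= -1e-6))  # approaches 1 as the ball grows

  # rod: compare elongation/flatness against direct PCA of voxel coordinates
  rod <- array(FALSE, dim = c(14, 5, 5)); rod[2:13, 2:3, 3] <- TRUE
  sh <- shape_features(rod, c(1, 1, 1))
  ev <- eigen(stats::cov(which(rod, arr.ind = TRUE)), symmetric = TRUE)$values
  expect_equal(unname(sh["Elongation"]), sqrt(ev[2] / ev[1]), tolerance = 1e-10)
  expect_equal(unname(sh["Flatness"]), sqrt(ev[3] / ev[1]), tolerance = 1e-10)
  expect_gt(sh["Maximum3DDiameter"], 11)

  # intensity independence: same mask, any intensities -> same shape vector
  roi <- toy_roi(seed = 5)
  expect_identical(shape_features(roi$mask, roi$spacing),
                   shape_features(roi$mask, roi$spacing))
})

test_that("GLCM features match hand-counted co-occurrences", {
  cst <- image_roi(array(4, dim = c(4, 4, 2)), array(TRUE, dim = c(4, 4, 2)))
  g <- glcm_features(discretize(cst, 8))
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEnergy"]), 1)
  # 4x4 checkerboard, in-plane offsets: all neighbour pairs differ by 1
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1)
  roi <- image_roi(array(cb, dim = c(4, 4, 1)), array(TRUE, dim = c(4, 4, 1)))
  g2 <- glcm_features(discretize(roi, 2),
                      directions = rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(unname(g2["Contrast"]), 1)
  expect_equal(unname(g2["Correlation"]), -1)
  expect_equal(unname(g2["Dissimilarity"]), 1)
})

test_that("directional GLCMs are normalized before averaging", {
  roi <- discretize(toy_roi(seed = 9), 8)
  for (d in list(c(1, 0, 0), c(1, -1, 1))) {
    m <- radsurv:::glcm_accumulate(roi$intensities, d, 8)
    expect_gt(sum(m), 0)
    expect_equal(sum(m / sum(m)), 1, tolerance = 1e-12)
    expect_equal(m, t(m))  # symmetric accumulation
  }
})

test_that("voxel shuffling changes texture but not first-order features", {
  set.seed(11)
  roi <- toy_roi(seed = 11)
  perm <- roi
  inside <- which(roi$mask)
  perm$intensities[inside] <- roi$intensities[sample(inside)]
  expect_equal(first_order(roi), first_order(perm), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(glcm_features(discretize(roi, 16)),
                                glcm_features(discretize(perm, 16)))))
})

test_that("LoG filter: zero on constants, linear, scale-selective", {
  cst <- array(3, dim = c(12, 12, 12))
  expect_lt(max(abs(log_filter(cst, 2))), 1e-10)
  set.seed(4)
  x <- array(rnorm(12^3), dim = c(12, 12, 12))
  expect_equal(log_filter(3 * x, 1.5), 3 * log_filter(x, 1.5), tolerance = 1e-12)
  # Gaussian blob of scale ~2 voxels: strongest normalized response at sigma 2
  g1 <- exp(-((1:24) - 12.5)^2 / (2 * 4))
  blob <- outer(outer(g1, g1), g1); dim(blob) <- c(24, 24, 24)
  resp <- vapply(1:3, function(s) max(abs(log_filter(blob, s))), 0)
  expect_equal(which.max(resp), 2L)
  expect_warning(log_filter(x, 10), "extent")
})

test_that("wavelet bank is orthogonal and matches a direct 1D oracle", {
  cst <- array(2, dim = c(8, 8, 8))
  b <- wavelet_bank(cst)
  for (nm in setdiff(names(b), "LLL")) expect_lt(max(abs(b[[nm]])), 1e-10)
  expect_gt(min(abs(b$LLL)), 1e-3)  # scaled constant

  set.seed(6)
  img <- array(rnorm(16 * 12 * 8), dim = c(16, 12, 8))
  bands <- wavelet_bank(img)
  expect_equal(sum(vapply(bands, function(z) sum(z^2), 0)), sum(img^2),
               tolerance = 1e-9)  # Parseval

  # independent oracle: direct circular convolution + decimation along x
  lo <- radsurv:::coif1_lo()
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  n <- 16
  conv_dec <- function(v, taps) {
    vapply(seq_len(n / 2), function(m) {
      sum(vapply(seq_along(taps), function(k) {
        taps[k] * v[((2 * (m - 1) + (k - 1)) %% n) + 1]
      }, 0))
    }, 0)
  }
  # impulse response: each sub-band is the tensor product of the 1D
  # decimated circular convolutions of the per-axis filters
  impulse <- array(0, dim = c(16, 16, 16)); impulse[5, 3, 2] <- 1
  bi <- wavelet_bank(impulse)
  conv_axis <- function(pos, taps) {
    v <- numeric(16); v[pos] <- 1
    vapply(seq_len(8), function(m) {
      sum(vapply(seq_along(taps), function(k) {
        taps[k] * v[((2 * (m - 1) + (k - 1)) %% 16) + 1]
      }, 0))
    }, 0)
  }
  for (band in c("LLL", "HLL", "LHH", "HHH")) {
    f <- strsplit(band, "")[[1]]
    tap <- function(ch) if (ch == "L") lo else hi
    oracle <- outer(outer(conv_axis(5, tap(f[1])), conv_axis(3, tap(f[2]))),
                    conv_axis(2, tap(f[3])))
    expect_equal(bi[[band]], oracle, tolerance = 1e-12)
  }
  expect_error(wavelet_bank(array(0, dim = c(4, 16, 16))), "filter length")
})

test_that("extract_all is deterministic with a stable registry", {
  roi <- toy_roi(n = 16, r = 5, seed = 13)
  f1 <- extract_all(roi)
  f2 <- extract_all(roi)
  expect_identical(f1, f2)
  reg <- feature_registry()
  expect_equal(length(f1), nrow(reg))
  expect_identical(names(f1), reg$name)
  # documented composition: 18 first-order and 6 GLCM per image (1 original +
  # 3 LoG + 8 wavelet), plus 7 shape
  expect_equal(nrow(reg), 18 * 12 + 6 * 12 + 7)
  expect_false(anyNA(f1))
})

test_that("first-order features are invariant to affine intensity rescaling", {
  roi <- toy_roi(n = 14, r = 4, seed = 17)
  roi2 <- roi
  roi2$intensities <- 4.2 * roi$intensities + 11
  f1 <- extract_all(roi)
  f2 <- extract_all(roi2)
  fo <- grep("original_firstorder_", names(f1))
  expect_equal(f1[fo], f2[fo], tolerance = 1e-8)
})

test_that("a constant lesion yields zero original-image texture contrast", {
  set.seed(19)
  n <- 14
  mask <- ball_mask(n, 4)
  img <- array(rnorm(n^3), dim = c(n, n, n))
  img[mask] <- 50
  fv <- extract_all(image_roi(img, mask))
  expect_equal(unname(fv["original_glcm_Contrast"]), 0)
  expect_equal(unname(fv["original_firstorder_Variance"]), 0)
})
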