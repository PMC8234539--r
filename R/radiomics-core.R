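#' Lesion-masked image volume
#'
#' Container for a 3D intensity volume with an aligned binary lesion mask and
#' voxel spacing in mm. All radiomic feature operations take an `image_roi`.
#'
#' @param intensities 3D numeric array (arbitrary units).
#' @param mask 3D logical (or 0/1) array, same shape; at least one voxel TRUE.
#' @param spacing numeric length 3, mm per axis, all positive.
#' @return An object of class `image_roi`.
#' @export
image_roi <- function(intensities, mask, spacing = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3L) stop("intensities must be a 3D array")
  if (!identical(dim(intensities), dim(mask))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match intensities shape ",
         paste(dim(intensities), collapse = "x"))
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask is empty: at least one voxel must be inside the ROI")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive finite numbers (mm)")
  }
  structure(list(intensities = intensities, mask = mask, spacing = spacing),
            class = "image_roi")
}

#' @export
print.image_roi <- function(x, ...) {
  cat("<image_roi> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, ", sum(x$mask), " in mask, spacing ",
      paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Z-score normalization of an image volume
#'
#' Centers and scales the whole volume to mean 0 and (population) SD 1,
#' the standard intensity normalization applied before feature extraction.
#' Operates on the full volume, not just the mask, so that lesion/background
#' contrast is preserved in the normalized units.
#'
#' @param image 3D numeric array or an [image_roi] (normalized in place).
#' @return Same type as the input.
#' @export
znormalize <- function(image) {
  if (inherits(image, "image_roi")) {
    image$intensities <- znormalize(image$intensities)
    return(image)
  }
  mu <- mean(image)
  sdv <- sqrt(mean((image - mu)^2))
  if (!is.finite(sdv) || sdv == 0) stop("zero variance: cannot z-normalize a constant volume")
  (image - mu) / sdv
}

#' Equal-width gray-level discretization inside the mask
#'
#' Maps masked intensities to integer gray levels `1..n_bins` by equal-width
#' binning over the in-mask intensity range; the maximum maps to `n_bins`.
#' A constant ROI maps to level 1 everywhere. Voxels outside the mask get
#' level 0 and are ignored by all texture computations.
#'
#' @param roi an [image_roi].
#' @param n_bins number of gray levels (>= 2); default 32.
#' @return An [image_roi] whose intensities are integer labels in `0..n_bins`,
#'   with attribute `n_bins`.
#' @export
discretize <- function(roi, n_bins = 32L) {
  stopifnot(inherits(roi, "image_roi"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  v <- roi$intensities[roi$mask]
  lab <- array(0L, dim = dim(roi$intensities))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lab[roi$mask] <- 1L
  } else {
    b <- floor((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    b[b > n_bins] <- n_bins
    lab[roi$mask] <- b
  }
  out <- roi
  out$intensities <- lab
  attr(out, "n_bins") <- n_bins
  out
}

#' First-order (histogram/intensity) features
#'
#' Computes the 18 first-order statistics of the masked intensities. Variance,
#' skewness and kurtosis use population moments; entropy and uniformity are
#' computed on the equal-width discretized histogram (`n_bins` levels,
#' entropy in bits); kurtosis is uncorrected (a Gaussian scores ~3).
#' On a zero-variance ROI skewness and kurtosis return the sentinel 0.
#'
#' @param roi an [image_roi].
#' @param n_bins gray levels for the histogram-based features; default 32.
#' @return Named numeric vector of 18 features.
#' @export
first_order <- function(roi, n_bins = 32L) {
  stopifnot(inherits(roi, "image_roi"))
  x <- roi$intensities[roi$mask]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  qs <- unname(stats::quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  mid <- x[x >= qs[1] & x <= qs[5]]
  lab <- discretize(roi, n_bins)
  p <- tabulate(lab$intensities[lab$mask], nbins = n_bins) / n
  pz <- p[p > 0]
  c(
    Mean = mu,
    Median = qs[3],
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(x^2),
    TotalEnergy = prod(roi$spacing) * sum(x^2),
    Entropy = -sum(pz * log2(pz)),
    Uniformity = sum(p^2),
    RootMeanSquared = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    InterquartileRange = qs[4] - qs[2]
  )
}

# Surface area of the mask boundary by the co-area formula: smooth the binary
# indicator with a small Gaussian and integrate |gradient|. Converges to the
# true area for smooth surfaces and is far less staircase-biased than counting
# exposed voxel faces (which overestimates a sphere by ~50%).
surface_area_coarea <- function(mask, spacing, sigma_vox = 0.8) {
  m <- array(as.double(mask), dim = dim(mask))
  pad <- ceiling(4 * sigma_vox)
  dmp <- dim(m) + 2L * pad
  mp <- array(0, dim = dmp)
  mp[pad + seq_len(dim(m)[1]), pad + seq_len(dim(m)[2]), pad + seq_len(dim(m)[3])] <- m
  sm <- gaussian_smooth(mp, sigma_vox = rep(sigma_vox, 3))
  g2 <- array(0, dim = dmp)
  for (ax in 1:3) {
    d <- central_diff(sm, ax) / spacing[ax]
    g2 <- g2 + d^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

central_diff <- function(x, axis) {
  n <- dim(x)[axis]
  idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
  slice <- function(i) {
    ix <- rep(list(quote(expr = )), 3); ix[[axis]] <- i
    do.call(`[`, c(list(x), ix, list(drop = FALSE)))
  }
  (slice(idx_p) - slice(idx_m)) / 2
}

#' Shape features of a lesion mask
#'
#' Mask-only descriptors: volume, surface area (co-area estimate of the
#' boundary integral), sphericity, surface-to-volume ratio, maximum 3D
#' diameter (largest pairwise distance between boundary voxels), and
#' elongation/flatness from the principal axes of the voxel point cloud
#' (square roots of eigenvalue ratios, second/first and third/first).
#'
#' @param mask 3D logical array with at least one voxel.
#' @param spacing mm per axis.
#' @return Named numeric vector of 7 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  nv <- sum(mask)
  vol <- nv * prod(spacing)
  area <- surface_area_coarea(mask, spacing)
  # the co-area area estimate can undershoot by a few % on near-spherical
  # digitized masks; clip so sphericity stays in (0, 1]
  sph <- min(1, pi^(1 / 3) * (6 * vol)^(2 / 3) / area)

  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx, 2, spacing, `*`)
  # boundary voxels: at least one 6-neighbour outside the mask (or grid edge)
  on_boundary <- rep(FALSE, nrow(idx))
  dm <- dim(mask)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx
    nb[, ax] <- nb[, ax] + s
    inside <- nb[, ax] >= 1L & nb[, ax] <= dm[ax]
    val <- rep(FALSE, nrow(nb))
    val[inside] <- mask[nb[inside, , drop = FALSE]]
    on_boundary <- on_boundary | !val
  }
  bp <- pts[on_boundary, , drop = FALSE]
  if (nrow(bp) > 400L) bp <- bp[seq(1L, nrow(bp), length.out = 400L), , drop = FALSE]
  if (nrow(bp) >= 2L) {
    maxd <- sqrt(max(as.matrix(stats::dist(bp))^2))
  } else {
    maxd <- 0
  }

  if (nv >= 2L) {
    ev <- eigen(stats::cov(pts), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
    flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  } else {
    elong <- flat <- 0
  }
  c(VoxelVolume = vol, SurfaceArea = area, Sphericity = sph,
    SurfaceVolumeRatio = area / vol, Maximum3DDiameter = maxd,
    Elongation = elong, Flatness = flat)
}

# the 13 unique 3D direction offsets (opposites folded in by symmetry)
glcm_directions <- function() {
  rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
  )
}

# co-occurrence counts of labels (0 = outside mask) for one voxel offset
glcm_accumulate <- function(lab, offset, n_bins) {
  dm <- dim(lab)
  r <- lapply(1:3, function(ax) {
    o <- offset[ax]
    if (o >= 0) seq_len(dm[ax] - o) else seq(1 - o, dm[ax])
  })
  a <- lab[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b <- lab[r[[1]] + offset[1], r[[2]] + offset[2], r[[3]] + offset[3], drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(matrix(0, n_bins, n_bins))
  counts <- tabulate((a[ok] - 1L) * n_bins + b[ok], nbins = n_bins * n_bins)
  m <- matrix(counts, n_bins, n_bins, byrow = TRUE)
  m + t(m)  # symmetric accumulation
}

#' Gray-level co-occurrence matrix (GLCM) texture features
#'
#' Builds symmetric co-occurrence matrices at a fixed voxel distance for each
#' 3D direction, normalizes each to sum 1, averages the matrices over the
#' directions with at least one valid voxel pair, and computes the texture
#' features from the averaged matrix.
#'
#' @param roi_disc a discretized [image_roi] (see [discretize]); an
#'   undiscretized ROI is discretized with `n_bins` first.
#' @param distance offset length in voxels (default 1).
#' @param directions integer matrix of offsets (rows); default the 13 unique
#'   3D directions.
#' @param n_bins gray levels used if `roi_disc` is not yet discretized.
#' @return Named numeric vector: Contrast, Correlation, JointEnergy,
#'   JointEntropy, Homogeneity (inverse difference moment), Dissimilarity.
#'   If no direction has a valid pair, sentinel values are returned with a
#'   warning (Contrast/Dissimilarity 0, Correlation 0, JointEnergy 1,
#'   JointEntropy 0, Homogeneity 1).
#' @export
glcm_features <- function(roi_disc, distance = 1L, directions = NULL, n_bins = 32L) {
  stopifnot(inherits(roi_disc, "image_roi"))
  if (is.null(attr(roi_disc, "n_bins"))) roi_disc <- discretize(roi_disc, n_bins)
  nb <- attr(roi_disc, "n_bins")
  lab <- roi_disc$intensities
  if (sum(lab > 0L) < 2L) stop("GLCM needs at least 2 voxels in the mask")
  if (is.null(directions)) directions <- glcm_directions()
  acc <- matrix(0, nb, nb)
  n_used <- 0L
  for (d in seq_len(nrow(directions))) {
    m <- glcm_accumulate(lab, as.integer(directions[d, ]) * as.integer(distance), nb)
    s <- sum(m)
    if (s > 0) {
      acc <- acc + m / s
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) {
    warning("no valid voxel pairs for any GLCM direction; returning sentinel features")
    return(c(Contrast = 0, Correlation = 0, JointEnergy = 1,
             JointEntropy = 0, Homogeneity = 1, Dissimilarity = 0))
  }
  p <- acc / n_used
  i <- matrix(seq_len(nb), nb, nb)
  j <- t(i)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  sd_i <- sqrt(sum(p * (i - mu_i)^2)); sd_j <- sqrt(sum(p * (j - mu_j)^2))
  corr <- if (sd_i > 0 && sd_j > 0) sum(p * (i - mu_i) * (j - mu_j)) / (sd_i * sd_j) else 0
  pz <- p[p > 0]
  c(Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    JointEnergy = sum(p^2),
    JointEntropy = -sum(pz * log2(pz)),
    Homogeneity = sum(p / (1 + (i - j)^2)),
    Dissimilarity = sum(p * abs(i - j)))
}
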