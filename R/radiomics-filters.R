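# ---- separable filtering helpers ------------------------------------------

# apply a filter matrix W (m x n) along one axis of a 3D array
apply_along_axis <- function(x, axis, W) {
  dm <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = dm[axis])
  out <- W %*% m
  dm_out <- dm[perm]; dm_out[1] <- nrow(W)
  out <- array(out, dim = dm_out)
  aperm(out, order(perm))
}

# n x n Gaussian smoothing matrix with reflected boundary
gaussian_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    # reflect indices at the edges (symmetric padding)
    idx <- ifelse(idx < 1L, 1L - idx + 1L, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (t in seq_along(idx)) W[i, idx[t]] <- W[i, idx[t]] + k[t]
  }
  W
}

gaussian_smooth <- function(x, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0) {
      x <- apply_along_axis(x, ax, gaussian_matrix(dim(x)[ax], sigma_vox[ax]))
    }
  }
  x
}

# second difference along an axis with reflected boundary, per mm^2
second_diff <- function(x, axis, h) {
  n <- dim(x)[axis]
  idx_p <- c(2:n, n - 1L); idx_m <- c(2L, 1:(n - 1))
  slice <- function(i) {
    ix <- rep(list(quote(expr = )), 3); ix[[axis]] <- i
    do.call(`[`, c(list(x), ix, list(drop = FALSE)))
  }
  (slice(idx_p) - 2 * x + slice(idx_m)) / h^2
}

#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Smooths the volume with an isotropic Gaussian of physical scale `sigma_mm`
#' (converted per axis through the voxel spacing), applies the discrete
#' Laplacian, and multiplies by `sigma_mm^2` (scale normalization, so the
#' response of a blob of physical scale s peaks near `sigma_mm ~ s`).
#'
#' @param image 3D numeric array.
#' @param sigma_mm Gaussian scale in mm (> 0).
#' @param spacing mm per axis.
#' @return Filtered 3D array, same shape.
#' @export
log_filter <- function(image, sigma_mm, spacing = c(1, 1, 1)) {
  if (sigma_mm <= 0) stop("sigma_mm must be > 0")
  ext <- dim(image) * spacing
  if (sigma_mm > min(ext) / 2) {
    warning("LoG sigma ", sigma_mm, " mm exceeds half the grid extent (",
            signif(min(ext), 3), " mm axis)")
  }
  sm <- gaussian_smooth(image, sigma_vox = sigma_mm / spacing)
  lap <- second_diff(sm, 1, spacing[1]) +
         second_diff(sm, 2, spacing[2]) +
         second_diff(sm, 3, spacing[3])
  sigma_mm^2 * lap
}

# ---- one-level 3D separable orthogonal wavelet -----------------------------

# Coiflet-1 decomposition low-pass taps; high-pass by the QMF relation.
coif1_lo <- function() {
  c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
     0.852572020212255,  0.337897662457809, -0.072732619512854)
}

# (n/2 x n) decimated circular-convolution analysis matrix
dwt_matrix <- function(n, taps) {
  if (n %% 2L != 0L) stop("wavelet axis length must be even, got ", n)
  if (n < length(taps)) stop("axis length ", n, " shorter than filter length ", length(taps))
  W <- matrix(0, n %/% 2L, n)
  L <- length(taps)
  for (m in seq_len(n %/% 2L)) {
    for (k in seq_len(L)) {
      col <- ((2L * (m - 1L) + (k - 1L)) %% n) + 1L
      W[m, col] <- W[m, col] + taps[k]
    }
  }
  W
}

#' One-level 3D wavelet decomposition into 8 sub-bands
#'
#' Separable orthogonal decomposition (decimated, periodic boundary) with
#' coiflet-1 filters. Each axis is halved; sub-bands are named by the filter
#' applied per axis in x,y,z order (`LLL`, `LLH`, ..., `HHH`). Because the
#' filter pair is orthonormal and the extension periodic, the transform is
#' orthogonal: sub-band energies sum to the input energy.
#'
#' @param image 3D numeric array; each axis even and >= the filter length (6).
#' @return Named list of 8 arrays, each of half the input resolution per axis.
#' @export
wavelet_bank <- function(image) {
  lo <- coif1_lo()
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  dm <- dim(image)
  Ws <- lapply(1:3, function(ax) list(L = dwt_matrix(dm[ax], lo),
                                      H = dwt_matrix(dm[ax], hi)))
  bands <- list()
  for (fx in c("L", "H")) for (fy in c("L", "H")) for (fz in c("L", "H")) {
    b <- apply_along_axis(image, 1, Ws[[1]][[fx]])
    b <- apply_along_axis(b, 2, Ws[[2]][[fy]])
    b <- apply_along_axis(b, 3, Ws[[3]][[fz]])
    bands[[paste0(fx, fy, fz)]] <- b
  }
  bands
}

# decimate a mask to the wavelet grid: 2x2x2 block "any" pooling, so a
# non-empty mask stays non-empty at half resolution
decimate_mask <- function(mask) {
  dm <- dim(mask)
  i1 <- seq(1L, dm[1], 2L); i2 <- pmin(i1 + 1L, dm[1])
  j1 <- seq(1L, dm[2], 2L); j2 <- pmin(j1 + 1L, dm[2])
  k1 <- seq(1L, dm[3], 2L); k2 <- pmin(k1 + 1L, dm[3])
  m <- mask[i1, j1, k1, drop = FALSE] | mask[i2, j1, k1, drop = FALSE] |
       mask[i1, j2, k1, drop = FALSE] | mask[i2, j2, k1, drop = FALSE] |
       mask[i1, j1, k2, drop = FALSE] | mask[i2, j1, k2, drop = FALSE] |
       mask[i1, j2, k2, drop = FALSE] | mask[i2, j2, k2, drop = FALSE]
  m
}

# ---- full extraction --------------------------------------------------------

first_order_names <- function() {
  c("Mean", "Median", "Minimum", "Maximum", "Range", "Variance", "Skewness",
    "Kurtosis", "Energy", "TotalEnergy", "Entropy", "Uniformity",
    "RootMeanSquared", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
    "10Percentile", "90Percentile", "InterquartileRange")
}

glcm_names <- function() {
  c("Contrast", "Correlation", "JointEnergy", "JointEntropy",
    "Homogeneity", "Dissimilarity")
}

shape_names <- function() {
  c("VoxelVolume", "SurfaceArea", "Sphericity", "SurfaceVolumeRatio",
    "Maximum3DDiameter", "Elongation", "Flatness")
}

#' Registry of extracted feature names
#'
#' The fixed, ordered list of feature names produced by [extract_all]:
#' 18 first-order + 6 GLCM features for the original image, each LoG scale
#' and each of the 8 wavelet sub-bands, plus 7 shape features. With the
#' default 3 LoG scales this is 18*(1+3+8) + 6*(1+3+8) + 7 = 295 features.
#'
#' @param sigmas LoG scales in mm.
#' @return data.frame with columns `name`, `image_type`, `class`, `feature`.
#' @export
feature_registry <- function(sigmas = c(1, 2, 3)) {
  imgs <- c("original",
            sprintf("log-sigma-%g", sigmas),
            paste0("wavelet-", names_wavelet_bands()))
  rows <- list()
  for (im in imgs) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(im, "_firstorder_", first_order_names()),
      image_type = im, class = "firstorder", feature = first_order_names())
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste0(im, "_glcm_", glcm_names()),
      image_type = im, class = "texture", feature = glcm_names())
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = paste0("original_shape_", shape_names()),
    image_type = "original", class = "shape", feature = shape_names())
  do.call(rbind, rows)
}

names_wavelet_bands <- function() {
  out <- character(0)
  for (fx in c("L", "H")) for (fy in c("L", "H")) for (fz in c("L", "H")) {
    out <- c(out, paste0(fx, fy, fz))
  }
  out
}

#' Extract the full radiomic feature vector for one lesion ROI
#'
#' Z-normalizes the volume, then computes first-order and GLCM features on
#' the original image, on LoG-filtered images at each `sigmas` scale, and on
#' the 8 one-level wavelet sub-bands (mask decimated alongside), plus shape
#' features of the mask. Feature names follow the
#' `image_firstorder_Feature` convention and match [feature_registry].
#'
#' @param roi an [image_roi] (raw intensities; normalization is internal).
#' @param n_bins gray levels for histogram/texture discretization.
#' @param sigmas LoG scales in mm.
#' @return Named numeric vector, length `nrow(feature_registry(sigmas))`.
#' @export
extract_all <- function(roi, n_bins = 32L, sigmas = c(1, 2, 3)) {
  stopifnot(inherits(roi, "image_roi"))
  zn <- znormalize(roi)
  out <- numeric(0)
  fo_glcm <- function(img, mask, spacing, prefix) {
    r <- image_roi(img, mask, spacing)
    fo <- first_order(r, n_bins)
    gl <- glcm_features(discretize(r, n_bins))
    names(fo) <- paste0(prefix, "_firstorder_", names(fo))
    names(gl) <- paste0(prefix, "_glcm_", names(gl))
    c(fo, gl)
  }
  out <- c(out, fo_glcm(zn$intensities, zn$mask, zn$spacing, "original"))
  for (s in sigmas) {
    f <- log_filter(zn$intensities, s, zn$spacing)
    out <- c(out, fo_glcm(f, zn$mask, zn$spacing, sprintf("log-sigma-%g", s)))
  }
  bands <- wavelet_bank(zn$intensities)
  dmask <- decimate_mask(zn$mask)
  for (b in names(bands)) {
    out <- c(out, fo_glcm(bands[[b]], dmask, zn$spacing * 2, paste0("wavelet-", b)))
  }
  sh <- shape_features(zn$mask, zn$spacing)
  names(sh) <- paste0("original_shape_", names(sh))
  out <- c(out, sh)
  reg <- feature_registry(sigmas)
  if (!identical(names(out), reg$name)) stop("feature registry mismatch")  # internal guard
  out
}

#' Extract features for a whole cohort
#'
#' @param rois list of [image_roi] objects (one per patient), or a character
#'   vector of paired NIfTI paths as produced by [generate_cohort] (image
#'   files; masks found by the `_mask` suffix).
#' @param ids optional patient ids (default names of `rois` or seq).
#' @inheritParams extract_all
#' @return data.frame: one row per patient, `id` column plus one column per
#'   feature.
#' @export
extract_cohort <- function(rois, ids = NULL, n_bins = 32L, sigmas = c(1, 2, 3)) {
  if (is.character(rois)) {
    paths <- rois
    rois <- lapply(paths, function(p) {
      img <- read_nifti(p)
      msk <- read_nifti(sub("\\.nii(\\.gz)?$", "_mask.nii\\1", p))
      image_roi(img$data, msk$data > 0.5, img$spacing)
    })
  }
  if (is.null(ids)) ids <- if (!is.null(names(rois))) names(rois) else seq_along(rois)
  mat <- t(vapply(rois, extract_all, numeric(nrow(feature_registry(sigmas))),
                  n_bins = n_bins, sigmas = sigmas))
  out <- data.frame(id = ids, mat, check.names = FALSE)
  rownames(out) <- NULL
  out
}
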