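#' Synthetic-cohort configuration
#'
#' Describes the stated world of the generator: lesion phantoms on a voxel
#' grid whose mean intensity, texture roughness (Gaussian-field correlation
#' length) and size carry a known proportional-hazards signal, clinical
#' covariates drawn from published-cohort-like marginals coupled to the same
#' latent factor, Weibull baseline hazard (time in months) and independent
#' exponential plus administrative right-censoring.
#'
#' When `baseline_scale` is `NULL` it is calibrated (deterministically, by
#' quadrature over the latent-risk distribution) so that the marginal 3-year
#' event fraction matches `target_event_rate_3yr`, the ~22% short-horizon
#' relapse rate typical of post-prostatectomy cohorts.
#'
#' @param n_patients cohort size (>= 2).
#' @param grid_shape voxels per axis.
#' @param voxel_spacing mm per axis.
#' @param lesion_radius_range sampled lesion radius range, mm.
#' @param intensity_effect log hazard ratio per SD of lesion mean intensity.
#' @param texture_effect log-HR per SD of the texture-roughness parameter.
#' @param size_effect log-HR per SD of log lesion volume.
#' @param clinical_effects named log-HRs per SD of (encoded) clinical
#'   covariates; names among psa, gg_nb, gg_rp, ct, pt, sm, epe, svi, ppb, age.
#' @param clinical_image_cor loading of the shared latent factor that couples
#'   image signal and clinical covariates (0 = independent).
#' @param baseline_shape,baseline_scale Weibull parameters (months).
#' @param target_event_rate_3yr calibration target for the marginal 3-year
#'   event fraction (used when `baseline_scale` is NULL).
#' @param censor_rate exponential censoring rate (per month, >= 0).
#' @param admin_censor administrative censoring time (months, may be `Inf`).
#' @param lesion_mu_mean,lesion_mu_sd lesion mean-intensity distribution.
#' @param texture_sd SD of the correlated intensity field inside the lesion.
#' @param corr_len_mid,corr_len_slope correlation length (voxels) =
#'   `corr_len_mid * exp(-corr_len_slope * z_roughness)`.
#' @param bg_mean,bg_sd background intensity and white-noise SD.
#' @param seed integer master seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 368L,
                          grid_shape = c(32L, 32L, 32L),
                          voxel_spacing = c(1, 1, 1),
                          lesion_radius_range = c(4, 10),
                          intensity_effect = 0.7,
                          texture_effect = 0.5,
                          size_effect = 0.3,
                          clinical_effects = c(psa = 0.25, gg_rp = 0.3,
                                               sm = 0.15, svi = 0.15),
                          clinical_image_cor = 0.3,
                          baseline_shape = 1.3,
                          baseline_scale = NULL,
                          target_event_rate_3yr = 0.22,
                          censor_rate = 1 / 120,
                          admin_censor = 96,
                          lesion_mu_mean = 100, lesion_mu_sd = 10,
                          texture_sd = 10,
                          corr_len_mid = 1.2, corr_len_slope = 0.35,
                          bg_mean = 60, bg_sd = 5,
                          seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  stopifnot(baseline_shape > 0, censor_rate >= 0, admin_censor > 0,
            length(grid_shape) == 3, length(voxel_spacing) == 3,
            all(voxel_spacing > 0), lesion_radius_range[1] > 0,
            diff(lesion_radius_range) >= 0)
  eff <- c(intensity_effect, texture_effect, size_effect, clinical_effects)
  if (any(!is.finite(eff))) stop("all effect sizes must be finite")
  max_r_vox <- max(lesion_radius_range) / min(voxel_spacing)
  if (2 * max_r_vox + 2 > min(grid_shape)) {
    stop("max lesion radius ", max(lesion_radius_range), " mm does not fit in grid ",
         paste(grid_shape, collapse = "x"), " at spacing ",
         paste(voxel_spacing, collapse = "x"))
  }
  cfg <- structure(as.list(environment()), class = "cohort_config")
  if (is.null(cfg$baseline_scale)) {
    cfg$baseline_scale <- calibrate_baseline_scale(cfg)
  }
  stopifnot(cfg$baseline_scale > 0)
  cfg
}

#' Strong-signal image-only cohort preset
#'
#' The stated world for discrimination-recovery experiments: all survival
#' signal flows through the image (mean intensity, texture roughness, size;
#' no clinical effects), with wide parameter spread so the latent risk is,
#' in principle, recoverable from the extracted features
#' (oracle C-index around 0.8-0.85). Light censoring keeps most events
#' observable. Grid 24 voxels per axis for CPU-scale runs.
#'
#' @param n_patients cohort size.
#' @param seed master seed.
#' @param ... overrides forwarded to [cohort_config].
#' @return A [cohort_config].
#' @export
strong_signal_config <- function(n_patients = 600L, seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_patients = n_patients, grid_shape = c(24L, 24L, 24L),
         lesion_radius_range = c(4, 8),
         intensity_effect = 1.3, texture_effect = 0.9,
         size_effect = 0.6, clinical_effects = c(),
         clinical_image_cor = 0, lesion_mu_sd = 20,
         corr_len_slope = 0.6, censor_rate = 1 / 200,
         target_event_rate_3yr = 0.4, admin_censor = 120,
         seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# theoretical moments of the encoded covariates, used so that all z-scores
# entering the latent risk are standard normal / exactly standardized
cohort_marginals <- function() {
  list(
    gg_nb = c(138, 114, 63, 89, 81) / 485,
    gg_rp = c(82, 127, 93, 65, 118) / 485,
    ct = c(`2` = 221, `3` = 264, `4` = 9) / 494,
    pt = c(`1` = 2, `2` = 303, `3` = 165, `4` = 15) / 485,
    sm = 170 / 485, epe = 171 / 485, svi = 67 / 485,
    psa_meanlog = log(10.7), psa_sdlog = 0.6,
    age_mean = 69, age_sd = 7,
    ppb_shape1 = 2, ppb_shape2 = 3
  )
}

# draw the latent-risk machinery for n patients: image-parameter z-scores,
# clinical covariates and the resulting linear predictor eta
simulate_latent <- function(config, n, seed) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  mg <- cohort_marginals()
  rho <- config$clinical_image_cor
  u <- stats::rnorm(n)  # shared latent factor
  mix <- function(lambda) lambda * u + sqrt(1 - lambda^2) * stats::rnorm(n)
  z_mu <- mix(rho)
  z_rough <- mix(rho)
  radius <- stats::runif(n, config$lesion_radius_range[1], config$lesion_radius_range[2])
  logvol <- 3 * log(radius)
  # uniform-radius theoretical moments of 3*log(r)
  r1 <- config$lesion_radius_range[1]; r2 <- config$lesion_radius_range[2]
  if (r2 > r1) {
    m_lv <- 3 * (r2 * log(r2) - r1 * log(r1) - (r2 - r1)) / (r2 - r1)
    m2_lv <- stats::integrate(function(r) (3 * log(r))^2 / (r2 - r1), r1, r2)$value
    sd_lv <- sqrt(max(m2_lv - m_lv^2, 1e-12))
    z_logvol <- (logvol - m_lv) / sd_lv
  } else {
    z_logvol <- rep(0, n)
  }

  lam_c <- 0.4  # within-clinical loading on the shared factor
  ord_from_latent <- function(probs) {
    v <- stats::pnorm(mix(lam_c))
    cut(v, c(0, cumsum(probs) / sum(probs)), labels = FALSE, include.lowest = TRUE)
  }
  bin_from_latent <- function(p) as.integer(stats::pnorm(mix(lam_c)) < p)
  gg_nb <- ord_from_latent(mg$gg_nb)
  gg_rp <- ord_from_latent(mg$gg_rp)
  ct <- c(2L, 3L, 4L)[ord_from_latent(mg$ct)]
  pt <- c(1L, 2L, 3L, 4L)[ord_from_latent(mg$pt)]
  sm <- bin_from_latent(mg$sm)
  epe <- bin_from_latent(mg$epe)
  svi <- bin_from_latent(mg$svi)
  psa <- exp(mg$psa_meanlog + mg$psa_sdlog * mix(lam_c))
  age <- mg$age_mean + mg$age_sd * stats::rnorm(n)
  ppb <- 100 * stats::qbeta(stats::pnorm(mix(lam_c)), mg$ppb_shape1, mg$ppb_shape2)

  zc <- function(x, m, s) (x - m) / s
  ord_mom <- function(p) {
    k <- seq_along(p); m <- sum(k * p) / sum(p)
    list(m = m, s = sqrt(sum(p * (k - m)^2) / sum(p)))
  }
  enc <- list(
    psa = zc(log(psa), mg$psa_meanlog, mg$psa_sdlog),
    gg_nb = { mm <- ord_mom(mg$gg_nb); zc(gg_nb, mm$m, mm$s) },
    gg_rp = { mm <- ord_mom(mg$gg_rp); zc(gg_rp, mm$m, mm$s) },
    ct = { mm <- ord_mom(mg$ct); zc(match(ct, c(2L, 3L, 4L)), mm$m, mm$s) },
    pt = { mm <- ord_mom(mg$pt); zc(pt, mm$m, mm$s) },
    sm = zc(sm, mg$sm, sqrt(mg$sm * (1 - mg$sm))),
    epe = zc(epe, mg$epe, sqrt(mg$epe * (1 - mg$epe))),
    svi = zc(svi, mg$svi, sqrt(mg$svi * (1 - mg$svi))),
    ppb = zc(ppb, 100 * 2 / 5, 100 * sqrt(2 * 3 / (25 * 6))),
    age = zc(age, mg$age_mean, mg$age_sd)
  )
  eta <- config$intensity_effect * z_mu +
         config$texture_effect * z_rough +
         config$size_effect * z_logvol
  for (nm in names(config$clinical_effects)) {
    if (!nm %in% names(enc)) stop("unknown clinical effect: ", nm)
    eta <- eta + config$clinical_effects[[nm]] * enc[[nm]]
  }
  clinical <- data.frame(psa = psa, gg_nb = gg_nb, gg_rp = gg_rp, ct = ct,
                         pt = pt, sm = sm, epe = epe, svi = svi,
                         ppb = ppb, age = age)
  list(eta = eta, z_mu = z_mu, z_rough = z_rough, radius = radius,
       clinical = clinical)
}

# deterministic calibration of the Weibull scale so the marginal 3-year event
# fraction hits the configured target
calibrate_baseline_scale <- function(config, n_mc = 20000L) {
  lat <- simulate_latent(config, n_mc, seed = 987654L)
  a <- config$baseline_shape
  target <- config$target_event_rate_3yr
  f <- function(logb) {
    mean(1 - exp(-(36 / exp(logb))^a * exp(lat$eta))) - target
  }
  exp(stats::uniroot(f, c(log(5), log(5000)))$root)
}

#' Generate one lesion phantom
#'
#' Ellipsoidal lesion of sampled radius centered in the grid. Intensities
#' inside the mask are the patient mean plus a spatially correlated Gaussian
#' field (white noise smoothed at the patient's correlation length, rescaled
#' to `texture_sd`); the background has a distinct mean plus white noise.
#' Deterministic given `patient_seed`.
#'
#' @param config a [cohort_config].
#' @param patient_seed integer seed for this patient's image stream.
#' @param params optional list overriding the sampled parameters:
#'   `mu` (lesion mean), `corr_len` (voxels), `radius` (mm).
#' @return An [image_roi]; sampled parameters in `attr(, "params")`.
#' @export
generate_lesion <- function(config, patient_seed, params = NULL) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(patient_seed)
  dm <- as.integer(config$grid_shape)
  sp <- config$voxel_spacing
  radius <- if (!is.null(params$radius)) params$radius else {
    stats::runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
  }
  mu <- if (!is.null(params$mu)) params$mu else {
    stats::rnorm(1, config$lesion_mu_mean, config$lesion_mu_sd)
  }
  corr_len <- if (!is.null(params$corr_len)) params$corr_len else config$corr_len_mid
  if (2 * radius / min(sp) + 2 > min(dm)) {
    stop("lesion radius ", signif(radius, 3), " mm does not fit in grid ",
         paste(dm, collapse = "x"))
  }
  axes <- radius * c(1, stats::runif(2, 0.75, 1))  # mildly anisotropic, mm
  ctr <- (dm + 1) / 2
  q <- lapply(1:3, function(ax) ((seq_len(dm[ax]) - ctr[ax]) * sp[ax] / axes[ax])^2)
  d2 <- outer(outer(q[[1]], q[[2]], `+`), q[[3]], `+`)
  mask <- array(d2 <= 1, dim = dm)
  bg <- config$bg_mean + stats::rnorm(prod(dm), sd = config$bg_sd)
  img <- array(bg, dim = dm)
  field <- array(stats::rnorm(prod(dm)), dim = dm)
  if (is.finite(corr_len) && corr_len > 0) {
    field <- gaussian_smooth(field, rep(corr_len, 3))
  } else if (!is.finite(corr_len)) {
    field <- array(0, dim = dm)  # infinite correlation length: flat field
  }
  s <- stats::sd(field[mask])
  if (config$texture_sd > 0 && is.finite(s) && s > 0) {
    field <- field / s * config$texture_sd
  } else {
    field <- array(0, dim = dm)
  }
  img[mask] <- mu + field[mask]
  roi <- image_roi(img, mask, sp)
  attr(roi, "params") <- list(mu = mu, corr_len = corr_len, radius = radius,
                              axes = axes)
  roi
}

#' Generate censored survival times under Weibull proportional hazards
#'
#' `T ~ Weibull-PH` with cumulative hazard `(t/scale)^shape * exp(eta)`,
#' censoring `C = min(Exponential(censor_rate), admin_censor)`; returns
#' `time = min(T, C)`, `event = 1[T <= C]` plus the latent `true_time`.
#'
#' @param latent_risks linear predictors eta (finite).
#' @param config a [cohort_config] (uses the baseline/censoring fields).
#' @param seed integer seed.
#' @return data.frame: `time`, `event`, `true_time`.
#' @export
generate_survival <- function(latent_risks, config, seed = config$seed) {
  if (any(!is.finite(latent_risks))) stop("latent risks must be finite")
  if (config$censor_rate < 0) stop("censor_rate must be >= 0")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- length(latent_risks)
  E <- stats::rexp(n)
  T <- config$baseline_scale * (E / exp(latent_risks))^(1 / config$baseline_shape)
  C <- if (config$censor_rate > 0) stats::rexp(n, config$censor_rate) else rep(Inf, n)
  C <- pmin(C, config$admin_censor)
  data.frame(time = pmin(T, C), event = as.integer(T <= C), true_time = T)
}

#' Generate a full synthetic cohort
#'
#' Draws the latent risk machinery (image parameters, clinical covariates,
#' eta), synthesizes one lesion phantom per patient, draws censored survival
#' times, and optionally writes the cohort to disk (NIfTI image/mask pairs,
#' a cohort CSV and a ground-truth sidecar JSON). Fully reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config].
#' @param dir optional output directory (created if missing).
#' @param images generate image phantoms (set `FALSE` for survival-only
#'   simulations at large n).
#' @return List of class `synth_cohort`: `clinical` (data.frame incl. id),
#'   `survival` (time/event), `rois` (list of [image_roi] or NULL),
#'   `truth` (eta, effect sizes, informative feature families, per-patient
#'   image parameters).
#' @export
generate_cohort <- function(config, dir = NULL, images = TRUE) {
  n <- config$n_patients
  lat <- simulate_latent(config, n, seed = config$seed)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  surv <- generate_survival(lat$eta, config, seed = config$seed + 2L)
  mu <- config$lesion_mu_mean + config$lesion_mu_sd * lat$z_mu
  corr_len <- pmin(pmax(config$corr_len_mid * exp(-config$corr_len_slope * lat$z_rough),
                        0.3), 4)
  rois <- NULL
  if (images) {
    rois <- lapply(seq_len(n), function(i) {
      generate_lesion(config, patient_seeds[i],
                      params = list(mu = mu[i], corr_len = corr_len[i],
                                    radius = lat$radius[i]))
    })
    names(rois) <- sprintf("patient-%04d", seq_len(n))
  }
  clinical <- cbind(id = sprintf("patient-%04d", seq_len(n)), lat$clinical)
  truth <- list(
    eta = lat$eta,
    effects = list(intensity = config$intensity_effect,
                   texture = config$texture_effect,
                   size = config$size_effect,
                   clinical = as.list(config$clinical_effects)),
    informative_families = c("firstorder", "texture", "shape"),
    image_params = data.frame(mu = mu, corr_len = corr_len, radius = lat$radius),
    baseline = list(shape = config$baseline_shape, scale = config$baseline_scale)
  )
  out <- list(clinical = clinical,
              survival = surv[, c("time", "event")],
              true_time = surv$true_time,
              rois = rois, truth = truth, config = config)
  class(out) <- "synth_cohort"
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> n =", nrow(x$clinical), "patients,",
      sum(x$survival$event), "events",
      if (is.null(x$rois)) "(no images)" else "(with images)", "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' `cohort.csv` holds id, time, event and the clinical columns;
#' `truth.json` the ground-truth sidecar; images go to `<id>.nii.gz` with
#' masks `<id>_mask.nii.gz`.
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- cbind(cohort$clinical[, "id", drop = FALSE], cohort$survival,
              cohort$clinical[, setdiff(colnames(cohort$clinical), "id")])
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 10))  # byte-stable output
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = 10)
  if (!is.null(cohort$rois)) {
    for (nm in names(cohort$rois)) {
      roi <- cohort$rois[[nm]]
      write_nifti(roi$intensities, file.path(dir, paste0(nm, ".nii.gz")), roi$spacing)
      write_nifti(roi$mask, file.path(dir, paste0(nm, "_mask.nii.gz")), roi$spacing)
    }
  }
  invisible(dir)
}
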