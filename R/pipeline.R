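#' Combine the deep-radiomic score with clinical covariates (DRC-BCR)
#'
#' Cox proportional-hazards fit on the DRS-BCR score plus the clinical point
#' covariates (combined pre/post set) that carry univariate prognostic power
#' (Wald p < 0.05). Zero-variance columns are dropped (a constant DRS
#' degrades gracefully to the clinical signature).
#'
#' @param drs_scores per-patient DRS-BCR scores.
#' @param clinical_records clinical data.frame (see [clinical_scores]).
#' @inheritParams fit_cox
#' @return List: `fit` (`cox_fit`), `score` (combined linear predictor),
#'   `covariates` (design actually used).
#' @export
drc_combine <- function(drs_scores, clinical_records, time, event) {
  Xc <- signature_covariates(clinical_records, "combine")
  ps <- vapply(Xc, function(v) {
    if (stats::sd(v) == 0) return(1)
    suppressWarnings(univariate_p(v, time, event))
  }, 0)
  Xc <- Xc[, ps < 0.05, drop = FALSE]
  X <- cbind(drs = drs_scores, Xc)
  X <- X[, vapply(X, function(v) stats::sd(v) > 0, TRUE), drop = FALSE]
  if (ncol(X) == 0) stop("no usable covariates (all constant)")
  fit <- fit_cox(X, time, event)
  list(fit = fit, score = fit$linear_predictor, covariates = X)
}

#' Evaluate one risk score on one cohort
#'
#' C-index with percentile-bootstrap CI, univariate Cox HR of the
#' standardized score, time-dependent AUC/sensitivity/specificity at the
#' horizon, Youden-cutoff risk groups with the log-rank test, and (via
#' [risk_to_prob]) calibration and decision-curve summaries.
#'
#' @param score risk score (larger = higher risk).
#' @inheritParams fit_cox
#' @param t_star evaluation horizon in months (default 36).
#' @param n_boot bootstrap replicates for the C-index CI.
#' @param seed RNG seed for the bootstrap.
#' @param cutoff optional fixed risk cutoff for the K-M groups (e.g. a
#'   training-cohort Youden cutoff); default: the cohort's own Youden cutoff.
#' @return List of class `eval_report`.
#' @export
evaluate_model <- function(score, time, event, t_star = 36, n_boot = 500L,
                           seed = 1L, cutoff = NULL) {
  ci <- cindex_ci(score, time, event, n_boot = n_boot, seed = seed)
  roc <- time_roc(score, time, event, t_star)
  hr_fit <- if (stats::sd(score) > 0) {
    fit_cox((score - mean(score)) / stats::sd(score), time, event)
  } else NULL
  if (is.null(cutoff)) cutoff <- roc$youden_cutoff
  grp <- ifelse(score > cutoff, "high", "low")
  lr <- if (length(unique(grp)) == 2) log_rank(time, event, grp) else NULL
  prob <- risk_to_prob(score, time, event, t_star)
  cal <- tryCatch(calibration_at(prob, time, event, t_star),
                  error = function(e) NULL)
  out <- list(
    c_index = ci$c_index, c_lower = ci$lower, c_upper = ci$upper,
    hr = if (!is.null(hr_fit)) unname(hr_fit$hr[1]) else NA_real_,
    hr_p = if (!is.null(hr_fit)) unname(hr_fit$p[1]) else NA_real_,
    auc = roc$auc, sens = roc$sens, spec = roc$spec,
    youden_cutoff = roc$youden_cutoff, cutoff_used = cutoff,
    logrank_p = if (!is.null(lr)) lr$p else NA_real_,
    hl_p = if (!is.null(cal)) cal$p else NA_real_,
    t_star = t_star
  )
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("C %.3f [%.3f-%.3f]  AUC(%g mo) %.3f  HR/SD %.3f (p %.2g)  log-rank p %.2g  HL p %.2g\n",
              x$c_index, x$c_lower, x$c_upper, x$t_star, x$auc, x$hr, x$hr_p,
              x$logrank_p, x$hl_p))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Synthetic three-cohort design mirroring a primary cohort (PC, trains the
#' network) and two independently seeded validation cohorts (VC1, VC2).
#' Sizes default to 368/34/83. `n_boot` and grid size are kept modest so a
#' full run stays in CPU-minutes territory; scale up for production use.
#'
#' @param seed master seed; cohort seeds are derived from it.
#' @param n_pc,n_vc1,n_vc2 cohort sizes.
#' @param grid voxels per axis for the phantoms.
#' @param t_star evaluation horizon (months).
#' @param n_boot bootstrap replicates for C-index CIs.
#' @param cohort_args extra arguments passed to [cohort_config].
#' @param dsnn_args extra arguments passed to [dsnn_config].
#' @return Nested list of class `pipeline_config` (JSON-serializable).
#' @export
pipeline_config <- function(seed = 1L, n_pc = 368L, n_vc1 = 34L, n_vc2 = 83L,
                            grid = c(24L, 24L, 24L), t_star = 36,
                            n_boot = 200L, cohort_args = list(),
                            dsnn_args = list()) {
  structure(list(seed = as.integer(seed), n_pc = n_pc, n_vc1 = n_vc1,
                 n_vc2 = n_vc2, grid = grid, t_star = t_star, n_boot = n_boot,
                 cohort_args = cohort_args, dsnn_args = dsnn_args),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, extract, screen, train, evaluate, compare
#'
#' Executes every stage on synthetic cohorts: generates PC/VC1/VC2, extracts
#' radiomic features, screens them on the PC, trains the deep survival
#' network (DRS-BCR), builds the clinical comparators (CAPRA, CAPRA-S, NCCN,
#' GG-RP, clinical signatures, DRC-BCR), and emits a per-cohort performance
#' table plus paired C-index comparisons against DRS-BCR. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [pipeline_config] (or a path to a JSON file of one).
#' @param out_dir optional directory for the report JSON and run manifest.
#' @return List of class `pipeline_result`: `performance` (data.frame:
#'   cohort, model, C-index + CI, HR, AUC), `comparisons` (data.frame of
#'   paired C-index tests vs DRS-BCR), `screen` summary, `manifest`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) {
    config <- utils::modifyList(pipeline_config(),
                                jsonlite::read_json(config, simplifyVector = TRUE))
  }
  t_start <- Sys.time()
  mk_cohort <- function(n, seed_off) {
    args <- utils::modifyList(
      list(n_patients = n, grid_shape = config$grid,
           seed = config$seed + seed_off),
      config$cohort_args)
    generate_cohort(do.call(cohort_config, args))
  }
  cohorts <- list(PC = mk_cohort(config$n_pc, 0L),
                  VC1 = mk_cohort(config$n_vc1, 1000L),
                  VC2 = mk_cohort(config$n_vc2, 2000L))
  feats <- lapply(cohorts, function(ch) extract_cohort(ch$rois))

  pc <- cohorts$PC
  tm <- pc$survival$time; ev <- pc$survival$event
  scr <- screen_features(feats$PC, tm, ev)
  sel <- scr$feature[scr$selected]
  if (length(sel) < 2) stop("stage screen: fewer than 2 features selected")

  dargs <- utils::modifyList(list(seed = config$seed), config$dsnn_args)
  model <- train_dsnn(feats$PC[, sel, drop = FALSE], tm, ev,
                      do.call(dsnn_config, dargs))

  cs_fits <- lapply(c(pre = "pre", post = "post", combine = "combine"),
                    function(w) clinical_signature(pc$clinical, tm, ev, w))
  drs_pc <- predict_risk(model, feats$PC[, sel, drop = FALSE])
  drc <- drc_combine(drs_pc, pc$clinical, tm, ev)

  scores_for <- function(cohort_nm) {
    ch <- cohorts[[cohort_nm]]
    fv <- feats[[cohort_nm]]
    drs <- predict_risk(model, fv[, sel, drop = FALSE])
    cs <- lapply(cs_fits, function(cf) {
      Xn <- signature_covariates(ch$clinical, "combine")[, colnames(cf$covariates), drop = FALSE]
      drop(as.matrix(Xn) %*% cf$fit$coefficients)
    })
    drc_s <- {
      Xn <- cbind(drs = drs,
                  signature_covariates(ch$clinical, "combine"))[, colnames(drc$covariates), drop = FALSE]
      drop(as.matrix(Xn) %*% drc$fit$coefficients)
    }
    list(
      `DRS-BCR` = drs, `DRC-BCR` = drc_s,
      `CS-pre` = cs$pre, `CS-post` = cs$post, `CS-combine` = cs$combine,
      CAPRA = as.numeric(capra(ch$clinical)$score),
      `CAPRA-S` = as.numeric(capra_s(ch$clinical)$score),
      NCCN = as.numeric(risk_level(nccn(ch$clinical))),
      `GG-RP` = as.numeric(gg_rp_group(ch$clinical))
    )
  }

  perf <- list(); comp <- list()
  youden_train <- NULL
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    sc <- scores_for(nm)
    if (is.null(youden_train)) {
      youden_train <- time_roc(sc$`DRS-BCR`, ch$survival$time,
                               ch$survival$event, config$t_star)$youden_cutoff
    }
    for (mdl in names(sc)) {
      ev_rep <- evaluate_model(sc[[mdl]], ch$survival$time, ch$survival$event,
                               t_star = config$t_star, n_boot = config$n_boot,
                               seed = config$seed,
                               cutoff = if (mdl == "DRS-BCR") youden_train else NULL)
      perf[[length(perf) + 1L]] <- data.frame(
        cohort = nm, model = mdl, c_index = ev_rep$c_index,
        c_lower = ev_rep$c_lower, c_upper = ev_rep$c_upper,
        hr = ev_rep$hr, hr_p = ev_rep$hr_p, auc = ev_rep$auc,
        logrank_p = ev_rep$logrank_p)
      if (!mdl %in% c("DRS-BCR")) {
        ct <- compare_cindex(sc$`DRS-BCR`, sc[[mdl]],
                             ch$survival$time, ch$survival$event)
        comp[[length(comp) + 1L]] <- data.frame(
          cohort = nm, model = mdl, c_drs = ct$c_a, c_model = ct$c_b,
          diff = ct$diff, p = ct$p)
      }
    }
  }
  result <- list(
    performance = do.call(rbind, perf),
    comparisons = do.call(rbind, comp),
    screen = list(n_selected = length(sel), families = screen_summary(scr)),
    model = model,
    manifest = list(
      seed = config$seed, config = unclass(config),
      cohort_sizes = vapply(cohorts, function(ch) nrow(ch$clinical), 0),
      n_features = ncol(feats$PC) - 1L, n_selected = length(sel),
      started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      artifacts = character(0))
  )
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c("report.json", "performance.csv"))
    exportable <- result[c("performance", "comparisons", "screen")]
    exportable$manifest <- result$manifest
    exportable$manifest$artifacts <- basename(paths)
    jsonlite::write_json(exportable, paths[1], auto_unbox = TRUE,
                         digits = 10, dataframe = "rows")
    utils::write.csv(result$performance, paths[2], row.names = FALSE)
    result$manifest$artifacts <- basename(paths)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$manifest$n_features, "features,",
      x$manifest$n_selected, "selected\n")
  tab <- x$performance
  tab$c_index <- sprintf("%.3f [%.3f-%.3f]", tab$c_index, tab$c_lower, tab$c_upper)
  print(tab[, c("cohort", "model", "c_index", "auc")], row.names = FALSE)
  invisible(x)
}
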