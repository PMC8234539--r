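#' Clinical comparator risk systems
#'
#' CAPRA (pre-operative, 0-10 points), CAPRA-S (post-surgical, 0-12 points)
#' and the three-tier NCCN risk groups are deterministic lookups against
#' point tables shipped as editable JSON under
#' `inst/extdata/score_tables/` (versioned with citations; table disputes
#' are config changes, not code changes). Gleason scores are handled at
#' grade-group resolution (1-5).
#'
#' Records are supplied as a data.frame with the columns each system
#' requires: CAPRA needs `psa`, `gg_nb`, `ct`, `ppb`, `age`; CAPRA-S needs
#' `psa`, `gg_rp`, `sm`, `epe`, `svi` (optional `ln`); NCCN needs `psa`,
#' `gg_nb`, `ct`. Binary pathology flags are 0/1.
#'
#' @param records data.frame of clinical records (one row per patient).
#' @return data.frame with `score` (integer points) and `category`
#'   (low/intermediate/high) per patient; `nccn` returns `category` only,
#'   `gg_rp_group` an integer 1-5.
#' @name clinical_scores
NULL

score_table <- function(system) {
  f <- system.file("extdata", "score_tables", paste0(system, ".json"),
                   package = "radsurv")
  if (f == "") {  # sourced without installation (development)
    f <- file.path("inst", "extdata", "score_tables", paste0(system, ".json"))
  }
  jsonlite::read_json(f)
}

points_from_breaks <- function(x, breaks) {
  vapply(x, function(v) {
    for (b in breaks) {
      if (is.null(b$max) || v <= b$max) return(as.numeric(b$points))
    }
    stop("value ", v, " not covered by point table")
  }, 0)
}

points_from_map <- function(x, map, field, system) {
  key <- as.character(x)
  bad <- !key %in% names(map)
  if (any(bad)) {
    stop(system, ": value '", key[which(bad)[1]], "' of field '", field,
         "' is outside the published categories (", paste(names(map), collapse = ","), ")")
  }
  vapply(key, function(k) as.numeric(map[[k]]), 0, USE.NAMES = FALSE)
}

require_fields <- function(records, fields, system) {
  miss <- setdiff(fields, colnames(records))
  if (length(miss)) {
    stop(system, ": missing required field(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(records$psa)) || any(records$psa <= 0)) {
    stop(system, ": psa must be positive")
  }
}

categorize <- function(score, cats) {
  vapply(score, function(s) {
    for (b in cats) if (is.null(b$max) || s <= b$max) return(b$label)
    stop("score ", s, " not categorized")
  }, "")
}

#' @rdname clinical_scores
#' @export
capra <- function(records) {
  tb <- score_table("capra")
  require_fields(records, c("psa", "gg_nb", "ct", "ppb", "age"), "CAPRA")
  score <- points_from_breaks(records$psa, tb$points$psa) +
    points_from_map(records$gg_nb, tb$points$gg_nb, "gg_nb", "CAPRA") +
    points_from_map(records$ct, tb$points$ct, "ct", "CAPRA") +
    points_from_breaks(records$ppb, tb$points$ppb) +
    points_from_breaks(records$age, tb$points$age)
  data.frame(score = as.integer(score),
             category = categorize(score, tb$categories))
}

#' @rdname clinical_scores
#' @export
capra_s <- function(records) {
  tb <- score_table("capra_s")
  require_fields(records, c("psa", "gg_rp", "sm", "epe", "svi"), "CAPRA-S")
  ln <- if ("ln" %in% colnames(records)) records$ln else rep(0L, nrow(records))
  score <- points_from_breaks(records$psa, tb$points$psa) +
    points_from_map(records$gg_rp, tb$points$gg_rp, "gg_rp", "CAPRA-S") +
    points_from_map(records$sm, tb$points$sm, "sm", "CAPRA-S") +
    points_from_map(records$svi, tb$points$svi, "svi", "CAPRA-S") +
    points_from_map(records$epe, tb$points$epe, "epe", "CAPRA-S") +
    points_from_map(ln, tb$points$ln, "ln", "CAPRA-S")
  data.frame(score = as.integer(score),
             category = categorize(score, tb$categories))
}

#' @rdname clinical_scores
#' @export
nccn <- function(records) {
  tb <- score_table("nccn")
  require_fields(records, c("psa", "gg_nb", "ct"), "NCCN")
  r <- tb$rules
  low <- records$ct <= r$low$ct_max & records$gg_nb <= r$low$gg_nb_max &
         records$psa < r$low$psa_max
  high <- records$ct >= r$high$ct_min | records$gg_nb >= r$high$gg_nb_min |
          records$psa > r$high$psa_min
  ifelse(high, "high", ifelse(low, "low", "intermediate"))
}

#' @rdname clinical_scores
#' @export
gg_rp_group <- function(records) {
  if (!"gg_rp" %in% colnames(records)) stop("GG-RP: missing required field: gg_rp")
  g <- as.integer(records$gg_rp)
  if (any(g < 1 | g > 5)) stop("GG-RP: grade group must be 1-5")
  g
}

# numeric risk level for C-index/Cox use: low/intermediate/high -> 1/2/3
risk_level <- function(category) {
  match(category, c("low", "intermediate", "high"))
}

# CAPRA/CAPRA-S-normalized covariate encodings used by the clinical
# signatures: each covariate contributes its published point value
signature_covariates <- function(records, which = c("pre", "post", "combine")) {
  which <- match.arg(which)
  tb_pre <- score_table("capra")
  tb_post <- score_table("capra_s")
  pre <- data.frame(
    psa = points_from_breaks(records$psa, tb_pre$points$psa),
    ct = points_from_map(records$ct, tb_pre$points$ct, "ct", "CAPRA"),
    gg_nb = points_from_map(records$gg_nb, tb_pre$points$gg_nb, "gg_nb", "CAPRA"),
    ppb = points_from_breaks(records$ppb, tb_pre$points$ppb)
  )
  post <- data.frame(
    psa_s = points_from_breaks(records$psa, tb_post$points$psa),
    gg_rp = points_from_map(records$gg_rp, tb_post$points$gg_rp, "gg_rp", "CAPRA-S"),
    sm = points_from_map(records$sm, tb_post$points$sm, "sm", "CAPRA-S"),
    epe = points_from_map(records$epe, tb_post$points$epe, "epe", "CAPRA-S"),
    svi = points_from_map(records$svi, tb_post$points$svi, "svi", "CAPRA-S")
  )
  switch(which, pre = pre, post = post, combine = cbind(pre, post))
}

#' Clinical signature (Cox model on grouped, score-normalized covariates)
#'
#' Builds the pre-operative (`pre`: PSA, cT, biopsy grade group, percent
#' positive biopsies), post-operative (`post`: PSA, pathological grade group,
#' margin, extraprostatic extension, seminal-vesicle invasion) or combined
#' clinical signature: covariates are encoded as their CAPRA / CAPRA-S point
#' contributions, optionally screened for univariate significance, and fed
#' to a multivariable Cox model. The signature score is the fitted linear
#' predictor.
#'
#' @param records clinical data.frame (see [clinical_scores]).
#' @inheritParams fit_cox
#' @param which `"pre"`, `"post"` or `"combine"`.
#' @param select drop covariates with univariate Wald p >= 0.05 before the
#'   multivariable fit (default TRUE; with FALSE all covariates enter).
#' @return List: `fit` (a `cox_fit`), `score` (per-patient signature),
#'   `covariates` (encoded design).
#' @export
clinical_signature <- function(records, time, event,
                               which = c("pre", "post", "combine"),
                               select = TRUE) {
  which <- match.arg(which)
  if (sum(event == 1) < 10) {
    stop("clinical_signature needs at least 10 events for a stable fit")
  }
  X <- signature_covariates(records, which)
  keep_var <- vapply(X, function(v) stats::sd(v) > 0, TRUE)
  X <- X[, keep_var, drop = FALSE]
  if (ncol(X) == 0) stop("all covariates are constant")
  # aliased (perfectly collinear) columns are an error, as the design is tiny
  qrX <- qr(scale(as.matrix(X)))
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  if (select) {
    ps <- vapply(X, function(v) suppressWarnings(univariate_p(v, time, event)), 0)
    if (any(ps < 0.05)) X <- X[, ps < 0.05, drop = FALSE]
  }
  fit <- fit_cox(X, time, event)
  list(fit = fit, score = fit$linear_predictor, covariates = X)
}
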