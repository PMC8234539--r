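#' Univariate Cox Wald p-value for a single feature
#'
#' Standardizes the feature (z-score across patients) and fits a univariate
#' Cox model; returns the two-sided Wald p. Degenerate inputs (constant
#' feature, non-convergent fit) return p = 1 with a warning.
#'
#' @param score feature values, one per patient.
#' @inheritParams fit_cox
#' @return p-value in `(0, 1]`.
#' @export
univariate_p <- function(score, time, event) {
  s <- stats::sd(score)
  if (!is.finite(s) || s == 0) {
    warning("constant feature: degenerate Cox fit, p = 1")
    return(1)
  }
  z <- (score - mean(score)) / s
  fit <- withCallingHandlers(
    tryCatch(fit_cox(z, time, event), error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(fit) || !fit$converged || !is.finite(fit$p[1])) {
    warning("univariate Cox fit did not converge; p = 1")
    return(1)
  }
  unname(fit$p[1])
}

#' Univariate concordance screening of a feature table
#'
#' Computes, for every feature, Harrell's C-index against survival and the
#' univariate Cox Wald p-value, and retains features with
#' `C-index > c_threshold` and `p < alpha`. Features with C below 0.5 are
#' deliberately not rescued by sign-flipping. No multiplicity correction is
#' applied (liberal by design; the screen only feeds the downstream model).
#'
#' @param features data.frame or matrix of features (numeric columns; an
#'   `id` column, if present, is ignored).
#' @inheritParams fit_cox
#' @param c_threshold concordance threshold (default 0.5).
#' @param alpha significance threshold (default 0.05).
#' @return Object of class `screen_result`: data.frame with one row per
#'   feature (`feature`, `c_index`, `p_value`, `selected`).
#' @export
screen_features <- function(features, time, event,
                            c_threshold = 0.5, alpha = 0.05) {
  df <- as.data.frame(features)
  df <- df[, setdiff(colnames(df), "id"), drop = FALSE]
  stopifnot(nrow(df) == length(time))
  ps <- pair_structure(time, event)
  if (length(ps$i) == 0) stop("no usable pairs in the survival data")
  res <- lapply(colnames(df), function(nm) {
    v <- df[[nm]]
    ci <- cindex_from_pairs(v, ps)
    p <- suppressWarnings(univariate_p(v, time, event))
    data.frame(feature = nm, c_index = ci, p_value = p,
               selected = ci > c_threshold & p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Family accounting of selected features
#'
#' Tallies selected features per feature class (texture / first-order /
#' shape, parsed from the `image_class_feature` naming convention) and
#' reports each family's percentage of the selected pool, rounded to 3
#' significant digits as conventionally printed (e.g. `125 (80.6%)`).
#'
#' @param screen a [screen_features] result (or any data.frame with
#'   `feature` and `selected` columns).
#' @return data.frame: `class`, `n_selected`, `percent`.
#' @export
screen_summary <- function(screen) {
  sel <- screen$feature[screen$selected]
  cls <- feature_class(sel)
  total <- length(sel)
  if (total == 0) {
    return(data.frame(class = character(0), n_selected = integer(0),
                      percent = numeric(0)))
  }
  tab <- table(cls)
  out <- data.frame(class = names(tab), n_selected = as.integer(tab),
                    percent = signif(100 * as.integer(tab) / total, 3))
  out[order(-out$n_selected), , drop = FALSE]
}

# class of a feature from its registry name: *_glcm_* -> texture,
# *_firstorder_* -> firstorder, *_shape_* -> shape
feature_class <- function(names) {
  ifelse(grepl("_glcm_", names), "texture",
         ifelse(grepl("_firstorder_", names), "firstorder",
                ifelse(grepl("_shape_", names), "shape", "other")))
}

#' Percentage table from printed counts
#'
#' Utility used for cohort accounting: given event counts and totals, the
#' percentage of each, rounded to one decimal as conventionally reported
#' (`81/368 -> 22.0`).
#'
#' @param events integer vector of event counts.
#' @param totals integer vector of totals, same length.
#' @return data.frame: `events`, `n`, `percent`.
#' @export
event_rate_table <- function(events, totals) {
  stopifnot(length(events) == length(totals), all(events <= totals))
  data.frame(events = events, n = totals,
             percent = round(100 * events / totals, 1))
}
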