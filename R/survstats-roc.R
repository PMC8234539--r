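# censoring survival curve G(t) (Kaplan-Meier with the censoring indicator)
censoring_km <- function(time, event) kaplan_meier(time, 1 - event)

# left limit G(t-): survival just before t
km_prob_before <- function(curve, t) {
  vapply(t, function(tt) {
    k <- which(curve$time < tt)
    if (length(k) == 0) 1 else curve$surv[max(k)]
  }, 0)
}

# inverse-probability-of-censoring weights for cumulative cases / dynamic
# controls at horizon t_star; weight 0 marks excluded observations
ipcw_weights <- function(time, event, t_star) {
  G <- censoring_km(time, event)
  is_case <- time <= t_star & event == 1
  is_ctrl <- time > t_star
  w <- numeric(length(time))
  gc_case <- km_prob_before(G, time[is_case])
  w[is_case] <- ifelse(gc_case > 0, 1 / gc_case, 0)
  g_star <- km_prob_at(G, t_star)
  w[is_ctrl] <- if (g_star > 0) 1 / g_star else 0
  list(case = is_case, ctrl = is_ctrl, w = w)
}

#' Time-dependent ROC curve at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC with inverse-probability-of-censoring
#' weights from the censoring Kaplan-Meier: cases are patients with an event
#' by `t_star` (weight `1/G(T-)`), controls those still event-free after
#' `t_star` (weight `1/G(t_star)`). Sensitivity/specificity are swept over all
#' observed score cutoffs (predicted positive: score > cutoff) and the
#' Youden-optimal cutoff (max sens + spec - 1) is reported. The AUC is the
#' weighted probability that a case outscores a control (ties 1/2).
#'
#' @param score risk score (larger = higher risk).
#' @inheritParams fit_cox
#' @param t_star horizon, same units as `time` (must not exceed the last
#'   observed time).
#' @return Object of class `time_roc`: `t_star`, `auc`, data.frame `curve`
#'   (cutoff, sens, spec), `youden_cutoff`, `sens`, `spec` at that cutoff.
#' @export
time_roc <- function(score, time, event, t_star) {
  if (t_star > max(time)) {
    stop("t_star = ", t_star, " is beyond the last observed time ", max(time))
  }
  ww <- ipcw_weights(time, event, t_star)
  wc <- ww$w[ww$case]; sc <- score[ww$case]
  wk <- ww$w[ww$ctrl]; sk <- score[ww$ctrl]
  if (sum(wc) == 0 || sum(wk) == 0) stop("no usable cases or controls at t_star")
  cuts <- sort(unique(score))
  cuts <- c(-Inf, cuts)
  sens <- vapply(cuts, function(ct) sum(wc[sc > ct]) / sum(wc), 0)
  spec <- vapply(cuts, function(ct) sum(wk[sk <= ct]) / sum(wk), 0)
  gt <- outer(sc, sk, `>`)
  eq <- outer(sc, sk, `==`)
  wmat <- outer(wc, wk)
  auc <- sum(wmat * (gt + 0.5 * eq)) / sum(wmat)
  youden <- sens + spec - 1
  k <- which.max(youden)
  out <- list(t_star = t_star, auc = auc,
              curve = data.frame(cutoff = cuts, sens = sens, spec = spec),
              youden_cutoff = cuts[k], sens = sens[k], spec = spec[k])
  class(out) <- "time_roc"
  out
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t* = %g: AUC %.3f; Youden cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$t_star, x$auc, x$youden_cutoff, x$sens, x$spec))
  invisible(x)
}

#' Calibration of predicted event probabilities at a horizon
#'
#' Groups patients into `n_groups` quantile bins of the predicted probability,
#' compares the mean predicted probability per bin with the Kaplan-Meier
#' observed event fraction by `t_star`, and computes the Hosmer-Lemeshow
#' chi-square (df = groups - 2).
#'
#' @param predicted_prob predicted event probability by `t_star`, in `[0,1]`.
#' @inheritParams fit_cox
#' @param t_star horizon.
#' @param n_groups number of risk bins (default 10).
#' @return List: `table` (per-bin n, mean predicted, KM-observed fraction),
#'   `statistic`, `df`, `p`.
#' @export
calibration_at <- function(predicted_prob, time, event, t_star, n_groups = 10L) {
  if (any(predicted_prob < 0 | predicted_prob > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  br <- unique(stats::quantile(predicted_prob, seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 4) {
    stop("predictions too concentrated to form at least 3 risk groups; ",
         "use fewer groups or a non-degenerate model")
  }
  grp <- cut(predicted_prob, br, include.lowest = TRUE)
  tab <- lapply(levels(grp), function(l) {
    k <- grp == l
    obs <- 1 - km_prob_at(kaplan_meier(time[k], event[k]), t_star)
    data.frame(group = l, n = sum(k), predicted = mean(predicted_prob[k]),
               observed = obs)
  })
  tab <- do.call(rbind, tab)
  expvar <- tab$predicted * (1 - tab$predicted)
  ok <- expvar > 0
  stat <- sum(tab$n[ok] * (tab$observed[ok] - tab$predicted[ok])^2 / expvar[ok])
  df <- max(1L, sum(ok) - 2L)
  list(table = tab, statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @rdname calibration_at
#' @export
calibration_3yr <- function(predicted_prob, time, event, n_groups = 10L) {
  calibration_at(predicted_prob, time, event, t_star = 36, n_groups = n_groups)
}

#' Decision-curve analysis for a survival outcome
#'
#' Survival-adapted net benefit at each threshold probability `p_t`:
#' among patients predicted positive (`prob >= p_t`), the event fraction by
#' `t_star` is taken from the group Kaplan-Meier, giving
#' `NB = TP/n - FP/n * p_t/(1-p_t)`. Treat-all and treat-none references are
#' included.
#'
#' @param predicted_prob predicted event probability by `t_star`.
#' @inheritParams fit_cox
#' @param t_star horizon.
#' @param thresholds threshold probabilities to sweep.
#' @return data.frame: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(predicted_prob, time, event, t_star,
                           thresholds = seq(0.05, 0.6, by = 0.05)) {
  n <- length(predicted_prob)
  rate <- 1 - km_prob_at(kaplan_meier(time, event), t_star)
  out <- lapply(thresholds, function(pt) {
    pos <- predicted_prob >= pt
    if (!any(pos)) {
      nb <- 0
    } else {
      risk_pos <- 1 - km_prob_at(kaplan_meier(time[pos], event[pos]), t_star)
      tp <- sum(pos) / n * risk_pos
      fp <- sum(pos) / n * (1 - risk_pos)
      nb <- tp - fp * pt / (1 - pt)
    }
    data.frame(threshold = pt, net_benefit = nb,
               treat_all = rate - (1 - rate) * pt / (1 - pt),
               treat_none = 0)
  })
  do.call(rbind, out)
}

#' Integrated discrimination improvement and continuous NRI at a horizon
#'
#' Censoring-aware (IPCW) versions of the IDI (difference of discrimination
#' slopes) and the continuous net reclassification improvement
#' (`NRI_events + NRI_nonevents`, sign-of-change definition) comparing a new
#' against an old predicted probability. A percentile-bootstrap standard error
#' gives two-sided p values.
#'
#' @param prob_new,prob_old predicted event probabilities by `t_star`.
#' @inheritParams fit_cox
#' @param t_star horizon.
#' @param n_boot bootstrap replicates for the p values.
#' @param seed RNG seed for the bootstrap.
#' @return List: `idi`, `idi_p`, `nri`, `nri_p`.
#' @export
idi_nri <- function(prob_new, prob_old, time, event, t_star,
                    n_boot = 300L, seed = 1L) {
  est <- function(idx) {
    ww <- ipcw_weights(time[idx], event[idx], t_star)
    w <- ww$w
    pn <- prob_new[idx]; po <- prob_old[idx]
    wc <- w[ww$case]; wk <- w[ww$ctrl]
    if (sum(wc) == 0 || sum(wk) == 0) return(c(NA_real_, NA_real_))
    mean_w <- function(v, w) sum(v * w) / sum(w)
    idi <- (mean_w(pn[ww$case], wc) - mean_w(pn[ww$ctrl], wk)) -
           (mean_w(po[ww$case], wc) - mean_w(po[ww$ctrl], wk))
    d <- pn - po
    up_case <- mean_w(d[ww$case] > 0, wc) - mean_w(d[ww$case] < 0, wc)
    dn_ctrl <- mean_w(d[ww$ctrl] < 0, wk) - mean_w(d[ww$ctrl] > 0, wk)
    c(idi, up_case + dn_ctrl)
  }
  n <- length(time)
  e0 <- est(seq_len(n))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    boots[b, ] <- tryCatch(est(sample.int(n, n, replace = TRUE)),
                           error = function(e) c(NA, NA))
  }
  pval <- function(stat, bs) {
    se <- stats::sd(bs, na.rm = TRUE)
    if (!is.finite(se) || se == 0) return(if (stat == 0) 1 else 0)
    2 * stats::pnorm(-abs(stat / se))
  }
  list(idi = e0[1], idi_p = pval(e0[1], boots[, 1]),
       nri = e0[2], nri_p = pval(e0[2], boots[, 2]))
}

#' Wilcoxon signed-rank test for paired values
#'
#' Exact null distribution (enumeration via the rank-sum recursion) for up to
#' 25 non-zero untied pairs; normal approximation with tie and continuity
#' corrections otherwise. Two-sided.
#'
#' @param a,b paired measurements.
#' @return List: `statistic` (V, sum of positive ranks), `p`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # counts of rank-sum values over all 2^n sign patterns
    maxs <- n * (n + 1) / 2
    f <- c(1, numeric(maxs))
    for (k in seq_len(n)) {
      shifted <- c(numeric(k), f)[seq_len(maxs + 1)]
      f <- f + shifted
    }
    probs <- f / 2^n
    lo <- sum(probs[seq_len(V + 1)])            # P(V <= v)
    hi <- sum(probs[(V + 1):(maxs + 1)])        # P(V >= v)
    p <- min(1, 2 * min(lo, hi))
    return(list(statistic = V, p = p, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tt <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  list(statistic = V, p = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}
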