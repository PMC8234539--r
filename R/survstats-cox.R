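#' Cox proportional-hazards regression (Breslow partial likelihood)
#'
#' Newton-Raphson maximization of the Breslow partial likelihood, converging
#' when the max-norm of the score vector drops below `tol` (1e-8). Covariates
#' are centered internally for numerical stability (the estimate is
#' invariant). Wald standard errors, hazard ratios with 95% CI, and the
#' C-index of the fitted linear predictor are reported. Monotone likelihood
#' (separation) is caught by the iteration cap and reported with a warning.
#'
#' @param x covariate vector, matrix or data.frame (numeric columns).
#' @param time follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param max_iter Newton iteration cap.
#' @param tol convergence tolerance on the score max-norm.
#' @return Object of class `cox_fit`: coefficients, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `z`, `p`, `loglik`, `loglik_null`, `c_index`,
#'   `linear_predictor`, `converged`, `iter`.
#' @export
fit_cox <- function(x, time, event, max_iter = 25L, tol = 1e-8) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event == 1) < 1) stop("fit_cox needs at least one event")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)

  ord <- order(-time)
  ts <- time[ord]; es <- event[ord]; Xs <- Xc[ord, , drop = FALSE]
  # risk set of an observation = all positions up to the end of its tie group
  grp_end <- cummax_by_ties(ts)
  ev_pos <- which(es == 1)

  pl_parts <- function(beta) {
    eta <- drop(Xs %*% beta)
    w <- exp(eta - max(eta))
    S0 <- cumsum(w)
    S1 <- apply(Xs * w, 2, cumsum)
    if (p == 1) S1 <- matrix(S1, ncol = 1)
    e0 <- S0[grp_end[ev_pos]]
    e1 <- S1[grp_end[ev_pos], , drop = FALSE]
    xbar <- e1 / e0
    ll <- sum(eta[ev_pos] - (log(e0) + max(eta)))
    g <- colSums(Xs[ev_pos, , drop = FALSE] - xbar)
    H <- matrix(0, p, p)
    # S2/S0 term accumulated per event via weighted cross-products up to the
    # risk-set boundary; loop over distinct boundaries to stay O(n p^2)
    bnd <- grp_end[ev_pos]
    ubnd <- sort(unique(bnd))
    cnt <- table(factor(bnd, levels = ubnd))
    S2run <- matrix(0, p, p)
    last <- 0L
    for (k in seq_along(ubnd)) {
      b <- ubnd[k]
      idx <- (last + 1L):b
      Xi <- Xs[idx, , drop = FALSE]
      S2run <- S2run + crossprod(Xi, Xi * w[idx])
      last <- b
      m <- as.numeric(cnt[k])
      e0b <- S0[b]
      e1b <- S1[b, ] / e0b
      H <- H + m * (S2run / e0b - outer(e1b, e1b))
    }
    list(ll = ll, g = g, H = H)
  }

  beta <- rep(0, p)
  parts <- pl_parts(beta)
  ll_null <- pl_parts(rep(0, p))$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$H, parts$g), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_parts <- pl_parts(new_beta)
    halves <- 0L
    while ((!is.finite(new_parts$ll) || new_parts$ll < parts$ll - 1e-12) && halves < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_parts <- pl_parts(new_beta)
      halves <- halves + 1L
    }
    beta <- new_beta
    parts <- new_parts
  }
  if (!converged && max(abs(parts$g)) < tol) converged <- TRUE
  if (!converged) {
    warning("fit_cox did not converge in ", max_iter,
            " iterations (possible monotone likelihood/separation); ",
            "coefficients from the last iteration are returned")
  }
  Hinv <- tryCatch(solve(parts$H), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(Hinv), 0))
  z <- beta / se
  lp <- drop(X %*% beta)  # uncentered scale, used for the Breslow baseline
  names(beta) <- names(se) <- colnames(X)
  res <- list(
    coefficients = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    loglik = parts$ll, loglik_null = ll_null,
    c_index = if (stats::sd(lp) > 0) harrell_cindex(lp, time, event) else 0.5,
    linear_predictor = lp, converged = converged, iter = iter,
    time = time, event = event
  )
  class(res) <- "cox_fit"
  res
}

cummax_by_ties <- function(ts_desc) {
  # for descending sorted times, the last index sharing each value
  n <- length(ts_desc)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ts_desc[j + 1L] == ts_desc[i]) j <- j + 1L
    out[i:j] <- j
    i <- j + 1L
  }
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow), C-index",
      sprintf("%.3f", x$c_index), "\n")
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    `lower .95` = x$ci_lower, `upper .95` = x$ci_upper,
                    se = x$se, p = x$p, check.names = FALSE)
  print(signif(tab, 4))
  invisible(x)
}

# Breslow cumulative baseline hazard at t_star, evaluated at linear
# predictor 0 on the uncentered covariate scale
breslow_cumhaz <- function(lp, time, event, t_star) {
  w <- exp(lp)
  ut <- sort(unique(time[event == 1 & time <= t_star]))
  if (length(ut) == 0) return(0)
  sum(vapply(ut, function(t) {
    sum(time == t & event == 1) / sum(w[time >= t])
  }, 0))
}

#' Convert a risk score into an absolute event probability at a horizon
#'
#' Fits a univariate Cox model on the score, computes the Breslow baseline
#' cumulative hazard, and returns `1 - exp(-H0(t*) exp(beta * score))` per
#' patient. When the score is constant the Cox slope is fixed at 0 and all
#' patients share the baseline probability.
#'
#' @param score per-patient risk score.
#' @inheritParams fit_cox
#' @param t_star prediction horizon (same units as `time`).
#' @return Vector of event probabilities in `[0, 1]`.
#' @export
risk_to_prob <- function(score, time, event, t_star) {
  if (stats::sd(score) == 0) {
    lp <- rep(0, length(score))
  } else {
    fit <- fit_cox(score, time, event)
    lp <- fit$linear_predictor
  }
  H0 <- breslow_cumhaz(lp, time, event, t_star)
  pmin(pmax(1 - exp(-H0 * exp(lp)), 0), 1)
}
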