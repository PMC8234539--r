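#' Kaplan-Meier product-limit estimator
#'
#' @param time follow-up times (> 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return An object of class `km_curve`: data.frame with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `surv` and Greenwood `se`.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time <= 0)) stop("times must be positive")
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0), se = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    surv = surv, se = se)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability from a Kaplan-Meier curve at a time point
#'
#' Right-continuous step function; 1 before the first event time.
#'
#' @param curve a [kaplan_meier] fit.
#' @param t time point(s).
#' @return Estimated survival probability at `t`.
#' @export
km_prob_at <- function(curve, t) {
  vapply(t, function(tt) {
    k <- which(curve$time <= tt)
    if (length(k) == 0) 1 else curve$surv[max(k)]
  }, 0)
}

#' Log-rank test for equality of survival across groups
#'
#' Classic observed-minus-expected chi-square with hypergeometric variance,
#' for two or more groups.
#'
#' @inheritParams kaplan_meier
#' @param group group labels (factor or coercible; >= 2 levels present).
#' @return List: `statistic`, `df`, `p`, `observed`, `expected` (per group).
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  g <- droplevels(group)
  K <- nlevels(g)
  if (K < 2) stop("log_rank needs at least 2 groups")
  if (sum(event == 1) < 1) stop("log_rank needs at least one event")
  ut <- sort(unique(time[event == 1]))
  O <- numeric(K); E <- numeric(K)
  V <- matrix(0, K, K)
  gi <- as.integer(g)
  for (t in ut) {
    at_risk <- time >= t
    N <- sum(at_risk)
    d <- sum(time == t & event == 1)
    nk <- vapply(1:K, function(k) sum(at_risk & gi == k), 0)
    dk <- vapply(1:K, function(k) sum(time == t & event == 1 & gi == k), 0)
    O <- O + dk
    E <- E + nk * d / N
    if (N > 1) {
      f <- d * (N - d) / (N^2 * (N - 1))
      V <- V + f * (diag(nk * N, K) - outer(nk, nk))
    }
  }
  idx <- 1:(K - 1)
  u <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vi, u)), error = function(e) {
    drop(t(u) %*% pinv_sym(Vi) %*% u)
  })
  df <- K - 1
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}

# Moore-Penrose fallback for a singular log-rank variance (degenerate groups)
pinv_sym <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
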