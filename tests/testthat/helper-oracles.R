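# Independent brute-force oracles. These deliberately use naive loops and a
# different code structure from the package implementations they check.

# pairwise-enumeration concordance
brute_cindex <- function(score, time, event) {
  n <- length(score)
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
              (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (score[i] > score[j]) num <- num + 1
    else if (score[i] == score[j]) num <- num + 0.5
  }
  num / den
}

# explicit risk-set-loop Breslow partial likelihood
brute_cox_nll <- function(risk, time, event) {
  nll <- 0
  for (i in seq_along(risk)) {
    if (event[i] != 1) next
    rs <- which(time >= time[i])
    nll <- nll - (risk[i] - log(sum(exp(risk[rs]))))
  }
  nll
}

# naive observed/expected log-rank for two groups
brute_logrank2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    at <- time >= t
    N <- sum(at); d <- sum(time == t & event == 1)
    n1 <- sum(at & g == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / N
    if (N > 1) V <- V + d * (N - d) * n1 * (N - n1) / (N^2 * (N - 1))
  }
  (O1 - E1)^2 / V
}

# IPCW cumulative/dynamic ROC AUC by direct double loop
brute_time_auc <- function(score, time, event, t_star) {
  Gfit <- radsurv::kaplan_meier(time, 1 - event)
  G_at <- function(t) {
    k <- which(Gfit$time <= t)
    if (length(k) == 0) 1 else Gfit$surv[max(k)]
  }
  G_before <- function(t) {
    k <- which(Gfit$time < t)
    if (length(k) == 0) 1 else Gfit$surv[max(k)]
  }
  cases <- which(time <= t_star & event == 1)
  ctrls <- which(time > t_star)
  num <- 0; den <- 0
  for (i in cases) for (j in ctrls) {
    wi <- 1 / G_before(time[i])
    wj <- 1 / G_at(t_star)
    if (!is.finite(wi) || !is.finite(wj)) next
    w <- wi * wj
    den <- den + w
    if (score[i] > score[j]) num <- num + w
    else if (score[i] == score[j]) num <- num + w / 2
  }
  num / den
}

# exact Wilcoxon signed-rank p by enumeration of all sign patterns
brute_wilcoxon_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  vals <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vals[m + 1] <- sum(r[signs == 1])
  }
  lo <- mean(vals <= V); hi <- mean(vals >= V)
  min(1, 2 * min(lo, hi))
}

# random censored-survival instance for property tests
random_surv_instance <- function(n, tie_prob = 0.3) {
  time <- if (runif(1) < tie_prob) sample(1:max(3, n %/% 3), n, replace = TRUE)
          else round(rexp(n, 0.1), 3) + 0.01
  event <- rbinom(n, 1, 0.7)
  if (sum(event) == 0) event[sample(n, 1)] <- 1
  score <- if (runif(1) < 0.3) sample(1:5, n, replace = TRUE) else rnorm(n)
  list(score = score, time = time, event = event)
}

# small lesion-bearing ROI for radiomics tests
toy_roi <- function(n = 12, r = 4, seed = 1, lesion_shift = 3) {
  set.seed(seed)
  cc <- (n + 1) / 2
  d2 <- outer(outer((1:n - cc)^2, (1:n - cc)^2, `+`), (1:n - cc)^2, `+`)
  mask <- array(d2 <= r^2, dim = c(n, n, n))
  img <- array(rnorm(n^3), dim = c(n, n, n)) + lesion_shift * mask
  image_roi(img, mask)
}

ball_mask <- function(n, r) {
  cc <- (n + 1) / 2
  d2 <- outer(outer((1:n - cc)^2, (1:n - cc)^2, `+`), (1:n - cc)^2, `+`)
  array(d2 <= r^2, dim = c(n, n, n))
}
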