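test_that("Kaplan-Meier matches hand product-limit computations", {
  # times (1,2,3), events (1,0,1): S = 2/3 after t=1, 0 at t=3 (risk set 1)
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_prob_at(km, 1), 2 / 3)
  expect_equal(km_prob_at(km, 2.5), 2 / 3)
  expect_equal(km_prob_at(km, 3), 0)
  expect_equal(km_prob_at(km, 0.5), 1)
  # no censoring: empirical survival fraction
  tt <- c(2, 4, 1, 7, 3)
  km2 <- kaplan_meier(tt, rep(1, 5))
  expect_equal(km_prob_at(km2, 3.5), mean(tt > 3.5))
  # all censored
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_prob_at(km3, 10), 1)
})

test_that("KM is monotone with non-negative Greenwood variance (property)", {
  set.seed(301)
  for (rep in 1:10) {
    inst <- random_surv_instance(sample(10:60, 1))
    km <- kaplan_meier(inst$time, inst$event)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$se >= 0))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
  }
})

test_that("log-rank agrees with a hand O/E table and the survival package", {
  # duplicated groups: exactly zero
  tt <- c(3, 5, 7, 9); ev <- c(1, 0, 1, 1)
  lr0 <- log_rank(c(tt, tt), c(ev, ev), rep(1:2, each = 4))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  # 4-patient worked example against an independent O/E loop
  time <- c(1, 2, 3, 4); event <- c(1, 1, 0, 1); grp <- c(1, 2, 1, 2)
  lr <- log_rank(time, event, grp)
  expect_equal(lr$statistic, brute_logrank2(time, event, grp), tolerance = 1e-12)
  # random instances vs survival::survdiff
  set.seed(303)
  for (rep in 1:8) {
    inst <- random_surv_instance(40)
    g <- rbinom(40, 1, 0.5)
    if (length(unique(g)) < 2) next
    lr2 <- log_rank(inst$time, inst$event, g)
    sd2 <- survival::survdiff(survival::Surv(inst$time, inst$event) ~ g)
    expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-9)
  }
})

test_that("fit_cox matches coxph (Breslow) and a brute-force likelihood grid", {
  set.seed(305)
  for (rep in 1:6) {
    n <- 60
    X <- matrix(rnorm(n * 2), n, 2)
    eta <- drop(X %*% c(0.7, -0.4))
    t0 <- rexp(n, exp(eta) / 30)
    cns <- rexp(n, 1 / 40)
    time <- pmin(t0, cns); event <- as.integer(t0 <= cns)
    f1 <- fit_cox(X, time, event)
    f2 <- survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow")
    expect_equal(unname(f1$coefficients), unname(coef(f2)), tolerance = 1e-7)
    expect_equal(unname(f1$se), unname(sqrt(diag(vcov(f2)))), tolerance = 1e-7)
    expect_equal(f1$loglik, f2$loglik[2], tolerance = 1e-8)
  }
  # 4-patient binary covariate: maximum found by direct likelihood grid
  time <- c(2, 3, 5, 8); event <- c(1, 1, 1, 0); x <- c(1, 0, 1, 0)
  fit <- fit_cox(x, time, event)
  grid <- seq(-4, 4, by = 1e-3)
  ll <- vapply(grid, function(b) -brute_cox_nll(b * x, time, event), 0)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)], tolerance = 2e-3)
  # separation warns rather than looping forever
  expect_warning(fit_cox(-(1:8), 1:8, rep(1, 8), max_iter = 10), "converge")
})

test_that("bootstrap C-index CI behaves at the extremes and shrinks with n", {
  time <- c(5, 4, 3, 2, 1); ev <- rep(1, 5)
  ci <- cindex_ci(-time, time, ev, n_boot = 100, seed = 1)
  expect_equal(ci$c_index, 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  set.seed(307)
  cfg <- cohort_config(n_patients = 368, baseline_scale = 150, seed = 31)
  eta <- rnorm(368)
  sv <- generate_survival(eta, cfg, seed = 32)
  w_big <- with(cindex_ci(eta, sv$time, sv$event, n_boot = 300, seed = 3),
                upper - lower)
  idx <- 1:34
  w_small <- with(cindex_ci(eta[idx], sv$time[idx], sv$event[idx],
                            n_boot = 300, seed = 3), upper - lower)
  expect_gt(w_small, w_big)
})

test_that("paired C-index comparison: identity, power, and self-test", {
  set.seed(309)
  n <- 400
  cfg <- cohort_config(n_patients = n, baseline_scale = 150, seed = 33)
  eta <- rnorm(n, sd = 1.2)
  sv <- generate_survival(eta, cfg, seed = 34)
  expect_equal(compare_cindex(eta, eta, sv$time, sv$event)$p, 1)
  ct <- compare_cindex(eta, rnorm(n), sv$time, sv$event)
  expect_lt(ct$p, 0.01)
  expect_gt(ct$diff, 0)
})

test_that("time-dependent ROC reduces to the plain ROC without censoring", {
  set.seed(311)
  n <- 80
  s <- rnorm(n)
  tt <- rexp(n, exp(0.8 * s) / 30)
  t_star <- unname(stats::quantile(tt, 0.55))
  tr <- time_roc(s, tt, rep(1, n), t_star)
  lab <- tt <= t_star
  plain <- mean(outer(s[lab], s[!lab], `>`) + 0.5 * outer(s[lab], s[!lab], `==`))
  expect_equal(tr$auc, plain, tolerance = 1e-12)
  # anti-score flips the AUC
  expect_equal(time_roc(-s, tt, rep(1, n), t_star)$auc, 1 - tr$auc,
               tolerance = 1e-12)
  expect_error(time_roc(s, tt, rep(1, n), max(tt) + 1), "beyond")
})

test_that("IPCW time-dependent AUC matches the brute-force weighted oracle", {
  set.seed(313)
  for (rep in 1:10) {
    n <- sample(30:50, 1)
    s <- rnorm(n)
    t0 <- rexp(n, exp(0.7 * s) / 20)
    cns <- rexp(n, 1 / 25)
    time <- pmin(t0, cns); event <- as.integer(t0 <= cns)
    t_star <- unname(stats::quantile(time, 0.5))
    if (sum(time <= t_star & event == 1) < 2 || sum(time > t_star) < 2) next
    expect_equal(time_roc(s, time, event, t_star)$auc,
                 brute_time_auc(s, time, event, t_star), tolerance = 1e-10)
  }
})

test_that("Youden cutoff maximizes sens + spec - 1", {
  set.seed(315)
  n <- 60
  s <- rnorm(n); t0 <- rexp(n, exp(s) / 10)
  tr <- time_roc(s, t0, rep(1, n), unname(stats::quantile(t0, 0.5)))
  youden <- tr$curve$sens + tr$curve$spec - 1
  expect_equal(tr$sens + tr$spec - 1, max(youden), tolerance = 1e-12)
})

test_that("risk_to_prob: bounds, flat limit, exponential closed form", {
  set.seed(317)
  n <- 2000
  s <- rnorm(n)
  b <- 60
  t0 <- rexp(n, exp(0.8 * s) / b)   # shape-1 Weibull PH
  cns <- rexp(n, 1 / 80)
  time <- pmin(t0, cns); event <- as.integer(t0 <= cns)
  p <- risk_to_prob(s, time, event, 36)
  expect_true(all(p >= 0 & p <= 1))
  truth <- 1 - exp(-36 / b * exp(0.8 * s))
  expect_lt(mean(abs(p - truth)), 0.02)
  # constant score: every patient shares the baseline probability
  pc <- risk_to_prob(rep(1, n), time, event, 36)
  expect_equal(length(unique(round(pc, 12))), 1L)
})

test_that("calibration flags miscalibration and degenerate groupings", {
  set.seed(319)
  n <- 1000
  s <- rnorm(n)
  t0 <- rexp(n, exp(0.8 * s) / 60)
  time <- pmin(t0, 96); event <- as.integer(t0 <= 96)
  p_true <- risk_to_prob(s, time, event, 36)
  cal <- calibration_3yr(p_true, time, event)
  expect_gt(cal$p, 0.01)  # well calibrated by construction
  p_bad <- pmin(p_true * 2, 0.999)
  expect_lt(calibration_3yr(p_bad, time, event)$p, 0.01)
  expect_error(calibration_3yr(rep(0.3, n), time, event), "group")
  expect_error(calibration_3yr(rep(1.2, n), time, event), "\\[0, 1\\]")
})

test_that("decision-curve closed forms hold exactly", {
  set.seed(321)
  n <- 200
  ev_by <- rbinom(n, 1, 0.3)
  time <- ifelse(ev_by == 1, 12, 60)   # no censoring before the horizon
  event <- ev_by
  rate <- mean(ev_by)
  th <- seq(0.05, 0.6, by = 0.05)
  # treat-none and treat-all references
  dc <- decision_curve(rep(0, n), time, event, 36, th)
  expect_true(all(dc$treat_none == 0))
  expect_equal(dc$treat_all, rate - (1 - rate) * th / (1 - th), tolerance = 1e-12)
  # a perfect predictor keeps net benefit at the event rate for all p_t
  dc2 <- decision_curve(as.numeric(ev_by), time, event, 36, th)
  expect_equal(dc2$net_benefit, rep(rate, length(th)), tolerance = 1e-12)
  # an all-in predictor reproduces treat-all
  dc3 <- decision_curve(rep(1, n), time, event, 36, th)
  expect_equal(dc3$net_benefit, dc3$treat_all, tolerance = 1e-12)
})

test_that("IDI/NRI: identity at equality, antisymmetry, signal detection", {
  set.seed(323)
  n <- 300
  s <- rnorm(n)
  t0 <- rexp(n, exp(s) / 40)
  cns <- rexp(n, 1 / 60)
  time <- pmin(t0, cns); event <- as.integer(t0 <= cns)
  t_star <- unname(stats::quantile(time, 0.5))
  p_new <- risk_to_prob(s, time, event, t_star)
  p_old <- risk_to_prob(rnorm(n), time, event, t_star)
  same <- idi_nri(p_new, p_new, time, event, t_star, n_boot = 50, seed = 1)
  expect_equal(same$idi, 0)
  expect_equal(same$nri, 0)
  ab <- idi_nri(p_new, p_old, time, event, t_star, n_boot = 150, seed = 2)
  ba <- idi_nri(p_old, p_new, time, event, t_star, n_boot = 150, seed = 2)
  expect_equal(ab$idi, -ba$idi, tolerance = 1e-12)
  expect_equal(ab$nri, -ba$nri, tolerance = 1e-12)
  expect_gt(ab$idi, 0)
  expect_gt(ab$nri, 0)
  expect_lt(ab$idi_p, 0.01)
  expect_lt(ab$nri_p, 0.01)
})

test_that("Wilcoxon signed-rank: exact enumeration oracle and R agreement", {
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p, 1)
  set.seed(325)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    a <- rnorm(n); b <- rnorm(n)
    w <- wilcoxon_signed_rank(a, b)
    expect_equal(w$p, brute_wilcoxon_p(a, b), tolerance = 1e-12)
    expect_equal(w$p, stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # consistently positive (untied) shifts attain the minimal two-sided p, 2/2^n
  a <- rnorm(8); b <- a + seq(0.5, 1.2, length.out = 8)
  expect_equal(wilcoxon_signed_rank(b, a)$p, 2 / 2^8, tolerance = 1e-12)
  # tied |differences| fall back to the corrected normal approximation
  w2 <- wilcoxon_signed_rank(c(3, 4, 6, 9, 7, 8), c(2, 3, 5, 8, 9, 4))
  expect_false(w2$exact)
  expect_true(w2$p > 0 && w2$p <= 1)
})

test_that("without censoring, AUC(t*) equals concordance on dichotomized failure", {
  set.seed(327)
  n <- 60
  s <- rnorm(n); t0 <- rexp(n, exp(s) / 15)
  t_star <- unname(stats::quantile(t0, 0.5))
  tr <- time_roc(s, t0, rep(1, n), t_star)
  # collapse times to case (T <= t*) vs control (T > t*): the usable pairs of
  # Harrell's C are then exactly the case-control pairs of the ROC
  time2 <- ifelse(t0 <= t_star, 1, 2)
  event2 <- as.integer(t0 <= t_star)
  expect_equal(tr$auc, harrell_cindex(s, time2, event2), tolerance = 1e-12)
})
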