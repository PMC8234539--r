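test_that("Cox partial NLL has its analytic values", {
  # equal risks, distinct event times, no censoring: sum log k
  for (n in c(3, 7, 12)) {
    expect_equal(cox_partial_nll(rep(0, n), seq_len(n), rep(1, n)),
                 sum(log(seq_len(n))), tolerance = 1e-12)
  }
  # single event with risk set of 4, all risks 0
  expect_equal(cox_partial_nll(rep(0, 4), c(1, 2, 3, 4), c(1, 0, 0, 0)), log(4))
  expect_error(cox_partial_nll(rnorm(3), 1:3, c(0, 0, 0)), "event")
})

test_that("Cox partial NLL matches the risk-set-loop oracle, with ties", {
  set.seed(201)
  for (rep in 1:25) {
    inst <- random_surv_instance(sample(5:60, 1))
    r <- rnorm(length(inst$time))
    expect_equal(cox_partial_nll(r, inst$time, inst$event),
                 brute_cox_nll(r, inst$time, inst$event), tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(203)
  cfg <- dsnn_config(dense_layers = c(5, 5, 5), autocode_layers = c(6, 6, 3),
                     dropout_rate = 0, l1_activity_weight = 1e-3, seed = 3)
  n <- 20; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7); event[1] <- 1
  params <- build_network(cfg, p)
  lg <- radsurv:::dsnn_loss_grads(params, X, time, event, cfg)
  h <- 1e-5
  for (nm in names(params)) for (slot in c("W", "b")) {
    th <- params[[nm]][[slot]]
    for (i in seq_len(min(4, length(th)))) {
      pp <- params; pp[[nm]][[slot]][i] <- th[i] + h
      pm <- params; pm[[nm]][[slot]][i] <- th[i] - h
      num <- (radsurv:::dsnn_loss_grads(pp, X, time, event, cfg)$loss -
              radsurv:::dsnn_loss_grads(pm, X, time, event, cfg)$loss) / (2 * h)
      ana <- lg$grads[[nm]][[slot]][i]
      # relative check with an absolute floor: near-zero gradients are
      # dominated by finite-difference cancellation noise
      expect_lt(abs(num - ana), 1e-6 + 1e-5 * (abs(num) + abs(ana)))
    }
  }
})

test_that("parameter count matches the documented wiring", {
  cfg <- dsnn_config()
  params <- build_network(cfg, 155)
  # dense box: each layer sees the raw input plus all previous outputs;
  # auto-coding box: 48 -> 48 -> 24; linear head
  expected <- (155 * 48 + 48) + ((155 + 48) * 48 + 48) + ((155 + 96) * 48 + 48) +
    ((155 + 144) * 48 + 48) + (48 * 48 + 48) + (48 * 24 + 24) + (24 + 1)
  expect_equal(radsurv:::dsnn_n_params(params), expected)
})

test_that("forward pass and prediction are deterministic and name-aligned", {
  set.seed(205)
  n <- 60; p <- 6
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("f", 1:p)
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.6)
  event[1:5] <- 1
  cfg <- dsnn_config(seed = 5, max_epochs = 30, dropout_rate = 0.2)
  m1 <- train_dsnn(X, time, event, cfg)
  m2 <- train_dsnn(X, time, event, cfg)
  expect_identical(m1$params, m2$params)  # seeded dropout/init/split
  r1 <- predict_risk(m1, X)
  expect_identical(r1, predict_risk(m1, X))
  # column permutation is aligned by name
  expect_equal(predict_risk(m1, X[, sample(p)]), r1, tolerance = 1e-12)
  expect_error(predict_risk(m1, X[, -1]), "missing")
  Xe <- cbind(X, junk = 1)
  expect_error(predict_risk(m1, Xe), "extra")
})

test_that("an untrained network scores at chance on null data", {
  set.seed(207)
  n <- 400; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.7)
  cfg <- dsnn_config(seed = 11)
  params <- build_network(cfg, p)
  r <- radsurv:::dsnn_forward(params, X, cfg)$risk
  expect_lt(abs(harrell_cindex(r, time, event) - 0.5), 0.05)
})

test_that("training loss decreases initially at a small learning rate", {
  set.seed(209)
  n <- 150; p <- 8
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  eta <- rowSums(X[, 1:3])
  cfg0 <- cohort_config(n_patients = n, baseline_scale = 150, seed = 15)
  sv <- generate_survival(eta, cfg0, seed = 16)
  cfg <- dsnn_config(seed = 7, learning_rate = 1e-4, dropout_rate = 0,
                     max_epochs = 12, patience = 12)
  m <- train_dsnn(X, sv$time, sv$event, cfg)
  expect_true(all(diff(m$log$train_loss[1:10]) <= 1e-6))
})

test_that("early stopping restores the epoch with minimal validation loss", {
  set.seed(211)
  n <- 120; p <- 5
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  cfg0 <- cohort_config(n_patients = n, baseline_scale = 150, seed = 17)
  sv <- generate_survival(rowSums(X[, 1:2]), cfg0, seed = 18)
  m <- train_dsnn(X, sv$time, sv$event,
                  dsnn_config(seed = 9, max_epochs = 120, patience = 15))
  expect_equal(m$best_epoch, which.min(m$log$val_loss))
})

test_that("a linear ablation approximates the Cox linear predictor", {
  set.seed(213)
  n <- 300; p <- 6
  X <- matrix(rnorm(n * p), n, p); colnames(X) <- paste0("f", 1:p)
  eta <- drop(X %*% c(1, -0.8, 0.6, rep(0, p - 3)))
  cfg0 <- cohort_config(n_patients = n, baseline_scale = 120, seed = 19)
  sv <- generate_survival(eta, cfg0, seed = 20)
  cfg <- dsnn_config(architecture = "linear", dropout_rate = 0,
                     l1_activity_weight = 0, learning_rate = 5e-2,
                     max_epochs = 600, patience = 100, seed = 3)
  m <- train_dsnn(as.data.frame(X), sv$time, sv$event, cfg)
  r <- predict_risk(m, as.data.frame(X))
  cox_lp <- fit_cox(X, sv$time, sv$event)$linear_predictor
  expect_gt(stats::cor(r, cox_lp, method = "spearman"), 0.98)
})

test_that("a constant shift of inputs shifts linear-ablation scores by a constant", {
  set.seed(215)
  n <- 50; p <- 4
  X <- as.data.frame(matrix(rnorm(n * p), n, p))
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.8); event[1:2] <- 1
  cfg <- dsnn_config(architecture = "linear", dropout_rate = 0, seed = 2,
                     max_epochs = 20)
  m <- train_dsnn(X, time, event, cfg)
  r1 <- predict_risk(m, X)
  # shift in raw units must propagate through the stored standardization
  r2 <- predict_risk(m, X + 1)
  expect_lt(stats::sd(r2 - r1), 1e-10)
})
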