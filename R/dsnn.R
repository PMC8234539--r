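#' Negative log Cox partial likelihood ("deep survival loss")
#'
#' Breslow handling of tied event times, numerically stabilized by
#' max-subtraction:
#' `-sum_{i: event} [ r_i - log sum_{j: t_j >= t_i} exp(r_j) ]`.
#'
#' @param risk per-patient risk scores.
#' @inheritParams fit_cox
#' @return Scalar loss (a sum over events, not a mean).
#' @export
cox_partial_nll <- function(risk, time, event) {
  cox_nll_grad(risk, time, event)$nll
}

# loss and per-patient gradient in one pass (original ordering)
cox_nll_grad <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  if (sum(event == 1) < 1) stop("cox_partial_nll needs at least one event")
  ord <- order(-time)
  r <- risk[ord]; es <- event[ord]
  M <- max(r)
  w <- exp(r - M)
  S0 <- cumsum(w)
  ge <- cummax_by_ties(time[ord])
  ev <- which(es == 1)
  b <- ge[ev]
  nll <- -sum(r[ev] - (log(S0[b]) + M))
  # d nll / d r_k = exp(r_k) * sum_{events i: k in riskset_i} 1/S0_i - e_k
  A <- numeric(n)
  inv <- 1 / S0[b]
  for (t in seq_along(b)) A[b[t]] <- A[b[t]] + inv[t]
  factor <- rev(cumsum(rev(A)))
  g_sorted <- w * factor - es
  g <- numeric(n)
  g[ord] <- g_sorted
  list(nll = nll, grad = g)
}

#' Configuration of the deep survival network
#'
#' Architecture: input -> dense box -> auto-coding box -> linear risk head.
#' The dense box is three 48-unit layers where each layer sees the raw input
#' concatenated with all previous layer outputs (DenseNet-style multi-level
#' abstraction). The auto-coding box is a 48-48-24 bottleneck whose 24-unit
#' code can carry an L1 activity penalty ("sparse features"); weight 0 gives
#' a plain bottleneck. Activation SELU, inverted dropout on hidden layers
#' (never on the code or at inference), full-batch Adam, early stopping on
#' the validation partial likelihood with best-weight restore.
#'
#' @param dense_layers dense-box widths (default `c(48, 48, 48)`).
#' @param autocode_layers auto-coding widths, bottleneck last
#'   (default `c(48, 48, 24)`).
#' @param dropout_rate hidden dropout probability in `[0, 1)`.
#' @param learning_rate Adam step size.
#' @param max_epochs training cap.
#' @param patience early-stop patience (epochs without validation improvement).
#' @param val_fraction validation split fraction in `(0, 1)`.
#' @param l1_activity_weight L1 penalty weight on the code activations.
#' @param l2_weight L2 weight-decay coefficient on all weight matrices
#'   (biases excluded); 0 disables.
#' @param activation `"selu"` or `"linear"` (the latter for ablations).
#' @param architecture `"dsnn"` or `"linear"` (single linear layer ablation).
#' @param seed integer; seeds the split, initialization and dropout streams.
#' @return List of class `dsnn_config`.
#' @export
dsnn_config <- function(dense_layers = c(48L, 48L, 48L),
                        autocode_layers = c(48L, 48L, 24L),
                        dropout_rate = 0.2, learning_rate = 1e-3,
                        max_epochs = 500L, patience = 20L,
                        val_fraction = 0.2, l1_activity_weight = 1e-4,
                        l2_weight = 0,
                        activation = c("selu", "linear"),
                        architecture = c("dsnn", "linear"), seed = 1L) {
  activation <- match.arg(activation)
  architecture <- match.arg(architecture)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            val_fraction > 0, val_fraction < 1, l1_activity_weight >= 0,
            l2_weight >= 0)
  structure(list(dense_layers = as.integer(dense_layers),
                 autocode_layers = as.integer(autocode_layers),
                 dropout_rate = dropout_rate, l2_weight = l2_weight,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_fraction = val_fraction,
                 l1_activity_weight = l1_activity_weight,
                 activation = activation, architecture = architecture,
                 seed = as.integer(seed)),
            class = "dsnn_config")
}

selu_lambda <- 1.0507009873554805
selu_alpha <- 1.6732632423543772

act_fun <- function(z, kind) {
  if (kind == "linear") return(z)
  ifelse(z > 0, selu_lambda * z, selu_lambda * selu_alpha * (exp(z) - 1))
}

act_grad <- function(z, kind) {
  if (kind == "linear") return(array(1, dim = dim(z)))
  ifelse(z > 0, selu_lambda, selu_lambda * selu_alpha * exp(z))
}

#' Build an untrained deep survival network
#'
#' LeCun-normal initialization (`sd = 1/sqrt(fan_in)`), seeded.
#'
#' @param config a [dsnn_config].
#' @param n_features input dimensionality.
#' @return List of weight matrices/bias vectors (one entry per layer).
#' @export
build_network <- function(config, n_features) {
  stopifnot(n_features >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  mk <- function(fan_in, units) {
    list(W = matrix(stats::rnorm(fan_in * units, sd = 1 / sqrt(fan_in)),
                    fan_in, units),
         b = numeric(units))
  }
  if (config$architecture == "linear") {
    return(list(head = mk(n_features, 1L)))
  }
  params <- list()
  acc <- n_features
  for (k in seq_along(config$dense_layers)) {
    params[[paste0("dense", k)]] <- mk(acc, config$dense_layers[k])
    acc <- acc + config$dense_layers[k]
  }
  d_in <- acc  # raw input + every dense-box layer output
  for (k in seq_along(config$autocode_layers)) {
    params[[paste0("auto", k)]] <- mk(d_in, config$autocode_layers[k])
    d_in <- config$autocode_layers[k]
  }
  params$head <- mk(d_in, 1L)
  params
}

dsnn_n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), 0))
}

# forward pass; when `masks` is non-NULL (training), inverted dropout is
# applied to hidden activations (not the code); returns cached activations
dsnn_forward <- function(params, X, config, masks = NULL) {
  if (config$architecture == "linear") {
    risk <- drop(X %*% params$head$W + rep(params$head$b, each = nrow(X)))
    return(list(risk = risk))
  }
  nd <- length(config$dense_layers)
  na <- length(config$autocode_layers)
  cache <- list(C = list(), Z = list(), H = list())
  cur <- X
  for (k in seq_len(nd)) {
    nm <- paste0("dense", k)
    cache$C[[nm]] <- cur
    z <- cur %*% params[[nm]]$W + rep(params[[nm]]$b, each = nrow(X))
    h <- act_fun(z, config$activation)
    if (!is.null(masks) && !is.null(masks[[nm]])) h <- h * masks[[nm]]
    cache$Z[[nm]] <- z
    cache$H[[nm]] <- h
    cur <- cbind(cur, h)
  }
  for (k in seq_len(na)) {
    nm <- paste0("auto", k)
    cache$C[[nm]] <- cur
    z <- cur %*% params[[nm]]$W + rep(params[[nm]]$b, each = nrow(X))
    h <- act_fun(z, config$activation)
    is_code <- k == na
    if (!is_code && !is.null(masks) && !is.null(masks[[nm]])) h <- h * masks[[nm]]
    cache$Z[[nm]] <- z
    cache$H[[nm]] <- h
    cur <- h
  }
  cache$C$head <- cur
  risk <- drop(cur %*% params$head$W + rep(params$head$b, each = nrow(X)))
  cache$risk <- risk
  cache
}

# backward pass: d_risk is dLoss/drisk (n-vector); returns gradient list
dsnn_backward <- function(params, cache, config, d_risk, masks = NULL,
                          l1_on_code = 0) {
  grads <- list()
  n <- length(d_risk)
  if (config$architecture == "linear") {
    X <- cache$X
    grads$head <- list(W = crossprod(X, matrix(d_risk, ncol = 1)),
                       b = sum(d_risk))
    return(grads)
  }
  nd <- length(config$dense_layers)
  na <- length(config$autocode_layers)
  code_nm <- paste0("auto", na)
  d_cur <- matrix(d_risk, ncol = 1) %*% t(params$head$W)  # into code
  grads$head <- list(W = crossprod(cache$C$head, matrix(d_risk, ncol = 1)),
                     b = sum(d_risk))
  if (l1_on_code > 0) d_cur <- d_cur + l1_on_code * sign(cache$H[[code_nm]])
  # autocode box, last to first
  for (k in rev(seq_len(na))) {
    nm <- paste0("auto", k)
    is_code <- k == na
    dh <- d_cur
    if (!is_code && !is.null(masks) && !is.null(masks[[nm]])) dh <- dh * masks[[nm]]
    dz <- dh * act_grad(cache$Z[[nm]], config$activation)
    grads[[nm]] <- list(W = crossprod(cache$C[[nm]], dz), b = colSums(dz))
    d_cur <- dz %*% t(params[[nm]]$W)
  }
  # d_cur now flows into D = [X, h1, ..., h_nd]; split and run dense box back
  p_in <- ncol(cache$C$dense1)
  dh_acc <- vector("list", nd)
  off <- p_in
  for (k in seq_len(nd)) {
    w <- config$dense_layers[k]
    dh_acc[[k]] <- d_cur[, (off + 1):(off + w), drop = FALSE]
    off <- off + w
  }
  for (k in rev(seq_len(nd))) {
    nm <- paste0("dense", k)
    dh <- dh_acc[[k]]
    if (!is.null(masks) && !is.null(masks[[nm]])) dh <- dh * masks[[nm]]
    dz <- dh * act_grad(cache$Z[[nm]], config$activation)
    grads[[nm]] <- list(W = crossprod(cache$C[[nm]], dz), b = colSums(dz))
    back <- dz %*% t(params[[nm]]$W)  # into [X, h1, .., h_{k-1}]
    if (k > 1) {
      off2 <- p_in
      for (j in seq_len(k - 1)) {
        w2 <- config$dense_layers[j]
        dh_acc[[j]] <- dh_acc[[j]] + back[, (off2 + 1):(off2 + w2), drop = FALSE]
        off2 <- off2 + w2
      }
    }
  }
  grads
}

# full loss + gradients for one parameter set (used by training and by the
# finite-difference tests)
dsnn_loss_grads <- function(params, X, time, event, config, masks = NULL) {
  cache <- dsnn_forward(params, X, config, masks)
  if (config$architecture == "linear") cache$X <- X
  lg <- cox_nll_grad(cache$risk, time, event)
  loss <- lg$nll
  l1 <- config$l1_activity_weight
  if (config$architecture != "linear" && l1 > 0) {
    code_nm <- paste0("auto", length(config$autocode_layers))
    loss <- loss + l1 * sum(abs(cache$H[[code_nm]]))
  }
  grads <- dsnn_backward(params, cache, config, lg$grad, masks,
                         l1_on_code = if (config$architecture == "linear") 0 else l1)
  l2 <- config$l2_weight
  if (!is.null(l2) && l2 > 0) {
    for (nm in names(params)) {
      loss <- loss + l2 / 2 * sum(params[[nm]]$W^2)
      grads[[nm]]$W <- grads[[nm]]$W + l2 * params[[nm]]$W
    }
  }
  list(loss = loss, grads = grads, risk = cache$risk)
}

#' Train the deep survival network
#'
#' Full-batch Adam on the Breslow Cox partial likelihood (plus the optional
#' L1 code-activity penalty). The cohort is split into training and
#' validation sets (stratified on the event indicator, seeded); training
#' stops when the validation partial likelihood has not improved for
#' `patience` epochs and the best-validation weights are restored. Features
#' are standardized internally (parameters stored for prediction).
#'
#' @param features data.frame or matrix of input features (an `id` column is
#'   dropped); one row per patient.
#' @inheritParams fit_cox
#' @param config a [dsnn_config].
#' @return Object of class `dsnn_model` with elements `params`, `config`,
#'   `feature_names`, `center`, `scale`, `log` (per-epoch train/val loss),
#'   `best_epoch`.
#' @export
train_dsnn <- function(features, time, event, config = dsnn_config()) {
  df <- as.data.frame(features)
  df <- df[, setdiff(colnames(df), "id"), drop = FALSE]
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(length(time) == n, length(event) == n)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  ev_idx <- which(event == 1); cs_idx <- which(event != 1)
  n_val_ev <- max(1L, round(config$val_fraction * length(ev_idx)))
  n_val_cs <- round(config$val_fraction * length(cs_idx))
  val <- c(sample(ev_idx, n_val_ev), if (n_val_cs > 0) sample(cs_idx, n_val_cs))
  tr <- setdiff(seq_len(n), val)
  if (sum(event[tr] == 1) < 2) stop("training split has fewer than 2 events")

  params <- build_network(config, ncol(Xs))
  adam_m <- rapply(params, function(x) x * 0, how = "replace")
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  keep <- 1 - config$dropout_rate

  hidden_names <- if (config$architecture == "linear") character(0) else {
    c(paste0("dense", seq_along(config$dense_layers)),
      paste0("auto", seq_len(length(config$autocode_layers) - 1L)))
  }
  widths <- if (config$architecture == "linear") integer(0) else {
    c(config$dense_layers,
      config$autocode_layers[-length(config$autocode_layers)])
  }

  Xtr <- Xs[tr, , drop = FALSE]; Xvl <- Xs[val, , drop = FALSE]
  log_tr <- numeric(0); log_vl <- numeric(0)
  best_val <- Inf; best_epoch <- 0L; best_params <- params; wait <- 0L
  t_adam <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    masks <- NULL
    if (config$dropout_rate > 0 && length(hidden_names) > 0) {
      masks <- stats::setNames(lapply(seq_along(hidden_names), function(k) {
        matrix(stats::rbinom(nrow(Xtr) * widths[k], 1, keep) / keep,
               nrow(Xtr), widths[k])
      }), hidden_names)
    }
    lg <- dsnn_loss_grads(params, Xtr, time[tr], event[tr], config, masks)
    if (!is.finite(lg$loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           "; last finite epoch was ", epoch - 1L)
    }
    t_adam <- t_adam + 1L
    for (nm in names(params)) {
      for (slot in c("W", "b")) {
        g <- lg$grads[[nm]][[slot]]
        adam_m[[nm]][[slot]] <- b1 * adam_m[[nm]][[slot]] + (1 - b1) * g
        adam_v[[nm]][[slot]] <- b2 * adam_v[[nm]][[slot]] + (1 - b2) * g^2
        mhat <- adam_m[[nm]][[slot]] / (1 - b1^t_adam)
        vhat <- adam_v[[nm]][[slot]] / (1 - b2^t_adam)
        params[[nm]][[slot]] <- params[[nm]][[slot]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_risk <- dsnn_forward(params, Xvl, config)$risk
    val_loss <- cox_partial_nll(val_risk, time[val], event[val])
    log_tr <- c(log_tr, lg$loss); log_vl <- c(log_vl, val_loss)
    if (is.finite(val_loss) && val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_epoch <- epoch
      best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  res <- list(params = best_params, config = config,
              feature_names = colnames(X), center = ctr, scale = scl,
              log = data.frame(epoch = seq_along(log_tr),
                               train_loss = log_tr, val_loss = log_vl),
              best_epoch = best_epoch,
              train_idx = tr, val_idx = val)
  class(res) <- "dsnn_model"
  res
}

#' @export
print.dsnn_model <- function(x, ...) {
  cat("<dsnn_model> ", length(x$feature_names), " features, ",
      dsnn_n_params(x$params), " parameters, best epoch ", x$best_epoch,
      "/", nrow(x$log), "\n", sep = "")
  invisible(x)
}

#' Predict the deep-radiomic risk score (DRS-BCR)
#'
#' Deterministic forward pass (dropout disabled). Feature columns are
#' aligned to the training registry by name; missing or extra columns are an
#' error.
#'
#' @param model a trained [train_dsnn] model.
#' @param features data.frame/matrix with the training feature columns
#'   (order free; `id` ignored).
#' @return Numeric risk score per patient (larger = higher BCR hazard).
#' @export
predict_risk <- function(model, features) {
  stopifnot(inherits(model, "dsnn_model"))
  df <- as.data.frame(features)
  df <- df[, setdiff(colnames(df), "id"), drop = FALSE]
  missing <- setdiff(model$feature_names, colnames(df))
  extra <- setdiff(colnames(df), model$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature columns do not match the training registry; missing: [",
         paste(utils::head(missing, 5), collapse = ", "), "], extra: [",
         paste(utils::head(extra, 5), collapse = ", "), "]")
  }
  X <- as.matrix(df[, model$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  dsnn_forward(model$params, Xs, model$config)$risk
}

#' @export
predict.dsnn_model <- function(object, newdata, ...) predict_risk(object, newdata)
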