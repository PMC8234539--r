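# Usable-pair structure for Harrell's C under right censoring: pair (i, j)
# is usable when the member with the shorter follow-up had the event, or the
# times are tied and exactly one member had the event (that member is treated
# as the earlier failure). `i` indexes the earlier-failing member.
pair_structure <- function(time, event) {
  n <- length(time)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  ei <- matrix(event == 1, n, n)
  ej <- t(ei)
  usable <- (ti < tj & ei) | (ti == tj & ei & !ej)
  diag(usable) <- FALSE
  idx <- which(usable, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], n = n)
}

cindex_from_pairs <- function(score, ps) {
  si <- score[ps$i]; sj <- score[ps$j]
  (sum(si > sj) + 0.5 * sum(si == sj)) / length(si)
}

#' Harrell's concordance index
#'
#' Probability that, among usable pairs of patients, the one failing earlier
#' carries the higher risk score. Usable pairs are those where the shorter
#' observed time ended in an event, or tied times with exactly one event.
#' Score ties count 1/2. 0.5 is chance, 1 perfect concordance.
#'
#' @param score per-patient risk score (larger = higher hazard).
#' @param time follow-up time.
#' @param event event indicator, 1 = event, 0 = censored.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  if (sum(event == 1) < 1) stop("harrell_cindex needs at least one event")
  ps <- pair_structure(time, event)
  if (length(ps$i) == 0) stop("no usable pairs (all comparisons censored)")
  cindex_from_pairs(score, ps)
}

#' Bootstrap confidence interval for Harrell's C
#'
#' Percentile bootstrap over patients.
#'
#' @inheritParams harrell_cindex
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level.
#' @return List with `c_index`, `lower`, `upper`, `n_boot`.
#' @export
cindex_ci <- function(score, time, event, n_boot = 2000L, seed = 1L, conf = 0.95) {
  est <- harrell_cindex(score, time, event)
  n <- length(score)
  boots <- numeric(n_boot)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    k <- sample.int(n, n, replace = TRUE)
    boots[b] <- tryCatch(harrell_cindex(score[k], time[k], event[k]),
                         error = function(e) NA_real_)
  }
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(c_index = est, lower = unname(qs[1]), upper = unname(qs[2]), n_boot = n_boot)
}

#' Paired comparison of two C-indices on the same patients
#'
#' Tests H0: C(a) = C(b) using the jackknife estimate of the variance of the
#' difference of the two concordance U-statistics (leave-one-patient-out).
#'
#' @param score_a,score_b two risk scores for the same patients.
#' @inheritParams harrell_cindex
#' @return List: `c_a`, `c_b`, `diff`, `se`, `z`, `p`.
#' @export
compare_cindex <- function(score_a, score_b, time, event) {
  ps <- pair_structure(time, event)
  if (length(ps$i) == 0) stop("no usable pairs")
  n <- ps$n
  contrib <- function(score) {
    si <- score[ps$i]; sj <- score[ps$j]
    (si > sj) + 0.5 * (si == sj)
  }
  ca_pair <- contrib(score_a)
  cb_pair <- contrib(score_b)
  N <- length(ca_pair)
  Ca <- sum(ca_pair) / N
  Cb <- sum(cb_pair) / N
  # leave-one-out totals: pairs touching patient k
  cnt_k <- tabulate(ps$i, n) + tabulate(ps$j, n)
  sum_by <- function(v, g) {
    out <- numeric(n)
    t1 <- tapply(v, g, sum)
    out[as.integer(names(t1))] <- t1
    out
  }
  sa <- sum_by(ca_pair, ps$i) + sum_by(ca_pair, ps$j)
  sb <- sum_by(cb_pair, ps$i) + sum_by(cb_pair, ps$j)
  keep <- cnt_k < N  # leave-one-out must keep at least one pair
  da <- (sum(ca_pair) - sa[keep]) / (N - cnt_k[keep])
  db <- (sum(cb_pair) - sb[keep]) / (N - cnt_k[keep])
  d <- da - db
  m <- length(d)
  se <- sqrt((m - 1) / m * sum((d - mean(d))^2))
  diff <- Ca - Cb
  if (diff == 0) {
    p <- 1
    z <- 0
  } else if (se == 0) {
    p <- 0
    z <- Inf * sign(diff)
  } else {
    z <- diff / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(c_a = Ca, c_b = Cb, diff = diff, se = se, z = z, p = p)
}

# save/restore the global RNG so seeded internals do not clobber user streams
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
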