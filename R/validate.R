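# Model qualification: nonparametric bootstrap, visual-predictive-check
# quantities, and goodness-of-fit residual tables.

#' Nonparametric bootstrap of a fitted model
#'
#' Resamples subjects (with all their rows) with replacement to the
#' original subject count, refits each replicate starting from the point
#' estimates, and summarizes every free parameter by its bootstrap median,
#' 2.5th/97.5th percentiles (type-7 interpolation) and relative bias,
#' `(median - estimate)/estimate x 100`. Failed or non-converged replicate
#' fits are excluded and counted; more than 20% failures flags the result
#' as unreliable.
#'
#' @param dataset the `tdm_dataset` the fit used.
#' @param fit the `ppk_fit` to validate.
#' @param n_boot number of bootstrap replicates (1000 for a full run;
#'   scaled-down runs use fewer).
#' @param seed optional seed.
#' @param spec [fit_spec()] for the refits; defaults to the fit's own.
#' @return A `bootstrap_result` data frame (one row per free parameter:
#'   `estimate`, `median`, `ci_lo`, `ci_hi`, `bias_pct`) with attributes
#'   `n_success`, `n_failed` and `unreliable`.
#' @export
bootstrap_ppk <- function(dataset, fit, n_boot = 1000L, seed = NULL,
                          spec = NULL) {
  stopifnot(inherits(fit, "ppk_fit"))
  check_number(n_boot, "n_boot", 1)
  if (!inherits(dataset, "tdm_dataset")) dataset <- as_tdm_dataset(dataset)
  spec <- spec %||% fit$spec
  spec$estimate <- fit$free
  spec$init <- NULL
  ids <- unique(dataset$ID)
  n <- length(ids)
  bysub <- split(seq_len(nrow(dataset)), factor(dataset$ID, levels = ids))
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(fit$free),
                  dimnames = list(NULL, fit$free))
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      pick <- sample.int(n, n, replace = TRUE)
      rows <- unlist(bysub[pick], use.names = FALSE)
      dsb <- dataset[rows, , drop = FALSE]
      dsb$ID <- rep(seq_len(n), lengths(bysub[pick]))
      ft <- tryCatch(fit_ppk(dsb, fit$model, spec), error = function(e) NULL)
      if (is.null(ft) || !is.finite(ft$ofv) || !ft$convergence) {
        n_fail <- n_fail + 1L
      } else {
        draws[b, ] <- ft$estimates[fit$free]
      }
    }
  })
  ok <- stats::complete.cases(draws)
  est <- fit$estimates[fit$free]
  med <- apply(draws[ok, , drop = FALSE], 2, stats::median)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), type = 7)
  out <- data.frame(parameter = fit$free, estimate = unname(est),
                    median = unname(med),
                    ci_lo = unname(qs[1, ]), ci_hi = unname(qs[2, ]),
                    bias_pct = unname(bootstrap_bias(med, est)))
  attr(out, "n_success") <- sum(ok)
  attr(out, "n_failed") <- n_boot - sum(ok)
  attr(out, "unreliable") <- (n_boot - sum(ok)) > 0.2 * n_boot
  class(out) <- c("bootstrap_result", "data.frame")
  out
}

#' Bootstrap bias
#'
#' `(median - estimate) / estimate x 100` (percent).
#'
#' @param median bootstrap median.
#' @param estimate original point estimate.
#' @return Percent bias, vectorised.
#' @export
bootstrap_bias <- function(median, estimate) {
  (median - estimate) / estimate * 100
}

# simulate one replicate DV vector on the original design
simulate_dv <- function(prep, model, truncate = FALSE) {
  tp <- typical_params(model, prep$subjects)
  eta <- stats::rnorm(prep$S, 0, omega_sd(model))
  C <- prep_conc(prep, tp, eta)
  sg <- sigma_sd(model)
  dv <- C * (1 + stats::rnorm(length(C), 0, sg[1])) +
    stats::rnorm(length(C), 0, sg[2])
  if (truncate) pmax(dv, 0) else dv
}

#' Visual-predictive-check quantities
#'
#' Computes, per time bin, the observed 2.5/50/97.5 percentiles and the
#' envelope (2.5--97.5%) plus median of the same percentiles across
#' `n_rep` datasets simulated from the model on the original design (same
#' subjects, times, doses and covariates; only random effects and residual
#' errors are re-drawn). Bins are time-quantile bins; empty bins are
#' reported with `NA` statistics, not dropped.
#'
#' @param dataset a `tdm_dataset`.
#' @param model [pop_model()] to simulate from.
#' @param n_rep number of simulated replicate datasets (>= 100 recommended).
#' @param bins number of time-quantile bins.
#' @param seed optional seed.
#' @return A `vpc_result` data frame, one row per bin and observed
#'   percentile (`p` in 2.5/50/97.5): observed value `obs`, simulated
#'   envelope `sim_lo`/`sim_med`/`sim_hi`, bin edges and counts.
#' @export
vpc_ppk <- function(dataset, model, n_rep = 200L, bins = 6L, seed = NULL) {
  check_number(n_rep, "n_rep", 1)
  prep <- prep_dataset(dataset)
  probs <- c(0.025, 0.5, 0.975)
  edges <- unique(stats::quantile(prep$time, seq(0, 1, length.out = bins + 1),
                                  type = 7))
  if (length(edges) < 2L) edges <- range(prep$time) + c(-0.5, 0.5)
  bin <- cut(prep$time, edges, include.lowest = TRUE)
  qs_by_bin <- function(x) {
    vapply(levels(bin), function(lv) {
      v <- x[bin == lv]
      if (!length(v)) rep(NA_real_, 3) else stats::quantile(v, probs, type = 7)
    }, numeric(3))
  }
  obs_q <- qs_by_bin(prep$B)
  sims <- with_seed(seed, {
    replicate(n_rep, qs_by_bin(simulate_dv(prep, model)))
  })
  # sims: 3 x nbin x n_rep
  env <- apply(sims, c(1, 2), stats::quantile, probs = c(0.025, 0.5, 0.975),
               na.rm = TRUE)
  nb <- nlevels(bin)
  out <- data.frame(
    bin = rep(levels(bin), each = 3),
    t_lo = rep(utils::head(edges, -1), each = 3),
    t_hi = rep(utils::tail(edges, -1), each = 3),
    n = rep(as.vector(table(bin)), each = 3),
    p = rep(100 * probs, nb),
    obs = as.vector(obs_q),
    sim_lo = as.vector(env[1, , ]),
    sim_med = as.vector(env[2, , ]),
    sim_hi = as.vector(env[3, , ]))
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Goodness-of-fit residual table
#'
#' One row per observation: population prediction (`pred`, random effects
#' at zero), individual prediction (`ipred`, empirical Bayes random
#' effects), individual weighted residual
#' `iwres = (DV - ipred) / sd(ipred)` with the standard deviation taken
#' from the residual model at the individual prediction, and the analogous
#' population-level weighted residual `wres`. Rows whose predicted
#' standard deviation is zero are flagged rather than dropped.
#'
#' @param dataset a `tdm_dataset`.
#' @param model [pop_model()].
#' @param fit optional `ppk_fit` supplying the empirical Bayes `eta`;
#'   computed from `model` when absent.
#' @return A `gof_table` data frame.
#' @export
gof_table <- function(dataset, model, fit = NULL) {
  prep <- prep_dataset(dataset)
  tp <- typical_params(model, prep$subjects)
  eta <- if (!is.null(fit)) {
    stopifnot(inherits(fit, "ppk_fit"))
    unname(fit$eta[as.character(prep$ids)])
  } else {
    ofv_engine(prep, model, "focei")$eta
  }
  sg <- sigma_sd(model)
  pred <- prep_conc(prep, tp, rep(0, prep$S))
  ipred <- prep_conc(prep, tp, eta)
  sd_i <- sqrt((sg[1] * ipred)^2 + sg[2]^2)
  sd_p <- sqrt((sg[1] * pred)^2 + sg[2]^2)
  out <- data.frame(
    id = prep$ids[prep$obs_si],
    time = prep$time,
    dv = prep$B,
    pred = pred,
    ipred = ipred,
    iwres = ifelse(sd_i > 0, (prep$B - ipred) / sd_i, NA_real_),
    wres = ifelse(sd_p > 0, (prep$B - pred) / sd_p, NA_real_),
    zero_sd = sd_i == 0 | sd_p == 0)
  class(out) <- c("gof_table", "data.frame")
  out
}
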