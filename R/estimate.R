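# Nonlinear mixed-effects estimation for the one-compartment trough model.
#
# The final model carries a single random effect (exponential, on CL/F), so
# each subject's marginal likelihood is a one-dimensional integral. It is
# approximated either by FOCE with interaction (Gauss-Newton curvature at
# the conditional mode, residual variance evaluated at the individual
# prediction) or by a full Laplace approximation (exact second derivative
# at the mode). The inner conditional-mode problem is solved for all
# subjects simultaneously with a damped Newton iteration on numerically
# differentiated per-subject objectives; the outer problem is quasi-Newton
# on log/log1p-transformed parameters.

INNER_H <- 1e-4      # step for inner numeric derivatives (eta scale)
INNER_TOL <- 1e-7    # gradient tolerance at the conditional mode
INNER_MAXIT <- 50L

# ---- dataset preparation -------------------------------------------------

# Flatten a tdm_dataset into the vectors the likelihood engine needs. Each
# observation is interpreted as a steady-state concentration under the most
# recent dose row's (AMT, II), at time (TIME - dose TIME) mod II.
prep_dataset <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  if (!inherits(dataset, "tdm_dataset")) dataset <- as_tdm_dataset(dataset)
  ids <- unique(dataset$ID)
  keep <- vapply(ids, function(id) {
    any(dataset$ID == id & dataset$MDV == 0)
  }, TRUE)
  ids <- ids[keep]
  if (!length(ids)) stop_bad("dataset has no observations")
  S <- length(ids)
  obs_si <- integer(0); B <- amt <- ii <- tin <- tobs <- numeric(0)
  first_row <- integer(S)
  for (s in seq_len(S)) {
    rows <- which(dataset$ID == ids[s])
    first_row[s] <- rows[1L]
    drow <- rows[dataset$MDV[rows] == 1]
    orow <- rows[dataset$MDV[rows] == 0]
    di <- findInterval(dataset$TIME[orow], dataset$TIME[drow])
    obs_si <- c(obs_si, rep.int(s, length(orow)))
    B <- c(B, dataset$DV[orow])
    amt <- c(amt, dataset$AMT[drow][di])
    ii <- c(ii, dataset$II[drow][di])
    tobs <- c(tobs, dataset$TIME[orow])
    tin <- c(tin, (dataset$TIME[orow] - dataset$TIME[drow][di]) %%
               dataset$II[drow][di])
  }
  covs <- dataset[first_row,
                  setdiff(names(dataset),
                          c("TIME", "AMT", "II", "DV", "MDV")),
                  drop = FALSE]
  rownames(covs) <- NULL
  list(S = S, ids = ids, n_obs = length(B), obs_si = obs_si, B = B,
       amt = amt, ii = ii, tin = tin, time = tobs, subjects = covs)
}

# ---- inner problem -------------------------------------------------------

# Per-observation predicted concentration given per-subject eta.
prep_conc <- function(prep, tp, eta) {
  cli <- tp$cl * exp(eta)
  concss_core(prep$amt, prep$ii, prep$tin,
              cli[prep$obs_si], tp$v[prep$obs_si], tp$ka[prep$obs_si])
}

# -2 log of the residual density per observation.
res_m2l <- function(B, C, sg) {
  vr <- (sg[1] * C)^2 + sg[2]^2
  (B - C)^2 / vr + log(2 * pi * vr)
}

# Damped Newton for the per-subject conditional modes, all subjects at once.
solve_eta <- function(jfun, S, eta0 = NULL, maxit = INNER_MAXIT,
                      tol = INNER_TOL) {
  eta <- if (is.null(eta0)) rep(0, S) else eta0
  f <- jfun(eta)
  h <- INNER_H
  for (it in seq_len(maxit)) {
    fp <- jfun(eta + h)
    fm <- jfun(eta - h)
    g <- (fp - fm) / (2 * h)
    crv <- pmax((fp - 2 * f + fm) / h^2, 1e-8)
    step <- pmax(pmin(-g / crv, 2), -2)
    en <- eta + step
    fn <- jfun(en)
    for (bt in seq_len(15L)) {
      bad <- !(fn <= f + 1e-12)
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
      en <- eta + step
      fn <- jfun(en)
    }
    bad <- !(fn <= f + 1e-12)
    en[bad] <- eta[bad]
    fn[bad] <- f[bad]
    moved <- max(abs(en - eta))
    eta <- en
    f <- fn
    if (max(abs(g)) < tol || moved < 1e-10) break
  }
  list(eta = eta, f = f)
}

# Approximate -2 log marginal likelihood. Returns ofv = Inf (never an
# error) when a subject's curvature at the mode is not positive, with the
# offending subjects reported.
ofv_engine <- function(prep, model, method = c("focei", "laplace"),
                       eta_start = NULL) {
  method <- match.arg(method)
  om <- omega_sd(model)
  sg <- sigma_sd(model)
  if (sg[1] == 0 && sg[2] == 0) {
    stop_bad("residual model is degenerate (both sigma components zero)")
  }
  tp <- typical_params(model, prep$subjects)
  if (any(!is.finite(tp$cl)) || any(tp$cl <= 0) || any(tp$v <= 0)) {
    return(list(ofv = Inf, eta = rep(0, prep$S), ok = FALSE,
                bad_subjects = prep$ids))
  }
  if (om == 0) {
    eta <- rep(0, prep$S)
    r <- res_m2l(prep$B, prep_conc(prep, tp, eta), sg)
    per <- as.vector(rowsum(r, prep$obs_si))
    return(list(ofv = sum(per), eta = eta, ok = TRUE,
                per_subject = per, bad_subjects = prep$ids[0]))
  }
  jfun <- function(eta) {
    r <- res_m2l(prep$B, prep_conc(prep, tp, eta), sg)
    as.vector(rowsum(r, prep$obs_si)) + eta^2 / om^2 + log(2 * pi * om^2)
  }
  sol <- solve_eta(jfun, prep$S, eta0 = eta_start)
  eta <- sol$eta
  h <- INNER_H
  if (method == "laplace") {
    f0 <- jfun(eta)
    crv <- (jfun(eta + h) - 2 * f0 + jfun(eta - h)) / h^2
    Hmode <- crv / 2     # curvature of -log joint
  } else {
    C0 <- prep_conc(prep, tp, eta)
    dC <- (prep_conc(prep, tp, eta + h) - prep_conc(prep, tp, eta - h)) /
      (2 * h)
    vr <- (sg[1] * C0)^2 + sg[2]^2
    Hmode <- as.vector(rowsum(dC^2 / vr, prep$obs_si)) + 1 / om^2
    f0 <- sol$f
  }
  bad <- !is.finite(Hmode) | Hmode <= 0
  per <- f0 + log(Hmode) - log(2 * pi)
  if (any(bad)) {
    return(list(ofv = Inf, eta = eta, ok = FALSE,
                per_subject = per, bad_subjects = prep$ids[bad]))
  }
  list(ofv = sum(per), eta = eta, ok = TRUE, per_subject = per,
       bad_subjects = prep$ids[0])
}

#' Objective function value of a model on a dataset
#'
#' Minus twice the approximate marginal log-likelihood (constants
#' included), marginalizing each subject's clearance random effect under
#' the chosen approximation. Additive over independent subjects and
#' deterministic given dataset, model and method. A subject whose inner
#' curvature is not positive definite makes the value non-finite (with the
#' subjects recorded in the `bad_subjects` attribute) rather than being
#' silently patched.
#'
#' @param dataset a `tdm_dataset`.
#' @param model [pop_model()] with a non-degenerate residual model.
#' @param method `"focei"` (first-order conditional with interaction,
#'   default) or `"laplace"`.
#' @return The OFV (numeric scalar).
#' @export
ofv <- function(dataset, model, method = c("focei", "laplace")) {
  prep <- prep_dataset(dataset)
  e <- ofv_engine(prep, model, method)
  if (!e$ok) {
    out <- Inf
    attr(out, "bad_subjects") <- e$bad_subjects
    return(out)
  }
  e$ofv
}

# ---- parameter packing ---------------------------------------------------

free_param_names <- function(model) {
  c("cl_pop", "v_pop", "ka",
    if (length(model$covariates)) paste0("theta_", names(model$covariates)),
    "omega_cl", "sigma_prop", "sigma_add")
}

param_get <- function(model, name) {
  if (startsWith(name, "theta_")) {
    model$covariates[[sub("^theta_", "", name)]]$theta
  } else {
    model[[name]]
  }
}

param_set <- function(model, name, value) {
  value <- unname(value)
  if (startsWith(name, "theta_")) {
    model$covariates[[sub("^theta_", "", name)]]$theta <- value
  } else {
    model[[name]] <- value
  }
  model
}

# transform kind per parameter: positivity via log; linear covariate theta
# via log1p so 1 + theta stays positive; power theta unconstrained
param_trans <- function(model, name) {
  if (startsWith(name, "theta_")) {
    ce <- model$covariates[[sub("^theta_", "", name)]]
    if (ce$kind == "linear") "log1p" else "identity"
  } else if (name %in% c("cl_pop", "v_pop", "ka", "wt_ref")) {
    "log"
  } else if (name %in% c("omega_cl", "sigma_prop", "sigma_add")) {
    "log"
  } else {
    "identity"
  }
}

t_fwd <- function(kind, x) switch(kind, log = log(x), log1p = log(1 + x), x)
t_inv <- function(kind, y) switch(kind, log = exp(y), log1p = expm1(y), y)
t_dnat <- function(kind, x) switch(kind, log = abs(x), log1p = abs(1 + x), 1)

pack_params <- function(model, free) {
  vapply(free, function(nm) {
    t_fwd(param_trans(model, nm), param_get(model, nm))
  }, 0)
}

unpack_params <- function(model, free, x) {
  for (i in seq_along(free)) {
    model <- param_set(model, free[i],
                       t_inv(param_trans(model, free[i]), x[i]))
  }
  model
}

# ---- fitting -------------------------------------------------------------

#' Estimation settings
#'
#' Which parameters are estimated, starting values and optimizer controls.
#' By default the absorption rate and both allometric exponents are fixed
#' (the sparse trough design carries almost no absorption information) and
#' everything else -- typical clearance and volume, every covariate
#' coefficient, the inter-individual variability and both residual-error
#' components -- is free.
#'
#' @param fix names of parameters to hold at their model values; any of
#'   `cl_pop`, `v_pop`, `ka`, `theta_<covariate>`, `omega_cl`,
#'   `sigma_prop`, `sigma_add` (the allometric exponents are never
#'   estimated).
#' @param estimate explicit character vector of free parameters,
#'   overriding the fix-based default.
#' @param init named list of starting values overriding the model's.
#' @param method likelihood approximation, `"focei"` or `"laplace"`.
#' @param maxit,reltol outer optimizer controls.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(fix = "ka", estimate = NULL, init = NULL,
                     method = c("focei", "laplace"),
                     maxit = 500L, reltol = 1e-10) {
  method <- match.arg(method)
  structure(list(fix = fix, estimate = estimate, init = init,
                 method = method, maxit = as.integer(maxit),
                 reltol = reltol),
            class = "fit_spec")
}

#' Fit the population model by approximate maximum likelihood
#'
#' Minimizes the [ofv()] over the free parameters, starting from the
#' values in `model`. The outer problem runs BFGS on transformed
#' parameters with a Nelder-Mead fallback; the best visited point is always
#' returned, so non-convergence degrades the result rather than losing it.
#' Standard errors come from the numerically differentiated outer Hessian
#' when it is positive definite.
#'
#' @param dataset a `tdm_dataset`.
#' @param model starting [pop_model()]; fixed parameters keep its values.
#' @param spec [fit_spec()].
#' @return An object of class `ppk_fit`: point `estimates`, `se` and
#'   `se_pct` (when available), minimized `ofv`, per-subject empirical
#'   Bayes `eta`, the fitted `model`, and convergence information.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_subjects = 40, seed = 7))
#' ds <- simulate_tdm(cohort, sertraline_final_model(),
#'                    troughs_per_subject = 2, seed = 8)
#' fit <- fit_ppk(ds, sertraline_final_model())
#' fit
#' }
#' @export
fit_ppk <- function(dataset, model, spec = fit_spec()) {
  stopifnot(inherits(model, "pop_model"), inherits(spec, "fit_spec"))
  prep <- prep_dataset(dataset)
  model0 <- model
  if (!is.null(spec$init)) {
    for (nm in names(spec$init)) {
      model0 <- param_set(model0, nm, spec$init[[nm]])
    }
  }
  all_free <- free_param_names(model0)
  free <- spec$estimate %||% setdiff(all_free, spec$fix)
  bad <- setdiff(free, all_free)
  if (length(bad)) stop_bad("unknown parameters: ", paste(bad, collapse = ", "))
  if (!length(free)) stop_bad("no free parameters")

  x0 <- pack_params(model0, free)
  best <- list(x = x0, f = Inf)
  eta_warm <- NULL
  objfun <- function(x) {
    m <- unpack_params(model0, free, x)
    e <- ofv_engine(prep, m, spec$method, eta_start = eta_warm)
    f <- e$ofv
    if (!is.finite(f)) return(1e10)
    eta_warm <<- e$eta   # warm-start the next inner solve
    if (f < best$f) best <<- list(x = x, f = f)
    f
  }
  f0 <- objfun(x0)
  run_bfgs <- function(x) tryCatch(
    stats::optim(x, objfun, method = "BFGS",
                 control = list(maxit = spec$maxit, reltol = spec$reltol)),
    error = function(e) NULL)
  opt <- run_bfgs(x0)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
    opt <- stats::optim(x0, objfun, method = "Nelder-Mead",
                        control = list(maxit = spec$maxit,
                                       reltol = spec$reltol))
  }
  # a stale quasi-Newton Hessian can stall near the optimum; restarting
  # from the best visited point resets it and usually closes convergence
  for (r in 1:2) {
    if (!is.null(opt) && opt$convergence == 0) break
    opt <- run_bfgs(best$x) %||% opt
  }
  converged <- !is.null(opt) && opt$convergence == 0 && best$f < 1e9
  xhat <- best$x
  fitted <- unpack_params(model0, free, xhat)
  final <- ofv_engine(prep, fitted, spec$method)

  est <- vapply(free, function(nm) param_get(fitted, nm), 0)
  se <- se_pct <- rep(NA_real_, length(free))
  H <- tryCatch(stats::optimHess(xhat, objfun), error = function(e) NULL)
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    cov_t <- if (all(ev > 1e-10 * max(abs(ev)))) {
      tryCatch(2 * solve(H), error = function(e) NULL)  # objective is -2 log L
    }
    if (!is.null(cov_t)) {
      se_t <- sqrt(pmax(diag(cov_t), 0))
      dnat <- vapply(seq_along(free), function(i) {
        t_dnat(param_trans(fitted, free[i]), est[i])
      }, 0)
      se <- se_t * dnat
      se_pct <- 100 * se / abs(est)
    }
  }
  names(se) <- names(se_pct) <- names(est) <- free

  fixed <- setdiff(all_free, free)
  fixed_vals <- vapply(fixed, function(nm) param_get(fitted, nm), 0)
  eta <- final$eta
  names(eta) <- prep$ids
  structure(list(model = fitted, estimates = est, se = se, se_pct = se_pct,
                 fixed = fixed_vals, ofv = final$ofv, start_ofv = f0,
                 eta = eta, free = free, method = spec$method, spec = spec,
                 convergence = converged,
                 n_subjects = prep$S, n_obs = prep$n_obs,
                 counts = if (!is.null(opt)) opt$counts else NULL),
            class = "ppk_fit")
}

#' @export
print.ppk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%s): OFV %.3f, %d subjects / %d observations%s\n",
              x$method, x$ofv, x$n_subjects, x$n_obs,
              if (x$convergence) "" else " [did not converge]"))
  print(fit_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter table of a fit
#'
#' Estimate / SE% / fixed-flag layout of a fit report, one row per model
#' parameter (fixed parameters carry their value and an empty SE).
#'
#' @param fit a `ppk_fit`.
#' @return A data frame with columns `parameter`, `estimate`, `se_pct`,
#'   `fixed`.
#' @export
fit_table <- function(fit) {
  stopifnot(inherits(fit, "ppk_fit"))
  rbind(
    data.frame(parameter = fit$free, estimate = unname(fit$estimates),
               se_pct = unname(fit$se_pct), fixed = FALSE),
    if (length(fit$fixed))
      data.frame(parameter = names(fit$fixed),
                 estimate = unname(fit$fixed),
                 se_pct = NA_real_, fixed = TRUE)
  )
}

# machine-readable fit summary for the pipeline
fit_report <- function(fit) {
  list(method = fit$method, ofv = fit$ofv, converged = fit$convergence,
       n_subjects = fit$n_subjects, n_obs = fit$n_obs,
       estimates = as.list(fit$estimates), se_pct = as.list(fit$se_pct),
       fixed = as.list(fit$fixed),
       omega_mode = fit$model$omega_mode, sigma_mode = fit$model$sigma_mode,
       eta = as.list(fit$eta))
}

#' Empirical Bayes estimates of the clearance random effects
#'
#' Posterior modes of each subject's `eta` given the model parameters --
#' the conditional estimates behind individual predictions and iWRES. With
#' `omega_cl = 0` the prior dominates and every estimate is zero.
#'
#' @param dataset a `tdm_dataset`.
#' @param model [pop_model()].
#' @return Named numeric vector of `eta` estimates (names are subject IDs).
#' @export
empirical_bayes <- function(dataset, model) {
  prep <- prep_dataset(dataset)
  e <- ofv_engine(prep, model, "focei")
  out <- e$eta
  names(out) <- prep$ids
  out
}
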