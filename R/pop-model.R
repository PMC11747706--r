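# Population parameter model: typical values, allometric weight scaling,
# covariate effects, inter-individual variability and residual error.

#' Covariate effect on a structural parameter
#'
#' Two functional forms are supported, matching pharmacometric convention:
#' `power` for continuous covariates, `TV * (x / reference)^theta`, and
#' `linear` for binary covariates, `TV * (1 + theta * x)`.
#'
#' @param name covariate name; must match a column of the dataset / cohort
#'   (e.g. `"ZOP"` for the zopiclone co-administration flag).
#' @param parameter structural parameter the effect scales, `"cl"` or `"v"`.
#' @param kind `"linear"` (binary covariate) or `"power"` (continuous).
#' @param theta effect coefficient. For `linear` on a 0/1 covariate,
#'   `1 + theta` must stay positive so that clearance does.
#' @param reference covariate reference value (continuous kind only),
#'   conventionally the dataset median.
#' @return An object of class `covariate_effect`.
#' @examples
#' covariate_effect("ZOP", "cl", "linear", theta = -0.547)
#' @export
covariate_effect <- function(name, parameter = c("cl", "v"),
                             kind = c("linear", "power"),
                             theta = 0, reference = NULL) {
  parameter <- match.arg(parameter)
  kind <- match.arg(kind)
  check_number(theta, "theta")
  if (kind == "linear" && 1 + theta <= 0) {
    stop_bad("linear effect needs 1 + theta > 0 (parameter must stay positive)")
  }
  if (kind == "power") {
    if (is.null(reference)) stop_bad("power effect needs a positive reference")
    check_number(reference, "reference", lower = 0, strict = TRUE)
  }
  structure(list(name = name, parameter = parameter, kind = kind,
                 theta = theta, reference = reference),
            class = "covariate_effect")
}

#' Population pharmacokinetic model
#'
#' Container for the fixed effects (typical clearance and volume at the
#' reference weight, fixed absorption rate, allometric exponents), the
#' covariate sub-models, the inter-individual variability on clearance and
#' the combined proportional-plus-additive residual error.
#'
#' The printed variability entries of a fitted model report can be read
#' either as standard deviations or as variances; `omega_mode` /
#' `sigma_mode` declare the convention and every consumer of the model
#' honours it. The default is `"sd"` (so `omega_cl = 0.391` means a
#' log-scale standard deviation, about 39% CV).
#'
#' @param cl_pop typical CL/F at `wt_ref` (L/h).
#' @param v_pop typical V/F at `wt_ref` (L).
#' @param ka absorption rate constant (1/h).
#' @param wt_ref reference body weight (kg), 70 by convention.
#' @param exp_cl,exp_v allometric weight exponents on clearance (0.75) and
#'   volume (1).
#' @param covariates list of [covariate_effect()] objects.
#' @param omega_cl inter-individual variability of clearance (log scale).
#' @param sigma_prop,sigma_add proportional (dimensionless) and additive
#'   (ng/mL) residual-error scales; both zero is allowed for deterministic
#'   simulation but rejected at estimation time.
#' @param omega_mode,sigma_mode `"sd"` or `"var"`; interpretation of the
#'   variability entries above.
#' @return An object of class `pop_model`.
#' @seealso [sertraline_final_model()] for the published pediatric model.
#' @export
pop_model <- function(cl_pop, v_pop, ka = 0.5, wt_ref = 70,
                      exp_cl = 0.75, exp_v = 1,
                      covariates = list(),
                      omega_cl = 0, sigma_prop = 0, sigma_add = 0,
                      omega_mode = c("sd", "var"),
                      sigma_mode = c("sd", "var")) {
  omega_mode <- match.arg(omega_mode)
  sigma_mode <- match.arg(sigma_mode)
  check_number(cl_pop, "cl_pop", 0, strict = TRUE)
  check_number(v_pop, "v_pop", 0, strict = TRUE)
  check_number(ka, "ka", 0, strict = TRUE)
  check_number(wt_ref, "wt_ref", 0, strict = TRUE)
  check_number(exp_cl, "exp_cl")
  check_number(exp_v, "exp_v")
  check_number(omega_cl, "omega_cl", 0)
  check_number(sigma_prop, "sigma_prop", 0)
  check_number(sigma_add, "sigma_add", 0)
  if (!is.list(covariates) ||
      !all(vapply(covariates, inherits, TRUE, "covariate_effect"))) {
    stop_bad("covariates must be a list of covariate_effect objects")
  }
  nm <- vapply(covariates, `[[`, "", "name")
  if (anyDuplicated(nm)) stop_bad("duplicate covariate effects: ",
                                  paste(nm[duplicated(nm)], collapse = ", "))
  names(covariates) <- nm
  structure(list(cl_pop = cl_pop, v_pop = v_pop, ka = ka, wt_ref = wt_ref,
                 exp_cl = exp_cl, exp_v = exp_v, covariates = covariates,
                 omega_cl = omega_cl, sigma_prop = sigma_prop,
                 sigma_add = sigma_add, omega_mode = omega_mode,
                 sigma_mode = sigma_mode),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (one-compartment oral)\n")
  cat(sprintf("  CL/F %g L/h, V/F %g L at %g kg; ka %g /h\n",
              x$cl_pop, x$v_pop, x$wt_ref, x$ka))
  cat(sprintf("  allometric exponents: CL %g, V %g\n", x$exp_cl, x$exp_v))
  for (ce in x$covariates) {
    cat(sprintf("  covariate %s on %s (%s): theta %g%s\n", ce$name,
                ce$parameter, ce$kind, ce$theta,
                if (is.null(ce$reference)) "" else
                  sprintf(", ref %g", ce$reference)))
  }
  cat(sprintf("  omega_cl %g (%s), sigma_prop %g / sigma_add %g ng/mL (%s)\n",
              x$omega_cl, x$omega_mode, x$sigma_prop, x$sigma_add,
              x$sigma_mode))
  invisible(x)
}

#' Published final sertraline model for pediatric MDD
#'
#' The fitted population model this package's simulations start from:
#' `CL/F = 74 (wt/70)^0.75 (1 - 0.547 ZOP)` L/h, `V/F = 874 wt/70` L,
#' ka fixed at 0.5 /h, inter-individual variability 0.391 on clearance and
#' combined residual error 0.159 (proportional) + 9.803 ng/mL (additive),
#' variability entries read as standard deviations.
#'
#' @return A [pop_model()].
#' @examples
#' m <- sertraline_final_model()
#' typical_params(m, data.frame(WT = 70, ZOP = c(0, 1)))
#' @export
sertraline_final_model <- function() {
  pop_model(cl_pop = 74, v_pop = 874, ka = 0.5, wt_ref = 70,
            exp_cl = 0.75, exp_v = 1,
            covariates = list(covariate_effect("ZOP", "cl", "linear",
                                               theta = -0.547)),
            omega_cl = 0.391, sigma_prop = 0.159, sigma_add = 9.803,
            omega_mode = "sd", sigma_mode = "sd")
}

#' Add a covariate effect to a model
#'
#' Returns the model with one more [covariate_effect()] attached (its
#' `theta` becomes an estimable parameter named `theta_<name>`).
#'
#' @param model [pop_model()].
#' @param effect a [covariate_effect()].
#' @return The extended [pop_model()].
#' @export
add_covariate <- function(model, effect) {
  stopifnot(inherits(model, "pop_model"), inherits(effect, "covariate_effect"))
  if (effect$name %in% names(model$covariates)) {
    stop_bad("model already has a covariate effect named ", effect$name)
  }
  model$covariates <- c(model$covariates,
                        stats::setNames(list(effect), effect$name))
  model
}

omega_sd <- function(model) {
  if (model$omega_mode == "sd") model$omega_cl else sqrt(model$omega_cl)
}

sigma_sd <- function(model) {
  s <- c(model$sigma_prop, model$sigma_add)
  if (model$sigma_mode == "sd") s else sqrt(s)
}

# Locate the weight column of a covariate table (dialect WT, or weight_kg).
weight_col <- function(data) {
  for (cand in c("WT", "weight_kg")) if (cand %in% names(data)) return(cand)
  stop_bad("data needs a WT (or weight_kg) column")
}

covariate_values <- function(data, ce) {
  if (!ce$name %in% names(data)) {
    stop_bad("covariate column '", ce$name, "' not found in data")
  }
  x <- data[[ce$name]]
  if (any(!is.finite(x))) stop_bad("covariate '", ce$name, "' has non-finite values")
  if (ce$kind == "linear" && !all(x %in% c(0, 1))) {
    stop_bad("covariate '", ce$name, "' must be coded 0/1 for a linear effect")
  }
  if (ce$kind == "power" && any(x <= 0)) {
    stop_bad("covariate '", ce$name, "' must be positive for a power effect")
  }
  x
}

effect_multiplier <- function(data, ce) {
  x <- covariate_values(data, ce)
  if (ce$kind == "linear") 1 + ce$theta * x else (x / ce$reference)^ce$theta
}

#' Typical structural parameters for subjects
#'
#' Evaluates the covariate model: allometric weight scaling plus every
#' covariate effect, with all random effects at zero. At the reference
#' weight without zopiclone this returns the typical values themselves.
#'
#' @param model [pop_model()].
#' @param data data frame with a weight column (`WT`, kg) and one column per
#'   model covariate (e.g. `ZOP` coded 0/1).
#' @return Data frame with columns `cl` (L/h), `v` (L), `ka` (1/h), one row
#'   per row of `data`.
#' @examples
#' typical_params(sertraline_final_model(), data.frame(WT = 70, ZOP = 0))
#' @export
typical_params <- function(model, data) {
  stopifnot(inherits(model, "pop_model"), is.data.frame(data))
  wt <- data[[weight_col(data)]]
  if (any(!is.finite(wt)) || any(wt <= 0)) stop_bad("weights must be positive")
  cl <- model$cl_pop * (wt / model$wt_ref)^model$exp_cl
  v <- model$v_pop * (wt / model$wt_ref)^model$exp_v
  for (ce in model$covariates) {
    mult <- effect_multiplier(data, ce)
    if (ce$parameter == "cl") cl <- cl * mult else v <- v * mult
  }
  data.frame(cl = cl, v = v, ka = rep_len(model$ka, nrow(data)))
}

#' Individual structural parameters
#'
#' Applies the exponential inter-individual random effect on clearance to
#' the typical parameters: `cl_i = cl_typ * exp(eta_i)`. Volume and
#' absorption carry no random effect in this model.
#'
#' @inheritParams typical_params
#' @param eta numeric vector of subject-level random effects, recycled to
#'   `nrow(data)`.
#' @return Data frame with columns `cl`, `v`, `ka`.
#' @export
individual_params <- function(model, data, eta) {
  if (any(!is.finite(eta))) stop_bad("eta must be finite")
  tp <- typical_params(model, data)
  tp$cl <- tp$cl * exp(rep_len(eta, nrow(tp)))
  tp
}

#' Draw inter-individual random effects
#'
#' Samples `eta ~ N(0, omega^2)` on the log-clearance scale, with `omega`
#' taken from the model under its declared interpretation mode.
#'
#' @param model [pop_model()].
#' @param n number of draws.
#' @param seed optional seed; the caller's RNG stream is restored afterwards.
#' @return Numeric vector of length `n`.
#' @export
sample_eta <- function(model, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop_bad("n must be a positive integer")
  }
  with_seed(seed, stats::rnorm(as.integer(n), 0, omega_sd(model)))
}

#' Apply residual observation error
#'
#' Turns model-predicted concentrations into observed-scale values under the
#' combined error model `B = C (1 + eps1) + eps2` with independent Gaussian
#' `eps` draws. Negative realized observations are kept by default so the
#' error model stays exactly as declared; `truncate = TRUE` floors them at
#' zero for reporting layers.
#'
#' @param model [pop_model()].
#' @param conc predicted concentrations (ng/mL), non-negative.
#' @param truncate floor realized values at zero?
#' @param seed optional seed.
#' @return Observed-scale concentrations (ng/mL).
#' @export
apply_residual <- function(model, conc, truncate = FALSE, seed = NULL) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_bad("conc must be finite and >= 0")
  }
  sg <- sigma_sd(model)
  out <- with_seed(seed, {
    n <- length(conc)
    conc * (1 + stats::rnorm(n, 0, sg[1])) + stats::rnorm(n, 0, sg[2])
  })
  if (truncate) pmax(out, 0) else out
}

# ---- flat-config serialization ------------------------------------------

model_to_list <- function(model) {
  list(cl_pop = model$cl_pop, v_pop = model$v_pop, ka = model$ka,
       wt_ref = model$wt_ref, exp_cl = model$exp_cl, exp_v = model$exp_v,
       omega_cl = model$omega_cl, omega_mode = model$omega_mode,
       sigma_prop = model$sigma_prop, sigma_add = model$sigma_add,
       sigma_mode = model$sigma_mode,
       covariates = lapply(unname(model$covariates), function(ce) {
         list(name = ce$name, parameter = ce$parameter, kind = ce$kind,
              theta = ce$theta, reference = ce$reference)
       }))
}

model_from_list <- function(x) {
  covs <- lapply(x$covariates %||% list(), function(ce) {
    covariate_effect(ce$name, ce$parameter, ce$kind, theta = ce$theta,
                     reference = ce$reference)
  })
  pop_model(cl_pop = x$cl_pop, v_pop = x$v_pop, ka = x$ka %||% 0.5,
            wt_ref = x$wt_ref %||% 70, exp_cl = x$exp_cl %||% 0.75,
            exp_v = x$exp_v %||% 1, covariates = covs,
            omega_cl = x$omega_cl %||% 0,
            sigma_prop = x$sigma_prop %||% 0,
            sigma_add = x$sigma_add %||% 0,
            omega_mode = x$omega_mode %||% "sd",
            sigma_mode = x$sigma_mode %||% "sd")
}

#' Write / read a model specification as a flat config file
#'
#' The format is chosen from the file extension: `.yaml`/`.yml` or `.json`.
#' Round-tripping a model through a config file reproduces it exactly.
#'
#' @param model [pop_model()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a [pop_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "pop_model"))
  x <- model_to_list(model)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    stop_bad("unsupported config extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop_bad("unsupported config extension: ", ext)
  }
  model_from_list(x)
}
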