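# Closed-form one-compartment kinetics with first-order absorption.
#
# Internal unit convention: dose mg, volume L, clearance L/h, time h.
# mg/L and ng/mL differ by a factor of 1000; all concentration returns are
# ng/mL, conversion applied once at the reporting boundary of each formula.

MGL_TO_NGML <- 1000

# Relative ka ~ ke proximity below which the analytic limit form is used.
KA_KE_SWITCH <- 1e-6

#' Structural pharmacokinetic parameters
#'
#' Apparent parameters of the one-compartment oral model. Bioavailability F
#' is not separable from sparse trough data, so clearance and volume are
#' apparent (`CL/F`, `V/F`); the elimination rate `ke = cl/v` is always
#' derived, never stored.
#'
#' @param cl apparent clearance CL/F (L/h), positive.
#' @param v apparent distribution volume V/F (L), positive.
#' @param ka first-order absorption rate constant (1/h), positive.
#' @return An object of class `structural_params`.
#' @examples
#' structural_params(cl = 74, v = 874, ka = 0.5)
#' @export
structural_params <- function(cl, v, ka) {
  if (!is.numeric(cl) || !is.numeric(v) || !is.numeric(ka)) {
    stop_bad("cl, v, ka must be numeric")
  }
  if (any(!is.finite(cl)) || any(!is.finite(v)) || any(!is.finite(ka))) {
    stop_bad("cl, v, ka must be finite")
  }
  if (any(cl <= 0) || any(v <= 0) || any(ka <= 0)) {
    stop_bad("cl, v, ka must be positive")
  }
  structure(list(cl = cl, v = v, ka = ka), class = "structural_params")
}

#' Dosing regimen
#'
#' @param dose_mg dose per administration (mg), non-negative.
#' @param tau_h inter-dose interval (h), positive; the once- and twice-daily
#'   schemes of interest use 24 h and 12 h.
#' @return An object of class `regimen` with the derived
#'   `n_doses_per_day = 24 / tau_h`.
#' @export
regimen <- function(dose_mg, tau_h) {
  if (any(!is.finite(dose_mg)) || any(dose_mg < 0)) {
    stop_bad("dose_mg must be finite and >= 0")
  }
  if (any(!is.finite(tau_h)) || any(tau_h <= 0)) {
    stop_bad("tau_h must be finite and > 0")
  }
  structure(list(dose_mg = dose_mg, tau_h = tau_h,
                 n_doses_per_day = 24 / tau_h),
            class = "regimen")
}

# Vectorised single-dose concentration (ng/mL); no argument checking.
conc1_core <- function(dose, t, cl, v, ka) {
  n <- max(length(dose), length(t), length(cl), length(v), length(ka))
  dose <- rep_len(dose, n); t <- rep_len(t, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  ke <- cl / v
  out <- numeric(n)
  near <- abs(ka - ke) < KA_KE_SWITCH * pmax(ka, ke)
  if (any(!near)) {
    i <- !near
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) - exp(-ka[i] * t[i]))
  }
  if (any(near)) {
    i <- near
    out[i] <- dose[i] * ka[i] * t[i] * exp(-ka[i] * t[i]) / v[i]
  }
  MGL_TO_NGML * out
}

# Vectorised steady-state concentration (ng/mL) at time t within an interval
# of length tau; periodic, so conc_ss(0) == conc_ss(tau) (the trough).
concss_core <- function(dose, tau, t, cl, v, ka) {
  n <- max(length(dose), length(tau), length(t),
           length(cl), length(v), length(ka))
  dose <- rep_len(dose, n); tau <- rep_len(tau, n); t <- rep_len(t, n)
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  ke <- cl / v
  out <- numeric(n)
  near <- abs(ka - ke) < KA_KE_SWITCH * pmax(ka, ke)
  if (any(!near)) {
    i <- !near
    accke <- 1 - exp(-ke[i] * tau[i])
    accka <- 1 - exp(-ka[i] * tau[i])
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - ke[i])) *
      (exp(-ke[i] * t[i]) / accke - exp(-ka[i] * t[i]) / accka)
  }
  if (any(near)) {
    # limit ke -> ka of the superposed profile
    i <- near
    acc <- 1 - exp(-ka[i] * tau[i])
    out[i] <- dose[i] * ka[i] / v[i] * exp(-ka[i] * t[i]) *
      (t[i] / acc + tau[i] * exp(-ka[i] * tau[i]) / acc^2)
  }
  MGL_TO_NGML * out
}

#' Concentration after a single oral dose
#'
#' Closed-form concentration of the one-compartment first-order-absorption
#' model, `C(t) = D ka / (V (ka - ke)) (e^{-ke t} - e^{-ka t})`, with the
#' analytic limit used when `ka` approaches `ke`.
#'
#' @param p [structural_params()].
#' @param dose_mg dose (mg).
#' @param t_h time since dosing (h), vectorised, non-negative.
#' @return Concentration in ng/mL.
#' @examples
#' p <- structural_params(74, 874, 0.5)
#' conc_single_dose(p, 100, c(0, 6, 24))
#' @export
conc_single_dose <- function(p, dose_mg, t_h) {
  stopifnot(inherits(p, "structural_params"))
  if (any(!is.finite(dose_mg)) || any(dose_mg < 0)) {
    stop_bad("dose_mg must be finite and >= 0")
  }
  if (any(!is.finite(t_h))) stop_bad("t_h must be finite")
  if (any(t_h < 0)) stop_bad("t_h must be >= 0")
  conc1_core(dose_mg, t_h, p$cl, p$v, p$ka)
}

#' Concentration at steady state under repeated dosing
#'
#' Multiple-dose superposition of the single-dose solution, evaluated at a
#' time `t_h` within the dosing interval. The profile is periodic with
#' period `tau_h`, so `t_h = 0` and `t_h = tau_h` both give the pre-dose
#' trough.
#'
#' @param p [structural_params()].
#' @param r [regimen()].
#' @param t_h time within the dosing interval (h), `0 <= t_h <= tau_h`.
#' @return Concentration in ng/mL.
#' @export
conc_steady_state <- function(p, r, t_h) {
  stopifnot(inherits(p, "structural_params"), inherits(r, "regimen"))
  if (any(!is.finite(t_h))) stop_bad("t_h must be finite")
  if (any(t_h < 0) || any(t_h > max(r$tau_h))) {
    stop_bad("t_h must lie within [0, tau_h]")
  }
  concss_core(r$dose_mg, r$tau_h, t_h, p$cl, p$v, p$ka)
}

#' Steady-state trough concentration
#'
#' The concentration immediately pre-dose at steady state, i.e.
#' [conc_steady_state()] at `t_h = tau_h`. This is the quantity therapeutic
#' drug monitoring measures and the reference point of the 10--150 ng/mL
#' therapeutic window.
#'
#' @inheritParams conc_steady_state
#' @return Trough concentration in ng/mL.
#' @export
trough_steady_state <- function(p, r) {
  conc_steady_state(p, r, r$tau_h)
}
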