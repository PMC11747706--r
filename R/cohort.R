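# Synthetic TDM cohort generator. Emulates the demographic structure of the
# study population (n = 111, weight 56.58 +/- 15.01 kg on 35-117 kg, 3/111
# on zopiclone) and produces sparse steady-state trough datasets.

# kth raw moment of a log-normal(mu, sig) truncated to [lo, hi]
tln_moment <- function(k, mu, sig, lo, hi) {
  a <- (log(lo) - mu) / sig
  b <- (log(hi) - mu) / sig
  z <- stats::pnorm(b) - stats::pnorm(a)
  exp(k * mu + k^2 * sig^2 / 2) *
    (stats::pnorm(b - k * sig) - stats::pnorm(a - k * sig)) / z
}

# Solve (mu, sig) of a truncated log-normal so its truncated mean and sd hit
# the targets. Moment equations via the closed-form truncated moments above.
tln_solve <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mu <- p[1]; sig <- exp(p[2])
    m1 <- tln_moment(1, mu, sig, lo, hi)
    m2 <- tln_moment(2, mu, sig, lo, hi)
    s <- sqrt(max(m2 - m1^2, 0))
    (m1 / mean - 1)^2 + (s / sd - 1)^2
  }
  cv2 <- (sd / mean)^2
  start <- c(log(mean / sqrt(1 + cv2)), log(sqrt(log(1 + cv2))))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  if (fit$value > 1e-6) stop_bad("weight distribution cannot match ",
                                 "the requested truncated moments")
  list(mu = fit$par[1], sig = exp(fit$par[2]))
}

rtlnorm <- function(n, mu, sig, lo, hi) {
  u <- stats::runif(n, stats::plnorm(lo, mu, sig), stats::plnorm(hi, mu, sig))
  stats::qlnorm(u, mu, sig)
}

#' Specification of a synthetic pediatric cohort
#'
#' Defaults mirror the study demographics: 111 subjects, body weight from a
#' truncated log-normal moment-matched to mean 56.58 kg / SD 15.01 kg on
#' 35--117 kg (log-normal respects the positivity and right skew implied by
#' median 52.5 < mean), zopiclone prevalence 3/111, and maintenance doses
#' drawn uniformly over the clinical 0.5--5 mg/kg/day range given either
#' once or twice daily.
#'
#' @param n_subjects number of subjects.
#' @param weight_mean,weight_sd,weight_min,weight_max truncated log-normal
#'   weight distribution (kg); the mean must lie inside the bounds.
#' @param zop_prevalence probability of the zopiclone flag.
#' @param dose_per_kg_range uniform range for total daily dose (mg/kg/day).
#' @param intervals candidate dosing intervals (h), sampled per subject.
#' @param troughs_per_subject integer count or candidate range of trough
#'   observations per subject (sampled per subject).
#' @param visit_days candidate steady-state visit days for trough sampling.
#' @param round_doses round the per-administration dose to 25 mg tablet
#'   strengths (minimum 25 mg)? Off by default: simulated doses are exact
#'   mg/kg.
#' @param seed optional seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 111,
                        weight_mean = 56.58, weight_sd = 15.01,
                        weight_min = 35, weight_max = 117,
                        zop_prevalence = 3 / 111,
                        dose_per_kg_range = c(0.5, 5),
                        intervals = c(24, 12),
                        troughs_per_subject = 1:3,
                        visit_days = 7:28,
                        round_doses = FALSE,
                        seed = NULL) {
  dose_per_kg_range <- as.numeric(unlist(dose_per_kg_range))
  intervals <- as.numeric(unlist(intervals))
  troughs_per_subject <- as.numeric(unlist(troughs_per_subject))
  visit_days <- as.numeric(unlist(visit_days))
  check_number(n_subjects, "n_subjects", 1)
  check_number(zop_prevalence, "zop_prevalence", 0)
  if (zop_prevalence > 1) stop_bad("zop_prevalence must be <= 1")
  check_number(weight_min, "weight_min", 0, strict = TRUE)
  if (weight_max <= weight_min) stop_bad("weight_min must be < weight_max")
  if (weight_mean <= weight_min || weight_mean >= weight_max) {
    stop_bad("weight_mean must lie strictly inside [weight_min, weight_max]")
  }
  check_number(weight_sd, "weight_sd", 0, strict = TRUE)
  if (any(troughs_per_subject < 1)) stop_bad("troughs_per_subject must be >= 1")
  if (max(troughs_per_subject) > length(visit_days)) {
    stop_bad("not enough visit_days for the requested troughs_per_subject")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 weight_min = weight_min, weight_max = weight_max,
                 zop_prevalence = zop_prevalence,
                 dose_per_kg_range = dose_per_kg_range,
                 intervals = intervals,
                 troughs_per_subject = troughs_per_subject,
                 visit_days = visit_days,
                 round_doses = round_doses, seed = seed),
            class = "cohort_spec")
}

#' Generate a virtual cohort of subjects with regimens
#'
#' Draws weights, zopiclone flags, daily mg/kg doses and dosing intervals
#' per the spec. Reproducible under `spec$seed`.
#'
#' @param spec [cohort_spec()].
#' @return A `cohort` data frame: `id`, `WT` (kg), `ZOP` (0/1),
#'   `dose_per_kg_day` (mg/kg/day), `tau_h` (h), `dose_mg` (mg per
#'   administration).
#' @examples
#' head(generate_cohort(cohort_spec(n_subjects = 5, seed = 1)))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  pars <- tln_solve(spec$weight_mean, spec$weight_sd,
                    spec$weight_min, spec$weight_max)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    wt <- rtlnorm(n, pars$mu, pars$sig, spec$weight_min, spec$weight_max)
    zop <- stats::rbinom(n, 1, spec$zop_prevalence)
    dpk <- stats::runif(n, spec$dose_per_kg_range[1], spec$dose_per_kg_range[2])
    tau <- if (length(spec$intervals) == 1L) rep(spec$intervals, n) else
      sample(spec$intervals, n, replace = TRUE)
    dose <- dpk * wt / (24 / tau)
    if (spec$round_doses) dose <- pmax(25, round(dose / 25) * 25)
    structure(data.frame(id = seq_len(n), WT = wt, ZOP = zop,
                         dose_per_kg_day = dpk, tau_h = tau, dose_mg = dose),
              class = c("cohort", "data.frame"))
  })
}

#' Simulate a sparse trough TDM dataset from a cohort
#'
#' Forward-simulates the population model: one clearance random effect per
#' subject, the subject's deterministic steady-state trough at each visit,
#' and combined residual error on every observation. The dataset uses the
#' steady-state event encoding of [read_tdm()]: one dose row per subject
#' (`TIME` 0, `AMT` per administration, interval `II`) followed by trough
#' observation rows at multiples of `II`.
#'
#' The per-subject true random effects are retained in the `eta_true`
#' attribute so that estimation can be checked against the generating truth.
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param model [pop_model()] to simulate from.
#' @param troughs_per_subject,visit_days sampling design; see
#'   [cohort_spec()].
#' @param truncate floor negative realized observations at zero? Off by
#'   default (keeps the declared error model during estimation work).
#' @param seed optional seed.
#' @return A `tdm_dataset` (see [read_tdm()]) with attribute `eta_true`.
#' @export
simulate_tdm <- function(cohort, model, troughs_per_subject = 1:3,
                         visit_days = 7:28, truncate = FALSE, seed = NULL) {
  stopifnot(is.data.frame(cohort), inherits(model, "pop_model"))
  need <- c("id", "WT", "ZOP", "tau_h", "dose_mg")
  if (!all(need %in% names(cohort))) {
    stop_bad("cohort must have columns ", paste(need, collapse = ", "))
  }
  with_seed(seed, {
    n <- nrow(cohort)
    eta <- sample_eta(model, n)
    ip <- individual_params(model, cohort, eta)
    trough <- concss_core(cohort$dose_mg, cohort$tau_h, cohort$tau_h,
                          ip$cl, ip$v, ip$ka)
    rows <- vector("list", n)
    extra <- setdiff(names(cohort),
                     c("id", "dose_per_kg_day", "WT", "ZOP", "tau_h",
                       "dose_mg"))
    for (i in seq_len(n)) {
      k <- resample1(troughs_per_subject)
      days <- sort(sample(visit_days, k))
      tm <- days * 24
      # align observation times to the dosing grid
      tm <- round(tm / cohort$tau_h[i]) * cohort$tau_h[i]
      dv <- apply_residual(model, rep(trough[i], k), truncate = truncate)
      sub <- data.frame(ID = cohort$id[i],
                        TIME = c(0, tm),
                        AMT = c(cohort$dose_mg[i], rep(NA_real_, k)),
                        II = c(cohort$tau_h[i], rep(NA_real_, k)),
                        DV = c(NA_real_, dv),
                        MDV = c(1L, rep(0L, k)),
                        WT = cohort$WT[i],
                        ZOP = cohort$ZOP[i])
      for (cc in extra) sub[[cc]] <- cohort[[cc]][i]
      rows[[i]] <- sub
    }
    out <- as_tdm_dataset(do.call(rbind, rows))
    attr(out, "eta_true") <- data.frame(ID = cohort$id, eta = eta)
    out
  })
}
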