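# Mixed-effects estimation: OFV correctness, fitting, empirical Bayes.

test_that("OFV with no IIV and additive error equals the closed-form Gaussian value", {
  m <- final_model
  m$omega_cl <- 0
  m$sigma_prop <- 0
  m$sigma_add <- 8
  ds <- sim_dataset(n = 15, seed = 11, model = m)
  # direct least-squares oracle
  obs <- ds[ds$MDV == 0, ]
  dose <- ds[ds$MDV == 1, ]
  pred <- vapply(seq_len(nrow(obs)), function(i) {
    dd <- dose[dose$ID == obs$ID[i], ]
    tp <- typical_params(m, obs[i, ])
    trough_steady_state(structural_params(tp$cl, tp$v, tp$ka),
                        regimen(dd$AMT, dd$II))
  }, 0)
  oracle <- sum((obs$DV - pred)^2 / 8^2 + log(2 * pi * 8^2))
  expect_equal(ofv(ds, m), oracle, tolerance = 1e-6)
  expect_equal(ofv(ds, m, "laplace"), oracle, tolerance = 1e-6)
})

test_that("OFV is additive over independent subjects", {
  ds <- sim_dataset(n = 12, seed = 13)
  ds2 <- ds
  ds2$ID <- ds2$ID + 1000
  both <- as_tdm_dataset(rbind(as.data.frame(ds), as.data.frame(ds2)))
  for (method in c("focei", "laplace")) {
    expect_equal(ofv(both, final_model, method),
                 2 * ofv(ds, final_model, method), tolerance = 1e-9)
  }
})

test_that("jointly rescaling doses, observations and sigma_add shifts OFV by the Jacobian constant", {
  ds <- sim_dataset(n = 10, seed = 17)
  k <- 3.7
  dss <- ds
  dss$DV <- dss$DV * k
  dss$AMT <- dss$AMT * k
  ms <- final_model
  ms$sigma_add <- ms$sigma_add * k
  n_obs <- sum(ds$MDV == 0)
  for (method in c("focei", "laplace")) {
    expect_equal(ofv(dss, ms, method),
                 ofv(ds, final_model, method) + 2 * n_obs * log(k),
                 tolerance = 1e-7)
  }
})

test_that("Laplace and FOCE-I agree with a brute-force quadrature of the marginal likelihood", {
  ds <- sim_dataset(n = 6, seed = 19)
  m <- final_model
  om <- m$omega_cl
  tot <- 0
  for (id in unique(ds$ID)) {
    rows <- ds[ds$ID == id, ]
    dd <- rows[rows$MDV == 1, ]
    oo <- rows[rows$MDV == 0, ]
    tp <- typical_params(m, rows[1, ])
    lik <- function(eta) {
      C <- trough_steady_state(structural_params(tp$cl * exp(eta), tp$v,
                                                 tp$ka),
                               regimen(dd$AMT, dd$II))
      vr <- (m$sigma_prop * C)^2 + m$sigma_add^2
      exp(sum(dnorm(oo$DV, C, sqrt(vr), log = TRUE))) * dnorm(eta, 0, om)
    }
    tot <- tot - 2 * log(stats::integrate(Vectorize(lik), -8 * om, 8 * om,
                                          rel.tol = 1e-12)$value)
  }
  # both approximations carry genuine (small) error at omega = 0.391
  expect_equal(ofv(ds, m, "laplace"), tot, tolerance = 5e-3)
  expect_equal(ofv(ds, m, "focei"), tot, tolerance = 0.02)
  # the approximations become exact as the random-effect scale shrinks
  m_small <- m
  m_small$omega_cl <- 0.02
  tot_small <- 0
  for (id in unique(ds$ID)) {
    rows <- ds[ds$ID == id, ]
    dd <- rows[rows$MDV == 1, ]
    oo <- rows[rows$MDV == 0, ]
    tp <- typical_params(m_small, rows[1, ])
    lik <- function(eta) {
      C <- trough_steady_state(structural_params(tp$cl * exp(eta), tp$v,
                                                 tp$ka),
                               regimen(dd$AMT, dd$II))
      vr <- (m_small$sigma_prop * C)^2 + m_small$sigma_add^2
      exp(sum(dnorm(oo$DV, C, sqrt(vr), log = TRUE))) *
        dnorm(eta, 0, 0.02)
    }
    tot_small <- tot_small -
      2 * log(stats::integrate(Vectorize(lik), -0.2, 0.2,
                               rel.tol = 1e-12)$value)
  }
  expect_equal(ofv(ds, m_small, "laplace"), tot_small, tolerance = 1e-5)
  expect_equal(ofv(ds, m_small, "focei"), tot_small, tolerance = 1e-3)
})

test_that("noiseless data identify the generating clearance exactly", {
  m <- det_model()
  m$sigma_add <- 0.1   # tiny noise floor keeps the likelihood proper
  co <- generate_cohort(cohort_spec(n_subjects = 10, seed = 23))
  ds <- simulate_tdm(co, det_model(), troughs_per_subject = 2, seed = 24)
  start <- m
  start$cl_pop <- 55
  ft <- fit_ppk(ds, start, fit_spec(estimate = "cl_pop"))
  expect_equal(unname(ft$estimates["cl_pop"]), 74, tolerance = 1e-4)
  expect_true(ft$convergence)
  expect_lte(ft$ofv, ft$start_ofv)
})

test_that("adding a free parameter never worsens the minimized OFV", {
  ds <- sim_dataset(n = 25, seed = 29)
  f_small <- fit_ppk(ds, final_model,
                     fit_spec(estimate = c("cl_pop", "omega_cl")))
  f_big <- fit_ppk(ds, final_model,
                   fit_spec(estimate = c("cl_pop", "omega_cl", "v_pop",
                                         "sigma_add")))
  expect_lte(f_big$ofv, f_small$ofv + 1e-6)
})

test_that("suppressing a real zopiclone effect costs likelihood", {
  m <- final_model
  co <- generate_cohort(cohort_spec(n_subjects = 60, zop_prevalence = 0.4,
                                    seed = 31))
  ds <- simulate_tdm(co, m, troughs_per_subject = 2, seed = 32)
  with_eff <- fit_ppk(ds, m)
  m0 <- m
  m0$covariates$ZOP$theta <- 0
  without <- fit_ppk(ds, m0, fit_spec(fix = c("ka", "theta_ZOP")))
  expect_gt(without$ofv, with_eff$ofv + 3.84)
})

test_that("empirical Bayes estimates match a grid-search oracle", {
  ds <- sim_dataset(n = 8, seed = 37, troughs = 3)
  eta_hat <- empirical_bayes(ds, final_model)
  m <- final_model
  for (id in names(eta_hat)[1:4]) {
    rows <- ds[ds$ID == as.numeric(id), ]
    dd <- rows[rows$MDV == 1, ]
    oo <- rows[rows$MDV == 0, ]
    tp <- typical_params(m, rows[1, ])
    joint <- function(eta) {
      C <- trough_steady_state(structural_params(tp$cl * exp(eta), tp$v,
                                                 tp$ka),
                               regimen(dd$AMT, dd$II))
      vr <- (m$sigma_prop * C)^2 + m$sigma_add^2
      sum((oo$DV - C)^2 / vr + log(vr)) + eta^2 / m$omega_cl^2
    }
    grid <- seq(-2, 2, by = 1e-4)
    oracle <- grid[which.min(vapply(grid, joint, 0))]
    expect_lt(abs(unname(eta_hat[id]) - oracle), 1.5e-4)  # grid resolution
  }
})

test_that("empirical Bayes shrinks to zero as omega vanishes and at perfect data", {
  m <- det_model()
  m$sigma_add <- 5
  co <- generate_cohort(cohort_spec(n_subjects = 6, seed = 41))
  # simulate without noise: DV equals the typical trough exactly
  ds <- simulate_tdm(co, det_model(), troughs_per_subject = 2, seed = 42)
  m2 <- m
  m2$omega_cl <- 0.4
  expect_equal(unname(empirical_bayes(ds, m2)), rep(0, 6), tolerance = 1e-6)
  # noisy data, prior domination
  dsn <- sim_dataset(n = 6, seed = 43)
  m3 <- final_model
  m3$omega_cl <- 1e-5
  expect_equal(unname(empirical_bayes(dsn, m3)), rep(0, 6), tolerance = 1e-4)
})

test_that("fit reports SE%, fixed flags and a Table-style parameter layout", {
  ds <- sim_dataset(n = 40, seed = 47, spec_args = list(zop_prevalence = 0.3))
  ft <- fit_ppk(ds, final_model)
  tab <- fit_table(ft)
  expect_setequal(tab$parameter,
                  c("cl_pop", "v_pop", "theta_ZOP", "omega_cl",
                    "sigma_prop", "sigma_add", "ka"))
  expect_true(tab$fixed[tab$parameter == "ka"])
  expect_true(all(is.finite(tab$se_pct[!tab$fixed])))
  expect_true(is.finite(ft$ofv))
})
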