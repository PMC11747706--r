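# Closed-form one-compartment kinetics against independent oracles.

ode_conc <- function(cl, v, ka, dose, times) {
  # two-state absorption/central system integrated tightly
  rhs <- function(t, y, parms) {
    list(c(-ka * y[1], ka * y[1] - (cl / v) * y[2]))
  }
  out <- deSolve::lsoda(c(gut = dose, central = 0), c(0, times), rhs,
                        parms = NULL, rtol = 1e-11, atol = 1e-12)
  1000 * out[-1, "central"] / v
}

test_that("single-dose concentration matches a numerical ODE oracle", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(cl = c(10, 74), v = c(400, 874), ka = c(0.1, 0.5, 2))
  for (i in seq_len(nrow(grid))) {
    p <- structural_params(grid$cl[i], grid$v[i], grid$ka[i])
    times <- c(1, 6, 24, 72)
    expect_equal(conc_single_dose(p, 100, times),
                 unname(ode_conc(grid$cl[i], grid$v[i], grid$ka[i], 100,
                                 times)),
                 tolerance = 1e-6)
  }
  # the paper-typical subject at 24 h
  p <- structural_params(74, 874, 0.5)
  expect_equal(conc_single_dose(p, 100, 24),
               unname(ode_conc(74, 874, 0.5, 100, 24)), tolerance = 1e-6)
})

test_that("single-dose profile is continuous across the ka = ke degeneracy", {
  skip_if_not_installed("deSolve")
  cl <- 50; v <- 500; ke <- cl / v
  for (ka in ke * (1 + c(-1e-8, 0, 1e-8, 1e-5))) {
    p <- structural_params(cl, v, ka)
    expect_equal(conc_single_dose(p, 80, c(2, 12, 30)),
                 unname(ode_conc(cl, v, ka, 80, c(2, 12, 30))),
                 tolerance = 1e-6)
  }
})

test_that("no drug at t = 0 and the AUC identity dose/cl holds", {
  p <- structural_params(30, 600, 0.7)
  expect_identical(conc_single_dose(p, 150, 0), 0)
  auc <- stats::integrate(function(t) conc_single_dose(p, 150, t), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(auc, 1000 * 150 / 30, tolerance = 1e-6)  # ng/mL * h
})

test_that("steady state matches brute-force superposition of single doses", {
  cases <- list(
    list(p = structural_params(33.52, 874, 0.5), r = regimen(70, 24)),
    list(p = structural_params(74, 874, 0.5), r = regimen(105, 12)),
    list(p = structural_params(10, 200, 1.5), r = regimen(50, 24)))
  for (cs in cases) {
    expect_equal(trough_steady_state(cs$p, cs$r),
                 superposition_trough(cs$p, cs$r), tolerance = 1e-6)
    # mid-interval point: shift the superposition by tau/2
    tmid <- cs$r$tau_h / 2
    brute <- sum(conc_single_dose(cs$p, cs$r$dose_mg,
                                  tmid + cs$r$tau_h * (0:400)))
    expect_equal(conc_steady_state(cs$p, cs$r, tmid), brute,
                 tolerance = 1e-6)
  }
})

test_that("steady state reduces to the single dose for very long intervals", {
  p <- structural_params(74, 874, 0.5)
  r <- regimen(100, 1e6)
  expect_equal(conc_steady_state(p, r, 24), conc_single_dose(p, 100, 24),
               tolerance = 1e-9)
})

test_that("mean steady-state concentration equals dose/(cl tau)", {
  p <- structural_params(40, 900, 0.5)
  r <- regimen(120, 12)
  avg <- stats::integrate(function(t) conc_steady_state(p, r, t), 0, 12,
                          rel.tol = 1e-10)$value / 12
  expect_equal(avg, 1000 * 120 / (40 * 12), tolerance = 1e-8)
})

test_that("kinetics are dose-linear and accumulation is non-negative", {
  p <- structural_params(25, 400, 0.8)
  r1 <- regimen(50, 24); r3 <- regimen(150, 24)
  expect_equal(3 * trough_steady_state(p, r1), trough_steady_state(p, r3))
  expect_equal(3 * conc_single_dose(p, 50, 7), conc_single_dose(p, 150, 7))
  expect_identical(trough_steady_state(p, regimen(0, 24)), 0)
  tgrid <- seq(0, 24, by = 3)
  expect_true(all(conc_steady_state(p, r1, tgrid) >=
                    conc_single_dose(p, 50, tgrid)))
})

test_that("steady-state trough decreases strictly with clearance", {
  cls <- seq(10, 150, by = 10)
  troughs <- vapply(cls, function(cl) {
    trough_steady_state(structural_params(cl, 874, 0.5), regimen(100, 24))
  }, 0)
  expect_true(all(diff(troughs) < 0))
})

test_that("steady-state profile is periodic: conc at 0 equals the trough", {
  p <- structural_params(74, 874, 0.5)
  r <- regimen(100, 24)
  expect_equal(conc_steady_state(p, r, 0), trough_steady_state(p, r),
               tolerance = 1e-12)
})

test_that("invalid kinetic inputs are rejected", {
  expect_error(structural_params(-1, 874, 0.5), "positive")
  expect_error(structural_params(74, 874, Inf), "finite")
  p <- structural_params(74, 874, 0.5)
  expect_error(conc_single_dose(p, 100, -1), ">= 0")
  expect_error(conc_single_dose(p, NA_real_, 1), "finite")
  expect_error(conc_steady_state(p, regimen(100, 24), 25), "within")
  expect_error(regimen(100, 0), "> 0")
})
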