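# Monte Carlo probability of target attainment and dose recommendation.

test_that("degenerate windows and doses give certain outcomes", {
  m <- final_model
  sc_all <- pta_scenario(zop = 0, interval = 24, window = c(0, Inf),
                         n_virtual = 500, seed = 1)
  expect_equal(as.numeric(simulate_pta(m, sc_all, 50, 2)), 1)
  sc <- pta_scenario(zop = 0, interval = 24, n_virtual = 500, seed = 1)
  expect_equal(as.numeric(simulate_pta(m, sc, 50, 0)), 0)
})

test_that("PTA carries its binomial Monte Carlo standard error", {
  sc <- pta_scenario(zop = 1, interval = 24, n_virtual = 2000, seed = 3)
  p <- simulate_pta(final_model, sc, 70, 1)
  expect_equal(attr(p, "mc_se"), sqrt(as.numeric(p) * (1 - as.numeric(p)) / 2000))
  expect_identical(attr(p, "n"), 2000L)
})

test_that("the grid is reproducible cell by cell from the scenario seed", {
  sc <- pta_scenario(zop = 1, interval = 24, weights = c(40, 70),
                     doses = c(1, 3), n_virtual = 400, seed = 11)
  g1 <- pta_grid(final_model, sc)
  g2 <- pta_grid(final_model, sc)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 4L)
  # a one-cell grid equals simulate_pta under the derived cell seed
  sc1 <- pta_scenario(zop = 1, interval = 24, weights = 70, doses = 1,
                      n_virtual = 400, seed = 11)
  g <- pta_grid(final_model, sc1)
  expect_equal(g$pta,
               as.numeric(simulate_pta(final_model, sc1, 70, 1,
                                       seed = sertmipd:::derive_seed(11, 1))))
})

test_that("jointly scaling dose, clearance and volume leaves the PTA invariant", {
  # concentration depends on (dose/V, ka, ke); scaling dose, CL and V by
  # the same factor changes none of them
  k <- 1 / 0.453
  m2 <- final_model
  m2$cl_pop <- k * m2$cl_pop
  m2$v_pop <- k * m2$v_pop
  for (interval in c(24, 12)) {
    sc <- pta_scenario(zop = 0, interval = interval, n_virtual = 800,
                       seed = 13)
    for (w in c(30, 80)) {
      p1 <- as.numeric(simulate_pta(final_model, sc, w, 1.0))
      p2 <- as.numeric(simulate_pta(m2, sc, w, 1.0 * k))
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  }
})

test_that("PTA is unimodal or plateaued in dose: undershoot low, overshoot high", {
  sc <- pta_scenario(zop = 0, interval = 24, n_virtual = 4000, seed = 17)
  g <- pta_grid(final_model, sc)
  for (w in sc$weights) {
    p <- g$pta[g$weight == w][order(g$dose_per_kg_day[g$weight == w])]
    i <- which.max(p)
    tol <- 0.025   # Monte Carlo wiggle at n = 4000
    if (i > 1) expect_true(all(diff(p[1:i]) > -tol))
    if (i < length(p)) expect_true(all(diff(p[i:length(p)]) < tol))
  }
})

test_that("residual error on the observed scale lowers attainment near the window edges", {
  sc0 <- pta_scenario(zop = 1, interval = 24, n_virtual = 5000, seed = 19,
                      include_residual = FALSE)
  sc1 <- pta_scenario(zop = 1, interval = 24, n_virtual = 5000, seed = 19,
                      include_residual = TRUE)
  p0 <- as.numeric(simulate_pta(final_model, sc0, 70, 1))
  p1 <- as.numeric(simulate_pta(final_model, sc1, 70, 1))
  expect_gt(p0, p1)
})

test_that("recommendation picks the band argmax with ties to the lower dose", {
  tab <- data.frame(zop = 0, interval = 24,
                    weight = rep(c(30, 40), each = 3),
                    dose_per_kg_day = rep(c(1, 2, 3), 2),
                    pta = c(0.5, 0.8, 0.7, 0.6, 0.8, 0.75),
                    mc_se = 0.01, n = 1000)
  class(tab) <- c("pta_table", "data.frame")
  rec <- recommend_dose(tab, bands = list(c(30, 40)))
  expect_equal(rec$dose_per_kg_day, 2)
  expect_equal(rec$pta_min, 0.8)
  # single weight, single dose
  one <- tab[tab$weight == 30 & tab$dose_per_kg_day == 1, ]
  class(one) <- c("pta_table", "data.frame")
  expect_equal(recommend_dose(one, list(c(25, 35)))$dose_per_kg_day, 1)
  # exact tie between doses 2 and 3 at a single weight goes to dose 2
  tie <- tab[tab$weight == 30, ]
  tie$pta <- c(0.1, 0.9, 0.9)
  class(tie) <- c("pta_table", "data.frame")
  expect_equal(recommend_dose(tie, list(c(30, 30)))$dose_per_kg_day, 2)
  expect_error(recommend_dose(tab, list(c(90, 100))), "no grid weight")
})

test_that("min-statistic recommendation uses the worst weight in the band", {
  tab <- data.frame(zop = 0, interval = 24,
                    weight = rep(c(30, 40), each = 2),
                    dose_per_kg_day = rep(c(1, 2), 2),
                    pta = c(0.9, 0.6, 0.5, 0.58),
                    mc_se = 0.01, n = 1000)
  class(tab) <- c("pta_table", "data.frame")
  # mean rule: dose 1 (0.70 vs 0.59); min rule: dose 2 (0.58 vs 0.50)
  expect_equal(recommend_dose(tab, list(c(30, 40)))$dose_per_kg_day, 1)
  expect_equal(recommend_dose(tab, list(c(30, 40)),
                              statistic = "min")$dose_per_kg_day, 2)
})
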