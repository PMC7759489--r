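test_that("individual simulation honors the log-normal IIV model", {
  # no IIV: every individual equals the typical subject
  ind0 <- simulate_individuals(2, 8, 0, 0, 50, seed = 1)
  expect_equal(ind0$c50, rep(2, 50))
  expect_equal(ind0$gamma, rep(8, 50))
  # same seed, same draws
  a <- simulate_individuals(1, 5, 0.1, 0.2, 100, seed = 9)
  b <- simulate_individuals(1, 5, 0.1, 0.2, 100, seed = 9)
  expect_identical(a, b)
  # log-scale sample variance matches the omega within 5% at n = 10,000
  ind <- simulate_individuals(1, 5, 0.1, 0.2, 10000, seed = 42)
  expect_equal(var(log(ind$c50)), 0.1, tolerance = 0.05)
  expect_equal(var(log(ind$gamma)), 0.2, tolerance = 0.05)
  expect_equal(median(ind$c50), 1, tolerance = 0.02)
})

test_that("population curve without IIV is the individual Emax curve", {
  cc <- concentration_grid(1, 5)
  ind <- simulate_individuals(1, 5, 0, 0, 3, seed = 1)
  cv <- population_curve(ind, cc)
  expect_equal(cv$p, prob_emax(cc, 1, 5))
})

test_that("dichotomizing the curve only adds binomial noise", {
  n <- 50000
  gs <- gamma_star(5, 0.1, 0)
  cc <- concentration_grid(1, gs$gamma_star)
  ind <- simulate_individuals(1, 5, 0.1, 0, n, seed = 77)
  smooth <- population_curve(ind, cc)
  binom <- population_curve(ind, cc, dichotomize = TRUE, seed = 78)
  expect_lt(max(abs(smooth$p - binom$p)), 3 * sqrt(0.25 / n))
  f1 <- fit_population_curve(smooth)
  f2 <- fit_population_curve(binom)
  expect_equal(f1$steepness, f2$steepness, tolerance = 0.01)
})

test_that("curve fitting recovers exact curves to machine precision", {
  cc <- concentration_grid(1, 5)
  fe <- fit_population_curve(data.frame(conc = cc, p = prob_emax(cc, 1, 5)))
  expect_equal(fe$c50, 1, tolerance = 1e-6)
  expect_equal(fe$steepness, 5, tolerance = 1e-6)
  expect_lt(fe$sse, 1e-12)
  expect_true(fe$converged)
  fl <- fit_population_curve(
    data.frame(conc = cc, p = prob_lognormal(cc, 2, 0.4)), "lognormal")
  expect_equal(fl$c50, 2, tolerance = 1e-6)
  expect_equal(fl$steepness, 0.4, tolerance = 1e-6)
  expect_error(fit_population_curve(data.frame(conc = 1:2, p = c(0.2, 0.8))))
})

test_that("calibration grid shows the expected flattening and 1.7 coupling", {
  tab <- run_grid(gamma_grid = c(1, 5, 30), omega_c50_grid = c(0, 0.1),
                  omega_gamma_grid = c(0, 0.1), n_individuals = 3000,
                  seed = 15)
  expect_equal(nrow(tab), 12)
  iiv <- tab$omega_c50 > 0 | tab$omega_gamma > 0
  # population curve is never steeper than the individual curve
  expect_true(all(tab$gamma_mc[iiv] <= tab$gamma[iiv]))
  # Emax and log-normal steepness estimates stay coupled through ~1.7
  expect_true(all(tab$gamma_mc * tab$sigma_mc > 1.6 &
                    tab$gamma_mc * tab$sigma_mc < 1.8))
  # no-IIV cells are recovered essentially exactly
  expect_true(all(abs(tab$pct_diff_gamma[!iiv]) < 0.5))
  expect_true(all(tab$converged))
})

test_that("fitted steepness has no systematic dependence on the MC sample size", {
  one <- function(n) run_grid(gamma_grid = 5, omega_c50_grid = 0.1,
                              omega_gamma_grid = 0, n_individuals = n,
                              seed = 5)$gamma_mc
  expect_equal(one(2000), one(4000), tolerance = 0.01)
})

test_that("rmse_report does plain arithmetic on the percent differences", {
  tab <- data.frame(pct_diff_gamma = c(3, -3))
  r <- rmse_report(tab)
  expect_equal(r$rmse_pct, 3)
  expect_equal(r$min_pct, -3)
  expect_equal(r$max_pct, 3)
  expect_equal(rmse_report(data.frame(pct_diff_gamma = rep(0, 5)))$rmse_pct, 0)
  expect_error(rmse_report(data.frame(x = 1)))
})

test_that("a grid without IIV variation only identifies p1 and p5", {
  expect_warning(
    p <- fit_pi_constants(gamma_grid = c(1, 5, 30), omega_c50_grid = 0,
                          omega_gamma_grid = 0, n_individuals = 2000,
                          seed = 3, max_outer = 1),
    "identifiable")
  expect_equal(unname(p[["p1"]]), 1, tolerance = 0.05)
  expect_equal(unname(p[["p5"]]), 0, tolerance = 0.05)
  expect_equal(unname(p[c("p2", "p3", "p4", "p6", "p7", "p8")]),
               rep(0, 6), ignore_attr = TRUE)
})
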