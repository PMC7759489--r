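test_that("sigmoid Emax probabilities are exact and well-behaved", {
  expect_equal(prob_emax(1, 1, 30), 0.5)
  expect_equal(prob_emax(99^(1/5), 1, 5), 0.99)
  expect_equal(prob_emax(1.1, 1, 30), 1.1^30 / (1 + 1.1^30))
  expect_equal(prob_emax(0, 1, 5), 0)
  # strictly increasing, bounded
  cc <- exp(seq(-5, 5, length.out = 200))
  p <- prob_emax(cc, 2, 7)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(prob_emax(1, -1, 5))
  expect_error(prob_emax(1, 1, 0))
  expect_error(prob_emax(-1, 1, 5))
})

test_that("cumulative log-normal probabilities hit the normal quantiles", {
  expect_equal(prob_lognormal(2, 2, 0.3), 0.5)
  expect_equal(prob_lognormal(2 * exp(0.3), 2, 0.3), pnorm(1))
  expect_equal(prob_lognormal(2 * exp(1.96 * 0.3), 2, 0.3), pnorm(1.96))
  expect_error(prob_lognormal(1, 1, 0))
})

test_that("logistic approximation is antisymmetric and saturates", {
  expect_equal(prob_logistic(0), 0.5)
  expect_equal(prob_logistic(1, 1.7), 1 / (1 + exp(-1.7)))
  expect_equal(prob_logistic(50), 1)
  z <- seq(-4, 4, by = 0.5)
  expect_equal(prob_logistic(z) + prob_logistic(-z), rep(1, length(z)))
})

test_that("gamma and sigma interconvert exactly through 1.7", {
  expect_equal(signif(sigma_from_gamma(30), 3), 0.0567)
  expect_equal(gamma_from_sigma(1), 1.7)
  x <- c(0.05, 0.5, 1.7, 12, 50)
  expect_equal(sigma_from_gamma(gamma_from_sigma(x)), x)
  expect_equal(gamma_from_sigma(x) * x, rep(1.7, length(x)))
  expect_error(sigma_from_gamma(0))
})

test_that("minimax logistic-probit constant is 1.702 with deviation < 0.01", {
  a <- calibrate_logistic_constant()
  expect_equal(signif(as.numeric(a), 4), 1.702)
  expect_lt(attr(a, "max_dev"), 0.01)
  # at the optimum both functions agree exactly at the median
  expect_equal(prob_logistic(0, as.numeric(a)), pnorm(0))
})

test_that("population steepness formula reproduces the reference values", {
  gs <- gamma_star(30, 0.1, 0.1)
  expect_equal(signif(gs$gamma_star, 3), 5.27)
  expect_equal(signif(gs$sigma_star, 3), 0.323)
  expect_equal(signif(gamma_star(5, 0.1, 0)$gamma_star, 3), 3.66)
  expect_equal(signif(sqrt(sigma_star_sq(5, 0.1, 0)), 3), 0.464)
  expect_equal(signif(gamma_star(1, 0.1, 0.1)$gamma_star, 3), 0.959)
})

test_that("without IIV the population steepness equals the individual one", {
  for (g in c(0.5, 1, 5, 30, 50)) {
    gs <- gamma_star(g, 0, 0)
    expect_equal(gs$gamma_star, g)
    expect_equal(gs$sigma_star, 1.7 / g)
    expect_equal(sigma_star_sq(g, 0, 0), (1.7 / g)^2)
  }
})

test_that("gamma* decreases with either IIV variance and never exceeds gamma", {
  om <- c(0, 0.05, 0.1, 0.2, 0.5)
  for (g in c(1, 5, 30)) {
    along_w1 <- gamma_star(g, om, 0)$gamma_star
    along_w2 <- gamma_star(g, 0, om)$gamma_star
    expect_true(all(diff(along_w1) < 0))
    expect_true(all(diff(along_w2) < 0))
    expect_true(all(along_w1 <= g & along_w2 <= g))
    # sigma*^2 monotone nondecreasing in each omega on a 2-d grid
    grid <- expand.grid(w1 = om, w2 = om)
    ss <- sigma_star_sq(g, grid$w1, grid$w2)
    expect_true(all(ss >= (1.7 / g)^2))
  }
})

test_that("concentration grid is log-symmetric with exact endpoint probabilities", {
  gs <- 5.27
  cc <- concentration_grid(2, gs, p_edge = 0.01, n_half = 50)
  expect_length(cc, 101)
  expect_true(all(diff(cc) > 0))
  expect_equal(cc[51], 2)                        # i = 0
  expect_equal(cc * rev(cc), rep(4, 101))        # C_{-i} C_{+i} = c50^2
  expect_equal(prob_emax(cc[1], 2, gs), 0.01, tolerance = 1e-12)
  expect_equal(prob_emax(cc[101], 2, gs), 0.99, tolerance = 1e-12)
  expect_error(concentration_grid(1, 5, p_edge = 0.6))
})

test_that("matched Emax and log-normal population curves differ by < 0.01", {
  d <- max_delta_p(5.27, 0.323)
  expect_lt(as.numeric(d), 0.01)
  # zero difference at C50 and sign changes near P = 0.115 and 0.885
  delta <- attr(d, "delta")
  conc <- attr(d, "conc")
  expect_equal(delta[which.min(abs(conc - 1))], 0, tolerance = 1e-6)
  sgn <- sign(delta[abs(delta) > 1e-10])
  crossings <- which(diff(sgn) != 0)
  p_at <- prob_emax(conc[abs(delta) > 1e-10][crossings], 1, 5.27)
  expect_true(any(abs(p_at - 0.115) < 0.02))
  expect_true(any(abs(p_at - 0.885) < 0.02))
  # probit-logit agreement holds across the steepness range when matched
  for (g in c(0.5, 2, 10, 50))
    expect_lt(as.numeric(max_delta_p(g, 1.7 / g)), 0.01)
})
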