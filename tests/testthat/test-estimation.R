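test_that("pooled Bernoulli likelihood matches hand arithmetic", {
  ds <- data.frame(ID = 1, CONC = rep(2, 4), DV = rep(1, 4), KIND = "binary")
  class(ds) <- c("trial_dataset", "data.frame")
  # P = 0.5 at C = C50, four successes: -4 log(0.5) = 4 log 2
  expect_equal(negloglik_pooled(2, 3, ds), 4 * log(2))
  ds$DV <- c(0, 1, 0, 1)
  expect_equal(negloglik_pooled(2, 3, ds), 4 * log(2))
  ds$DV <- c(0.5, 1, 0, 1)
  expect_error(negloglik_pooled(2, 3, ds), "0 or 1")
})

test_that("pooled binary MLE equals logistic regression on ln C", {
  for (cfg in list(c(1, 0, 0), c(5, 0.1, 0), c(30, 0.1, 0.1))) {
    ds <- simulate_binary_dataset(1, cfg[1], cfg[2], cfg[3],
                                  seed = 100 + cfg[1])
    fit <- fit_naive_pooled(ds)
    orc <- glm_oracle(ds)
    if (orc$gamma < 45) {  # compare only away from the estimation bound
      expect_equal(fit$gamma, orc$gamma, tolerance = 1e-6)
      expect_equal(fit$c50, orc$c50, tolerance = 1e-6)
    }
  }
})

test_that("pooled MLE is consistent on large no-IIV binary data", {
  ds <- simulate_binary_dataset(1, 5, 0, 0, design = trial_design(10000),
                                seed = 55)
  fit <- fit_naive_pooled(ds)
  expect_equal(fit$gamma, 5, tolerance = 0.05)
  expect_equal(fit$c50, 1, tolerance = 0.02)
  expect_true(fit$minimized && fit$covariance_ok)
})

test_that("pooled profile in gamma is unimodal on no-IIV data", {
  ds <- simulate_binary_dataset(1, 5, 0, 0, design = trial_design(200), seed = 9)
  gg <- exp(seq(log(0.5), log(40), length.out = 60))
  prof <- vapply(gg, function(g) negloglik_pooled(1, g, ds), numeric(1))
  # single sign change of the discrete derivative
  expect_equal(sum(diff(sign(diff(prof))) != 0), 1)
})

test_that("estimates are invariant to rescaling the concentration axis", {
  ds <- simulate_binary_dataset(1, 5, 0.1, 0, seed = 12)
  f1 <- fit_naive_pooled(ds)
  ds2 <- ds
  ds2$CONC <- ds2$CONC * 1000
  f2 <- fit_naive_pooled(ds2)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-5)
  expect_equal(f2$c50, f1$c50 * 1000, tolerance = 1e-5)
})

test_that("noiseless continuous data are recovered exactly", {
  ds <- simulate_continuous_dataset(1, 5, 0, 0, noise_sd = 0, seed = 5)
  fit <- fit_naive_pooled(ds)
  expect_equal(fit$gamma, 5, tolerance = 1e-6)
  expect_equal(fit$c50, 1, tolerance = 1e-6)
})

test_that("perfectly separated binary data pin gamma at the upper bound", {
  ds <- data.frame(ID = rep(1:10, each = 4),
                   CONC = rep(c(0.5, 0.8, 1.25, 2), 10),
                   DV = rep(c(0, 0, 1, 1), 10), KIND = "binary")
  class(ds) <- c("trial_dataset", "data.frame")
  fit <- fit_naive_pooled(ds)
  expect_true("gamma_upper" %in% fit$boundary)
  expect_false(fit$covariance_ok)
  expect_equal(fit$gamma, 50, tolerance = 0.01)
})

test_that("Laplace marginal likelihood reduces to pooling as omega -> 0", {
  ds <- simulate_binary_dataset(1, 5, 0.1, 0, design = trial_design(10), seed = 3)
  pooled <- negloglik_pooled(1.1, 4, ds)
  expect_lt(abs(as.numeric(marginal_negloglik_laplace(1.1, 4, 1e-9, 0, ds)) - pooled), 1e-6)
  expect_lt(abs(as.numeric(marginal_negloglik_laplace(1.1, 4, 0, 1e-9, ds)) - pooled), 1e-6)
  expect_equal(as.numeric(marginal_negloglik_laplace(1.1, 4, 0, 0, ds)), pooled)
})

test_that("Laplace agrees with adaptive Gauss-Hermite quadrature on toys", {
  ds <- simulate_binary_dataset(1, 1, 0.1, 0, design = trial_design(3), seed = 7)
  for (om in c(0.05, 0.1, 0.3)) {
    la <- as.numeric(marginal_negloglik_laplace(1, 1, om, 0, ds))
    expect_equal(la, gh_marginal_nll_c50(1, 1, om, ds), tolerance = 1e-3)
  }
  # two-dimensional random effects against a tensor-quadrature oracle
  ds2 <- simulate_binary_dataset(1, 1, 0.1, 0.1, design = trial_design(3), seed = 11)
  la2 <- as.numeric(marginal_negloglik_laplace(1, 1, 0.1, 0.1, ds2))
  expect_equal(la2, gh_marginal_nll_2d(1, 1, 0.1, 0.1, ds2), tolerance = 5e-3)
})

test_that("Laplace likelihood is invariant under subject relabeling", {
  ds <- simulate_binary_dataset(1, 2, 0.1, 0, design = trial_design(6), seed = 21)
  perm <- ds
  perm$ID <- 7 - perm$ID  # reverse the labels
  expect_equal(as.numeric(marginal_negloglik_laplace(1, 2, 0.1, 0, ds)),
               as.numeric(marginal_negloglik_laplace(1, 2, 0.1, 0, perm)))
})

test_that("mixed fit flags vanished variances and rejects continuous data", {
  ds <- simulate_binary_dataset(1, 5, 0, 0, seed = 44)  # no IIV in truth
  fit <- fit_mixed(ds, fit_spec(iiv_c50 = TRUE, iiv_gamma = FALSE))
  expect_lt(fit$omega_c50, 0.02)
  dc <- simulate_continuous_dataset(1, 5, 0.1, 0, seed = 1)
  expect_error(fit_mixed(dc), "binary")
  expect_error(fit_mixed(ds, fit_spec(FALSE, FALSE)), "IIV flag")
})

test_that("mixed fit recovers typical values and IIV on informative data", {
  ds <- simulate_binary_dataset(1, 2, 0.3, 0, design = trial_design(200), seed = 70)
  fit <- fit_mixed(ds, fit_spec(TRUE, FALSE))
  expect_true(fit$minimized)
  expect_equal(fit$gamma, 2, tolerance = 0.3)
  expect_equal(fit$c50, 1, tolerance = 0.15)
  expect_equal(fit$omega_c50, 0.3, tolerance = 0.5)
})
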