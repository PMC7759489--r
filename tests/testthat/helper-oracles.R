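# Independent oracles used to cross-check the package's own implementations.
# These deliberately share no code with the package internals.

# Adaptive Gauss-Hermite marginal negative log-likelihood for a single
# log-normal random effect on C50 (binary data).  Each subject's integrand
# is re-centered at its mode with curvature-matched scaling, then integrated
# with physicists' Gauss-Hermite nodes in log space.
gh_marginal_nll_c50 <- function(c50, gamma, omega, dataset, nodes = 61) {
  q <- pracma::gaussHermite(nodes)
  tot <- 0
  for (s in split(dataset, dataset$ID)) {
    x <- log(s$CONC); y <- s$DV
    ll <- function(eta) {
      l <- gamma * (x - log(c50) - eta)
      sum(y * l - (pmax(l, 0) + log1p(exp(-abs(l)))))
    }
    nh <- function(e) -(ll(e) - e^2 / (2 * omega))
    m <- stats::optimize(nh, c(-10, 10))$minimum
    h <- 1e-4
    curv <- (nh(m + h) - 2 * nh(m) + nh(m - h)) / h^2
    s2 <- 1 / max(curv, 1e-8)
    t <- m + sqrt(2 * s2) * q$x
    lg <- vapply(t, function(e) ll(e) + stats::dnorm(e, 0, sqrt(omega), log = TRUE),
                 numeric(1))
    terms <- log(q$w) + q$x^2 + lg
    M <- max(terms)
    tot <- tot - (0.5 * log(2 * s2) + M + log(sum(exp(terms - M))))
  }
  tot
}

# Tensor-product Gauss-Hermite oracle for random effects on both C50 and
# gamma (binary data), via the substitution eta_k = sqrt(2 omega_k) t_k.
gh_marginal_nll_2d <- function(c50, gamma, omega_c50, omega_gamma, dataset,
                               nodes = 41) {
  q <- pracma::gaussHermite(nodes)
  n1 <- sqrt(2 * omega_c50) * q$x
  n2 <- sqrt(2 * omega_gamma) * q$x
  lw <- log(q$w / sqrt(pi))
  tot <- 0
  for (s in split(dataset, dataset$ID)) {
    x <- log(s$CONC); y <- s$DV
    terms <- outer(seq_along(n1), seq_along(n2), Vectorize(function(i, j) {
      l <- gamma * exp(n2[j]) * (x - log(c50) - n1[i])
      sum(y * l - (pmax(l, 0) + log1p(exp(-abs(l))))) + lw[i] + lw[j]
    }))
    M <- max(terms)
    tot <- tot - (M + log(sum(exp(terms - M))))
  }
  tot
}

# Logistic-regression oracle: the pooled binary sigmoid Emax likelihood is
# exactly a logistic regression of the response on ln C, with slope gamma
# and intercept -gamma ln C50.
glm_oracle <- function(dataset) {
  g <- stats::glm(DV ~ log(CONC), family = stats::binomial, data = dataset,
                  control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  b <- stats::coef(g)
  list(gamma = unname(b[2]), c50 = unname(exp(-b[1] / b[2])))
}
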