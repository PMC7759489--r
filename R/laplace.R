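# Laplace-approximated marginal likelihood for binary sigmoid Emax data with
# log-normal random effects on C50 (eta1) and/or gamma (eta2).
#
# Per subject, with x_j = ln C_j - ln C50, the linear predictor is
#   l_j = gamma * exp(eta2) * (x_j - eta1),   P_j = logit^{-1}(l_j)
# and the joint negative log-density is
#   h(eta) = -sum_j [y_j l_j - log(1 + e^{l_j})]
#            + sum_k eta_k^2 / (2 omega_k) + 1/2 sum_k log(2 pi omega_k).
# The Laplace approximation of -log of the marginal likelihood is
#   h(eta_hat) + 1/2 log det H(eta_hat) - d/2 log(2 pi),
# where eta_hat minimizes h and H is its Hessian.  All first and second
# derivatives below are analytic.

# Split a long-format dataset by subject.  When every subject has the same
# number of observations, matrices are prepared for the vectorized path.
.subject_data <- function(dataset) {
  ids <- dataset$ID
  xs <- split(log(dataset$CONC), ids)
  ys <- split(dataset$DV, ids)
  nobs <- lengths(xs)
  balanced <- length(unique(nobs)) == 1L
  out <- list(x = xs, y = ys, balanced = balanced)
  if (balanced) {
    out$X <- do.call(rbind, xs)
    out$Y <- do.call(rbind, ys)
  }
  out
}

# Vectorized inner Newton for a single random effect on C50 (eta1 only),
# all subjects at once.  h is strictly convex in eta1, so damped Newton
# converges; step halving guards rounding pathologies.
.inner_c50_vec <- function(X, Y, c50, gamma, omega, tol = 1e-8, maxit = 100L) {
  S <- nrow(X)
  eta <- numeric(S)
  hfun <- function(eta) {
    L <- gamma * (X - log(c50) - eta)
    -rowSums(Y * L - log1pexp(L)) + eta^2 / (2 * omega)
  }
  h <- hfun(eta)
  for (it in seq_len(maxit)) {
    L <- gamma * (X - log(c50) - eta)
    P <- stats::plogis(L)
    gr <- gamma * rowSums(Y - P) + eta / omega
    if (max(abs(gr)) < tol) break
    hess <- gamma^2 * rowSums(P * (1 - P)) + 1 / omega
    step <- gr / hess
    repeat {
      eta_new <- eta - step
      h_new <- hfun(eta_new)
      worse <- h_new > h + 1e-12
      if (!any(worse) || max(abs(step)) < 1e-14) break
      step[worse] <- step[worse] / 2
    }
    eta <- eta_new; h <- h_new
  }
  L <- gamma * (X - log(c50) - eta)
  P <- stats::plogis(L)
  hess <- gamma^2 * rowSums(P * (1 - P)) + 1 / omega
  h_full <- h + 0.5 * log(2 * pi * omega)
  list(nll = sum(h_full + 0.5 * log(hess) - 0.5 * log(2 * pi)),
       converged = max(abs(gamma * rowSums(Y - P) + eta / omega)) < 1e-6)
}

# Generic per-subject inner Newton over the active random effects
# (dim 1 or 2), with ridge regularization when the Hessian is not positive
# definite and backtracking on the joint negative log-density.
.inner_generic <- function(x, y, c50, gamma, omega1, omega2, act1, act2,
                           tol = 1e-8, maxit = 100L) {
  d <- act1 + act2
  eta <- numeric(2)  # (eta1, eta2); inactive components stay 0
  hfun <- function(eta) {
    l <- gamma * exp(eta[2]) * (x - log(c50) - eta[1])
    h <- -sum(y * l - log1pexp(l))
    if (act1) h <- h + eta[1]^2 / (2 * omega1)
    if (act2) h <- h + eta[2]^2 / (2 * omega2)
    h
  }
  h <- hfun(eta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g <- gamma * exp(eta[2])
    u <- x - log(c50) - eta[1]
    l <- g * u
    P <- stats::plogis(l)
    r <- y - P
    w <- P * (1 - P)
    gr <- c(if (act1) g * sum(r) + eta[1] / omega1 else 0,
            if (act2) -sum(r * l) + eta[2] / omega2 else 0)
    gr_act <- gr[c(act1, act2)]
    if (max(abs(gr_act)) < tol) { converged <- TRUE; break }
    H11 <- g^2 * sum(w) + if (act1) 1 / omega1 else 0
    H22 <- sum(w * l^2) - sum(r * l) + if (act2) 1 / omega2 else 0
    H12 <- g * sum(r) - g * sum(w * l)
    H <- matrix(c(H11, H12, H12, H22), 2, 2)[c(act1, act2), c(act1, act2),
                                             drop = FALSE]
    ridge <- 0
    repeat {
      Hr <- H + diag(ridge, d)
      ch <- tryCatch(chol(Hr), error = function(e) NULL)
      if (!is.null(ch)) break
      ridge <- if (ridge == 0) 1e-4 else ridge * 10
      if (ridge > 1e8) { ch <- NULL; break }
    }
    if (is.null(ch)) break
    step <- backsolve(ch, forwardsolve(t(ch), gr_act))
    full <- numeric(2); full[c(act1, act2)] <- step
    alpha <- 1
    repeat {
      eta_new <- eta - alpha * full
      h_new <- hfun(eta_new)
      if (h_new <= h + 1e-12 || alpha < 1e-12) break
      alpha <- alpha / 2
    }
    if (h_new > h + 1e-12) break
    eta <- eta_new; h <- h_new
  }
  # curvature at the mode
  g <- gamma * exp(eta[2]); u <- x - log(c50) - eta[1]; l <- g * u
  P <- stats::plogis(l); r <- y - P; w <- P * (1 - P)
  H11 <- g^2 * sum(w) + if (act1) 1 / omega1 else 0
  H22 <- sum(w * l^2) - sum(r * l) + if (act2) 1 / omega2 else 0
  H12 <- g * sum(r) - g * sum(w * l)
  H <- matrix(c(H11, H12, H12, H22), 2, 2)[c(act1, act2), c(act1, act2),
                                           drop = FALSE]
  ldet <- determinant(H, logarithm = TRUE)
  ldet_ok <- ldet$sign > 0
  prior_norm <- 0
  if (act1) prior_norm <- prior_norm + 0.5 * log(2 * pi * omega1)
  if (act2) prior_norm <- prior_norm + 0.5 * log(2 * pi * omega2)
  list(nll = h + prior_norm +
         (if (ldet_ok) 0.5 * as.numeric(ldet$modulus) else 1e6) -
         d / 2 * log(2 * pi),
       converged = converged && ldet_ok)
}

# Internal driver shared by marginal_negloglik_laplace() and fit_mixed().
.laplace_nll <- function(c50, gamma, omega_c50, omega_gamma, sub) {
  act1 <- omega_c50 > 1e-10
  act2 <- omega_gamma > 1e-10
  if (!act1 && !act2) {
    nll <- 0
    for (s in seq_along(sub$x)) {
      l <- gamma * (sub$x[[s]] - log(c50))
      nll <- nll - sum(sub$y[[s]] * l - log1pexp(l))
    }
    return(list(value = nll, all_converged = TRUE))
  }
  if (act1 && !act2 && sub$balanced) {
    r <- .inner_c50_vec(sub$X, sub$Y, c50, gamma, omega_c50)
    return(list(value = r$nll, all_converged = r$converged))
  }
  nll <- 0; ok <- TRUE
  for (s in seq_along(sub$x)) {
    r <- .inner_generic(sub$x[[s]], sub$y[[s]], c50, gamma,
                        omega_c50, omega_gamma, act1, act2)
    nll <- nll + r$nll
    ok <- ok && r$converged
  }
  list(value = nll, all_converged = ok)
}

#' Laplace-approximated marginal negative log-likelihood
#'
#' For binary data with log-normal random effects on C50 and/or gamma, the
#' per-subject marginal likelihood integrates the Bernoulli likelihood over
#' the subject's random effects.  This function approximates each integral
#' by Laplace's method: an inner Newton optimization (analytic gradient and
#' Hessian) locates the mode of the joint log-density, and a second-order
#' expansion around it supplies the Gaussian correction
#' \eqn{\frac12 \log\det H - \frac{d}{2}\log 2\pi}.  As both omegas tend to
#' zero the result converges smoothly to [negloglik_pooled()].
#'
#' @param c50,gamma candidate typical-value parameters.
#' @param omega_c50,omega_gamma candidate random-effect variances; a value
#'   of 0 deactivates that random effect.
#' @param dataset a binary \code{"trial_dataset"}.
#' @return the total marginal negative log-likelihood, with attribute
#'   \code{"all_converged"} reporting whether every subject's inner
#'   optimization converged.
#' @export
marginal_negloglik_laplace <- function(c50, gamma, omega_c50 = 0,
                                       omega_gamma = 0, dataset) {
  check_positive(c50, "c50")
  check_positive(gamma, "gamma")
  check_nonnegative(omega_c50, "omega_c50")
  check_nonnegative(omega_gamma, "omega_gamma")
  if (.dataset_kind(dataset) != "binary")
    stop("the Laplace marginal likelihood is implemented for binary data",
         call. = FALSE)
  r <- .laplace_nll(c50, gamma, omega_c50, omega_gamma,
                    .subject_data(dataset))
  structure(r$value, all_converged = r$all_converged)
}
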