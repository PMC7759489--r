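#' Sigmoid Emax (Hill) probability of drug effect
#'
#' Computes \eqn{P = C^\gamma / (C50^\gamma + C^\gamma)}, the probability (or
#' fraction of maximal effect) at effect-site concentration \eqn{C} for an
#' individual with potency \code{c50} and steepness (Hill coefficient)
#' \code{gamma}.  Internally evaluated as
#' \eqn{\mathrm{logit}^{-1}(\gamma (\ln C - \ln C50))}, which is exact and
#' numerically stable for very steep curves.
#'
#' @param conc effect-site concentration(s), nonnegative. \code{conc = 0}
#'   returns exactly 0 (the limiting value, avoiding the \code{0^gamma}
#'   ambiguity).
#' @param c50 concentration giving \code{P = 0.5}; positive scalar.
#' @param gamma dimensionless steepness; positive scalar.
#' @return vector of probabilities in \code{[0, 1]}.
#' @seealso [prob_lognormal()], [gamma_star()]
#' @examples
#' prob_emax(1, c50 = 1, gamma = 30)       # 0.5 at C = C50
#' prob_emax(99^(1/5), c50 = 1, gamma = 5) # 0.99
#' @export
prob_emax <- function(conc, c50, gamma) {
  check_positive(c50, "c50")
  check_positive(gamma, "gamma")
  if (anyNA(conc) || any(conc < 0)) stop("'conc' must be nonnegative", call. = FALSE)
  stats::plogis(gamma * (log(conc) - log(c50)))
}

#' Cumulative log-normal probability of drug effect
#'
#' Computes \eqn{P = \Phi(z)} with \eqn{z = (\ln C - \ln C50)/\sigma}: the
#' cumulative log-normal concentration-effect relationship, the probit
#' counterpart of the sigmoid Emax model.  \code{sigma} is the dimensionless
#' log-scale SD controlling steepness (small sigma = steep curve).
#'
#' @inheritParams prob_emax
#' @param sigma positive log-scale standard deviation.
#' @return vector of probabilities in \code{[0, 1]}.
#' @export
prob_lognormal <- function(conc, c50, sigma) {
  check_positive(c50, "c50")
  check_positive(sigma, "sigma")
  if (anyNA(conc) || any(conc < 0)) stop("'conc' must be nonnegative", call. = FALSE)
  stats::pnorm((log(conc) - log(c50)) / sigma)
}

#' Logistic approximation to the standard normal CDF
#'
#' \eqn{P = 1 / (1 + e^{-a z})}.  With \eqn{a \approx 1.7} this approximates
#' \eqn{\Phi(z)} to within about 0.01 everywhere, which is what links the
#' sigmoid Emax (logistic in \eqn{\ln C}) and cumulative log-normal (probit in
#' \eqn{\ln C}) models and yields the conversion \eqn{\gamma = 1.7/\sigma}.
#'
#' @param z real-valued quantile(s).
#' @param a positive scaling constant; default 1.7.
#' @return probabilities in \code{(0, 1)}.
#' @export
prob_logistic <- function(z, a = 1.7) {
  check_positive(a, "a")
  stats::plogis(a * z)
}

#' Convert between Emax steepness gamma and log-normal SD sigma
#'
#' The two steepness parameterizations interconvert via
#' \eqn{\gamma = 1.7/\sigma} (and hence \eqn{\sigma = 1.7/\gamma}), using the
#' logistic-probit scaling constant 1.7.  The round trip is an exact identity.
#'
#' @param gamma,sigma positive steepness parameter to convert.
#' @return the converted parameter (positive scalar or vector).
#' @examples
#' sigma_from_gamma(30)   # 0.0567 (3 s.f.)
#' gamma_from_sigma(1.0)  # 1.7
#' @export
sigma_from_gamma <- function(gamma) {
  check_positive(gamma, "gamma")
  1.7 / gamma
}

#' @rdname sigma_from_gamma
#' @export
gamma_from_sigma <- function(sigma) {
  check_positive(sigma, "sigma")
  1.7 / sigma
}

#' Minimax calibration of the logistic-probit constant
#'
#' Finds the constant \code{a} minimizing the maximum absolute difference
#' between the logistic function \eqn{1/(1+e^{-az})} and the standard normal
#' CDF \eqn{\Phi(z)} over \eqn{z \in [-z_max, z_max]}.  A coarse grid over
#' \code{a} brackets the optimum, followed by golden-section refinement.
#' The minimax value is 1.702 (4 s.f.), with a maximum deviation just under
#' 0.01.
#'
#' @param a_range search interval for \code{a}.
#' @param z_max half-width of the z range scanned (the deviation vanishes for
#'   large |z|, so any generous value gives the same optimum).
#' @param n_z number of z grid points on \code{[0, z_max]} (the deviation is
#'   symmetric in z).
#' @return the optimal constant \code{a}, with the achieved maximum absolute
#'   deviation in attribute \code{"max_dev"}.
#' @export
calibrate_logistic_constant <- function(a_range = c(1.5, 1.9), z_max = 10,
                                        n_z = 5001L) {
  z <- seq(0, z_max, length.out = n_z)
  phi <- stats::pnorm(z)
  dev <- function(a) max(abs(stats::plogis(a * z) - phi))
  a_grid <- seq(a_range[1], a_range[2], length.out = 81L)
  d_grid <- vapply(a_grid, dev, numeric(1))
  k <- which.min(d_grid)
  lo <- a_grid[max(1L, k - 1L)]
  hi <- a_grid[min(length(a_grid), k + 1L)]
  opt <- stats::optimize(dev, c(lo, hi), tol = 1e-8)
  structure(opt$minimum, max_dev = opt$objective)
}

#' Constants of the population-variance approximation
#'
#' The population log-scale variance of the concentration-effect relationship
#' is approximated by summing the individual variance and the IIV variances:
#' \deqn{\sigma^{*2} = p_1 \sigma^2/\gamma^{p_5} + p_2 \omega_{C50}/\gamma^{p_6}
#'   + p_3 \omega_\gamma/\gamma^{p_7}
#'   + p_4 \omega_{C50}\omega_\gamma/\gamma^{p_8}}
#' The defaults are the calibrated, rounded values
#' \code{(1, 1, 1.25, 2.5, 0, 0, 2, 1)} obtained from the Monte Carlo
#' procedure in [fit_pi_constants()].
#'
#' @param p1,p2,p3,p4 nonnegative multiplicative constants.
#' @param p5,p6,p7,p8 nonnegative exponents of gamma in the denominators.
#' @return named numeric vector of length 8, class \code{"pi_constants"}.
#' @export
pi_constants <- function(p1 = 1, p2 = 1, p3 = 1.25, p4 = 2.5,
                         p5 = 0, p6 = 0, p7 = 2, p8 = 1) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7, p8 = p8)
  check_nonnegative(p, "p1..p8")
  structure(p, class = "pi_constants")
}

#' Population log-scale variance under inter-individual variability
#'
#' Evaluates the variance-summation approximation (see [pi_constants()]) at
#' individual steepness \code{gamma} (so \eqn{\sigma = 1.7/\gamma}) and IIV
#' variances \code{omega_c50} and \code{omega_gamma} of the log-scale random
#' effects on C50 and gamma.  With both omegas zero it reduces exactly to
#' \eqn{\sigma^2}.
#'
#' @param gamma individual (typical-subject) steepness, positive.
#' @param omega_c50,omega_gamma nonnegative IIV variances (NONMEM "omega"
#'   convention: variances of log-normal random effects).
#' @param constants a [pi_constants()] vector.
#' @return \eqn{\sigma^{*2}}, vectorized over the parameters.
#' @export
sigma_star_sq <- function(gamma, omega_c50 = 0, omega_gamma = 0,
                          constants = pi_constants()) {
  check_positive(gamma, "gamma")
  check_nonnegative(omega_c50, "omega_c50")
  check_nonnegative(omega_gamma, "omega_gamma")
  p <- unclass(constants)
  sig2 <- (1.7 / gamma)^2
  p[["p1"]] * sig2 / gamma^p[["p5"]] +
    p[["p2"]] * omega_c50 / gamma^p[["p6"]] +
    p[["p3"]] * omega_gamma / gamma^p[["p7"]] +
    p[["p4"]] * omega_c50 * omega_gamma / gamma^p[["p8"]]
}

#' Population-predicted steepness gamma* and sigma*
#'
#' Closed-form approximation of the steepness of the population-averaged
#' (marginal) concentration-effect curve.  With the default constants:
#' \deqn{\gamma^* = \frac{1.7}{\sqrt{(1.7/\gamma)^2 + \omega_{C50}
#'   + 1.25\,\omega_\gamma/\gamma^2 + 2.5\,\omega_{C50}\omega_\gamma/\gamma}}}
#' and \eqn{\sigma^* = 1.7/\gamma^*}.  In the absence of IIV,
#' \eqn{\gamma^* = \gamma} and \eqn{\sigma^* = \sigma}; otherwise
#' \eqn{\gamma^* < \gamma}: averaging steep individual curves whose C50s are
#' spread out produces a shallower population curve.
#'
#' @inheritParams sigma_star_sq
#' @return list with components \code{gamma_star} and \code{sigma_star}
#'   (vectors if the inputs are vectors), class \code{"pop_steepness"}.
#' @examples
#' gamma_star(30, 0.1, 0.1)  # gamma* = 5.27, sigma* = 0.323
#' @export
gamma_star <- function(gamma, omega_c50 = 0, omega_gamma = 0,
                       constants = pi_constants()) {
  ss <- sqrt(sigma_star_sq(gamma, omega_c50, omega_gamma, constants))
  structure(list(gamma_star = 1.7 / ss, sigma_star = ss),
            class = "pop_steepness")
}

#' @export
print.pop_steepness <- function(x, digits = 4, ...) {
  cat("Population-predicted steepness\n")
  cat("  gamma*:", signif(x$gamma_star, digits), "\n")
  cat("  sigma*:", signif(x$sigma_star, digits), "\n")
  invisible(x)
}

#' Log-spaced concentration grid covering the informative probability range
#'
#' Builds the \eqn{2 n_{half} + 1} concentrations
#' \eqn{C_i = C50 \exp\{i \ln(1/p - 1) / (n_{half}\, \gamma^*)\}},
#' \eqn{i = -n_{half}, \dots, n_{half}}, equally spaced on the log scale and
#' symmetric about C50.  By construction the population-predicted probability
#' (sigmoid Emax with steepness \code{gamma_star}) equals \code{p_edge} at the
#' first point and \code{1 - p_edge} at the last.
#'
#' @param c50 population C50 (grid center).
#' @param gamma_star population-predicted steepness used to scale the grid.
#' @param p_edge probability at the lowest concentration, in (0, 0.5);
#'   default 0.01 so the grid spans P from 0.01 to 0.99.
#' @param n_half number of points on each side of C50; default 50 (101-point
#'   grid).
#' @return strictly increasing numeric vector of length \code{2*n_half + 1}.
#' @export
concentration_grid <- function(c50, gamma_star, p_edge = 0.01, n_half = 50L) {
  check_positive(c50, "c50")
  check_positive(gamma_star, "gamma_star")
  if (!is.finite(p_edge) || p_edge <= 0 || p_edge >= 0.5)
    stop("'p_edge' must be in (0, 0.5)", call. = FALSE)
  if (n_half < 1L) stop("'n_half' must be a positive integer", call. = FALSE)
  i <- seq.int(-n_half, n_half)
  c50 * exp(i * log(1 / p_edge - 1) / (n_half * gamma_star))
}

#' Maximum discrepancy between the Emax and log-normal population curves
#'
#' Evaluates \eqn{|P_{Emax}(C; C50, \gamma^*) - \Phi((\ln C - \ln C50)/\sigma^*)|}
#' on a dense log-spaced concentration grid spanning Emax probabilities from
#' 0.001 to 0.999 and returns the maximum.  For matched steepness
#' (\eqn{\gamma^* \sigma^* = 1.7}) the two curves agree within about 0.01
#' over the whole scale, with the signed difference vanishing at P = 0.5 and
#' near P = 0.115 and 0.885.
#'
#' @param gamma_star Emax-scale population steepness.
#' @param sigma_star log-normal-scale population steepness.
#' @param c50 shared C50 (default 1; the result is scale-invariant).
#' @param n_points number of grid points (default 2001, dense enough that the
#'   maximum is grid-insensitive to < 1e-4).
#' @return the maximum absolute difference, with the evaluation grid and the
#'   signed differences in attributes \code{"conc"} and \code{"delta"}.
#' @export
max_delta_p <- function(gamma_star, sigma_star, c50 = 1, n_points = 2001L) {
  check_positive(gamma_star, "gamma_star")
  check_positive(sigma_star, "sigma_star")
  check_positive(c50, "c50")
  lq <- stats::qlogis(c(0.001, 0.999)) / gamma_star
  conc <- c50 * exp(seq(lq[1], lq[2], length.out = n_points))
  delta <- prob_emax(conc, c50, gamma_star) - prob_lognormal(conc, c50, sigma_star)
  structure(max(abs(delta)), conc = conc, delta = delta)
}
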