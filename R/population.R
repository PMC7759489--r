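#' Simulate individual parameter sets with log-normal IIV
#'
#' Draws \code{n} individuals around the typical values:
#' \code{c50_i = c50 * exp(eta1)}, \code{gamma_i = gamma * exp(eta2)} with
#' \code{eta1 ~ N(0, omega_c50)} and \code{eta2 ~ N(0, omega_gamma)}
#' (omegas are variances of the log-scale random effects).
#'
#' @inheritParams sigma_star_sq
#' @param c50 typical (population median) C50.
#' @param n number of individuals.
#' @param seed integer seed; the same seed always reproduces the same draws.
#' @return data frame with columns \code{c50} and \code{gamma}, one row per
#'   individual.
#' @export
simulate_individuals <- function(c50, gamma, omega_c50 = 0, omega_gamma = 0,
                                 n, seed) {
  check_positive(c50, "c50")
  check_positive(gamma, "gamma")
  check_nonnegative(omega_c50, "omega_c50")
  check_nonnegative(omega_gamma, "omega_gamma")
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  set.seed(seed)
  eta1 <- stats::rnorm(n, 0, sqrt(omega_c50))
  eta2 <- stats::rnorm(n, 0, sqrt(omega_gamma))
  data.frame(c50 = c50 * exp(eta1), gamma = gamma * exp(eta2))
}

#' Population-averaged probability curve
#'
#' For each concentration on the grid, averages the individual sigmoid Emax
#' probabilities over all simulated individuals (the marginal,
#' population-predicted P).  Optionally the individual probabilities are
#' first dichotomized into Bernoulli 0/1 outcomes before averaging; this
#' gives the same curve in expectation with binomial noise added, so it is
#' off by default.
#'
#' @param individuals data frame from [simulate_individuals()].
#' @param conc concentration grid (e.g. from [concentration_grid()]).
#' @param dichotomize draw Bernoulli outcomes instead of averaging
#'   probabilities directly.
#' @param seed seed for the Bernoulli draws (only used when
#'   \code{dichotomize = TRUE}).
#' @return data frame with columns \code{conc} and \code{p}.
#' @export
population_curve <- function(individuals, conc, dichotomize = FALSE,
                             seed = NULL) {
  if (nrow(individuals) == 0L || length(conc) == 0L)
    stop("need at least one individual and one concentration", call. = FALSE)
  if (anyNA(conc) || any(conc < 0)) stop("'conc' must be nonnegative", call. = FALSE)
  # n_ind x n_conc matrix of individual probabilities
  lp <- outer(individuals$gamma, log(conc)) -
    individuals$gamma * log(individuals$c50)
  p_ind <- stats::plogis(lp)
  if (dichotomize) {
    if (!is.null(seed)) set.seed(seed)
    u <- matrix(stats::runif(length(p_ind)), nrow = nrow(p_ind))
    p <- colMeans(p_ind > u)
  } else {
    p <- colMeans(p_ind)
  }
  data.frame(conc = conc, p = p)
}

# Crude starting values for curve fits: linearize the clamped probabilities
# with the appropriate link and regress on log concentration.
.curve_start <- function(conc, p, model) {
  keep <- p > 1e-4 & p < 1 - 1e-4
  if (sum(keep) < 3L) keep <- rep(TRUE, length(p))
  q <- if (model == "emax") stats::qlogis(clamp_prob(p[keep], 1e-4))
       else stats::qnorm(clamp_prob(p[keep], 1e-4))
  fit <- stats::lm.fit(cbind(1, log(conc[keep])), q)
  b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
  if (!is.finite(b1) || b1 <= 0)
    return(c(c50 = exp(mean(log(conc))), steep = 1))
  steep <- if (model == "emax") b1 else 1 / b1
  c(c50 = unname(exp(-b0 / b1)), steep = unname(steep))
}

#' Least-squares fit of a steepness model to a population curve
#'
#' Fits either the sigmoid Emax model (parameters C50 and gamma) or the
#' cumulative log-normal model (parameters C50 and sigma) to a
#' population-averaged probability curve by minimizing the unweighted sum of
#' squared differences over all grid points.  The optimization runs on
#' \code{(log c50, log steepness)} for positivity, with a multistart over
#' 0.5x / 1x / 2x the link-regression starting steepness to avoid local
#' minima on very steep curves.
#'
#' @param curve data frame with columns \code{conc} and \code{p} (from
#'   [population_curve()]).
#' @param model \code{"emax"} (steepness = gamma) or \code{"lognormal"}
#'   (steepness = sigma).
#' @return list with components \code{c50}, \code{steepness}, \code{sse},
#'   \code{model} and \code{converged}, class \code{"curve_fit"}.
#' @export
fit_population_curve <- function(curve, model = c("emax", "lognormal")) {
  model <- match.arg(model)
  conc <- curve$conc; p <- curve$p
  if (length(conc) < 3L)
    stop("curve must have at least 3 points", call. = FALSE)
  lc <- log(conc)
  pred <- if (model == "emax")
    function(lc50, th) stats::plogis(th * (lc - lc50))
  else
    function(lc50, th) stats::pnorm((lc - lc50) / th)
  sse <- function(par) {
    if (any(!is.finite(par)) || abs(par[2]) > 30) return(1e10)
    r <- p - pred(par[1], exp(par[2]))
    if (any(!is.finite(r))) return(1e10)
    sum(r * r)
  }
  st <- .curve_start(conc, p, model)
  best <- NULL
  for (f in c(0.5, 1, 2)) {
    par0 <- c(log(st["c50"]), log(st["steep"] * f))
    opt <- stats::optim(par0, sse, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  structure(list(c50 = unname(exp(best$par[1])),
                 steepness = unname(exp(best$par[2])),
                 sse = best$value, model = model,
                 converged = best$convergence == 0),
            class = "curve_fit")
}

#' Monte Carlo calibration grid of population steepness
#'
#' Runs the full factorial Monte Carlo experiment: for every combination of
#' typical steepness \code{gamma} and IIV variances, simulate
#' \code{n_individuals} parameter sets, average their Emax probability
#' profiles on the 101-point log-spaced grid scaled by the current
#' closed-form gamma*, and fit both the sigmoid Emax model (giving
#' \code{gamma_mc}) and the cumulative log-normal model (giving
#' \code{sigma_mc}) to the averaged curve.  The defaults reproduce the
#' 9 x 6 x 6 = 324-cell calibration study with 10,000 individuals per cell.
#'
#' @inheritParams sigma_star_sq
#' @param gamma_grid,omega_c50_grid,omega_gamma_grid factorial levels.
#' @param n_individuals individuals simulated per cell.
#' @param c50 typical C50 (arbitrary unit; results are scale-free).
#' @param p_edge,n_half grid specification, see [concentration_grid()].
#' @param dichotomize forwarded to [population_curve()].
#' @param seed master seed; each cell uses an independent substream.
#' @return data frame with one row per cell and columns \code{gamma},
#'   \code{omega_c50}, \code{omega_gamma}, \code{gamma_mc}, \code{sigma_mc},
#'   \code{gamma_star}, \code{sigma_star}, \code{pct_diff_gamma},
#'   \code{pct_diff_sigma}, \code{converged}, where
#'   \code{pct_diff_gamma = 100 (gamma* - gamma_mc)/gamma_mc} (and the sigma
#'   analogue).
#' @export
run_grid <- function(gamma_grid = c(0.5, 1, 2, 3, 5, 10, 20, 30, 50),
                     omega_c50_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                     omega_gamma_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                     n_individuals = 10000L, c50 = 1,
                     constants = pi_constants(),
                     p_edge = 0.01, n_half = 50L,
                     dichotomize = FALSE, seed = 1L) {
  cells <- expand.grid(omega_gamma = omega_gamma_grid,
                       omega_c50 = omega_c50_grid,
                       gamma = gamma_grid)[, 3:1]
  n_cell <- nrow(cells)
  out <- vector("list", n_cell)
  for (i in seq_len(n_cell)) {
    g <- cells$gamma[i]; w1 <- cells$omega_c50[i]; w2 <- cells$omega_gamma[i]
    ps <- gamma_star(g, w1, w2, constants)
    conc <- concentration_grid(c50, ps$gamma_star, p_edge, n_half)
    cell_seed <- derive_seed(seed, i)
    ind <- simulate_individuals(c50, g, w1, w2, n_individuals, cell_seed)
    curve <- population_curve(ind, conc, dichotomize,
                              seed = derive_seed(cell_seed, 1L))
    fe <- fit_population_curve(curve, "emax")
    fl <- fit_population_curve(curve, "lognormal")
    out[[i]] <- data.frame(
      gamma = g, omega_c50 = w1, omega_gamma = w2,
      gamma_mc = fe$steepness, sigma_mc = fl$steepness,
      gamma_star = ps$gamma_star, sigma_star = ps$sigma_star,
      pct_diff_gamma = 100 * (ps$gamma_star - fe$steepness) / fe$steepness,
      pct_diff_sigma = 100 * (ps$sigma_star - fl$steepness) / fl$steepness,
      converged = fe$converged && fl$converged)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Accuracy summary of the closed-form steepness prediction
#'
#' Root-mean-squared error and range of the percent differences between the
#' closed-form gamma* and the Monte Carlo fitted gamma_mc across a
#' calibration grid (see [run_grid()]).
#'
#' @param grid_results data frame from [run_grid()].
#' @param column which percent-difference column to summarize.
#' @return list with \code{rmse_pct}, \code{min_pct} and \code{max_pct}.
#' @export
rmse_report <- function(grid_results, column = "pct_diff_gamma") {
  pct <- grid_results[[column]]
  if (is.null(pct) || length(pct) == 0L)
    stop("no percent-difference column found", call. = FALSE)
  list(rmse_pct = sqrt(mean(pct^2)), min_pct = min(pct), max_pct = max(pct))
}

# Sum-of-squares objective for the p constants on the log gamma* scale.
.pi_objective <- function(p, tab) {
  g <- tab$gamma
  ss <- p[1] * (1.7 / g)^2 / g^p[5] +
    p[2] * tab$omega_c50 / g^p[6] +
    p[3] * tab$omega_gamma / g^p[7] +
    p[4] * tab$omega_c50 * tab$omega_gamma / g^p[8]
  if (any(ss <= 0) || any(!is.finite(ss))) return(1e10)
  sum((log(1.7 / sqrt(ss)) - log(tab$gamma_mc))^2)
}

# One pass of the stepwise-then-joint estimation of the eight constants from
# a fitted calibration table.
.fit_pi_to_table <- function(tab, start = pi_constants()) {
  p <- as.numeric(start)
  fit_subset <- function(free, rows, p) {
    obj <- function(x) { p[free] <- x; .pi_objective(p, tab[rows, ]) }
    opt <- stats::optim(p[free], obj, method = "L-BFGS-B",
                        lower = rep(0, length(free)),
                        upper = rep(20, length(free)),
                        control = list(maxit = 500))
    p[free] <- opt$par
    p
  }
  no_w1 <- tab$omega_c50 == 0
  no_w2 <- tab$omega_gamma == 0
  if (all(no_w1) && all(no_w2)) {
    warning("calibration grid has no IIV variation: only p1 and p5 are ",
            "identifiable; p2..p4 and p6..p8 fixed at 0")
    p[2:4] <- 0; p[6:8] <- 0
    p <- fit_subset(c(1L, 5L), no_w1 & no_w2, p)
    return(do.call(pi_constants, as.list(p)))
  }
  # stepwise initialization: (p1,p5) from the no-IIV cells, (p2,p6) adding
  # IIV in C50, (p3,p7) adding IIV in gamma, (p4,p8) from the full grid
  p <- fit_subset(c(1L, 5L), no_w1 & no_w2, p)
  if (any(!no_w1)) p <- fit_subset(c(2L, 6L), no_w2, p)
  if (any(!no_w2)) p <- fit_subset(c(3L, 7L), no_w1, p)
  if (any(!no_w1 & !no_w2)) p <- fit_subset(c(4L, 8L), rep(TRUE, nrow(tab)), p)
  # joint refinement of all eight constants on the full grid
  p <- fit_subset(1:8, rep(TRUE, nrow(tab)), p)
  do.call(pi_constants, as.list(p))
}

#' Estimate the population-variance constants by Monte Carlo calibration
#'
#' Estimates the eight constants of the variance-summation approximation
#' (see [pi_constants()]) by minimizing the sum of squared differences
#' between log gamma* predicted by the formula and log gamma_mc fitted to
#' Monte Carlo population curves.  Because the concentration grids used in
#' the simulation themselves depend on gamma* (hence on the constants), the
#' procedure alternates: fit the constants to the current calibration table,
#' regenerate the table with grids scaled by the updated constants, and
#' repeat until every constant changes by less than \code{tol} (relative).
#' Within each pass the constants are initialized stepwise -- (p1, p5) from
#' the no-IIV cells, (p2, p6) adding IIV in C50, (p3, p7) adding IIV in
#' gamma, (p4, p8) from the full grid -- before a joint refit of all eight.
#'
#' @inheritParams run_grid
#' @param init starting constants for the first grid generation.
#' @param grid_results optional precomputed [run_grid()] table consistent
#'   with \code{init}, used for the first pass instead of simulating.
#' @param tol relative convergence tolerance on the constants (0.001 = 0.1%).
#' @param max_outer maximum number of grid regenerations.
#' @return a [pi_constants()] vector with attributes \code{"iterations"},
#'   \code{"converged"} and \code{"objective"} (joint SSE on the last table).
#' @export
fit_pi_constants <- function(gamma_grid = c(0.5, 1, 2, 3, 5, 10, 20, 30, 50),
                             omega_c50_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                             omega_gamma_grid = c(0, 0.05, 0.1, 0.2, 0.3, 0.5),
                             n_individuals = 10000L, seed = 1L,
                             init = pi_constants(), grid_results = NULL,
                             tol = 0.001, max_outer = 5L) {
  constants <- init
  converged <- FALSE
  it <- 0L
  tab <- NULL
  while (it < max_outer) {
    it <- it + 1L
    tab <- if (it == 1L && !is.null(grid_results)) grid_results
    else run_grid(gamma_grid, omega_c50_grid, omega_gamma_grid,
                  n_individuals = n_individuals, constants = constants,
                  seed = seed)
    new <- .fit_pi_to_table(tab, constants)
    delta <- abs(as.numeric(new) - as.numeric(constants))
    rel_ok <- all(delta <= tol * abs(as.numeric(constants)) + 1e-4)
    constants <- new
    if (rel_ok) { converged <- TRUE; break }
  }
  attr(constants, "iterations") <- it
  attr(constants, "converged") <- converged
  attr(constants, "objective") <- .pi_objective(as.numeric(constants), tab)
  constants
}
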