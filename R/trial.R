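#' Trial design: subjects and target population probabilities
#'
#' A fixed design in which every subject is observed once at each of a small
#' number of drug levels, the levels being placed where the
#' population-predicted probability of effect equals given targets.  The
#' defaults (40 subjects, targets 0.10, 0.25, 0.75, 0.90) cover the
#' informative part of the concentration-effect profile with comparable
#' information density across parameter combinations.
#'
#' @param n_subjects number of individuals per simulated trial.
#' @param p_targets strictly increasing population probabilities in (0, 1);
#'   one observation per subject at each.
#' @return list with class \code{"trial_design"}.
#' @export
trial_design <- function(n_subjects = 40L,
                         p_targets = c(0.10, 0.25, 0.75, 0.90)) {
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (anyNA(p_targets) || any(p_targets <= 0) || any(p_targets >= 1) ||
      is.unsorted(p_targets, strictly = TRUE))
    stop("'p_targets' must be strictly increasing, each in (0, 1)",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), p_targets = p_targets),
            class = "trial_design")
}

#' Concentrations attaining target population probabilities
#'
#' Inverts the sigmoid Emax model at the population steepness:
#' \eqn{C = C50 (P/(1-P))^{1/\gamma^*}}, so that the population-predicted
#' probability of effect at each returned concentration equals the
#' corresponding target exactly.
#'
#' @param c50 population C50.
#' @param gamma_star population-predicted steepness (see [gamma_star()]).
#' @param p_targets probabilities in (0, 1).
#' @return concentrations, one per target.
#' @export
design_concentrations <- function(c50, gamma_star, p_targets) {
  check_positive(c50, "c50")
  check_positive(gamma_star, "gamma_star")
  if (anyNA(p_targets) || any(p_targets <= 0) || any(p_targets >= 1))
    stop("'p_targets' must be in (0, 1)", call. = FALSE)
  c50 * exp(stats::qlogis(p_targets) / gamma_star)
}

# Shared generator for binary and continuous trials.  Individual parameters
# are drawn once per subject and shared across that subject's observations;
# each subject uses an RNG substream derived from (seed, subject id), so the
# dataset is stable under subject reordering.
.simulate_trial <- function(c50, gamma, omega_c50, omega_gamma, design,
                            constants, seed, kind, noise_sd = 0.1) {
  stopifnot(inherits(design, "trial_design"))
  gs <- gamma_star(gamma, omega_c50, omega_gamma, constants)
  conc <- design_concentrations(c50, gs$gamma_star, design$p_targets)
  n_obs <- length(conc)
  n <- design$n_subjects
  lc <- log(conc)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    set.seed(derive_seed(seed, s))
    eta1 <- stats::rnorm(1, 0, sqrt(omega_c50))
    eta2 <- stats::rnorm(1, 0, sqrt(omega_gamma))
    p_i <- stats::plogis(gamma * exp(eta2) * (lc - log(c50) - eta1))
    dv <- if (kind == "binary") as.numeric(p_i > stats::runif(n_obs))
          else p_i + stats::rnorm(n_obs, 0, noise_sd)
    rows[[s]] <- data.frame(ID = s, CONC = conc, DV = dv, KIND = kind)
  }
  ds <- do.call(rbind, rows)
  attr(ds, "truth") <- list(c50 = c50, gamma = gamma, omega_c50 = omega_c50,
                            omega_gamma = omega_gamma,
                            gamma_star = gs$gamma_star,
                            sigma_star = gs$sigma_star,
                            noise_sd = if (kind == "continuous") noise_sd else NULL)
  attr(ds, "seed") <- seed
  class(ds) <- c("trial_dataset", "data.frame")
  ds
}

#' Simulate a binary (quantal) concentration-response trial
#'
#' Each subject gets individual parameters \code{c50_i = c50 exp(eta1)},
#' \code{gamma_i = gamma exp(eta2)} (log-normal IIV, drawn once per subject),
#' the individual probability of effect is computed at each design
#' concentration from the sigmoid Emax model, and the observed response is a
#' Bernoulli draw: effect present (1) if the probability exceeds a uniform
#' random number, absent (0) otherwise.  Design concentrations are placed at
#' the population targets using gamma*, mirroring how such trials are
#' designed around population behavior.
#'
#' @inheritParams sigma_star_sq
#' @param c50 typical C50.
#' @param design a [trial_design()].
#' @param seed integer seed (per-subject substreams are derived from it).
#' @return long-format data frame (class \code{"trial_dataset"}) with columns
#'   \code{ID}, \code{CONC}, \code{DV}, \code{KIND}; the generating
#'   parameters are kept in attribute \code{"truth"}.
#' @export
simulate_binary_dataset <- function(c50 = 1, gamma, omega_c50 = 0,
                                    omega_gamma = 0,
                                    design = trial_design(),
                                    constants = pi_constants(), seed) {
  .simulate_trial(c50, gamma, omega_c50, omega_gamma, design, constants,
                  seed, "binary")
}

#' Simulate a continuous concentration-response trial
#'
#' As [simulate_binary_dataset()], but instead of dichotomizing, additive
#' Gaussian measurement noise (default SD 0.1, i.e. 10% of the 0-1 response
#' scale) is added to the individual probability.  Responses are deliberately
#' not truncated to \code{[0, 1]}, keeping the error model exactly Gaussian
#' so that least squares is the maximum-likelihood analog.
#'
#' @inheritParams simulate_binary_dataset
#' @param noise_sd residual standard deviation (>= 0).
#' @return a \code{"trial_dataset"} data frame with \code{KIND =
#'   "continuous"}.
#' @export
simulate_continuous_dataset <- function(c50 = 1, gamma, omega_c50 = 0,
                                        omega_gamma = 0,
                                        design = trial_design(),
                                        noise_sd = 0.1,
                                        constants = pi_constants(), seed) {
  check_nonnegative(noise_sd, "noise_sd")
  .simulate_trial(c50, gamma, omega_c50, omega_gamma, design, constants,
                  seed, "continuous", noise_sd)
}

.dataset_kind <- function(dataset) {
  k <- unique(as.character(dataset$KIND))
  if (length(k) != 1L || !k %in% c("binary", "continuous"))
    stop("dataset must have a single KIND, 'binary' or 'continuous'",
         call. = FALSE)
  k
}

#' Read and write trial datasets as flat CSV
#'
#' Long-format, NONMEM-like flat file with header \code{ID,CONC,DV,KIND} and
#' one row per observation.
#'
#' @param dataset a \code{"trial_dataset"} (or compatible) data frame.
#' @param path file path.
#' @return \code{read_trial_csv} returns a \code{"trial_dataset"} data
#'   frame; \code{write_trial_csv} returns \code{path} invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  utils::write.csv(dataset[, c("ID", "CONC", "DV", "KIND")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "CONC", "DV", "KIND")
  if (!all(need %in% names(ds)))
    stop("trial CSV must have columns ID, CONC, DV, KIND", call. = FALSE)
  if (any(ds$KIND == "binary" & !ds$DV %in% c(0, 1)))
    stop("binary DV values must be 0 or 1", call. = FALSE)
  class(ds) <- c("trial_dataset", "data.frame")
  ds
}
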