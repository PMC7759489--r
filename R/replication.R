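#' Parameter combinations of the trial-replication study
#'
#' The 48 combinations used in the simulate-then-estimate validation study:
#' typical steepness gamma in {1, 5, 30} crossed with 16 IIV settings -- all
#' six omega_C50 levels \{0, 0.02, 0.05, 0.1, 0.2, 0.5\} at omega_gamma = 0,
#' plus the five nonzero omega_gamma levels at omega_C50 = 0 and at
#' omega_C50 = 0.1 (the full omega cross is dropped to limit the
#' computational burden).
#'
#' @param gamma_grid typical steepness levels.
#' @param omega_grid IIV variance levels (first element must be 0).
#' @return data frame with columns \code{gamma}, \code{omega_c50},
#'   \code{omega_gamma}.
#' @export
procedure2_combos <- function(gamma_grid = c(1, 5, 30),
                              omega_grid = c(0, 0.02, 0.05, 0.1, 0.2, 0.5)) {
  w_nz <- omega_grid[omega_grid > 0]
  iiv <- rbind(data.frame(omega_c50 = omega_grid, omega_gamma = 0),
               data.frame(omega_c50 = 0, omega_gamma = w_nz),
               data.frame(omega_c50 = 0.1, omega_gamma = w_nz))
  out <- merge(data.frame(gamma = gamma_grid), iiv, by = NULL)
  out[order(out$gamma, out$omega_c50, out$omega_gamma), , drop = FALSE]
}

#' Replicated simulation-estimation study
#'
#' For each parameter combination, simulates \code{n_reps} independent
#' trials (each with its own seed substream, so any single replication can
#' be re-run in isolation) and fits the chosen estimator to every dataset.
#' Summaries follow the usual simulation-study reporting: median and
#' empirical 2.5/97.5 percentiles of each estimate, counts of successful
#' minimizations and covariance steps, the closed-form gamma* for the
#' combination, and the percent difference
#' \code{100 (gamma* - median gamma_hat) / median gamma_hat}.
#'
#' @param combos data frame of \code{gamma}, \code{omega_c50},
#'   \code{omega_gamma} rows (default [procedure2_combos()]).
#' @param n_reps replications per combination (default 1000).
#' @param mode estimator: \code{"pooled"} (naive pooling),
#'   \code{"c50_iiv"} (mixed effects, random effect on C50 only) or
#'   \code{"both_iiv"} (random effects on C50 and gamma).
#' @param data_kind \code{"binary"} or \code{"continuous"} responses.
#' @param design a [trial_design()].
#' @param c50 true typical C50.
#' @param noise_sd residual SD for continuous data.
#' @param constants [pi_constants()] used for gamma* (design and reference).
#' @param seed master seed.
#' @param successful_only summarize over replications with successful
#'   minimization only (the convention used throughout); set \code{FALSE} to
#'   include every replication.
#' @param keep_fits also return the per-replication estimates.
#' @return data frame of per-combination summaries (class
#'   \code{"replication_summary"}); with \code{keep_fits = TRUE} the
#'   per-replication table is in attribute \code{"fits"}.
#' @export
run_replications <- function(combos = procedure2_combos(), n_reps = 1000L,
                             mode = c("pooled", "c50_iiv", "both_iiv"),
                             data_kind = c("binary", "continuous"),
                             design = trial_design(), c50 = 1,
                             noise_sd = 0.1, constants = pi_constants(),
                             seed = 1L, successful_only = TRUE,
                             keep_fits = FALSE) {
  mode <- match.arg(mode)
  data_kind <- match.arg(data_kind)
  if (n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  if (mode != "pooled" && data_kind != "binary")
    stop("mixed-effects estimation requires binary data", call. = FALSE)
  spec <- switch(mode,
                 pooled = fit_spec(FALSE, FALSE),
                 c50_iiv = fit_spec(TRUE, FALSE),
                 both_iiv = fit_spec(TRUE, TRUE))
  qs <- c(0.025, 0.975)
  rows <- vector("list", nrow(combos))
  all_fits <- if (keep_fits) vector("list", nrow(combos)) else NULL
  for (ci in seq_len(nrow(combos))) {
    g <- combos$gamma[ci]; w1 <- combos$omega_c50[ci]; w2 <- combos$omega_gamma[ci]
    est <- matrix(NA_real_, n_reps, 4,
                  dimnames = list(NULL, c("c50", "gamma", "omega_c50", "omega_gamma")))
    minim <- logical(n_reps); covok <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      ds_seed <- derive_seed(seed, ci, r)
      ds <- if (data_kind == "binary")
        simulate_binary_dataset(c50, g, w1, w2, design, constants, ds_seed)
      else
        simulate_continuous_dataset(c50, g, w1, w2, design, noise_sd,
                                    constants, ds_seed)
      fit <- tryCatch(
        if (mode == "pooled") fit_naive_pooled(ds, spec) else fit_mixed(ds, spec),
        error = function(e) NULL)
      if (is.null(fit)) next
      est[r, ] <- c(fit$c50, fit$gamma, fit$omega_c50, fit$omega_gamma)
      minim[r] <- isTRUE(fit$minimized)
      covok[r] <- isTRUE(fit$covariance_ok)
    }
    use <- if (successful_only) minim else !is.na(est[, "gamma"])
    gs <- gamma_star(g, w1, w2, constants)
    if (!any(use)) {
      rows[[ci]] <- data.frame(
        gamma = g, omega_c50 = w1, omega_gamma = w2,
        c50_med = NA_real_, c50_lo = NA_real_, c50_hi = NA_real_,
        gamma_med = NA_real_, gamma_lo = NA_real_, gamma_hi = NA_real_,
        omega_c50_med = NA_real_, omega_gamma_med = NA_real_,
        gamma_star = gs$gamma_star, pct_diff = NA_real_,
        n_minimized = sum(minim), n_covariance_ok = sum(covok),
        n_reps = n_reps, failed = TRUE)
    } else {
      e <- est[use, , drop = FALSE]
      qg <- stats::quantile(e[, "gamma"], qs, names = FALSE)
      qc <- stats::quantile(e[, "c50"], qs, names = FALSE)
      gm <- stats::median(e[, "gamma"])
      rows[[ci]] <- data.frame(
        gamma = g, omega_c50 = w1, omega_gamma = w2,
        c50_med = stats::median(e[, "c50"]), c50_lo = qc[1], c50_hi = qc[2],
        gamma_med = gm, gamma_lo = qg[1], gamma_hi = qg[2],
        omega_c50_med = stats::median(e[, "omega_c50"]),
        omega_gamma_med = stats::median(e[, "omega_gamma"]),
        gamma_star = gs$gamma_star,
        pct_diff = 100 * (gs$gamma_star - gm) / gm,
        n_minimized = sum(minim), n_covariance_ok = sum(covok),
        n_reps = n_reps, failed = FALSE)
    }
    if (keep_fits) {
      ef <- as.data.frame(est)
      names(ef) <- paste0(names(ef), "_hat")
      all_fits[[ci]] <- data.frame(gamma = g, omega_c50 = w1, omega_gamma = w2,
                                   rep = seq_len(n_reps), ef,
                                   minimized = minim, covariance_ok = covok)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("replication_summary", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "data_kind") <- data_kind
  attr(out, "seed") <- seed
  if (keep_fits) attr(out, "fits") <- do.call(rbind, all_fits)
  out
}

#' Precision of the closed-form steepness prediction across a study
#'
#' Root-mean-squared error (in percent) and range of the per-combination
#' percent differences between gamma* and the median estimated gamma from a
#' [run_replications()] summary.
#'
#' @param summary a \code{"replication_summary"} data frame (>= 2 combos).
#' @return list with \code{rmse_pct}, \code{min_pct}, \code{max_pct}.
#' @export
precision_report <- function(summary) {
  pct <- summary$pct_diff[!is.na(summary$pct_diff)]
  if (length(pct) < 2L)
    stop("need percent differences from at least 2 combinations", call. = FALSE)
  list(rmse_pct = sqrt(mean(pct^2)), min_pct = min(pct), max_pct = max(pct))
}
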