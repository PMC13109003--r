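#' Configuration of one Monte Carlo variance experiment
#'
#' @param scenario a [scenario()] object (see [scenario_presets()]).
#' @param n sample size per replicate.
#' @param reps number of replicates (at least 2).
#' @param base_seed integer; replicate `r` uses seed `base_seed + r`, so
#'   results are deterministic and replicates extendable. Must keep
#'   `base_seed + reps` below `2^31`.
#' @param nuisance a [nuisance_spec()]; default saturated, matching the
#'   correct-specification premise of the variance comparison.
#' @param aD_values which separable-effect estimators to run (subset of
#'   `c(0, 1)`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(scenario, n, reps, base_seed,
                              nuisance = nuisance_spec(), aD_values = c(0, 1)) {
  stopifnot(inherits(scenario, "scenario"), inherits(nuisance, "nuisance_spec"))
  if (!is.numeric(n) || n < 1) stop("'n' must be at least 1")
  if (!is.numeric(reps) || reps < 2) stop("'reps' must be at least 2")
  if (!is.numeric(base_seed) || base_seed + reps >= 2^31)
    stop("'base_seed' + reps must stay below 2^31")
  if (!length(aD_values) || !all(aD_values %in% c(0, 1)))
    stop("'aD_values' must be a nonempty subset of c(0, 1)")
  structure(list(scenario = scenario, n = as.integer(n),
                 reps = as.integer(reps), base_seed = as.integer(base_seed),
                 nuisance = nuisance, aD_values = sort(unique(aD_values))),
            class = "simulation_config")
}

#' Run the Monte Carlo variance experiment
#'
#' Draws `reps` independent datasets of size `n` from the scenario's
#' data-generating process (replicate `r` seeded with `base_seed + r`),
#' fits the competing-event nuisance model once per replicate, and
#' computes the censoring (IPCW) estimator and the separable-effect
#' estimator(s) on the shared fit. Replicates on which an estimator fails
#' (an empty treatment-covariate cell, or an estimated survivor
#' probability of zero where a weight is needed) are counted and excluded
#' from that estimator's moments; if more than half of the replicates fail
#' for any estimator the run aborts. Monte Carlo means and unbiased
#' (`reps - 1` denominator) variances are reported together with the full
#' error decomposition of each estimator against the actual causal target
#' `SDE0^{aD}`, computed exactly from the scenario parameters.
#'
#' @param config a [simulation_config()].
#' @return An object of class `simulation_result`: per-estimator list with
#'   replicate `estimates`, `mean`, `variance`, `mc_se_mean`,
#'   `mc_se_variance` (approximating `variance * sqrt(2 / (reps - 1))`),
#'   `max_weight` summary, `n_failed`, and (per `aD`) an attached
#'   [decompose_errors()] result.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sc <- config$scenario
  targets <- causal_targets(sc$params)
  labels <- c("ipcw", paste0("sde_aD", config$aD_values))
  est <- stats::setNames(lapply(labels, function(x)
    list(estimates = rep(NA_real_, config$reps),
         max_weights = rep(NA_real_, config$reps), n_failed = 0L)), labels)
  for (r in seq_len(config$reps)) {
    dat <- generate_point_data(sc$params, config$n, seed = config$base_seed + r)
    fit <- try(fit_nuisance(dat, config$nuisance), silent = TRUE)
    if (inherits(fit, "try-error")) {
      for (lb in labels) est[[lb]]$n_failed <- est[[lb]]$n_failed + 1L
      next
    }
    res <- try(ipcw_cde_hat(dat, fit), silent = TRUE)
    if (inherits(res, "try-error")) {
      est$ipcw$n_failed <- est$ipcw$n_failed + 1L
    } else {
      est$ipcw$estimates[r] <- res$estimate
      est$ipcw$max_weights[r] <- res$max_weight
    }
    for (aD in config$aD_values) {
      lb <- paste0("sde_aD", aD)
      res <- try(ipw_sde_hat(dat, fit, aD), silent = TRUE)
      if (inherits(res, "try-error")) {
        est[[lb]]$n_failed <- est[[lb]]$n_failed + 1L
      } else {
        est[[lb]]$estimates[r] <- res$estimate
        est[[lb]]$max_weights[r] <- res$max_weight
      }
    }
  }
  for (lb in labels) {
    e <- est[[lb]]
    if (e$n_failed > config$reps / 2)
      stop(sprintf("estimator '%s' failed on %d of %d replicates", lb,
                   e$n_failed, config$reps))
    ok <- !is.na(e$estimates)
    v <- stats::var(e$estimates[ok])
    nr <- sum(ok)
    est[[lb]]$mean <- mean(e$estimates[ok])
    est[[lb]]$variance <- v
    est[[lb]]$mc_se_mean <- sqrt(v / nr)
    est[[lb]]$mc_se_variance <- v * sqrt(2 / (nr - 1))
    est[[lb]]$max_weight <- stats::quantile(e$max_weights[ok],
                                            c(0.5, 0.9, 1), names = FALSE)
    names(est[[lb]]$max_weight) <- c("median", "q90", "max")
  }
  decomp <- list()
  for (aD in config$aD_values) {
    decomp[[paste0("ipcw_vs_aD", aD)]] <-
      decompose_errors(est$ipcw$mean, est$ipcw$variance, targets, "ipcw", aD)
    lb <- paste0("sde_aD", aD)
    decomp[[lb]] <-
      decompose_errors(est[[lb]]$mean, est[[lb]]$variance, targets, "sde", aD)
  }
  structure(list(config = config, targets = targets, estimators = est,
                 decompositions = decomp), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Simulation: scenario '%s', n = %d, reps = %d\n",
              cfg$scenario$name, cfg$n, cfg$reps))
  for (lb in names(x$estimators)) {
    e <- x$estimators[[lb]]
    cat(sprintf("  %-8s mean % .5f  var %.3g (MC SE %.2g)  max wt %.1f  failed %d\n",
                lb, e$mean, e$variance, e$mc_se_variance,
                e$max_weight[["max"]], e$n_failed))
  }
  invisible(x)
}

#' Variance comparison table across scenarios
#'
#' Runs [run_simulation()] for each configuration and assembles one row
#' per scenario: the three design flags, the Monte Carlo variances of the
#' separable-effect estimator(s) and the censoring estimator with their
#' Monte Carlo standard errors, and the variance ratio
#' `Var(IPCW) / Var(SDE, aD = 0)`.
#'
#' @param configs list of [simulation_config()] objects.
#' @return A `data.frame`, one row per configuration; the full
#'   `simulation_result` objects are attached as attribute `"results"`.
#' @export
variance_table <- function(configs) {
  stopifnot(length(configs) >= 1)
  results <- lapply(configs, run_simulation)
  rows <- lapply(results, function(res) {
    sc <- res$config$scenario
    row <- data.frame(
      scenario = sc$name,
      near_positivity_violation = sc$near_positivity_violation,
      u_dependence = sc$u_dependence,
      rare_competing_event = sc$rare_competing_event,
      n = res$config$n, reps = res$config$reps,
      var_cde = res$estimators$ipcw$variance,
      mc_se_var_cde = res$estimators$ipcw$mc_se_variance)
    for (aD in res$config$aD_values) {
      lb <- paste0("sde_aD", aD)
      row[[paste0("var_", lb)]] <- res$estimators[[lb]]$variance
      row[[paste0("mc_se_var_", lb)]] <- res$estimators[[lb]]$mc_se_variance
    }
    if ("sde_aD0" %in% names(res$estimators))
      row$var_ratio <- row$var_cde / row$var_sde_aD0
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
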