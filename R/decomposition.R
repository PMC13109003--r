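#' Three-way error decomposition of a weighted estimator
#'
#' Splits the bias of an estimator, relative to the *actual* causal target
#' `SDE0^{aD}`, into three additive components:
#'
#' * **estimand error** — ostensible causal target minus actual target.
#'   For the censoring (IPCW) estimator the ostensible target is `CDE0`,
#'   so this is `CDE0 - SDE0^{aD}`; for the separable-effect estimator the
#'   ostensible and actual targets coincide and this component is exactly 0.
#' * **non-identification error** — statistical target minus ostensible
#'   causal target (`CDEobs - CDE0`, or `SDEobs^{aD} - SDE0^{aD}`), the
#'   structural bias from unmeasured common causes of the two event
#'   processes.
#' * **statistical error** — mean of the estimator minus its statistical
#'   target.
#'
#' The three components sum exactly to `estimator_mean - SDE0^{aD}`, and
#' `mse = total_bias^2 + variance`.
#'
#' @param estimator_mean (Monte Carlo) expectation of the estimator.
#' @param estimator_variance (Monte Carlo) variance of the estimator.
#' @param targets a `target_values` object from [causal_targets()].
#' @param estimator `"ipcw"` (censoring estimator, ostensible target
#'   `CDE0`) or `"sde"` (separable-effect estimator).
#' @param aD arm at which the competing-event treatment component of the
#'   actual target is held (0 or 1).
#' @return An object of class `error_decomposition`.
#' @examples
#' p <- dgp_params(0.5, 0.5, c(-1, 1, 0.5, -0.5, 1, 0.5, 1),
#'                 c(-1, 1, 0.5, 0.5, 1, -0.5, 0.5))
#' tv <- causal_targets(p)
#' decompose_errors(tv$cdeobs, 1e-5, tv, "ipcw", aD = 0)
#' @export
decompose_errors <- function(estimator_mean, estimator_variance, targets,
                             estimator = c("ipcw", "sde"), aD) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(targets, "target_values"), aD %in% c(0, 1),
            is.numeric(estimator_mean), is.numeric(estimator_variance),
            estimator_variance >= 0)
  actual <- if (aD == 0) targets$sde0_aD0 else targets$sde0_aD1
  if (is.na(actual)) stop("true targets not populated in 'targets'")
  if (estimator == "ipcw") {
    stat_target <- targets$cdeobs
    if (is.na(stat_target))
      stop("CDEobs is undefined due to positivity failure; decomposition refused")
    ostensible <- targets$cde0
    estimand_error <- ostensible - actual
  } else {
    stat_target <- if (aD == 0) targets$sdeobs_aD0 else targets$sdeobs_aD1
    if (is.na(stat_target))
      stop(sprintf("SDEobs(aD=%d) is undefined due to positivity failure; decomposition refused", aD))
    ostensible <- actual
    estimand_error <- 0
  }
  nonid <- stat_target - ostensible
  stat_err <- estimator_mean - stat_target
  total <- estimand_error + nonid + stat_err
  structure(list(
    estimator = estimator, aD = as.integer(aD),
    actual_target = actual, ostensible_target = ostensible,
    statistical_target = stat_target, estimator_mean = estimator_mean,
    estimand_error = estimand_error, nonidentification_error = nonid,
    statistical_error = stat_err, total_bias = total,
    variance = estimator_variance,
    mse = total^2 + estimator_variance), class = "error_decomposition")
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf("Error decomposition: %s estimator vs actual target SDE0(aD=%d) = %.4f\n",
              toupper(x$estimator), x$aD, x$actual_target))
  cat(sprintf("  estimand error           % .5f\n", x$estimand_error))
  cat(sprintf("  non-identification error % .5f\n", x$nonidentification_error))
  cat(sprintf("  statistical error        % .5f\n", x$statistical_error))
  cat(sprintf("  total bias               % .5f\n", x$total_bias))
  cat(sprintf("  variance %.3g,  MSE %.3g\n", x$variance, x$mse))
  invisible(x)
}

#' Build a factorial parameter grid, or a seeded subsample of it
#'
#' Constructs [dgp_params()] objects over the factorial grid of slope
#' coefficients `theta1..theta6, beta1..beta6` drawn from `values`, with
#' intercepts fixed. The full factorial (`length(values)^12` points) is
#' combinatorially infeasible to scan, so `n_sample` draws a seeded random
#' subsample (coefficients drawn independently and uniformly from
#' `values`), which is recorded alongside the grid for reproducibility.
#'
#' @param values candidate values for each slope coefficient
#'   (default `c(-1, -0.5, 0.5, 1)`).
#' @param theta0,beta0 fixed intercepts of the two models; large negative
#'   `beta0` (e.g. -9) makes the competing event rare.
#' @param n_sample number of random grid points to draw.
#' @param seed integer seed for the subsample.
#' @param pL,pU covariate prevalences (default 0.5 and 0.5).
#' @return A list of `dgp_params` objects; the drawn coefficient matrix is
#'   attached as attribute `"grid"`.
#' @export
param_grid_sample <- function(values = c(-1, -0.5, 0.5, 1), theta0 = -1,
                              beta0 = -1, n_sample = 500, seed = 1,
                              pL = 0.5, pU = 0.5) {
  stopifnot(n_sample >= 1)
  draw <- with_seed(seed, matrix(sample(values, 12 * n_sample, replace = TRUE),
                                 nrow = n_sample))
  colnames(draw) <- c(paste0("theta", 1:6), paste0("beta", 1:6))
  out <- lapply(seq_len(n_sample), function(i)
    dgp_params(pL = pL, pU = pU,
               theta = c(theta0, draw[i, 1:6]),
               beta = c(beta0, draw[i, 7:12])))
  attr(out, "grid") <- draw
  out
}

#' Scan a parameter grid for targets, errors and sign discordance
#'
#' For each data-generating parameter set, computes all causal targets and
#' observed-data functionals exactly (no simulation), the estimand error
#' `CDE0 - SDE0^{aD}`, both non-identification errors, and whether the
#' controlled and separable direct effects disagree in sign. One row per
#' parameter set; rows whose observed functionals are undefined because of
#' a positivity failure are emitted with `NA` in the affected columns and
#' `positivity_ok = FALSE`, never dropped.
#'
#' The output is the scatter data behind estimand-error plots (`cde0`
#' versus `sde0_aD`) and non-identification-error plots (`cde0` versus
#' `cdeobs`; `sde0_aD` versus `sdeobs_aD`).
#'
#' @param param_grid list of [dgp_params()] objects, e.g. from
#'   [param_grid_sample()].
#' @param aD arm defining the actual causal target (0 or 1).
#' @return A `data.frame` with columns `cde0, sde0_aD0, sde0_aD1, cdeobs,
#'   sdeobs_aD0, sdeobs_aD1, estimand_error, nonid_cde, nonid_sde,
#'   discordant, positivity_ok`.
#' @export
grid_scan <- function(param_grid, aD = 0) {
  stopifnot(length(param_grid) >= 1, aD %in% c(0, 1))
  rows <- lapply(param_grid, function(p) {
    tv <- causal_targets(p)
    sde0 <- if (aD == 0) tv$sde0_aD0 else tv$sde0_aD1
    sdeobs <- if (aD == 0) tv$sdeobs_aD0 else tv$sdeobs_aD1
    data.frame(
      cde0 = tv$cde0, sde0_aD0 = tv$sde0_aD0, sde0_aD1 = tv$sde0_aD1,
      cdeobs = tv$cdeobs, sdeobs_aD0 = tv$sdeobs_aD0,
      sdeobs_aD1 = tv$sdeobs_aD1,
      estimand_error = tv$cde0 - sde0,
      nonid_cde = tv$cdeobs - tv$cde0,
      nonid_sde = sdeobs - sde0,
      discordant = sign_discordant(tv, aD),
      positivity_ok = length(tv$undefined) == 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
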