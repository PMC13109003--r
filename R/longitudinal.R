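#' Person-period (discrete-time) trial data
#'
#' Long-format container for a two-arm trial followed over `K` monthly
#' intervals. Each row is one person-month at risk: `id`, `month`
#' (1-based), randomized arm `a`, baseline covariate columns (constant
#' within person; any names, e.g. `hgb_low`, `age_group`, `in_bed`,
#' `hist_cvd`), competing-event indicator `d` and event-of-interest
#' indicator `y` for that interval. The competing event is evaluated
#' before the event of interest within an interval, so a row never has
#' both `d = 1` and `y = 1`, and a person's rows are the consecutive
#' months `1, 2, ...` up to and including the first month with an event
#' (or the administrative end of follow-up).
#'
#' @param df a data frame with at least columns `id, month, a, d, y`.
#' @return The validated data frame with class `person_period`.
#' @export
person_period <- function(df) {
  df <- as.data.frame(df)
  need <- c("id", "month", "a", "d", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("person-period data missing columns: ",
                         paste(miss, collapse = ", "))
  for (cl in c("a", "d", "y"))
    if (!all(df[[cl]] %in% c(0, 1))) stop(sprintf("column '%s' must be binary 0/1", cl))
  if (any(df$d == 1 & df$y == 1))
    stop("a person-month cannot have both d = 1 and y = 1 (the competing event precedes)")
  df <- df[order(df$id, df$month), , drop = FALSE]
  covs <- setdiff(names(df), need)
  sp <- split(seq_len(nrow(df)), df$id)
  for (idx in sp) {
    m <- df$month[idx]
    if (!identical(as.integer(m), seq_along(idx)))
      stop("months must be consecutive starting at 1 within each id (id ",
           df$id[idx[1]], ")")
    ev <- df$d[idx] + df$y[idx]
    if (any(ev[-length(idx)] == 1))
      stop("rows must stop at the first event (id ", df$id[idx[1]], ")")
    for (cl in c("a", covs))
      if (length(unique(df[[cl]][idx])) != 1L)
        stop(sprintf("column '%s' must be constant within id %s", cl, df$id[idx[1]]))
  }
  rownames(df) <- NULL
  class(df) <- c("person_period", "data.frame")
  df
}

#' Read / write person-period trial data as CSV
#'
#' On-disk format: header `id,month,a,hgb_low,age_group,in_bed,hist_cvd,d,y`
#' with `age_group` coded 0/1/2 (youngest to oldest) and all other
#' covariates 0/1. `col_map` renames nonstandard source columns on read
#' (a named character vector `c(standard_name = "source_name")`), so
#' externally published datasets can be loaded without editing files.
#'
#' @param path file path.
#' @param col_map optional named character vector mapping standard column
#'   names to the names used in the file.
#' @param x a `person_period` data frame.
#' @return `read_person_period` returns a validated `person_period`;
#'   `write_person_period` invisibly returns `path`.
#' @export
read_person_period <- function(path, col_map = NULL) {
  df <- utils::read.csv(path)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df)) stop("mapped column not found in file: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  need <- c("id", "month", "a", "hgb_low", "age_group", "in_bed", "hist_cvd", "d", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("person-period CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$age_group %in% 0:2)) stop("age_group must be coded 0, 1 or 2")
  person_period(df[, need])
}

#' @rdname read_person_period
#' @export
write_person_period <- function(x, path) {
  stopifnot(inherits(x, "data.frame"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specification of a discrete-time (pooled logistic) hazard model
#'
#' The default models the competing-event hazard as a pooled logistic
#' regression on a second-degree polynomial in month, treatment,
#' the four baseline covariates of the trial layout, and a
#' treatment-by-cardiovascular-history interaction (interactions between
#' treatment and competing-event risk factors widen the gap between the
#' controlled- and separable-effect functionals, so the default keeps
#' one). Supply any other model formula for different covariate sets;
#' time terms should normally be present.
#'
#' @param outcome `"competing"` (the `d` process; the only model the
#'   weighted estimators need) or `"interest"` (the `y` process among
#'   those without a competing event in the interval).
#' @param formula model formula; the default fits the trial layout.
#' @return An object of class `hazard_model_spec`.
#' @export
hazard_model_spec <- function(outcome = c("competing", "interest"),
                              formula = NULL) {
  outcome <- match.arg(outcome)
  if (is.null(formula)) {
    lhs <- if (outcome == "competing") "d" else "y"
    formula <- stats::as.formula(paste(
      lhs, "~ month + I(month^2) + a + hgb_low + factor(age_group) +",
      "in_bed + hist_cvd + a:hist_cvd"))
  }
  structure(list(outcome = outcome, formula = formula),
            class = "hazard_model_spec")
}

#' Fit a pooled logistic discrete-time hazard model
#'
#' Maximum-likelihood logistic fit on person-month rows at risk: all rows
#' for the competing-event hazard, rows with `d = 0` for the
#' event-of-interest hazard (the competing event precedes within an
#' interval). Non-convergence is an error; complete separation (e.g. no
#' events at all) is reported as a warning with near-degenerate fitted
#' hazards rather than silently accepted.
#'
#' @param data a [person_period()] data frame.
#' @param spec a [hazard_model_spec()].
#' @return An object of class `fitted_hazard` wrapping the `glm` fit.
#' @export
fit_discrete_hazard <- function(data, spec = hazard_model_spec()) {
  stopifnot(inherits(data, "person_period"), inherits(spec, "hazard_model_spec"))
  rows <- if (spec$outcome == "competing") data else data[data$d == 0, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no person-month rows at risk")
  outcome_col <- if (spec$outcome == "competing") "d" else "y"
  n_events <- sum(rows[[outcome_col]])
  fit <- withCallingHandlers(
    stats::glm(spec$formula, family = stats::binomial(), data = rows),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("hazard fit is separated (fitted hazards of 0 or 1); ",
                "predicted hazards may be degenerate", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    if (n_events == 0L || n_events == nrow(rows))
      warning("hazard fit is separated (no variation in the outcome); ",
              "fitted hazards are numerically degenerate", call. = FALSE)
    else stop("pooled logistic hazard fit did not converge")
  }
  structure(list(glm = fit, spec = spec), class = "fitted_hazard")
}

#' @export
print.fitted_hazard <- function(x, ...) {
  cat(sprintf("Pooled logistic %s-event hazard model\n",
              if (x$spec$outcome == "competing") "competing" else "interest"))
  print(stats::coef(x$glm))
  invisible(x)
}

# Predicted discrete hazard for given person-month rows, optionally with
# the treatment column forced to a fixed arm.
predict_hazard <- function(hazfit, rows, set_a = NULL) {
  nd <- as.data.frame(rows)
  if (!is.null(set_a)) nd$a <- as.integer(set_a)
  as.numeric(stats::predict(hazfit$glm, newdata = nd, type = "response"))
}

# Shared machinery for both weighted cumulative-incidence curves.
# numerator_arm = NULL gives censoring weights 1 / prod(1 - haz_own);
# otherwise ratio weights prod(1 - haz_num) / prod(1 - haz_own).
weighted_risk_curve <- function(data, hazfit, arm, months, numerator_arm,
                                label) {
  stopifnot(inherits(data, "person_period"), inherits(hazfit, "fitted_hazard"),
            arm %in% c(0, 1))
  if (hazfit$spec$outcome != "competing")
    stop("risk curves require the competing-event hazard model")
  months <- as.integer(months)
  if (!length(months)) {
    out <- numeric(0)
    attr(out, "max_weight") <- NA_real_
    return(out)
  }
  if (any(months < 1)) stop("months must be >= 1")
  rows <- data[data$a == arm, , drop = FALSE]
  n_arm <- length(unique(rows$id))
  if (n_arm == 0L) stop("no persons in arm ", arm)
  haz_own <- predict_hazard(hazfit, rows)
  surv_own <- 1 - haz_own
  if (any(surv_own <= 0)) {
    i <- which(surv_own <= 0)[1]
    stop(sprintf("positivity failure in %s weights: predicted hazard 1 at month %d, arm %d",
                 label, rows$month[i], arm))
  }
  ratio <- if (is.null(numerator_arm)) 1 / surv_own
           else (1 - predict_hazard(hazfit, rows, set_a = numerator_arm)) / surv_own
  # cumulative product within person; split() reorders ids, so realign
  ord <- order(rows$id, rows$month)
  w_aligned <- numeric(nrow(rows))
  w_aligned[ord] <- unlist(lapply(split(ratio[ord], rows$id[ord]), cumprod),
                           use.names = FALSE)
  contrib <- rows$y * w_aligned
  risk <- vapply(months, function(t) sum(contrib[rows$month <= t]) / n_arm,
                 numeric(1))
  names(risk) <- months
  attr(risk, "max_weight") <- max(w_aligned)
  risk
}

#' Discrete-time IPCW cumulative-incidence curve
#'
#' Generalizes the point-treatment censoring estimator to monthly data:
#' the risk of the event of interest in arm `a` by month `t` is the
#' average over the arm's persons of
#' `sum_{k <= t} I(Y_k = 1) * prod_{j <= k} 1 / (1 - pi_k_hat(a, L))`,
#' where `pi_k_hat` is the fitted discrete competing-event hazard.
#' Persons experiencing the competing event are treated as censored at
#' that month. Its statistical target is the
#' controlled-direct-effect (elimination-of-competing-events) functional.
#'
#' @param data a [person_period()] data frame.
#' @param hazfit a [fit_discrete_hazard()] result for the competing
#'   outcome.
#' @param arm which arm's curve to compute (0 or 1).
#' @param months evaluation months (default `c(12, 24, 36, 48)`).
#' @return Named numeric vector of per-month risks, with the maximum
#'   person-month weight attached as attribute `"max_weight"`.
#' @export
ipcw_risk_curve <- function(data, hazfit, arm, months = c(12, 24, 36, 48)) {
  weighted_risk_curve(data, hazfit, arm, months, numerator_arm = NULL,
                      label = "censoring")
}

#' Discrete-time separable-effect cumulative-incidence curve
#'
#' The counterpart of [ipcw_risk_curve()] targeting the separable-effect
#' functional: the curve for treatment component `aY` with the
#' competing-event component held at `aD` replaces the inverse-probability
#' weight with the ratio
#' `prod_{j <= k} (1 - pi_j_hat(aD, L)) / (1 - pi_j_hat(aY, L))`.
#' With `aD = aY` the weights are identically 1 and the curve equals the
#' crude cumulative incidence in arm `aY`.
#'
#' @inheritParams ipcw_risk_curve
#' @param aY arm whose event-of-interest component is evaluated.
#' @param aD arm at which the competing-event component is held.
#' @return Named numeric vector of per-month risks with attribute
#'   `"max_weight"`.
#' @export
sde_risk_curve <- function(data, hazfit, aY, aD, months = c(12, 24, 36, 48)) {
  stopifnot(aD %in% c(0, 1))
  weighted_risk_curve(data, hazfit, aY, months, numerator_arm = aD,
                      label = "separable-effect")
}

#' Risk-difference curves with bootstrap percentile intervals
#'
#' Computes the arm-1 minus arm-0 risk difference of the chosen weighted
#' cumulative-incidence estimator at the requested months, with
#' nonparametric bootstrap percentile confidence intervals: persons (not
#' person-months) are resampled with replacement within arm, the pooled
#' logistic hazard model is refit on each resample, and the 2.5th and
#' 97.5th percentiles of the resampled contrasts form the interval.
#' Resamples on which the hazard fit or a curve fails are counted and
#' skipped.
#'
#' @param data a [person_period()] data frame.
#' @param estimator `"ipcw"` or `"sde"`.
#' @param aD competing-event component arm, required for `"sde"`.
#' @param months evaluation months.
#' @param B number of bootstrap resamples.
#' @param seed integer seed; the resampling is deterministic given `seed`.
#' @param spec hazard model specification (default [hazard_model_spec()]).
#' @param level confidence level (default 0.95).
#' @return An object of class `risk_curve_result` with elements `months`,
#'   `risk1`, `risk0`, `contrast`, `ci_lower`, `ci_upper`, `max_weight`
#'   (over both arms at the point fit), `n_failed` and `B`.
#' @export
bootstrap_contrasts <- function(data, estimator = c("ipcw", "sde"), aD = NULL,
                                months = c(12, 24, 36, 48), B = 1000, seed,
                                spec = hazard_model_spec(), level = 0.95) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(data, "person_period"), B >= 2)
  if (estimator == "sde" && (is.null(aD) || !aD %in% c(0, 1)))
    stop("'aD' must be 0 or 1 for the separable-effect estimator")
  curve_fun <- function(dat, hazfit, arm) {
    if (estimator == "ipcw") ipcw_risk_curve(dat, hazfit, arm, months)
    else sde_risk_curve(dat, hazfit, aY = arm, aD = aD, months = months)
  }
  hazfit <- fit_discrete_hazard(data, spec)
  r1 <- curve_fun(data, hazfit, 1)
  r0 <- curve_fun(data, hazfit, 0)
  contrast <- as.numeric(r1) - as.numeric(r0)
  max_w <- max(attr(r1, "max_weight"), attr(r0, "max_weight"))

  ids_by_arm <- lapply(c(0, 1), function(arm)
    unique(data$id[data$a == arm]))
  rows_by_id <- split(seq_len(nrow(data)), data$id)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = B, ncol = length(months))
    n_failed <- 0L
    for (b in seq_len(B)) {
      take <- unlist(lapply(ids_by_arm, function(ids)
        sample(as.character(ids), length(ids), replace = TRUE)))
      idx <- unlist(rows_by_id[take], use.names = FALSE)
      bd <- data[idx, , drop = FALSE]
      # fresh ids so duplicated persons count with their multiplicity
      bd$id <- rep(seq_along(take),
                   times = vapply(rows_by_id[take], length, integer(1)))
      class(bd) <- c("person_period", "data.frame")
      res <- try(suppressWarnings({
        hf <- fit_discrete_hazard(bd, spec)
        as.numeric(curve_fun(bd, hf, 1)) - as.numeric(curve_fun(bd, hf, 0))
      }), silent = TRUE)
      if (inherits(res, "try-error")) n_failed <- n_failed + 1L
      else out[b, ] <- res
    }
    list(mat = out, n_failed = n_failed)
  })
  alpha <- (1 - level) / 2
  ci <- apply(boot$mat, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  structure(list(months = as.integer(months),
                 risk1 = as.numeric(r1), risk0 = as.numeric(r0),
                 contrast = contrast,
                 ci_lower = ci[1, ], ci_upper = ci[2, ],
                 max_weight = max_w, n_failed = boot$n_failed, B = B,
                 estimator = estimator, aD = aD, level = level),
            class = "risk_curve_result")
}

#' @export
print.risk_curve_result <- function(x, ...) {
  cat(sprintf("%s risk-difference curve%s (B = %d bootstrap resamples, %d failed)\n",
              toupper(x$estimator),
              if (!is.null(x$aD)) sprintf(", aD = %d", x$aD) else "",
              x$B, x$n_failed))
  df <- data.frame(month = x$months, risk1 = round(x$risk1, 4),
                   risk0 = round(x$risk0, 4), contrast = round(x$contrast, 4),
                   lower = round(x$ci_lower, 4), upper = round(x$ci_upper, 4))
  print(df, row.names = FALSE)
  cat(sprintf("max person-month weight: %.2f\n", x$max_weight))
  invisible(x)
}

default_trial_coefs <- function(outcome) {
  # Monthly baseline hazards around 1%, gently time-varying, with modest
  # covariate effects and a treatment-by-CVD-history interaction on the
  # competing (other-cause death) hazard.
  if (outcome == "competing")
    c(intercept = -4.8, month = 0.02, month2 = -2e-4, a = 0.3,
      hgb_low = 0.2, age_mid = 0.3, age_high = 0.8, in_bed = 0.7,
      hist_cvd = 0.6, a_hist_cvd = 0.5)
  else
    c(intercept = -4.3, month = 0.015, month2 = -1e-4, a = -0.4,
      hgb_low = 0.3, age_mid = 0.2, age_high = 0.4, in_bed = 0.5,
      hist_cvd = 0.1, a_hist_cvd = 0)
}

trial_linpred <- function(coefs, month, a, cov) {
  coefs[["intercept"]] + coefs[["month"]] * month + coefs[["month2"]] * month^2 +
    coefs[["a"]] * a + coefs[["hgb_low"]] * cov$hgb_low +
    coefs[["age_mid"]] * (cov$age_group == 1) +
    coefs[["age_high"]] * (cov$age_group == 2) +
    coefs[["in_bed"]] * cov$in_bed + coefs[["hist_cvd"]] * cov$hist_cvd +
    coefs[["a_hist_cvd"]] * a * cov$hist_cvd
}

#' Generate a synthetic two-arm discrete-time trial
#'
#' Emulates the structure of a prostate-cancer trial reanalysis: two arms
#' (default 125 treated, 127 placebo), 50 monthly intervals, four baseline
#' covariates (dichotomized hemoglobin, three-level age group, confinement
#' to bed, cardiovascular history), a competing-event (other-cause death)
#' hazard and an event-of-interest (cancer death) hazard, both discrete
#' logistic in a second-degree polynomial of month with covariate effects
#' and a treatment-by-cardiovascular-history interaction on the competing
#' hazard. Within each month the competing event is drawn first; a person
#' exits at the first event or at month `K` (administrative end). This is
#' synthetic data for exercising the longitudinal estimators, not a
#' calibrated replica of any real trial.
#'
#' @param n1,n0 arm sizes (treated / placebo).
#' @param K number of monthly intervals.
#' @param d_coef,y_coef named coefficient vectors for the two hazards with
#'   names `intercept, month, month2, a, hgb_low, age_mid, age_high,
#'   in_bed, hist_cvd, a_hist_cvd`; see `separisk:::default_trial_coefs`.
#' @param covariate_prev list with elements `hgb_low`, `age_group`
#'   (length-3 probabilities), `in_bed`, `hist_cvd`.
#' @param seed integer seed.
#' @return A [person_period()] data frame.
#' @examples
#' tr <- generate_synthetic_trial(seed = 4)
#' length(unique(tr$id))
#' @export
generate_synthetic_trial <- function(n1 = 125, n0 = 127, K = 50,
                                     d_coef = default_trial_coefs("competing"),
                                     y_coef = default_trial_coefs("interest"),
                                     covariate_prev = list(
                                       hgb_low = 0.4,
                                       age_group = c(0.25, 0.5, 0.25),
                                       in_bed = 0.1, hist_cvd = 0.4),
                                     seed) {
  stopifnot(n1 >= 1, n0 >= 1, K >= 1)
  need <- names(default_trial_coefs("competing"))
  if (!all(need %in% names(d_coef)) || !all(need %in% names(y_coef)))
    stop("hazard coefficient vectors must carry names: ",
         paste(need, collapse = ", "))
  pv <- covariate_prev
  stopifnot(pv$hgb_low >= 0, pv$hgb_low <= 1, length(pv$age_group) == 3,
            abs(sum(pv$age_group) - 1) < 1e-8, pv$in_bed >= 0, pv$in_bed <= 1,
            pv$hist_cvd >= 0, pv$hist_cvd <= 1)
  n <- n1 + n0
  with_seed(seed, {
    cov <- data.frame(
      id = seq_len(n),
      a = rep(c(1L, 0L), c(n1, n0)),
      hgb_low = stats::rbinom(n, 1L, pv$hgb_low),
      age_group = sample(0:2, n, replace = TRUE, prob = pv$age_group),
      in_bed = stats::rbinom(n, 1L, pv$in_bed),
      hist_cvd = stats::rbinom(n, 1L, pv$hist_cvd))
    active <- rep(TRUE, n)
    rows <- vector("list", K)
    for (k in seq_len(K)) {
      idx <- which(active)
      if (!length(idx)) break
      ck <- cov[idx, , drop = FALSE]
      hd <- stats::plogis(trial_linpred(d_coef, k, ck$a, ck))
      d_k <- stats::rbinom(length(idx), 1L, hd)
      y_k <- integer(length(idx))
      no_d <- which(d_k == 0L)
      if (length(no_d)) {
        hy <- stats::plogis(trial_linpred(y_coef, k, ck$a[no_d], ck[no_d, , drop = FALSE]))
        y_k[no_d] <- stats::rbinom(length(no_d), 1L, hy)
      }
      rows[[k]] <- data.frame(id = ck$id, month = k, a = ck$a,
                              hgb_low = ck$hgb_low, age_group = ck$age_group,
                              in_bed = ck$in_bed, hist_cvd = ck$hist_cvd,
                              d = d_k, y = y_k)
      active[idx] <- d_k == 0L & y_k == 0L
    }
    person_period(do.call(rbind, rows))
  })
}
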