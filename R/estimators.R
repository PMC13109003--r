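#' Specification of the competing-event nuisance model
#'
#' Describes how `pi_tilde(A, L) = Pr(D = 1 | A, L)` is fit. The default,
#' `"saturated"`, puts one parameter per `(a, l)` cell and reduces to the
#' cell proportions of `D = 1`; it is always correctly specified over
#' binary `(A, L)`. `"logistic"` fits a maximum-likelihood logistic
#' regression of `D` on the requested linear-predictor terms (subsets of
#' `"a"`, `"l"`, `"a:l"`, plus an intercept), which permits deliberate
#' misspecification experiments.
#'
#' @param kind `"saturated"` or `"logistic"`.
#' @param terms character vector of terms for the logistic kind; ignored
#'   for saturated. A logistic fit with all of `a`, `l`, `a:l` is
#'   equivalent to the saturated fit.
#' @return An object of class `nuisance_spec`.
#' @export
nuisance_spec <- function(kind = c("saturated", "logistic"),
                          terms = c("a", "l", "a:l")) {
  kind <- match.arg(kind)
  if (kind == "logistic") {
    bad <- setdiff(terms, c("a", "l", "a:l"))
    if (length(bad)) stop("unknown nuisance terms: ", paste(bad, collapse = ", "))
  }
  structure(list(kind = kind, terms = terms), class = "nuisance_spec")
}

#' Fit the competing-event nuisance model
#'
#' Estimates `pi_tilde(a, l)` from point-treatment data according to a
#' [nuisance_spec()]. The saturated fit returns the empirical proportion of
#' `D = 1` in each populated `(a, l)` cell (unpopulated cells are `NA` and
#' only raise an error if an estimator later needs them). The logistic fit
#' maximizes the binomial likelihood over the requested terms and predicts
#' all four cells.
#'
#' @param data a `point_data` data frame (columns `l, a, d, y`).
#' @param spec a [nuisance_spec()]; default saturated.
#' @return An object of class `fitted_nuisance` with elements `pi_hat`
#'   (2x2 matrix over `a` by `l`), `cell_n` (record counts), `coef`
#'   (logistic coefficients, or `NULL` for saturated) and `spec`.
#' @examples
#' p <- dgp_params(0.1, 0.5, c(-1, -2, 1, 3, 0, 0, 0), c(-1, 0.5, 0.5, 0, 0, 0, 0))
#' d <- generate_point_data(p, 2000, seed = 2)
#' fit_nuisance(d)$pi_hat
#' @export
fit_nuisance <- function(data, spec = nuisance_spec()) {
  data <- as_point_data(as.data.frame(data))
  stopifnot(inherits(spec, "nuisance_spec"))
  if (nrow(data) == 0L) stop("cannot fit nuisance model on empty data")
  cell <- data$a * 2L + data$l + 1L
  cell_n <- matrix(tabulate(cell, 4L), 2, 2, byrow = TRUE,
                   dimnames = list(a = c("0", "1"), l = c("0", "1")))
  if (spec$kind == "saturated") {
    d_n <- matrix(tabulate(cell[data$d == 1L], 4L), 2, 2, byrow = TRUE,
                  dimnames = dimnames(cell_n))
    pi_hat <- ifelse(cell_n > 0, d_n / cell_n, NA_real_)
    coefs <- NULL
  } else {
    rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
    fit <- stats::glm(stats::as.formula(paste("d ~", rhs)),
                      family = stats::binomial(), data = data)
    if (!fit$converged) stop("logistic nuisance fit did not converge")
    pi_hat <- matrix(stats::predict(fit, newdata = data.frame(
      a = c(0, 0, 1, 1), l = c(0, 1, 0, 1)), type = "response"),
      2, 2, byrow = TRUE, dimnames = dimnames(cell_n))
    coefs <- stats::coef(fit)
  }
  structure(list(pi_hat = pi_hat, cell_n = cell_n, coef = coefs, spec = spec),
            class = "fitted_nuisance")
}

#' @export
print.fitted_nuisance <- function(x, ...) {
  cat(sprintf("Fitted competing-event nuisance model (%s)\n", x$spec$kind))
  cat("  pi_hat(a, l):\n")
  print(signif(x$pi_hat, 4))
  invisible(x)
}

# Look up pi_hat for each record's (arm, l); error on inestimable cells.
predict_cells <- function(fit, arm, l, what) {
  p <- fit$pi_hat[cbind(arm + 1L, l + 1L)]
  if (any(is.na(p))) {
    bad <- unique(paste0("(a=", arm[is.na(p)], ", l=", l[is.na(p)], ")"))
    stop("inestimable nuisance cell(s) needed by ", what, ": ",
         paste(bad, collapse = ", "))
  }
  p
}

new_estimate_result <- function(label, aD, arm_means, arm_n, estimate, wts) {
  structure(list(label = label, aD = aD,
                 arm_means = arm_means, arm_n = arm_n,
                 estimate = estimate,
                 max_weight = if (length(wts)) max(wts) else NA_real_,
                 mean_weight = if (length(wts)) mean(wts) else NA_real_),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s%s: estimate = %.4f (arm1 %.4f - arm0 %.4f; n = %d/%d; max weight %.2f)\n",
              x$label, if (!is.null(x$aD) && !is.na(x$aD)) sprintf("[aD=%d]", x$aD) else "",
              x$estimate, x$arm_means[["a1"]], x$arm_means[["a0"]],
              x$arm_n[["a1"]], x$arm_n[["a0"]], x$max_weight))
  invisible(x)
}

#' Inverse-probability-of-censoring-weighted estimator
#'
#' Treats records with a competing event (`d = 1`) as censored and
#' reweights the uncensored by the inverse of their estimated probability
#' of remaining free of the competing event. Each arm's component is the
#' plain sample average, over all records with `A = a`, of
#' `y * I(d = 0) / (1 - pi_hat(a, l))`; the estimate is the arm-1 minus
#' arm-0 component. No renormalization and no weight truncation are
#' applied. The statistical target of this estimator is the
#' controlled-direct-effect functional `CDEobs`.
#'
#' @param data a `point_data` data frame.
#' @param fit a [fit_nuisance()] result on (typically) the same data.
#' @return An `estimate_result` with the point estimate, per-arm weighted
#'   means and sizes, and weight diagnostics over contributing
#'   (uncensored) records.
#' @export
ipcw_cde_hat <- function(data, fit) {
  data <- as_point_data(as.data.frame(data))
  stopifnot(inherits(fit, "fitted_nuisance"))
  pih <- predict_cells(fit, data$a, data$l, "the censoring weights")
  surv <- 1 - pih
  if (any(surv <= 0)) {
    bad <- unique(paste0("(a=", data$a, ", l=", data$l, ")")[surv <= 0])
    stop("positivity failure: estimated survivor probability is 0 in cell(s) ",
         paste(bad, collapse = ", "))
  }
  contrib <- ifelse(data$d == 0L, data$y / surv, 0)
  arm_means <- c(a0 = mean(contrib[data$a == 0L]), a1 = mean(contrib[data$a == 1L]))
  arm_n <- c(a0 = sum(data$a == 0L), a1 = sum(data$a == 1L))
  wts <- (1 / surv)[data$d == 0L]
  new_estimate_result("IPCW-CDE", NA_integer_, arm_means, arm_n,
                      arm_means[["a1"]] - arm_means[["a0"]], wts)
}

#' Separable-effect weighted estimator
#'
#' The alternative inverse-probability-weighted estimator built for a
#' separable direct effect with the competing-event treatment component
#' held at `aD`. Each arm's component is the sample average, over all
#' records with `A = a`, of
#' `y * (1 - pi_hat(aD, l)) / (1 - pi_hat(a, l))`; the estimate is the
#' arm-1 minus arm-0 component. Because `y = 0` whenever `d = 1`, no
#' explicit censoring indicator is needed. The weights are ratios of
#' survivor probabilities, so they stay bounded when both arms share a
#' small survivor probability — the source of this estimator's robustness
#' to near positivity violations. Its statistical target is
#' `SDEobs^{aD}`.
#'
#' @inheritParams ipcw_cde_hat
#' @param aD arm (0 or 1) at which the competing-event component is held.
#' @return An `estimate_result` with weight diagnostics over all records.
#' @export
ipw_sde_hat <- function(data, fit, aD) {
  data <- as_point_data(as.data.frame(data))
  stopifnot(inherits(fit, "fitted_nuisance"), aD %in% c(0, 1))
  stopifnot(all(data$y[data$d == 1L] == 0L))
  surv_own <- 1 - predict_cells(fit, data$a, data$l, "the separable-effect weights")
  surv_aD <- 1 - predict_cells(fit, rep(as.integer(aD), nrow(data)), data$l,
                               "the separable-effect weights")
  if (any(surv_own <= 0 & surv_aD > 0)) {
    bad <- unique(paste0("(a=", data$a, ", l=", data$l, ")")[surv_own <= 0 & surv_aD > 0])
    stop("positivity failure: estimated survivor probability is 0 in cell(s) ",
         paste(bad, collapse = ", "))
  }
  w <- ifelse(surv_aD == 0, 0, surv_aD / surv_own)
  contrib <- data$y * w
  arm_means <- c(a0 = mean(contrib[data$a == 0L]), a1 = mean(contrib[data$a == 1L]))
  arm_n <- c(a0 = sum(data$a == 0L), a1 = sum(data$a == 1L))
  new_estimate_result("IPW-SDE", as.integer(aD), arm_means, arm_n,
                      arm_means[["a1"]] - arm_means[["a0"]], w)
}

#' Weight diagnostics for either estimator
#'
#' Summarizes the weights the named estimator would apply: maximum, mean
#' and 99th percentile over contributing records (uncensored records for
#' the censoring weights; all records for the separable-effect ratio
#' weights). Extreme maxima signal near positivity violations.
#'
#' @inheritParams ipcw_cde_hat
#' @param estimator `"ipcw"` or `"sde"`.
#' @param aD required when `estimator = "sde"`.
#' @return Named numeric vector `c(max, mean, q99)`.
#' @examples
#' p <- dgp_params(0.1, 0.5, c(-1, -2, 1, 3, 0, 0, 0), c(-1, 0.3, 7, 0, 0, 0, 0))
#' d <- generate_point_data(p, 5000, seed = 3)
#' f <- fit_nuisance(d)
#' weight_summary(d, f, "ipcw")
#' weight_summary(d, f, "sde", aD = 0)
#' @export
weight_summary <- function(data, fit, estimator = c("ipcw", "sde"), aD = NULL) {
  data <- as_point_data(as.data.frame(data))
  stopifnot(inherits(fit, "fitted_nuisance"))
  estimator <- match.arg(estimator)
  if (estimator == "ipcw") {
    keep <- data$d == 0L
    surv <- 1 - predict_cells(fit, data$a[keep], data$l[keep], "the censoring weights")
    w <- 1 / surv
  } else {
    if (is.null(aD) || !aD %in% c(0, 1)) stop("'aD' must be 0 or 1 for the sde weights")
    surv_own <- 1 - predict_cells(fit, data$a, data$l, "the separable-effect weights")
    surv_aD <- 1 - predict_cells(fit, rep(as.integer(aD), nrow(data)), data$l,
                                 "the separable-effect weights")
    w <- ifelse(surv_aD == 0, 0, surv_aD / surv_own)
  }
  if (any(!is.finite(w))) stop("infinite weight: positivity failure")
  c(max = max(w), mean = mean(w),
    q99 = unname(stats::quantile(w, 0.99, names = FALSE, type = 7)))
}
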