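#' Marginalized competing-event probability
#'
#' Computes `pi_tilde(a, l) = Pr(D = 1 | A = a, L = l)` exactly under the
#' data-generating process, marginalizing [pi0()] over the unmeasured `U`:
#' `sum_u pi0(a, l, u) Pr(U = u)`. This is the population version of the
#' nuisance function the weighted estimators fit from data.
#'
#' @inheritParams mu0
#' @return Probabilities, vectorized over `a` and `l`.
#' @export
pi_tilde_true <- function(a, l, params) {
  stopifnot(inherits(params, "dgp_params"))
  check_binary(a = a, l = l)
  (1 - params$pU) * pi0(a, l, 0, params) + params$pU * pi0(a, l, 1, params)
}

# Pr(Y = 1 | A = a, D = 0, L = l) under the observed-data law, by
# enumeration over u. Returns NA when Pr(D = 0 | a, l) is numerically zero.
cond_y_given_d0 <- function(a, l, params) {
  pu <- c(1 - params$pU, params$pU)
  num <- sum(pu * mu0(a, l, 0:1, params) * (1 - pi0(a, l, 0:1, params)))
  den <- sum(pu * (1 - pi0(a, l, 0:1, params)))
  if (den <= 0) return(NA_real_)
  num / den
}

new_target_values <- function() {
  structure(list(
    psi0_cde = c(a0 = NA_real_, a1 = NA_real_),
    psi0_sde = matrix(NA_real_, 2, 2,
                      dimnames = list(aY = c("0", "1"), aD = c("0", "1"))),
    psi_tilde_cde = c(a0 = NA_real_, a1 = NA_real_),
    psi_tilde_sde = matrix(NA_real_, 2, 2,
                           dimnames = list(aY = c("0", "1"), aD = c("0", "1"))),
    cde0 = NA_real_, sde0_aD0 = NA_real_, sde0_aD1 = NA_real_,
    cdeobs = NA_real_, sdeobs_aD0 = NA_real_, sdeobs_aD1 = NA_real_,
    total_effect_obs = NA_real_,
    undefined = character(0)),
    class = "target_values")
}

#' True causal targets under the data-generating process
#'
#' Computes, exactly by enumeration over the discrete `(L, U)` support, the
#' counterfactual risks and the two direct-effect contrasts:
#'
#' * controlled risks `Pr(Y^{a, d=0} = 1) = sum_{l,u} mu0(a,l,u) Pr(L=l) Pr(U=u)`
#'   and the controlled direct effect `CDE0` (their `a = 1` minus `a = 0`
#'   contrast) — the effect under universal elimination of competing events;
#' * separable risks `Pr(Y^{aY, aD} = 1) =
#'   sum_{l,u} mu0(aY,l,u) (1 - pi0(aD,l,u)) Pr(L=l) Pr(U=u)` and the
#'   separable direct effects `SDE0^{aD}` for `aD` in `{0, 1}` — effects of
#'   the treatment component acting on the event of interest, holding the
#'   component acting on the competing event at `aD`.
#'
#' `L` and `U` are independent under this law.
#'
#' @param params a [dgp_params()] object.
#' @return A `target_values` object with the true-risk fields filled.
#' @seealso [observed_targets()], [causal_targets()]
#' @export
true_targets <- function(params) {
  stopifnot(inherits(params, "dgp_params"))
  tv <- new_target_values()
  cells <- expand.grid(l = 0:1, u = 0:1)
  w <- ifelse(cells$l == 1, params$pL, 1 - params$pL) *
    ifelse(cells$u == 1, params$pU, 1 - params$pU)
  for (a in 0:1)
    tv$psi0_cde[a + 1L] <- sum(w * mu0(a, cells$l, cells$u, params))
  for (aY in 0:1) for (aD in 0:1)
    tv$psi0_sde[aY + 1L, aD + 1L] <-
      sum(w * mu0(aY, cells$l, cells$u, params) *
            (1 - pi0(aD, cells$l, cells$u, params)))
  tv$cde0 <- tv$psi0_cde[["a1"]] - tv$psi0_cde[["a0"]]
  tv$sde0_aD0 <- tv$psi0_sde["1", "0"] - tv$psi0_sde["0", "0"]
  tv$sde0_aD1 <- tv$psi0_sde["1", "1"] - tv$psi0_sde["0", "1"]
  tv
}

#' Observed-data identifying functionals
#'
#' Computes, exactly under the data-generating process, the functionals of
#' the observed-data law `(L, A, D, Y)` that the two weighted estimators
#' converge to (their statistical targets):
#'
#' * `psi_tilde_cde(a) = sum_l Pr(Y=1 | A=a, D=0, L=l) Pr(L=l)` and the
#'   contrast `CDEobs`;
#' * `psi_tilde_sde(aY, aD) = sum_l Pr(Y=1 | A=aY, D=0, L=l)
#'   (1 - pi_tilde(aD, l)) Pr(L=l)` and the contrasts `SDEobs^{aD}`;
#' * the identified total effect `Pr(Y=1 | A=1) - Pr(Y=1 | A=0)`.
#'
#' When both event processes depend on the unmeasured `U`, these differ
#' from the causal targets of [true_targets()]; the difference is the
#' non-identification error. A functional whose positivity condition fails
#' (a survivor probability of numerically zero in a required
#' treatment-covariate cell) is not silently computed: its fields are `NA`
#' and its name is recorded in the `undefined` element of the result.
#'
#' @param params a [dgp_params()] object.
#' @return A `target_values` object with the observed-functional fields
#'   filled, and `undefined` naming any functional lost to positivity
#'   failure.
#' @export
observed_targets <- function(params) {
  stopifnot(inherits(params, "dgp_params"))
  tv <- new_target_values()
  pl <- c(1 - params$pL, params$pL)
  reach_l <- which(pl > 0) - 1L          # reachable covariate levels
  reach_a <- which(c(1 - params$pA, params$pA) > 0) - 1L
  surv <- outer(0:1, 0:1, function(a, l) 1 - pi_tilde_true(a, l, params))
  dimnames(surv) <- list(a = c("0", "1"), l = c("0", "1"))
  condy <- outer(0:1, 0:1, Vectorize(function(a, l) cond_y_given_d0(a, l, params)))

  # total effect: Pr(Y=1 | A=a) = sum_l Pr(L=l) * Pr(Y=1 | a, l), with
  # Pr(Y=1 | a, l) = sum_u Pr(U=u) (1-pi0) mu0 (Y=0 under D=1)
  pu <- c(1 - params$pU, params$pU)
  pr_y <- function(a) sum(vapply(reach_l, function(l)
    pl[l + 1L] * sum(pu * (1 - pi0(a, l, 0:1, params)) * mu0(a, l, 0:1, params)),
    numeric(1)))
  if (all(0:1 %in% reach_a))
    tv$total_effect_obs <- pr_y(1) - pr_y(0)

  # controlled-direct-effect functional: needs survivor > 0 in every
  # reachable (a, l) cell
  cde_ok <- all(surv[reach_a + 1L, reach_l + 1L, drop = FALSE] > 0)
  if (cde_ok) {
    for (a in reach_a)
      tv$psi_tilde_cde[a + 1L] <-
        sum(pl[reach_l + 1L] * condy[a + 1L, reach_l + 1L])
    if (all(0:1 %in% reach_a))
      tv$cdeobs <- tv$psi_tilde_cde[["a1"]] - tv$psi_tilde_cde[["a0"]]
  } else {
    tv$undefined <- c(tv$undefined, "psi_tilde_cde", "cdeobs")
  }

  # separable-direct-effect functionals: a cell with survivor(aD, l) = 0
  # contributes zero weight, so only cells with survivor(aD, l) > 0 must
  # satisfy survivor(aY, l) > 0 (the weaker positivity condition)
  for (aD in 0:1) {
    ok <- TRUE
    vals <- matrix(NA_real_, 2, 2)
    for (aY in reach_a) {
      terms <- numeric(0)
      for (l in reach_l) {
        if (surv[aD + 1L, l + 1L] <= 0) {
          terms <- c(terms, 0)            # zero-weight stratum
        } else if (surv[aY + 1L, l + 1L] <= 0) {
          ok <- FALSE
        } else {
          terms <- c(terms, pl[l + 1L] * condy[aY + 1L, l + 1L] *
                       surv[aD + 1L, l + 1L])
        }
      }
      if (ok) vals[aY + 1L, aD + 1L] <- sum(terms)
    }
    if (ok) {
      tv$psi_tilde_sde[, aD + 1L] <- vals[, aD + 1L]
      if (all(0:1 %in% reach_a)) {
        contrast <- vals[2L, aD + 1L] - vals[1L, aD + 1L]
        if (aD == 0) tv$sdeobs_aD0 <- contrast else tv$sdeobs_aD1 <- contrast
      }
    } else {
      tv$undefined <- c(tv$undefined,
                        sprintf("psi_tilde_sde_aD%d", aD),
                        sprintf("sdeobs_aD%d", aD))
    }
  }
  tv
}

#' All causal and statistical targets of one data-generating process
#'
#' Convenience wrapper merging [true_targets()] and [observed_targets()]
#' into a single `target_values` object.
#'
#' @param params a [dgp_params()] object.
#' @return A fully populated `target_values` object.
#' @examples
#' p <- dgp_params(0.5, 0.5, c(-1, 1, 0.5, -0.5, 1, 0.5, 1),
#'                 c(-1, 1, 0.5, 0.5, 1, -0.5, 0.5))
#' tv <- causal_targets(p)
#' c(cde0 = tv$cde0, sde0_aD0 = tv$sde0_aD0, cdeobs = tv$cdeobs)
#' @export
causal_targets <- function(params) {
  tv <- true_targets(params)
  ob <- observed_targets(params)
  for (fld in c("psi_tilde_cde", "psi_tilde_sde", "cdeobs", "sdeobs_aD0",
                "sdeobs_aD1", "total_effect_obs", "undefined"))
    tv[[fld]] <- ob[[fld]]
  tv
}

#' @export
print.target_values <- function(x, ...) {
  cat("Causal and statistical targets\n")
  cat(sprintf("  CDE0      = %s   SDE0(aD=0) = %s   SDE0(aD=1) = %s\n",
              fmt_na(x$cde0), fmt_na(x$sde0_aD0), fmt_na(x$sde0_aD1)))
  cat(sprintf("  CDEobs    = %s   SDEobs(aD=0) = %s   SDEobs(aD=1) = %s\n",
              fmt_na(x$cdeobs), fmt_na(x$sdeobs_aD0), fmt_na(x$sdeobs_aD1)))
  if (length(x$undefined))
    cat("  undefined due to positivity:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

fmt_na <- function(v) if (is.na(v)) "undefined" else sprintf("% .4f", v)

#' @export
as.data.frame.target_values <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    psi0_cde_a0 = x$psi0_cde[["a0"]], psi0_cde_a1 = x$psi0_cde[["a1"]],
    psi0_sde_00 = x$psi0_sde["0", "0"], psi0_sde_10 = x$psi0_sde["1", "0"],
    psi0_sde_01 = x$psi0_sde["0", "1"], psi0_sde_11 = x$psi0_sde["1", "1"],
    cde0 = x$cde0, sde0_aD0 = x$sde0_aD0, sde0_aD1 = x$sde0_aD1,
    cdeobs = x$cdeobs, sdeobs_aD0 = x$sdeobs_aD0, sdeobs_aD1 = x$sdeobs_aD1,
    total_effect_obs = x$total_effect_obs,
    row.names = row.names)
}

#' Positivity diagnostics for the two weighting schemes
#'
#' Evaluates, under the data-generating process, the marginal
#' competing-event probabilities `pi_tilde(a, l)` for the four
#' treatment-covariate cells and the two positivity conditions they imply:
#'
#' * the censoring condition — every reachable `(a, l)` cell must have
#'   survivor probability `1 - pi_tilde(a, l) > 0` — required by the
#'   controlled-direct-effect functional; and
#' * the weaker separable condition for each `aD` — only cells whose
#'   `aD`-arm survivor probability is positive need a positive survivor
#'   probability in the other arm.
#'
#' A *near violation* is flagged when some reachable cell's survivor
#' probability is positive yet below `eps`.
#'
#' @param params a [dgp_params()] object.
#' @param eps near-violation threshold in (0, 1); default 0.05.
#' @return An object of class `positivity_report` with elements
#'   `pi_tilde` (2x2 matrix over `a` by `l`), `cde_condition_holds`,
#'   `sde_condition_holds` (named logical, per `aD`), `min_survivor_prob`,
#'   `near_violation`, and `eps`.
#' @export
positivity_report <- function(params, eps = 0.05) {
  stopifnot(inherits(params, "dgp_params"))
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1)
    stop("'eps' must be in (0, 1)")
  pit <- outer(0:1, 0:1, function(a, l) pi_tilde_true(a, l, params))
  dimnames(pit) <- list(a = c("0", "1"), l = c("0", "1"))
  reach_a <- which(c(1 - params$pA, params$pA) > 0)
  reach_l <- which(c(1 - params$pL, params$pL) > 0)
  surv <- 1 - pit
  rsurv <- surv[reach_a, reach_l, drop = FALSE]
  cde_ok <- all(rsurv > 0)
  sde_ok <- c(aD0 = TRUE, aD1 = TRUE)
  for (aD in 0:1) {
    for (l in reach_l) {
      if (surv[aD + 1L, l] > 0 && any(surv[reach_a, l] <= 0))
        sde_ok[aD + 1L] <- FALSE
    }
  }
  pos_surv <- rsurv[rsurv > 0]
  structure(list(
    pi_tilde = pit,
    cde_condition_holds = cde_ok,
    sde_condition_holds = sde_ok,
    min_survivor_prob = min(rsurv),
    near_violation = length(pos_surv) > 0 && min(pos_surv) < eps,
    eps = eps), class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Positivity report (competing-event survivor probabilities)\n")
  print(signif(1 - x$pi_tilde, 4))
  cat(sprintf("  censoring condition holds: %s\n", x$cde_condition_holds))
  cat(sprintf("  separable condition holds: aD=0 %s, aD=1 %s\n",
              x$sde_condition_holds[["aD0"]], x$sde_condition_holds[["aD1"]]))
  cat(sprintf("  min survivor prob = %.5f (near violation at eps=%g: %s)\n",
              x$min_survivor_prob, x$eps, x$near_violation))
  invisible(x)
}

#' Do the controlled and separable direct effects disagree in sign?
#'
#' `TRUE` when `CDE0` and `SDE0^{aD}` have strictly opposite signs — the
#' scenarios in which targeting the wrong estimand flips the direction of
#' the conclusion. A zero effect is treated as concordant with everything.
#'
#' @param tv a `target_values` object with true-risk fields filled.
#' @param aD which separable direct effect to compare against (0 or 1).
#' @return Logical scalar.
#' @export
sign_discordant <- function(tv, aD) {
  stopifnot(inherits(tv, "target_values"), aD %in% c(0, 1))
  sde <- if (aD == 0) tv$sde0_aD0 else tv$sde0_aD1
  if (is.na(tv$cde0) || is.na(sde)) stop("true targets not populated")
  (tv$cde0 > 0 && sde < 0) || (tv$cde0 < 0 && sde > 0)
}
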