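# Path-enumeration oracle for the discrete-time estimators' statistical
# targets under known generator hazards: expectation of the per-person
# weighted event sum, summing over covariate patterns and event-month
# paths without the cancellations the closed forms would allow.

oracle_trial_lp <- function(co, k, a, cov)
  co[["intercept"]] + co[["month"]] * k + co[["month2"]] * k^2 +
  co[["a"]] * a + co[["hgb_low"]] * cov$hgb_low +
  co[["age_mid"]] * (cov$age_group == 1) +
  co[["age_high"]] * (cov$age_group == 2) +
  co[["in_bed"]] * cov$in_bed + co[["hist_cvd"]] * cov$hist_cvd +
  co[["a_hist_cvd"]] * a * cov$hist_cvd

# One covariate pattern: expected weighted cumulative event sum by month t
# for a person in arm `arm`, for either estimator. For "sde" the weight in
# month k is prod_{j<=k} (1 - hd_j(aD)) / (1 - hd_j(arm)); for "ipcw" it is
# prod_{j<=k} 1 / (1 - hd_j(arm)).
oracle_curve_one <- function(d_coef, y_coef, cov, arm, months, K,
                             estimator, aD = NULL) {
  ks <- seq_len(K)
  hd_own <- oracle_expit(oracle_trial_lp(d_coef, ks, arm, cov))
  hy <- oracle_expit(oracle_trial_lp(y_coef, ks, arm, cov))
  w_num <- if (estimator == "ipcw") rep(1, K)
           else 1 - oracle_expit(oracle_trial_lp(d_coef, ks, aD, cov))
  # P(event of interest exactly in month k) = prod_{j<k} (1-hd)(1-hy)
  #   * (1-hd_k) * hy_k ; weight at k = prod_{j<=k} w_num_j / (1-hd_own_j)
  surv_prev <- c(1, cumprod((1 - hd_own) * (1 - hy)))[ks]
  p_event <- surv_prev * (1 - hd_own) * hy
  wt <- cumprod(w_num / (1 - hd_own))
  vapply(months, function(t) sum((p_event * wt)[ks <= t]), numeric(1))
}

oracle_trial_target <- function(d_coef, y_coef, covariate_prev, arm, months,
                                K, estimator, aD = NULL) {
  pats <- expand.grid(hgb_low = 0:1, age_group = 0:2, in_bed = 0:1,
                      hist_cvd = 0:1)
  pv <- covariate_prev
  wts <- ifelse(pats$hgb_low == 1, pv$hgb_low, 1 - pv$hgb_low) *
    pv$age_group[pats$age_group + 1] *
    ifelse(pats$in_bed == 1, pv$in_bed, 1 - pv$in_bed) *
    ifelse(pats$hist_cvd == 1, pv$hist_cvd, 1 - pv$hist_cvd)
  out <- rep(0, length(months))
  for (i in seq_len(nrow(pats)))
    out <- out + wts[i] * oracle_curve_one(d_coef, y_coef, pats[i, ], arm,
                                           months, K, estimator, aD)
  out
}

# Small constant-hazard trial coefficients for targeted tests.
flat_coefs <- function(intercept, a = 0, hist_cvd = 0, a_hist_cvd = 0)
  c(intercept = intercept, month = 0, month2 = 0, a = a, hgb_low = 0,
    age_mid = 0, age_high = 0, in_bed = 0, hist_cvd = hist_cvd,
    a_hist_cvd = a_hist_cvd)
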