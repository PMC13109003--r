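test_that("person-period validation enforces the monotone-exit structure", {
  ok <- data.frame(id = c(1, 1, 2), month = c(1, 2, 1), a = c(1, 1, 0),
                   d = c(0, 1, 0), y = c(0, 0, 1))
  expect_s3_class(person_period(ok), "person_period")
  # both events in one month
  bad1 <- ok; bad1$y[2] <- 1
  expect_error(person_period(bad1), "both")
  # rows continuing past the first event
  bad2 <- data.frame(id = 1, month = 1:3, a = 1,
                     d = c(0, 1, 0), y = c(0, 0, 0))
  expect_error(person_period(bad2), "first event")
  # months not consecutive from 1
  bad3 <- data.frame(id = 1, month = c(1, 3), a = 1, d = 0, y = c(0, 1))
  expect_error(person_period(bad3), "consecutive")
  # time-varying covariate
  bad4 <- data.frame(id = 1, month = 1:2, a = 1, hgb_low = c(0, 1),
                     d = 0, y = c(0, 1))
  expect_error(person_period(bad4), "constant")
})

test_that("person-period CSV round-trips with optional column mapping", {
  tr <- generate_synthetic_trial(n1 = 20, n0 = 20, K = 10, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_person_period(tr, f)
  back <- read_person_period(f)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  # a file with foreign column names loads through col_map
  alt <- as.data.frame(tr)
  names(alt)[names(alt) == "a"] <- "rx"
  names(alt)[names(alt) == "hgb_low"] <- "anemia"
  write.csv(alt, f, row.names = FALSE)
  mapped <- read_person_period(f, col_map = c(a = "rx", hgb_low = "anemia"))
  expect_equal(as.data.frame(mapped), as.data.frame(tr))
  unlink(f)
})

test_that("the synthetic trial generator honors degenerate and moderate hazards", {
  none <- flat_coefs(-40)
  tr0 <- generate_synthetic_trial(n1 = 15, n0 = 15, K = 8, d_coef = none,
                                  y_coef = none, seed = 1)
  expect_equal(sum(tr0$d), 0); expect_equal(sum(tr0$y), 0)
  expect_true(all(table(tr0$id) == 8))  # everyone administratively censored at K

  only_y <- generate_synthetic_trial(n1 = 50, n0 = 50, K = 8, d_coef = none,
                                     y_coef = flat_coefs(-2), seed = 2)
  expect_equal(sum(only_y$d), 0)
  expect_gt(sum(only_y$y), 0)

  # empirical discrete hazards within Monte Carlo error of the generator's
  hd <- plogis(-3.5); hy <- plogis(-3)
  tr <- generate_synthetic_trial(n1 = 5000, n0 = 5000, K = 6,
                                 d_coef = flat_coefs(-3.5),
                                 y_coef = flat_coefs(-3), seed = 3)
  for (k in c(1, 3, 6)) {
    at_risk <- tr[tr$month == k, ]
    n_k <- nrow(at_risk)
    expect_lt(abs(mean(at_risk$d) - hd), 4 * sqrt(hd * (1 - hd) / n_k))
    no_d <- at_risk[at_risk$d == 0, ]
    expect_lt(abs(mean(no_d$y) - hy), 4 * sqrt(hy * (1 - hy) / nrow(no_d)))
  }
})

test_that("pooled logistic hazard fits recover generator coefficients", {
  # intercept-only model on a constant hazard = pooled event fraction
  tr <- generate_synthetic_trial(n1 = 300, n0 = 300, K = 5,
                                 d_coef = flat_coefs(-3),
                                 y_coef = flat_coefs(-40), seed = 6)
  f0 <- fit_discrete_hazard(tr, hazard_model_spec("competing", d ~ 1))
  expect_equal(plogis(coef(f0$glm)[[1]]), mean(tr$d), tolerance = 1e-8)

  # full-model coefficient recovery within 4 SEs at n = 5000
  dco <- default_trial_coefs("competing")
  tr2 <- generate_synthetic_trial(n1 = 2500, n0 = 2500, K = 20, seed = 7)
  fit <- fit_discrete_hazard(tr2)
  co <- summary(fit$glm)$coefficients
  truth <- c("(Intercept)" = dco[["intercept"]], month = dco[["month"]],
             "I(month^2)" = dco[["month2"]], a = dco[["a"]],
             hgb_low = dco[["hgb_low"]],
             "factor(age_group)1" = dco[["age_mid"]],
             "factor(age_group)2" = dco[["age_high"]],
             in_bed = dco[["in_bed"]], hist_cvd = dco[["hist_cvd"]],
             "a:hist_cvd" = dco[["a_hist_cvd"]])
  for (nm in names(truth))
    expect_lt(abs(co[nm, "Estimate"] - truth[[nm]]), 4 * co[nm, "Std. Error"])
})

test_that("hazard fitting reports separation and refuses empty risk sets", {
  tr <- generate_synthetic_trial(n1 = 30, n0 = 30, K = 5,
                                 d_coef = flat_coefs(-40),
                                 y_coef = flat_coefs(-2), seed = 8)
  expect_warning(fit_discrete_hazard(tr, hazard_model_spec("competing", d ~ a)),
                 "separated")
  all_d1 <- person_period(data.frame(id = 1:3, month = 1, a = c(1, 0, 1),
                                     d = 1, y = 0))
  expect_error(fit_discrete_hazard(all_d1, hazard_model_spec("interest", y ~ 1)),
               "at risk")
})

test_that("without competing events both curves equal the empirical cumulative incidence", {
  tr <- generate_synthetic_trial(n1 = 150, n0 = 150, K = 12,
                                 d_coef = flat_coefs(-40),
                                 y_coef = flat_coefs(-2.5, a = -0.5), seed = 9)
  months <- c(3, 6, 12)
  suppressWarnings(hf <- fit_discrete_hazard(tr))
  for (arm in 0:1) {
    n_arm <- length(unique(tr$id[tr$a == arm]))
    crude <- sapply(months, function(t)
      sum(tr$y[tr$a == arm & tr$month <= t]) / n_arm)
    expect_equal(as.numeric(ipcw_risk_curve(tr, hf, arm, months)), crude,
                 tolerance = 1e-8)
    expect_equal(as.numeric(sde_risk_curve(tr, hf, arm, aD = 0, months)), crude,
                 tolerance = 1e-8)
    expect_equal(as.numeric(sde_risk_curve(tr, hf, arm, aD = 1, months)), crude,
                 tolerance = 1e-8)
  }
})

test_that("curves are monotone, collapse at aD = aY, and handle empty month lists", {
  tr <- generate_synthetic_trial(seed = 10)
  hf <- fit_discrete_hazard(tr)
  months <- 1:50
  for (arm in 0:1) {
    ric <- ipcw_risk_curve(tr, hf, arm, months)
    expect_true(all(diff(ric) >= -1e-12))
    for (aD in 0:1) {
      rsc <- sde_risk_curve(tr, hf, arm, aD, months)
      expect_true(all(diff(rsc) >= -1e-12))
      expect_true(all(rsc >= 0 & rsc <= 1))
    }
    # aD = aY: weights cancel, exactly the crude cumulative incidence
    n_arm <- length(unique(tr$id[tr$a == arm]))
    crude <- sapply(months, function(t)
      sum(tr$y[tr$a == arm & tr$month <= t]) / n_arm)
    expect_equal(as.numeric(sde_risk_curve(tr, hf, arm, aD = arm, months)),
                 crude, tolerance = 1e-10)
  }
  empty <- ipcw_risk_curve(tr, hf, 1, integer(0))
  expect_length(empty, 0)
})

test_that("a two-month toy matches hand-computed weighted sums", {
  # one binary covariate ("hgb_low"), saturated-in-(month, arm) hazard model;
  # fitted hazards are then per-cell event fractions and the curves can be
  # recomputed by hand from the cell tables.
  set.seed(14)
  n <- 400
  df <- data.frame(id = 1:n, a = rep(0:1, each = n / 2),
                   hgb_low = rbinom(n, 1, 0.5))
  rows <- list()
  for (i in seq_len(n)) {
    hd <- c(0.3, 0.15)[df$a[i] + 1]; hy <- 0.2 + 0.1 * df$hgb_low[i]
    for (k in 1:2) {
      d <- rbinom(1, 1, hd); y <- if (d == 0) rbinom(1, 1, hy) else 0L
      rows[[length(rows) + 1]] <- data.frame(id = i, month = k, a = df$a[i],
                                             hgb_low = df$hgb_low[i], d = d, y = y)
      if (d == 1 || y == 1) break
    }
  }
  tr <- person_period(do.call(rbind, rows))
  hf <- fit_discrete_hazard(tr, hazard_model_spec("competing", d ~ factor(month) * a))
  # hand-computed fitted hazards: event fractions among at-risk rows
  frac <- function(k, arm) {
    at <- tr[tr$month == k & tr$a == arm, ]; mean(at$d)
  }
  for (arm in 0:1) {
    w1 <- 1 / (1 - frac(1, arm)); w2 <- w1 / (1 - frac(2, arm))
    n_arm <- sum(tr$month == 1 & tr$a == arm)
    hand <- c(sum(tr$y[tr$a == arm & tr$month == 1]) * w1,
              sum(tr$y[tr$a == arm & tr$month == 2]) * w2)
    expect_equal(as.numeric(ipcw_risk_curve(tr, hf, arm, 1:2)),
                 cumsum(hand) / n_arm, tolerance = 1e-10)
    # separable-effect weights: ratio of the aD-arm to own-arm survivors
    aD <- 1 - arm
    v1 <- (1 - frac(1, aD)) / (1 - frac(1, arm))
    v2 <- v1 * (1 - frac(2, aD)) / (1 - frac(2, arm))
    hand_s <- c(sum(tr$y[tr$a == arm & tr$month == 1]) * v1,
                sum(tr$y[tr$a == arm & tr$month == 2]) * v2)
    expect_equal(as.numeric(sde_risk_curve(tr, hf, arm, aD, 1:2)),
                 cumsum(hand_s) / n_arm, tolerance = 1e-10)
  }
})

test_that("curve contrasts converge to the path-enumeration statistical targets", {
  pv <- list(hgb_low = 0.4, age_group = c(0.25, 0.5, 0.25),
             in_bed = 0.1, hist_cvd = 0.4)
  dco <- default_trial_coefs("competing"); yco <- default_trial_coefs("interest")
  tr <- generate_synthetic_trial(n1 = 20000, n0 = 20000, K = 12,
                                 covariate_prev = pv, seed = 15)
  hf <- fit_discrete_hazard(tr)
  months <- c(6, 12)
  for (est in c("ipcw", "sde")) {
    aD <- if (est == "sde") 0 else NULL
    t1 <- oracle_trial_target(dco, yco, pv, 1, months, 12, est, aD)
    t0 <- oracle_trial_target(dco, yco, pv, 0, months, 12, est, aD)
    got1 <- if (est == "ipcw") ipcw_risk_curve(tr, hf, 1, months)
            else sde_risk_curve(tr, hf, 1, aD, months)
    got0 <- if (est == "ipcw") ipcw_risk_curve(tr, hf, 0, months)
            else sde_risk_curve(tr, hf, 0, aD, months)
    expect_lt(max(abs((as.numeric(got1) - as.numeric(got0)) - (t1 - t0))),
              0.02)
  }
})

test_that("bootstrap intervals are reproducible and degenerate data give zero width", {
  tr <- generate_synthetic_trial(n1 = 60, n0 = 60, K = 10, seed = 16)
  b1 <- bootstrap_contrasts(tr, "sde", aD = 0, months = c(5, 10), B = 12, seed = 33)
  b2 <- bootstrap_contrasts(tr, "sde", aD = 0, months = c(5, 10), B = 12, seed = 33)
  expect_identical(b1$ci_lower, b2$ci_lower)
  expect_identical(b1$contrast, b2$contrast)
  expect_true(all(b1$ci_lower <= b1$ci_upper))

  # no events of interest anywhere: contrast 0 on every resample
  none_y <- generate_synthetic_trial(n1 = 40, n0 = 40, K = 6,
                                     y_coef = flat_coefs(-40), seed = 17)
  b0 <- bootstrap_contrasts(none_y, "ipcw", months = c(3, 6), B = 8, seed = 2)
  expect_equal(b0$contrast, c(0, 0))
  expect_equal(b0$ci_lower, b0$ci_upper)
  expect_equal(b0$n_failed, 0L)
})

test_that("bootstrap interval coverage is near nominal on synthetic trials", {
  pv <- list(hgb_low = 0.4, age_group = c(0.25, 0.5, 0.25),
             in_bed = 0.1, hist_cvd = 0.4)
  dco <- default_trial_coefs("competing"); yco <- default_trial_coefs("interest")
  K <- 10; month <- 10
  truth <- oracle_trial_target(dco, yco, pv, 1, month, K, "sde", 0) -
    oracle_trial_target(dco, yco, pv, 0, month, K, "sde", 0)
  hits <- 0L; outer_reps <- 40
  for (r in seq_len(outer_reps)) {
    tr <- generate_synthetic_trial(n1 = 150, n0 = 150, K = K, seed = 4000 + r)
    bc <- bootstrap_contrasts(tr, "sde", aD = 0, months = month, B = 100,
                              seed = 8000 + r)
    if (bc$ci_lower <= truth && truth <= bc$ci_upper) hits <- hits + 1L
  }
  # nominal 95%; allow small-sample/percentile slack (4 binomial SDs)
  expect_gte(hits / outer_reps, 0.80)
})
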