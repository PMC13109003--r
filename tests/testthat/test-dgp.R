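base_params <- function(theta = c(-1, -2, 1, 3, 0, 0, 0),
                        beta = c(-1, 0.5, 0.5, 0, 0, 0, 0),
                        pL = 0.1, pU = 0.5)
  dgp_params(pL = pL, pU = pU, theta = theta, beta = beta)

test_that("conditional event models evaluate the stated logistic forms", {
  p0 <- base_params(theta = rep(0, 7), beta = rep(0, 7))
  g <- expand.grid(a = 0:1, l = 0:1, u = 0:1)
  expect_equal(mu0(g$a, g$l, g$u, p0), rep(0.5, 8))
  expect_equal(pi0(g$a, g$l, g$u, p0), rep(0.5, 8))

  p <- base_params()
  expect_equal(mu0(1, 1, 0, p), plogis(-1 - 2 + 1 + 3))
  pr <- base_params(beta = c(-9, 0, 0, 0, 0, 0, 0))
  expect_equal(pi0(1, 1, 1, pr), plogis(-9))

  # logistic monotonicity in the intercept
  mus <- sapply(c(-2, -5, -10, -20), function(t0)
    mu0(0, 0, 0, base_params(theta = c(t0, rep(0, 6)))))
  expect_true(all(diff(mus) < 0))

  # u has no effect when its coefficients vanish
  expect_equal(pi0(1, 0, 0, p), pi0(1, 0, 1, p))
})

test_that("malformed parameters and inputs are rejected", {
  expect_error(dgp_params(1.2, 0.5, rep(0, 7), rep(0, 7)), "pL")
  expect_error(dgp_params(0.5, 0.5, rep(0, 6), rep(0, 7)), "theta")
  expect_error(dgp_params(0.5, 0.5, rep(0, 7), c(rep(0, 6), Inf)), "beta")
  p <- base_params()
  expect_error(mu0(2, 0, 0, p), "binary")
  expect_error(pi0(0, 0.5, 0, p), "binary")
  expect_error(generate_point_data(p, -1, seed = 1), "nonnegative")
})

test_that("sampling is deterministic, respects the DGP and the competing-event determinism", {
  p <- base_params()
  expect_equal(nrow(generate_point_data(p, 0, seed = 1)), 0L)

  d1 <- generate_point_data(p, 500, seed = 42)
  d2 <- generate_point_data(p, 500, seed = 42)
  expect_identical(d1, d2)
  expect_false(identical(d1, generate_point_data(p, 500, seed = 43)))

  # degenerate hazard: competing event never occurs
  p_no_d <- base_params(beta = c(-20, rep(0, 6)))
  expect_true(all(generate_point_data(p_no_d, 2000, seed = 1)$d == 0))

  big <- generate_point_data(p, 1e5, seed = 7)
  expect_equal(sum(big$d == 1 & big$y == 1), 0L)
  se_l <- sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(mean(big$l) - 0.1), 4 * se_l)
})

test_that("sampled frequencies match the joint law cell by cell", {
  p <- dgp_params(0.3, 0.5, c(-1, -2, 1, 3, 1, -0.5, 0.5),
                  c(-1, 0.5, 0.5, 0, 1, 0.5, -0.5))
  d <- generate_point_data(p, 5e4, seed = 11)
  # (u, l, a) independence: chi-square GOF against product of marginals
  cell <- d$u * 4 + d$l * 2 + d$a + 1
  g <- expand.grid(a = 0:1, l = 0:1, u = 0:1)
  probs <- ifelse(g$u == 1, 0.5, 0.5) * ifelse(g$l == 1, 0.3, 0.7) * 0.5
  probs <- probs[order(g$u * 4 + g$l * 2 + g$a)]
  gof <- chisq.test(tabulate(cell, 8), p = probs)
  expect_gt(gof$p.value, 1e-4)
  # empirical Pr(D = 1 | a, l, u) within 4 binomial SEs of pi0 in all cells
  for (i in seq_len(8)) {
    idx <- d$u == g$u[i] & d$l == g$l[i] & d$a == g$a[i]
    pihat <- mean(d$d[idx])
    pi_true <- pi0(g$a[i], g$l[i], g$u[i], p)
    expect_lt(abs(pihat - pi_true),
              4 * sqrt(pi_true * (1 - pi_true) / sum(idx)))
  }
})

test_that("point-data CSV round-trips, with u optional and invalid rows rejected", {
  p <- base_params()
  d <- generate_point_data(p, 50, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_point_data(d, f)
  expect_equal(as.data.frame(read_point_data(f)), as.data.frame(d))
  # u column optional on read
  d2 <- d[, c("l", "a", "d", "y")]
  write.csv(d2, f, row.names = FALSE)
  rd <- read_point_data(f)
  expect_true(all(is.na(rd$u)))
  expect_equal(rd$y, d$y)
  # competing-event determinism enforced on read
  bad <- d; bad$d[1] <- 1L; bad$y[1] <- 1L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_point_data(f), "y must be 0")
  unlink(f)
})

test_that("the six packaged scenarios validate against their flags", {
  ps <- scenario_presets()
  expect_length(ps, 6L)
  flags <- t(sapply(ps, function(s) c(s$near_positivity_violation,
                                      s$u_dependence, s$rare_competing_event)))
  # the studied factorial rows: violation no/yes x U no/yes x rare
  expect_equal(unname(rowSums(flags[, 1, drop = FALSE])), c(0, 0, 0, 1, 1, 1))
  for (s in ps) {
    expect_silent(validate_scenario(s))
    expect_equal(unname(s$params$theta[1:4]), c(-1, -2, 1, 3))
    expect_equal(s$params$pL, 0.1)
    expect_equal(s$params$pU, 0.5)
    if (!s$u_dependence)
      expect_true(all(c(s$params$theta[5:7], s$params$beta[5:7]) == 0))
    rep <- positivity_report(s$params)
    expect_equal(rep$near_violation, s$near_positivity_violation)
  }
})

test_that("a config with wrong coefficient arity is rejected", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("scenarios:",
               "  - name: bad",
               "    theta: [0, 0, 0]",
               "    beta: [0, 0, 0, 0, 0, 0, 0]",
               "    flags: {near_positivity_violation: false, u_dependence: false, rare_competing_event: false}"),
             f)
  expect_error(scenario_presets(f), "7 entries")
  unlink(f)
})

test_that("inconsistent scenario flags are caught by validation", {
  p <- base_params()
  s <- scenario("wrong", p, near_positivity_violation = TRUE,
                u_dependence = FALSE, rare_competing_event = FALSE)
  expect_error(validate_scenario(s), "near-violation")
  s2 <- scenario("wrong2", p, near_positivity_violation = FALSE,
                 u_dependence = TRUE, rare_competing_event = FALSE)
  expect_error(validate_scenario(s2), "u_dependence")
})
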