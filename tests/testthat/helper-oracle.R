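# Independent brute-force oracles. These deliberately avoid the package's
# computation paths: observed-data functionals are derived by conditioning
# on the exhaustively enumerated joint probability table of (u, l, a, d, y),
# and counterfactual risks by direct probability-tree sums written out here.

oracle_expit <- function(x) 1 / (1 + exp(-x))

oracle_lp <- function(co, a, l, u)
  co[1] + co[2] * a + co[3] * l + co[4] * a * l + co[5] * u + co[6] * a * u +
  co[7] * l * u

# Full joint law of one record as a 32-row table with column p.
oracle_joint <- function(params) {
  tab <- expand.grid(u = 0:1, l = 0:1, a = 0:1, d = 0:1, y = 0:1)
  pu <- ifelse(tab$u == 1, params$pU, 1 - params$pU)
  pl <- ifelse(tab$l == 1, params$pL, 1 - params$pL)
  pa <- ifelse(tab$a == 1, params$pA, 1 - params$pA)
  mu <- oracle_expit(oracle_lp(params$theta, tab$a, tab$l, tab$u))
  pi <- oracle_expit(oracle_lp(params$beta, tab$a, tab$l, tab$u))
  pdy <- ifelse(tab$d == 1, pi * (tab$y == 0),
                (1 - pi) * ifelse(tab$y == 1, mu, 1 - mu))
  tab$p <- pu * pl * pa * pdy
  tab
}

# Observed-data functionals by conditioning on the joint table.
oracle_observed <- function(params) {
  tab <- oracle_joint(params)
  pr <- function(cond) sum(tab$p[cond])
  pi_tilde <- function(a, l) pr(tab$a == a & tab$l == l & tab$d == 1) /
    pr(tab$a == a & tab$l == l)
  cond_y <- function(a, l) pr(tab$a == a & tab$l == l & tab$d == 0 & tab$y == 1) /
    pr(tab$a == a & tab$l == l & tab$d == 0)
  pl <- c(1 - params$pL, params$pL)
  psi_cde <- function(a) sum(sapply(0:1, function(l) pl[l + 1] * cond_y(a, l)))
  psi_sde <- function(aY, aD) sum(sapply(0:1, function(l)
    pl[l + 1] * cond_y(aY, l) * (1 - pi_tilde(aD, l))))
  list(pi_tilde = outer(0:1, 0:1, Vectorize(pi_tilde)),
       cdeobs = psi_cde(1) - psi_cde(0),
       sdeobs_aD0 = psi_sde(1, 0) - psi_sde(0, 0),
       sdeobs_aD1 = psi_sde(1, 1) - psi_sde(0, 1),
       total = pr(tab$a == 1 & tab$y == 1) / pr(tab$a == 1) -
         pr(tab$a == 0 & tab$y == 1) / pr(tab$a == 0))
}

# Counterfactual risks by direct probability-tree evaluation.
oracle_true <- function(params) {
  cells <- expand.grid(l = 0:1, u = 0:1)
  w <- ifelse(cells$l == 1, params$pL, 1 - params$pL) *
    ifelse(cells$u == 1, params$pU, 1 - params$pU)
  mu <- function(a) oracle_expit(oracle_lp(params$theta, a, cells$l, cells$u))
  pi <- function(a) oracle_expit(oracle_lp(params$beta, a, cells$l, cells$u))
  psi0_cde <- function(a) sum(w * mu(a))
  psi0_sde <- function(aY, aD) sum(w * mu(aY) * (1 - pi(aD)))
  list(cde0 = psi0_cde(1) - psi0_cde(0),
       sde0_aD0 = psi0_sde(1, 0) - psi0_sde(0, 0),
       sde0_aD1 = psi0_sde(1, 1) - psi0_sde(0, 1))
}

# Random parameter draws for property tests.
rand_params <- function(seed, zero_theta_u = FALSE, zero_beta_u = FALSE,
                        range = 2, pL = NULL, pU = NULL) {
  set.seed(seed)
  th <- round(runif(7, -range, range), 3)
  be <- round(runif(7, -range, range), 3)
  if (zero_theta_u) th[5:7] <- 0
  if (zero_beta_u) be[5:7] <- 0
  dgp_params(pL = if (is.null(pL)) round(runif(1, 0.05, 0.95), 3) else pL,
             pU = if (is.null(pU)) round(runif(1, 0.05, 0.95), 3) else pU,
             theta = th, beta = be)
}

# The 8-record worked toy dataset: single stratum (l = 0), arm 1 has
# (d, y) = (0,1),(0,0),(0,0),(1,0), arm 0 has (0,1),(0,1),(1,0),(1,0).
toy_t1 <- function() {
  data.frame(l = 0L,
             a = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L),
             d = c(0L, 0L, 0L, 1L, 0L, 0L, 1L, 1L),
             y = c(1L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))
}
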