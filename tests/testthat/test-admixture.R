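# analytic expectation and variance of the K = 1 marginal log-likelihood
# under the exact Beta posterior (digamma/trigamma closed forms)
k1_estimator_moments <- function(m, lam = c(1, 1)) {
  n1 <- colSums(m$bands == 1L, na.rm = TRUE)
  n0 <- colSums(m$bands == 0L, na.rm = TRUE)
  a <- lam[1] + n1; b <- lam[2] + n0
  E <- sum(n1 * (digamma(a) - digamma(a + b)) +
           n0 * (digamma(b) - digamma(a + b)))
  V <- sum(n1^2 * (trigamma(a) - trigamma(a + b)) +
           n0^2 * (trigamma(b) - trigamma(a + b)) -
           2 * n1 * n0 * trigamma(a + b))
  list(E = E, V = V)
}

test_that("single-cluster fit matches the closed-form posterior moments", {
  set.seed(101)
  sim <- simulate_markers(sim_config(c(A = 12, B = 8), rep(8, 4), F = 0.3,
                                     seed = 101))
  m <- sim$matrix
  fit <- fit_admixture(m, K = 1, burn_in = 200, reps = 4000, seed = 7)
  expect_true(all(abs(fit$Q - 1) < 1e-12))
  mom <- k1_estimator_moments(m)
  # the sampler draws F from the exact posterior at K = 1, so lnL moments
  # have digamma/trigamma closed forms; allow Monte-Carlo error on both
  se_mean <- sqrt(mom$V / 4000)
  se_var <- mom$V * sqrt(2 / 3999)
  expect_lt(abs(fit$lnL_mean - mom$E), 4 * se_mean)
  expect_lt(abs(fit$lnL_var - mom$V), 5 * se_var)
  expect_lt(abs(fit$lnP - (mom$E - mom$V / 2)), 4 * se_mean + 3 * se_var)
  # the evidence summary has a known downward bias relative to the true
  # marginal (higher posterior cumulants); it must stay in its neighbourhood
  expect_lt(abs(fit$lnP - lnP_single_cluster(m)) / abs(lnP_single_cluster(m)),
            0.1)
})

test_that("membership rows sum to one, traces are finite, seeds reproduce bit-for-bit", {
  set.seed(33)
  sim <- simulate_markers(sim_config(c(A = 10, B = 10), rep(10, 2), F = 0.5,
                                     seed = 33))
  f1 <- fit_admixture(sim$matrix, K = 2, burn_in = 50, reps = 200, seed = 5)
  expect_equal(unname(rowSums(f1$Q)), rep(1, 20))
  expect_true(all(is.finite(f1$lnP)))
  expect_true(all(f1$F > 0 & f1$F < 1))
  f2 <- fit_admixture(sim$matrix, K = 2, burn_in = 50, reps = 200, seed = 5)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnP, f2$lnP)
  expect_error(fit_admixture(sim$matrix, K = 50), "exceeds")
})

test_that("duplicated samples receive equal membership up to Monte-Carlo error", {
  set.seed(44)
  sim <- simulate_markers(sim_config(c(A = 8, B = 8), rep(12, 2), F = 0.6,
                                     seed = 44))
  m <- sim$matrix
  dup <- marker_matrix(rbind(m$bands, dup1 = m$bands[1, ], dup2 = m$bands[1, ]),
                       pops = c(m$pops, "A", "A"), primers = m$primers)
  fit <- fit_admixture(dup, K = 2, burn_in = 200, reps = 2000, seed = 11)
  rows <- fit$Q[c(1, 17, 18), ]
  expect_lt(max(abs(rows[1, ] - rows[2, ])), 0.1)
  expect_lt(max(abs(rows[1, ] - rows[3, ])), 0.1)
})

test_that("alpha sampling moves alpha and keeps the fit valid", {
  set.seed(55)
  sim <- simulate_markers(sim_config(c(A = 10, B = 10), rep(10, 2), F = 0.5,
                                     seed = 55))
  fit <- fit_admixture(sim$matrix, K = 2, burn_in = 100, reps = 400, seed = 3,
                       sample_alpha = TRUE)
  expect_true(fit$alpha > 0 && fit$alpha < 10)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 20))
})

test_that("Evanno table matches hand evaluation and flags degenerate cases", {
  lnp <- rbind(c(-1000, -800, -700, -690),
               c(-1002, -798, -702, -688))
  colnames(lnp) <- 1:4
  ev <- evanno(lnp)
  expect_equal(ev$Lprime[2], mean(c(-800, -798)) - mean(c(-1000, -1002)))
  # per-run |L''(3)|: |-800 - 2(-700) + (-690)| = 90, |-798 - 2(-702) + (-688)| = 82
  expect_equal(ev$Lsecond[3], mean(c(90, 82)))
  expect_equal(ev$deltaK[3], 86 / sd(c(-700, -702)))
  expect_true(is.na(ev$deltaK[1]) && is.na(ev$deltaK[4]))

  # linear lnP in K: second differences vanish
  lin <- rbind(-c(100, 90, 80, 70), -c(101, 91, 81, 71) + 0.5)
  colnames(lin) <- 1:4
  expect_equal(evanno(lin)$deltaK[2:3], c(0, 0))

  # zero across-run sd -> warning and NA
  const <- rbind(c(-10, -8, -7), c(-10, -8, -7))
  colnames(const) <- 1:3
  expect_warning(ev0 <- evanno(const), "sd of lnP is 0")
  expect_true(is.na(ev0$deltaK[2]))

  expect_error(evanno(lnp[1, , drop = FALSE]), ">= 2 runs")
  expect_error(evanno(lnp[, c(1, 3, 4)]), "consecutive")
})

test_that("population membership summaries average Q over predefined groups", {
  Q <- rbind(c(0, 1), c(0, 1), c(1, 0), c(0.5, 0.5))
  res <- structure(list(Q = Q), class = "admixture_result")
  pm <- pop_membership(res, c("X", "X", "Y", "Z"))
  expect_equal(unname(pm["X", ]), c(0, 1))
  expect_equal(unname(pm["Y", ]), c(1, 0))
  expect_equal(unname(pm["Z", ]), c(0.5, 0.5))
  # uniform memberships stay uniform
  resu <- structure(list(Q = matrix(1 / 3, 6, 3)), class = "admixture_result")
  expect_true(all(abs(pop_membership(resu, rep(c("X", "Y"), 3)) - 1 / 3) < 1e-12))
  expect_error(pop_membership(res, c("X", "Y")), "one population label")
})
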