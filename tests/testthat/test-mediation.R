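# Two-step / MVMR mediation decomposition and proportion mediated.

test_that("product of coefficients and its delta-method SE", {
  ind <- two_step_indirect(list(beta = 0.5, se = 0.1),
                           list(beta = 0.4, se = 0.05))
  expect_equal(ind$beta, 0.2)
  expect_equal(ind$se, sqrt(0.4^2 * 0.1^2 + 0.5^2 * 0.05^2))

  expect_equal(two_step_indirect(list(beta = 0, se = 0.1),
                                 list(beta = 0.4, se = 0.05))$beta, 0)

  # exact form adds the second-order term
  exact <- two_step_indirect(list(beta = 0.5, se = 0.1),
                             list(beta = 0.4, se = 0.05), exact = TRUE)
  expect_equal(exact$se^2 - ind$se^2, 0.1^2 * 0.05^2)
})

test_that("delta-method SE matches a Monte-Carlo oracle within 5%", {
  set.seed(55)
  prod_draws <- rnorm(1e6, 0.5, 0.1) * rnorm(1e6, 0.4, 0.05)
  ind <- two_step_indirect(list(beta = 0.5, se = 0.1),
                           list(beta = 0.4, se = 0.05))
  expect_lt(abs(ind$se - sd(prod_draws)) / sd(prod_draws), 0.05)
})

test_that("single-exposure MVMR equals univariable IVW and matches the lm
          oracle with multiple exposures", {
  set.seed(61)
  k <- 20
  bx <- rnorm(k, 0.3, 0.1)
  by <- 0.25 * bx + rnorm(k, 0, 0.02)
  sy <- runif(k, 0.01, 0.05)
  uni <- mvmr_ivw(by, sy, matrix(bx, ncol = 1))
  ivw <- mr_ivw(hset(bx, rep(0.01, k), by, sy))$estimate
  expect_equal(uni$estimates$beta, ivw$beta, tolerance = 1e-10)
  expect_equal(uni$estimates$se, ivw$se, tolerance = 1e-10)

  BX <- cbind(e1 = rnorm(k, 0.3, 0.1), e2 = rnorm(k, -0.1, 0.15))
  by2 <- BX %*% c(0.3, -0.2) + rnorm(k, 0, 0.02)
  got <- mvmr_ivw(as.vector(by2), sy, BX)
  want <- oracle_mvmr(as.vector(by2), sy, BX)
  expect_equal(got$estimates$beta, want$beta, tolerance = 1e-10)
  expect_equal(got$estimates$se, want$se, tolerance = 1e-10)

  # collinear exposures are rejected with the offending pair named
  BXc <- cbind(a = bx, b = 2 * bx)
  expect_error(mvmr_ivw(by, sy, BXc), "collinear.*a.*b")
})

test_that("MVMR recovers two orthogonal direct effects within 3 SE", {
  set.seed(67)
  k <- 100
  BX <- cbind(e1 = rnorm(k, 0, 0.1), e2 = rnorm(k, 0, 0.1))
  sy <- rep(0.01, k)
  by <- BX %*% c(0.3, -0.2) + rnorm(k, 0, 0.01)
  SX <- matrix(0.005, k, 2)
  fit <- mvmr_ivw(as.vector(by), sy, BX, SX)
  expect_lt(abs(fit$estimates$beta[1] - 0.3), 3 * fit$estimates$se[1])
  expect_lt(abs(fit$estimates$beta[2] + 0.2), 3 * fit$estimates$se[2])
  expect_true(all(fit$conditional_f > 10))
})

test_that("proportion mediated follows the sign rule", {
  # worked example: indirect -5.65e-5 of total -7.30e-4 is 7.74%
  expect_equal(proportion_mediated(list(beta = -7.30e-4),
                                   list(beta = -5.65e-5)),
               100 * 5.65 / 73.0, tolerance = 1e-10)
  expect_equal(proportion_mediated(list(beta = 1), list(beta = 0)), 0)
  # opposite signs: not interpretable
  p <- proportion_mediated(list(beta = 4.60e-4), list(beta = -4.50e-5))
  expect_true(is.na(p))
  expect_equal(attr(p, "reason"), "inconsistent-sign")
  expect_error(proportion_mediated(list(beta = 0), list(beta = 1)),
               "undefined")
  # > 100% flagged, not truncated
  big <- proportion_mediated(list(beta = 0.1), list(beta = 0.12))
  expect_equal(as.numeric(big), 120)
  expect_equal(attr(big, "flag"), "gt-100")
  # scale invariance
  expect_equal(as.numeric(proportion_mediated(list(beta = -7.3),
                                              list(beta = -0.565))),
               as.numeric(proportion_mediated(list(beta = -7.3e-4),
                                              list(beta = -5.65e-5))))
})

test_that("the worked-example table reproduces: proportions within 0.15 pp
          and the NA pattern exactly", {
  tab <- read.delim(system.file("extdata", "mediation_worked_example.tsv",
                                package = "mrmediate"))
  for (i in seq_len(nrow(tab))) {
    for (cols in list(c("two_step_effect", "two_step_prop"),
                      c("mvmr_effect", "mvmr_prop"))) {
      got <- proportion_mediated(list(beta = tab$total_effect[i]),
                                 list(beta = tab[[cols[1]]][i]))
      want <- tab[[cols[2]]][i]
      if (is.na(want)) {
        expect_true(is.na(got))
        expect_equal(attr(got, "reason"), "inconsistent-sign")
      } else {
        expect_lt(abs(as.numeric(got) - want), 0.15)
      }
    }
  }
})

test_that("mediate recovers a known decomposition on synthetic data", {
  tr <- sim_truth(theta1 = 0.4, theta2 = 0.5, theta3 = 0.1,
                  n_snp_exposure = 50, n_snp_mediator = 30,
                  n_exp = 50000, n_med = 50000, n_out = 50000, seed = 71)
  ds <- simulate_gwas(tr)
  m <- mediate(ds$exposure, ds$mediator, ds$outcome,
               p_threshold_exposure = 1e-5, seed = 1)
  # indirect product CI covers theta1*theta2 = 0.2
  expect_lt(m$indirect_product$ci_low, 0.2)
  expect_gt(m$indirect_product$ci_high, 0.2)
  # proportion mediated near 100 * 0.2 / 0.3
  expect_lt(abs(m$prop_mediated_product - 100 * 0.2 / 0.3), 10)
  expect_equal(m$indirect_product$beta, m$theta1$beta * m$theta2$beta)
  expect_true(all(m$conditional_f > 9))
})

test_that("full-mediation and null-mediator truths behave as expected", {
  # theta3 = 0: both decompositions near 100%
  tr_full <- sim_truth(theta1 = 0.4, theta2 = 0.5, theta3 = 0,
                       n_snp_exposure = 50, n_snp_mediator = 30,
                       n_exp = 50000, n_med = 50000, n_out = 50000,
                       seed = 73)
  ds <- simulate_gwas(tr_full)
  m <- mediate(ds$exposure, ds$mediator, ds$outcome, seed = 1)
  expect_lt(abs(m$prop_mediated_product - 100), 15)
  expect_lt(abs(m$prop_mediated_difference - 100), 25)

  # theta2 = 0: indirect CI covers zero
  tr_null <- sim_truth(theta1 = 0.4, theta2 = 0, theta3 = 0.3,
                       n_snp_exposure = 50, n_snp_mediator = 30,
                       n_exp = 50000, n_med = 50000, n_out = 50000,
                       seed = 79)
  ds2 <- simulate_gwas(tr_null)
  m2 <- mediate(ds2$exposure, ds2$mediator, ds2$outcome, seed = 1)
  expect_lt(m2$indirect_product$ci_low, 0)
  expect_gt(m2$indirect_product$ci_high, 0)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(83)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})
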