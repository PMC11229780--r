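# Univariable estimators: Wald ratio, IVW, maximum likelihood, weighted
# median, MR-Egger, leave-one-out.

test_that("Wald ratio is by/bx with first-order delta SE", {
  est <- wald_ratio(0.5, 0.01, 0.1, 0.02)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "undefined")
})

test_that("Wald-ratio SE agrees with a Monte-Carlo oracle", {
  est <- wald_ratio(0.5, 0.01, 0.1, 0.02)
  set.seed(99)
  draws <- rnorm(1e6, 0.1, 0.02) / rnorm(1e6, 0.5, 0.01)
  expect_lt(abs(est$se - sd(draws)) / sd(draws), 0.05)
})

test_that("IVW degenerates to the Wald ratio for a single SNP and to the
          common ratio under homogeneity", {
  s1 <- hset(0.5, 0.01, 0.1, 0.02)
  one <- mr_ivw(s1)$estimate
  w <- wald_ratio(0.5, 0.01, 0.1, 0.02)
  expect_equal(one$beta, w$beta)
  expect_equal(one$se, w$se)

  bx <- c(0.2, 0.4, 0.5)
  s2 <- hset(bx, rep(0.01, 3), 0.3 * bx, rep(0.02, 3))
  fit <- mr_ivw(s2)
  expect_equal(fit$estimate$beta, 0.3, tolerance = 1e-12)
  expect_equal(fit$heterogeneity$q, 0, tolerance = 1e-20)
  expect_equal(fit$heterogeneity$scale_factor, 1)
})

test_that("IVW and Egger match independent weighted-regression oracles", {
  set.seed(11)
  for (k in c(3, 5, 10)) {
    bx <- rnorm(k, 0.3, 0.1)
    by <- 0.25 * bx + rnorm(k, 0, 0.02)
    sy <- runif(k, 0.01, 0.05)
    s <- hset(bx, rep(0.01, k), by, sy)

    o_ivw <- oracle_ivw(bx, by, sy)
    got <- mr_ivw(s)$estimate
    expect_equal(got$beta, o_ivw$beta, tolerance = 1e-10)
    expect_equal(got$se, o_ivw$se, tolerance = 1e-10)
    expect_equal(mr_ivw(s)$heterogeneity$q, o_ivw$q, tolerance = 1e-10)

    o_eg <- oracle_egger(bx, by, sy)
    eg <- mr_egger(s)
    expect_equal(eg$slope$beta, o_eg$slope, tolerance = 1e-10)
    expect_equal(eg$slope$se, o_eg$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$beta, o_eg$intercept, tolerance = 1e-10)
    expect_equal(eg$intercept$se, o_eg$se_intercept, tolerance = 1e-10)
  }
})

test_that("maximum likelihood approaches IVW as exposure SEs vanish and
          matches a profile-likelihood grid search", {
  set.seed(21)
  k <- 10
  bx <- rnorm(k, 0.3, 0.1)
  by <- 0.3 * bx + rnorm(k, 0, 0.01)
  sy <- runif(k, 0.01, 0.03)
  s_tiny <- hset(bx, rep(1e-8, k), by, sy)
  expect_equal(mr_max_likelihood(s_tiny)$beta, mr_ivw(s_tiny)$estimate$beta,
               tolerance = 1e-6)

  # 3-SNP instance: optimizer maximum equals a fine grid search
  bx3 <- c(0.2, 0.35, 0.5); sx3 <- c(0.02, 0.03, 0.02)
  by3 <- c(0.07, 0.10, 0.16); sy3 <- c(0.02, 0.02, 0.03)
  s3 <- hset(bx3, sx3, by3, sy3)
  nll <- function(beta) {
    g <- (bx3 / sx3^2 + beta * by3 / sy3^2) / (1 / sx3^2 + beta^2 / sy3^2)
    sum((bx3 - g)^2 / sx3^2 + (by3 - beta * g)^2 / sy3^2) / 2
  }
  grid <- seq(-1, 2, by = 1e-4)
  coarse <- grid[which.min(vapply(grid, nll, numeric(1)))]
  fine <- optimize(nll, c(coarse - 1e-3, coarse + 1e-3), tol = 1e-10)$minimum
  expect_equal(mr_max_likelihood(s3)$beta, fine, tolerance = 1e-6)
})

test_that("maximum likelihood recovers a simulated effect", {
  ds <- simulate_gwas(sim_truth(theta1 = 0, theta2 = 0, theta3 = 0.3,
                                n_snp_exposure = 20, n_snp_mediator = 0,
                                n_exp = 50000, n_out = 50000, seed = 5))
  h <- harmonize(ds$exposure, ds$outcome)
  est <- mr_max_likelihood(h)
  expect_lt(abs(est$beta - 0.3), 3 * est$se)
})

test_that("weighted median reduces to the plain median under equal weights
          and resists a minority outlier", {
  s <- hset(c(1, 1, 1), rep(1e-12, 3), c(0.1, 0.2, 0.3), rep(0.05, 3))
  expect_equal(mr_weighted_median(s, seed = 1)$beta, 0.2, tolerance = 1e-9)

  # outlier with < 25% of total weight barely moves the estimate
  s_out <- hset(c(1, 1, 1, 1), rep(1e-12, 4), c(0.1, 0.2, 0.3, 100),
                c(0.05, 0.05, 0.05, 0.12))
  clean <- mr_weighted_median(s, seed = 1)$beta
  robust <- mr_weighted_median(s_out, seed = 1)$beta
  expect_lt(abs(robust - clean), 0.06)
})

test_that("weighted-median interpolation matches a hand calculation", {
  # 4 ratios with unequal weights; cumulative-weight interpolation by hand
  ratio <- c(0.10, 0.20, 0.30, 0.40)
  w <- c(1, 2, 3, 4)
  sy <- 1 / sqrt(w)
  s <- hset(rep(1, 4), rep(1e-12, 4), ratio, sy)
  cw <- cumsum(w / sum(w)) - (w / sum(w)) / 2
  hand <- approx(cw, ratio, xout = 0.5)$y
  expect_equal(mr_weighted_median(s, seed = 1)$beta, hand, tolerance = 1e-9)
})

test_that("Egger finds a zero intercept on clean data and recovers
          directional pleiotropy", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  s <- hset(bx, rep(0.01, 4), 0.5 * bx, rep(0.02, 4))
  eg <- suppressWarnings(mr_egger(s))   # lm warns on the exact fit
  expect_lt(abs(eg$intercept$beta), 1e-12)
  expect_equal(eg$slope$beta, 0.5, tolerance = 1e-10)

  set.seed(31)
  k <- 50
  bx <- runif(k, 0.05, 0.3)
  sy <- rep(0.01, k)
  by_clean <- 0.3 * bx + rnorm(k, 0, 0.01)
  delta <- 0.05
  s_clean <- hset(bx, rep(0.005, k), by_clean, sy)
  s_pleio <- hset(bx, rep(0.005, k), by_clean + delta, sy)
  eg_c <- mr_egger(s_clean)
  eg_p <- mr_egger(s_pleio)
  # a constant shift moves only the intercept
  expect_equal(eg_p$intercept$beta - eg_c$intercept$beta, delta,
               tolerance = 1e-10)
  expect_equal(eg_p$slope$beta, eg_c$slope$beta, tolerance = 1e-10)
  expect_lt(abs(eg_p$intercept$beta - delta), 3 * eg_p$intercept$se)
})

test_that("leave-one-out is constant under homogeneity and isolates a gross
          outlier", {
  bx <- c(0.2, 0.3, 0.4, 0.5)
  s <- hset(bx, rep(0.01, 4), 0.3 * bx, rep(0.02, 4))
  loo <- mr_leave_one_out(s)
  expect_equal(nrow(loo), 4)
  expect_true(all(abs(loo$beta - 0.3) < 1e-12))

  s_out <- s
  s_out$records$beta_outcome[2] <- 1        # gross outlier
  full <- mr_ivw(s_out)$estimate$beta
  loo2 <- mr_leave_one_out(s_out)
  shifts <- abs(loo2$beta - full)
  expect_equal(which.max(shifts), 2L)
  expect_gt(max(shifts), sort(shifts, decreasing = TRUE)[2])
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(41)
  k <- 8
  bx <- rnorm(k, 0.3, 0.1)
  by <- 0.25 * bx + rnorm(k, 0, 0.01)
  sx <- rep(0.01, k); sy <- runif(k, 0.01, 0.03)
  s <- hset(bx, sx, by, sy)
  cc <- 3.7
  s_scaled <- hset(bx, sx, cc * by, cc * sy)
  s_negx <- hset(-bx, sx, by, sy)

  for (f in list(function(x) mr_ivw(x)$estimate,
                 mr_max_likelihood,
                 function(x) mr_egger(x)$slope,
                 function(x) mr_weighted_median(x, seed = 2))) {
    base <- f(s); scaled <- f(s_scaled); neg <- f(s_negx)
    expect_equal(scaled$beta, cc * base$beta, tolerance = 1e-6)
    expect_equal(scaled$se, cc * base$se, tolerance = 1e-6)
    expect_equal(neg$beta, -base$beta, tolerance = 1e-6)
  }
})

test_that("IVW recovers the true effect without bias on synthetic data", {
  reps <- 200
  est <- vapply(seq_len(reps), function(i) {
    ds <- simulate_gwas(sim_truth(theta1 = 0, theta2 = 0, theta3 = 0.3,
                                  n_snp_exposure = 50, n_snp_mediator = 0,
                                  n_exp = 50000, n_out = 50000,
                                  seed = 1000 + i))
    mr_ivw(harmonize(ds$exposure, ds$outcome))$estimate$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.01)
})
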