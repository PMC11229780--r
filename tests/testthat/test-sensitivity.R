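# MR-PRESSO, Steiger directionality, colocalization.

clean_set <- function(seed = 5, k = 21, n = 50000) {
  ds <- simulate_gwas(sim_truth(theta1 = 0, theta2 = 0, theta3 = 0.3,
                                n_snp_exposure = k, n_snp_mediator = 0,
                                n_exp = n, n_out = n, seed = seed))
  list(ds = ds, h = harmonize(ds$exposure, ds$outcome))
}

test_that("MR-PRESSO flags nothing on clean data and is deterministic", {
  h <- clean_set()$h
  pr <- mr_presso(h, n_sim = 300, seed = 7)
  expect_length(pr$outliers, 0)
  expect_equal(pr$corrected$beta, mr_ivw(h)$estimate$beta)
  expect_gte(pr$global_p, 1 / 301)

  pr2 <- mr_presso(h, n_sim = 300, seed = 7)
  expect_identical(pr, pr2)
})

test_that("MR-PRESSO uniquely flags an injected 10-SE outlier and the
          corrected estimate is closer to truth", {
  cs <- clean_set(seed = 201)
  ds <- inject_outlier(cs$ds, snp_index = 3, shift_in_se = 10)
  h <- harmonize(ds$exposure, ds$outcome)
  pr <- mr_presso(h, n_sim = 500, seed = 11)
  expect_equal(pr$outliers, ds$outcome$snp_id[3])
  full <- mr_ivw(h)$estimate$beta
  expect_lt(abs(pr$corrected$beta - 0.3), abs(full - 0.3))
  expect_false(is.na(pr$distortion_p))

  # sign-agnostic: a -10 SE shift is flagged just the same
  ds_neg <- inject_outlier(cs$ds, snp_index = 3, shift_in_se = -10)
  pr_neg <- mr_presso(harmonize(ds_neg$exposure, ds_neg$outcome),
                      n_sim = 500, seed = 11)
  expect_equal(pr_neg$outliers, ds$outcome$snp_id[3])
})

test_that("MR-PRESSO global p decreases as the outlier grows", {
  cs <- clean_set(seed = 13)
  p_at <- vapply(c(2, 6, 12), function(shift) {
    ds <- inject_outlier(cs$ds, snp_index = 5, shift_in_se = shift)
    mr_presso(harmonize(ds$exposure, ds$outcome),
              n_sim = 400, seed = 17)$global_p
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("inject_outlier with shift 0 is a no-op", {
  cs <- clean_set(seed = 15)
  ds0 <- inject_outlier(cs$ds, snp_index = 2, shift_in_se = 0)
  expect_equal(ds0$outcome$beta, cs$ds$outcome$beta)
})

test_that("Steiger direction follows the variance-explained ordering", {
  # strong exposure instruments, negligible outcome signal
  k <- 10
  n <- 8000
  bx <- rep(0.08, k); sx <- rep(1 / sqrt(n), k) # r2 ~ 0.05 summed
  by <- rep(0.002, k); sy <- rep(1 / sqrt(n), k)
  s <- hset(bx, sx, by, sy, n_exposure = n, n_outcome = n)
  st <- steiger(s)
  expect_equal(st$direction, "forward")
  expect_lt(st$pvalue, 1e-6)
  expect_gt(st$r2_exposure, st$r2_outcome)

  # closed-form z for this configuration
  r2x <- sum((bx / sx)^2 / ((bx / sx)^2 + n - 2))
  r2y <- sum((by / sy)^2 / ((by / sy)^2 + n - 2))
  z_hand <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) / sqrt(2 / (n - 3))
  expect_equal(st$z, z_hand, tolerance = 1e-12)

  # swapping the two traits flips the direction and negates z
  s_rev <- hset(by, sy, bx, sx, n_exposure = n, n_outcome = n)
  st_rev <- steiger(s_rev)
  expect_equal(st_rev$direction, "reverse")
  expect_equal(st_rev$z, -st$z)

  # identical traits: tie -> forward, p = 1, inconclusive
  s_tie <- hset(bx, sx, bx, sx, n_exposure = n, n_outcome = n)
  st_tie <- steiger(s_tie)
  expect_equal(st_tie$direction, "forward")
  expect_equal(st_tie$pvalue, 1)
  expect_true(st_tie$inconclusive)
})

test_that("Steiger direction is invariant to joint rescaling", {
  s <- hset(c(0.1, 0.2), c(0.01, 0.01), c(0.02, 0.03), c(0.01, 0.01),
            n_exposure = 9000, n_outcome = 9000)
  st1 <- steiger(s)
  s2 <- hset(c(0.1, 0.2) * 10, c(0.01, 0.01) * 10,
             c(0.02, 0.03) * 10, c(0.01, 0.01) * 10,
             n_exposure = 9000, n_outcome = 9000)
  expect_equal(steiger(s2)$direction, st1$direction)
  expect_equal(steiger(s2)$z, st1$z, tolerance = 1e-12)
})

test_that("coloc: no association favors H0; a strong shared variant gives
          PP.H4 above the 0.8 gate; PPs always sum to 1", {
  k <- 20
  t_null <- make_sumstats_df(k)
  t_null$beta <- 0; t_null$se <- 1
  t_null <- sumstats(t_null)
  cl0 <- coloc_abf(t_null, t_null)
  expect_gt(cl0$pp["H0"], 0.99)

  rp <- region_pair(z_shared = 16)
  cl4 <- coloc_abf(rp$t1, rp$t2)
  expect_gt(cl4$pp["H4"], 0.8)

  for (seed in 1:5) {
    set.seed(seed)
    ta <- make_sumstats_df(20); ta$beta <- rnorm(20, 0, 0.1)
    tb <- make_sumstats_df(20); tb$beta <- rnorm(20, 0, 0.1)
    pp <- coloc_abf(sumstats(ta), sumstats(tb))$pp
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    expect_true(all(pp >= 0 & pp <= 1))
  }
})

test_that("coloc posterior mass moves from H0 to H4 as the shared |z| grows", {
  h4 <- vapply(c(2, 6, 15), function(z)
    unname(coloc_abf(region_pair(z)$t1, region_pair(z)$t2)$pp["H4"]),
    numeric(1))
  expect_true(all(diff(h4) > 0))
  h0 <- vapply(c(2, 6, 15), function(z)
    unname(coloc_abf(region_pair(z)$t1, region_pair(z)$t2)$pp["H0"]),
    numeric(1))
  expect_true(all(diff(h0) < 0))
})
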