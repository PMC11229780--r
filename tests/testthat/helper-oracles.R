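# Independent oracles and small fixture builders used across test files.
# Oracles deliberately use a different computational route than the package
# (lm vs hand-coded normal equations, and vice versa).

# harmonized set straight from aligned effect vectors
hset <- function(bx, sx, by, sy, ...) {
  mrmediate:::harmonized_set(bx, sx, by, sy, ...)
}

# IVW oracle: weighted regression through the origin via stats::lm
oracle_ivw <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx - 1, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  se_fe <- s$coefficients[1, "Std. Error"] / sigma
  q <- sum(w * stats::residuals(fit)^2)
  k <- length(bx)
  list(beta = unname(stats::coef(fit)[1]),
       se = se_fe * max(1, sqrt(q / (k - 1))),
       q = q)
}

# Egger oracle: two-parameter weighted regression by explicit normal
# equations (the package path uses lm)
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  bx <- bx * flip; by <- by * flip
  W <- diag(1 / sy^2)
  X <- cbind(1, bx)
  xtwx <- t(X) %*% W %*% X
  beta <- solve(xtwx, t(X) %*% W %*% by)[, 1]
  resid <- by - X %*% beta
  k <- length(bx)
  sigma2 <- sum(resid^2 / sy^2) / (k - 2)
  se <- sqrt(diag(solve(xtwx))) * sqrt(max(1, sigma2))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]))
}

# multivariable IVW oracle via stats::lm with weights
oracle_mvmr <- function(by, sy, BX) {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ BX - 1, weights = w)
  s <- summary(fit)
  sigma <- s$sigma
  k <- length(by); p <- ncol(BX)
  q <- sum(w * stats::residuals(fit)^2)
  infl <- max(1, sqrt(q / (k - p)))
  list(beta = unname(stats::coef(fit)),
       se = unname(s$coefficients[, "Std. Error"]) / sigma * infl)
}

# step-by-step greedy clumping oracle: literal transcription of the
# definition, quadratic and index-based
oracle_clump <- function(records, r2mat, r2_threshold, window_kb) {
  remaining <- seq_len(nrow(records))
  accepted <- integer(0)
  while (length(remaining) > 0) {
    p <- records$pvalue[remaining]
    ids <- records$snp_id[remaining]
    best <- remaining[order(p, ids)][1]
    accepted <- c(accepted, best)
    remaining <- setdiff(remaining, best)
    kill <- c()
    for (j in remaining) {
      if (records$chrom[j] != records$chrom[best]) next
      if (abs(records$pos[j] - records$pos[best]) > window_kb * 1000) next
      if (r2mat[records$snp_id[best], records$snp_id[j]] >= r2_threshold)
        kill <- c(kill, j)
    }
    remaining <- setdiff(remaining, kill)
  }
  sort(records$snp_id[accepted])
}

# minimal well-formed sumstats data.frame
make_sumstats_df <- function(n = 3, beta = 0.1, se = 0.02, pvalue = 1e-9,
                             eaf = 0.25, ea = "A", oa = "G", nsamp = 10000) {
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1e6,
    effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
    eaf = rep_len(eaf, n), beta = rep_len(beta, n), se = rep_len(se, n),
    pvalue = rep_len(pvalue, n), n = rep_len(nsamp, n),
    stringsAsFactors = FALSE)
}

# quiet validation notes in tests
options(mrmediate.quiet = TRUE)

# shared-causal-variant region builder for colocalization tests
region_pair <- function(z_shared, k = 50, seed = 23) {
  # one shared causal SNP with |z| = z_shared in both traits, others null
  withr::with_seed(seed, {
    se <- rep(0.02, k)
    b1 <- rnorm(k, 0, 0.02 * 0.5)
    b2 <- rnorm(k, 0, 0.02 * 0.5)
    b1[1] <- z_shared * se[1]
    b2[1] <- z_shared * se[1]
    t1 <- make_sumstats_df(k)
    t1$beta <- b1; t1$se <- se
    t2 <- make_sumstats_df(k)
    t2$beta <- b2; t2$se <- se
    list(t1 = sumstats(t1), t2 = sumstats(t2))
  })
}

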