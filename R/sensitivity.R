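# Sensitivity suite: MR-PRESSO outlier machinery, Steiger directionality,
# and approximate-Bayes-factor colocalization.

# leave-one-out IVW predictions: fitted outcome effect for SNP j from the
# IVW slope estimated without SNP j
loo_predictions <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  beta_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  beta_loo * bx
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy through the residual sum of squares (RSS)
#' of outcome effects around leave-one-out IVW predictions, compared against
#' a parametric null: exposure and outcome effects are resampled from
#' normals centered on the fitted no-pleiotropy model with the observed SEs.
#' Per-SNP squared residuals are compared to their own simulated
#' distributions and Bonferroni-adjusted over SNPs; flagged outliers
#' (adjusted p below `sig`) are removed and the IVW estimate recomputed. A
#' distortion test resamples random subsets of the same size to ask whether
#' removing the flagged SNPs shifts the estimate more than removing random
#' ones. Empirical p-values carry the +1 correction, so the global p is
#' bounded below by 1/(n_sim + 1). Fully deterministic given `seed`.
#'
#' @param set `harmonized_set` with at least 4 SNPs.
#' @param n_sim resampling replicates (default 1000).
#' @param seed integer seed (required).
#' @param sig outlier significance threshold on the Bonferroni-adjusted
#'   per-SNP p (default 0.05).
#' @return object of class `presso_result`: `rss_obs`, `global_p`,
#'   `outlier_p` (named, adjusted), `outliers`, `distortion_p`, `corrected`
#'   (`mr_estimate` after outlier removal; equals the full IVW when nothing
#'   is flagged).
#' @export
mr_presso <- function(set, n_sim = 1000, seed, sig = 0.05) {
  d <- unpack(set)
  k <- length(d$beta_exposure)
  if (k < 4) stop("insufficient instruments: MR-PRESSO needs >= 4 SNPs")
  if (missing(seed)) stop("seed is required for MR-PRESSO resampling")
  snp_ids <- set$records$snp_id

  obs_pred <- loo_predictions(d$beta_exposure, d$beta_outcome, d$se_outcome)
  obs_res2 <- (d$beta_outcome - obs_pred)^2
  rss_obs <- sum(obs_res2)

  full_ivw <- mr_ivw(set)$estimate

  # resample around the leave-one-out predictions: each SNP's simulated
  # expectation excludes its own (possibly pleiotropic) contribution, so an
  # outlier cannot mask itself
  sims <- withr::with_seed(seed, {
    lapply(seq_len(n_sim), function(i) {
      bx_s <- stats::rnorm(k, d$beta_exposure, d$se_exposure)
      by_s <- stats::rnorm(k, obs_pred, d$se_outcome)
      res2 <- (by_s - loo_predictions(bx_s, by_s, d$se_outcome))^2
      res2
    })
  })
  sim_res2 <- do.call(rbind, sims)            # n_sim x k
  sim_rss <- rowSums(sim_res2)
  global_p <- (1 + sum(sim_rss >= rss_obs)) / (n_sim + 1)

  per_snp_p <- vapply(seq_len(k), function(j) {
    (1 + sum(sim_res2[, j] >= obs_res2[j])) / (n_sim + 1)
  }, numeric(1))
  outlier_p <- pmin(1, per_snp_p * k)          # Bonferroni over SNPs
  names(outlier_p) <- snp_ids
  outliers <- snp_ids[outlier_p < sig]

  if (length(outliers) == k)
    stop("degenerate correction: every SNP flagged as an outlier")

  if (length(outliers) > 0) {
    keep <- !(snp_ids %in% outliers)
    sub <- set
    sub$records <- set$records[keep, , drop = FALSE]
    corrected <- mr_ivw(sub)$estimate
    d_obs <- corrected$beta - full_ivw$beta
    # distortion null: shift in the estimate from removing random subsets of
    # the same size
    d_null <- withr::with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(k, length(outliers))
        sub_i <- set
        sub_i$records <- set$records[-drop_idx, , drop = FALSE]
        mr_ivw(sub_i)$estimate$beta - full_ivw$beta
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  } else {
    corrected <- full_ivw
    distortion_p <- NA_real_
  }

  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 distortion_p = distortion_p, corrected = corrected,
                 n_sim = n_sim),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g, %d outlier(s)%s\n",
              x$rss_obs, x$global_p, length(x$outliers),
              if (length(x$outliers)) paste0(" [",
                paste(x$outliers, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome. Per-SNP variance explained is r_j^2 = t_j^2 / (t_j^2 + n - 2)
#' with t_j = beta_j / se_j, summed over instruments (clipped below 1 with a
#' warning). The z statistic is the difference of Fisher-transformed
#' sqrt(r^2) values scaled by the sampling variances 1/(n-3); a positive z
#' (more variance explained in the exposure) supports the assumed
#' exposure-to-outcome ("forward") direction.
#'
#' @param set `harmonized_set`.
#' @param n_exposure,n_outcome GWAS sample sizes (default from the set's
#'   records).
#' @return object of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `z`, `pvalue`, `direction` ("forward"/"reverse"), `inconclusive`
#'   (TRUE on an exact tie, reported as forward with p = 1).
#' @export
steiger <- function(set, n_exposure = NULL, n_outcome = NULL) {
  d <- unpack(set)
  if (is.null(n_exposure)) n_exposure <- stats::median(set$records$n_exposure)
  if (is.null(n_outcome)) n_outcome <- stats::median(set$records$n_outcome)
  if (is.na(n_exposure) || is.na(n_outcome) ||
      n_exposure < 10 || n_outcome < 10)
    stop("steiger needs sample sizes >= 10 for both traits")

  sum_r2 <- function(beta, se, n) {
    t2 <- (beta / se)^2
    r2 <- sum(t2 / (t2 + n - 2))
    if (r2 >= 1) {
      warning("summed r2 >= 1; clipped")
      r2 <- 1 - 1e-12
    }
    r2
  }
  r2x <- sum_r2(d$beta_exposure, d$se_exposure, n_exposure)
  r2y <- sum_r2(d$beta_outcome, d$se_outcome, n_outcome)

  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  p <- 2 * stats::pnorm(-abs(z))
  inconclusive <- r2x == r2y
  direction <- if (r2x >= r2y) "forward" else "reverse"
  structure(list(r2_exposure = r2x, r2_outcome = r2y, z = z,
                 pvalue = if (inconclusive) 1 else p,
                 direction = direction, inconclusive = inconclusive),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger: r2(exposure) = %.3g, r2(outcome) = %.3g, z = %.3g, p = %.3g -> %s%s\n",
              x$r2_exposure, x$r2_outcome, x$z, x$pvalue, x$direction,
              if (x$inconclusive) " (inconclusive)" else ""))
  invisible(x)
}

# Wakefield log approximate Bayes factor per SNP
wakefield_labf <- function(beta, se, sd_prior) {
  z2 <- (beta / se)^2
  v <- se^2
  r <- sd_prior^2 / (sd_prior^2 + v)
  0.5 * (log(1 - r) + r * z2)
}

#' Colocalization by approximate Bayes factors
#'
#' Single-causal-variant colocalization of two traits over a shared region.
#' Per-SNP Wakefield approximate Bayes factors are computed from each
#' trait's (beta, se) with a normal prior on the true effect (SD
#' `sd_prior1`/`sd_prior2`; the conventional defaults are 0.15 for a
#' quantitative trait and 0.2 for a binary one), then summed over the five
#' causal configurations: H0 no association, H1/H2 one trait only, H3 two
#' distinct variants, H4 one shared variant. Posterior probabilities are
#' normalized to 1. PP.H4 above 0.8 is the usual gate for a shared variant.
#'
#' @param trait1,trait2 `sumstats` tables over the region (intersected on
#'   `snp_id`; fewer than 10 shared SNPs triggers a warning).
#' @param priors numeric vector `c(p1, p2, p12)`: prior probabilities that a
#'   SNP is causal for trait 1 only, trait 2 only, or both (defaults
#'   1e-4, 1e-4, 1e-5).
#' @param sd_prior1,sd_prior2 prior effect SDs (defaults 0.15 quantitative).
#' @return object of class `coloc_result`: `pp` (named vector H0..H4 summing
#'   to 1), `n_snps_region`, `priors`.
#' @export
coloc_abf <- function(trait1, trait2, priors = c(1e-4, 1e-4, 1e-5),
                      sd_prior1 = 0.15, sd_prior2 = 0.15) {
  shared <- intersect(trait1$snp_id, trait2$snp_id)
  if (length(shared) == 0) stop("no shared SNPs between traits")
  if (length(shared) < 10)
    warning("fewer than 10 shared SNPs in region; coloc may be unstable")
  t1 <- trait1[match(shared, trait1$snp_id), ]
  t2 <- trait2[match(shared, trait2$snp_id), ]

  l1 <- wakefield_labf(t1$beta, t1$se, sd_prior1)
  l2 <- wakefield_labf(t2$beta, t2$se, sd_prior2)
  p1 <- priors[1]; p2 <- priors[2]; p12 <- priors[3]

  ls1 <- logsumexp(l1)                      # sum_i ABF1_i
  ls2 <- logsumexp(l2)                      # sum_j ABF2_j
  ls12 <- logsumexp(l1 + l2)                # sum_i ABF1_i ABF2_i
  # sum over i != j of ABF1_i ABF2_j = S1*S2 - S12, in log space
  lh3_sum <- ls1 + ls2 +
    log1p(-exp(pmin(ls12 - ls1 - ls2, 0)))
  if (!is.finite(lh3_sum)) lh3_sum <- -Inf   # k = 1 region: H3 impossible

  lh <- c(H0 = 0,
          H1 = log(p1) + ls1,
          H2 = log(p2) + ls2,
          H3 = log(p1) + log(p2) + lh3_sum,
          H4 = log(p12) + ls12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_snps_region = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization posterior probabilities (", x$n_snps_region,
      " SNPs):\n", sep = "")
  print(round(x$pp, 4))
  invisible(x)
}
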